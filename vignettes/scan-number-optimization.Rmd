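---
title: "Choosing the FTIR scan number with the moment distance index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing the FTIR scan number with the moment distance index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scanstab)
```

## The problem

An FTIR spectrometer stores, as one spectrum, the average of `N`
interferometer sweeps ("scans"). More scans mean less noise — ideally the
standard deviation of the stored signal shrinks as `1/sqrt(N)` — but also
more instrument time per sample. In soil spectroscopy, where libraries of
thousands of specimens are acquired and then used to calibrate predictive
models for soil properties, the scan number is usually set by habit or by the
vendor's default. `scanstab` implements a quantitative way to choose it: a
scalar curve-shape statistic whose replicate-to-replicate variation measures
acquisition stability, an experiment design that maps that variation against
the scan setting, and a partial-least-squares calibration experiment that
shows how the setting propagates into prediction quality for five routine
soil properties (pH, total organic carbon, total nitrogen, cation exchange
capacity, Olsen phosphorus).

## The moment distance index

For a spectrum with intensities $\rho_p$ over the channels $p = 0, \dots, W$
of a selected window, and pivots at the two window ends, the moment distances
are

$$
MD_{LP} = \sum_{p=0}^{W} \sqrt{\rho_p^2 + d_p^2}, \qquad
MD_{RP} = \sum_{p=0}^{W} \sqrt{\rho_p^2 + (W - d_p)^2},
$$

where $d_p$ is the offset of channel $p$ from the left pivot, and the moment
distance index is their difference $MDI = MD_{RP} - MD_{LP}$. Each term is
the Euclidean distance from a pivot to the point $(d_p, \rho_p)$, so the
index weighs intensity near each end of the window differently and responds
to where the curve carries its mass: it is exactly zero for any constant
spectrum, and mirror-reversing the curve negates it. Identical acquisitions
have identical MDI; how far the MDIs of nominally identical replicates
disagree is therefore a one-number summary of acquisition stability.

Two conventions are deliberately exposed rather than fixed:

* **Offset units** (`x_unit`). The source formulation counts channels
  ("band numbers"), so the default measures $d_p$ in channel index units
  (0..W), which makes the statistic independent of the axis scale; offsets
  in wavenumber units are available as `x_unit = "axis_value"`.
* **Pivot orientation.** The canonical axis here is ascending wavenumber and
  the "left" pivot is the low-wavenumber end. Formulations written against
  wavelength mirror this choice. The orientation only negates every MDI in a
  group, which maps the standardized index to `1 - SMDI` and leaves every
  spread statistic unchanged, so no stability conclusion can depend on it
  (this is tested as a package invariant).

Raw MDI values are offset by the large, geometry-dominated sums, so they are
min–max standardized to the **SMDI** within groups — by default all
acquisitions of one sample, across every setting and replicate:

$$ SMDI = \frac{MDI - \min(MDI)}{\max(MDI) - \min(MDI)} \in [0, 1]. $$

Individual SMDI values carry no meaning; the stability signal is the
**spread** (max − min, with the standard deviation reported alongside) of
the replicate SMDIs at one scan setting. Groups in which all MDIs coincide
are refused with an error rather than mapped to a constant: a silent
constant would fake perfect stability.

## The two experiment designs

* **Stability design**: 12 samples (4 sandy, 4 clay, 4 organic soils), every
  scan setting in {10, 20, ..., 100}, 5 replicates each — 50 acquisitions
  per sample, 600 in total, on a 600–4000 cm⁻¹ grid at 4 cm⁻¹ resolution
  (851 channels). Plotting replicate SMDI against the setting produces a
  lying funnel that narrows as `N` grows.
* **Calibration design**: 40 samples spanning the property ranges, acquired
  once at each setting in {10, 20, 40, 60, 80}, with the five properties
  measured once per sample. Each (property, setting) cell gets its own
  first-difference + PLS1 calibration assessed by leave-one-out
  cross-validation.

The recommendation rule makes the visual "funnel has closed" judgement
explicit: the smallest tested `N` whose pooled spread — the median across
samples, robust to a single bad acquisition session — stays at or below a
threshold `tau` for every larger tested setting (`sustained = TRUE`; an
isolated lucky dip does not qualify). The default `tau = 0.05` SMDI units
sits between the spread scale of the unstable low-scan regime and that of a
converged setting under the generator defaults below. `tau` is a parameter,
not a constant of nature: labs with tighter repeatability requirements
should lower it.

## What the synthetic generator emulates

No public FTIR replicate dataset covers this design, so the package ships a
generator whose defaults *are* the study conditions; the experiments run on
synthetic acquisitions with the statistical structure the analysis assumes.

* **True spectra** are a fixed gentle quadratic baseline plus Gaussian bands
  placed at standard soil band-assignment positions (clay O–H 3695/3620 and
  Al–OH 3550 cm⁻¹, Si–O 1030/915; quartz 1080 and the 798/779 doublet;
  carbonate 2513/1430/875/712; organic C–H 2920/2850, C=O 1720, C=C 1630,
  broad O–H 3400), scaled linearly by per-sample component concentrations.
  Soil type sets which component dominates.
* **Acquisition noise** has three parts: white per-channel noise with sd
  `sigma0 * N^-gamma` (`sigma0 = 0.02`, `gamma = 0.5`, the ideal averaging
  law); a per-acquisition smooth random cubic drift with sd
  `drift_sd * N^-gamma` (`drift_sd = 0.008`), giving correlated error that
  moves curve shape rather than individual channels; and a **session drift**
  (`session_sd = 0.022`), one smooth random curve shared by all replicates
  of a (sample, setting) session and independent of `N`.

The session term deserves its justification. Replicate noise scaling as
`N^-gamma` is what makes the funnel close; but if replicate noise were the
*only* source of MDI variation, the per-sample min–max standardization would
pin the 10-scan replicates across nearly the whole [0, 1] range, and the
spread ratio between two settings would be locked to
`sqrt(N2/N1)` — the funnel could never reach a small absolute spread at 100
scans. Observed funnels do reach small spreads, which implies a systematic
MDI separation *between* settings that does not shrink with `N`: exactly
what slow instrument-state drift between acquisition sessions produces. The
generator models it as such. The magnitudes were chosen once so that the
10-scan setting visibly dominates each sample's SMDI range while the
100-scan replicates nearly coincide (pooled spreads ≈ 0.11 at 10 scans,
≈ 0.03 at 100); they are emulation parameters, documented as such, not
measured instrument truths.

* **Properties** are linear in the component concentrations with per-property
  measurement noise, kept inside plausible ranges (pH 4.5–8.5, TOC 0.2–8 %,
  TN from TOC via a per-sample C:N ratio in 8–15, CEC 2–45 cmol(+)/kg,
  Olsen P 2–60 mg/kg). Olsen P is linked with the weakest signal-to-noise of
  the five, so it is the hardest property to calibrate — its cross-validated
  R² plateaus near 0.7 where TOC approaches 0.99.
* **Determinism.** Every random draw comes from a substream keyed by the
  master seed and the acquisition identity (sample, setting, replicate), so
  datasets are bit-reproducible and any subset is reproducible on its own.
  A `cold_start` option inflates the noise of the very first acquisition to
  emulate an instrument that has not finished warming up; the
  reproducibility summary flags such sessions when their spread exceeds
  three times their soil-type median.

What passing tests on this generator do **not** show: that any particular
real instrument follows the `1/sqrt(N)` law exactly (detector nonlinearity,
atmospheric lines and deviations from ideal averaging are not modelled),
that real soil spectra are sums of Gaussians, or that the absolute spread
values transfer to other hardware. What they do show is that the machinery —
index, standardization, spread statistics, recommendation rule, calibration
trends — behaves correctly on data with the assumed structure, and that the
qualitative conclusions (funnel convergence; prediction quality improving
with `N`) follow from the noise law alone.

## Chemometrics choices

* **Preprocessing** is the plain first difference along the ascending axis
  (`p` channels to `p − 1` features), the simplest derivative filter; it
  removes additive offsets exactly (tested) and attenuates the smooth drift.
  Fuller derivative filters with smoothing windows are out of scope.
* **PLS1 by NIPALS** after mean-centering both blocks, with no variance
  scaling of channels (the spectroscopic convention; the derivative already
  equalizes scales). For a single response the weight step is closed-form,
  so fits are deterministic. The implementation is validated three ways:
  against a closed-form least-squares oracle at full rank, against an
  independent PLS implementation, and by analytic identities (centering,
  monotone training fit).
* **Validation** is leave-one-out cross-validation with the held-out sample
  excluded from centering and fitting (a leakage probe in the test suite
  verifies this). The component count is chosen per cell as the minimizer of
  RMSECV over 1..10 components, ties to fewer; whether the original
  instrument software optimized per setting or fixed the count globally is
  unknown, so the cap is a parameter. Reported figures of merit are
  `RMSECV = sqrt(mean((y - yhat_cv)^2))` and the coefficient of
  determination `R² = 1 − PRESS/TSS` of the cross-validated predictions,
  with the squared Pearson correlation stored alongside (the two coincide
  for well-calibrated models; "R²" in instrument-software reports is
  ambiguous between them).
* **Outliers** are never removed automatically; cross-validation residuals
  beyond 3·RMSECV are flagged in the per-sample prediction table and left in
  every computation.

## Numerical notes

* With index offsets over the full 851-channel window the moment-distance
  sums are ~3.6·10⁵ while their difference is order 10⁻². MDI is therefore
  computed in double precision from the two sums, and floating-point
  agreement between implementations must be judged relative to the sums, not
  the difference. The flat-spectrum identity still holds to 1e-12 absolute
  because the two offset multisets are exactly equal.
* Windowing is by closed interval on wavenumber values, so window configs
  are resolution-independent; windows with fewer than two channels, and
  degenerate standardization groups, raise errors rather than sentinel
  values.
* CSV writers emit 17 significant digits, which round-trips doubles exactly;
  rerunning any experiment with the same config and seed reproduces every
  tabular output byte-for-byte.

## Problem sizes

The test suite and the acceptance script regenerate everything from code.
The stability design (600 acquisitions × 851 channels) takes about two
seconds to generate and index; the calibration experiment (25 PLS-LOOCV
cells at 40 samples, 850 derivative features, up to 10 components) about
four seconds. Monte-Carlo checks use 100 seeds for the funnel contrast,
50 seeds for the calibration trends and 200 replicates for the noise-law
slope.

## Known limitations

* Gaussian line shapes only; no Kubelka–Munk or radiative-transfer physics,
  no atmospheric/CO₂ features, no detector nonlinearity.
* The session-drift hypothesis reproduces the observed funnel scale but is
  one of several mechanisms that could; the generator makes it explorable
  (`session_sd = 0` removes it), it claims no ground truth.
* JCAMP-DX import covers only uncompressed single-block `(X++(Y..Y))` files.
* The recommendation rule compares pooled medians to a fixed threshold; it
  does not perform a formal test of variance equality across settings.
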