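#' Default mid-infrared wavenumber grid
#'
#' 600 to 4000 cm^-1 at 4 cm^-1 resolution (851 channels), the acquisition
#' range and step of a typical bench-top FTIR soil protocol.
#'
#' @return ascending numeric vector of wavenumbers (cm^-1)
#' @export
default_grid <- function() seq(600, 4000, by = 4)

#' Default peak library for soil-like FTIR spectra
#'
#' Gaussian bands for four soil components -- clay minerals, organic matter,
#' carbonate and quartz -- placed at positions standard band-assignment tables
#' give for soils: clay O-H stretching around 3600-3700 cm^-1 and Al-OH near
#' 3550 cm^-1, Si-O fingerprint bands near 1030 and 915 cm^-1, quartz doublet
#' at 798/779 cm^-1, carbonate bands near 2513, 1430, 875 and 712 cm^-1, and
#' organic C-H (2920/2850), C=O (1720) and C=C (1630) stretches.  Amplitudes
#' are in intensity units per unit component concentration.  The table is built
#' so a clay-dominated composition peaks (above baseline) in the O-H stretching
#' region, the visually dominant feature of clay soils.
#'
#' @return data.frame with columns `component`, `center`, `width`, `amplitude`
#' @export
default_peak_table <- function() {
  tab <- rbind(
    data.frame(component = "clay",
               center = c(3695, 3620, 3550, 1030, 915),
               width  = c(  30,   30,   45,   55,  25),
               amplitude = c(0.50, 1.10, 0.45, 0.50, 0.30)),
    data.frame(component = "quartz",
               center = c(1080, 1160, 798, 779, 695),
               width  = c(  50,   30,  14,  14,  12),
               amplitude = c(0.80, 0.25, 0.35, 0.30, 0.20)),
    data.frame(component = "carbonate",
               center = c(2513, 1430, 875, 712),
               width  = c(  40,   70,  14,  10),
               amplitude = c(0.25, 0.80, 0.40, 0.20)),
    data.frame(component = "organics",
               center = c(3400, 2920, 2850, 2250, 1720, 1630, 1240),
               width  = c( 150,   30,   25,   30,   45,   55,  50),
               amplitude = c(0.30, 0.50, 0.35, 0.08, 0.40, 0.50, 0.30)))
  rownames(tab) <- NULL
  tab
}

soil_components <- c("clay", "organics", "carbonate", "quartz")

#' Acquisition noise model
#'
#' Measurement error for an acquisition that averages `N` interferometer
#' sweeps has three parts:
#' \itemize{
#' \item white per-channel noise with sd `sigma0 * N^-gamma` -- `gamma = 0.5`
#'   is the ideal averaging law (sd of a mean of `N` independent sweeps);
#' \item a smooth low-frequency baseline wobble per acquisition (a random
#'   cubic over the axis) with sd `drift_sd * N^-gamma`, giving correlated
#'   error that moves curve shape, not just channel values;
#' \item a session drift: one smooth random curve per acquisition session
#'   (all replicates recorded back-to-back at one scan setting share it) with
#'   sd `session_sd`, independent of `N` -- instrument-state drift between
#'   sessions does not average away with more scans.  This is what separates
#'   the SMDI values of different settings within a sample, so that the
#'   replicate spread of a converged setting is a small fraction of the
#'   sample's SMDI range rather than pinned near 1 by the standardization.
#' }
#' `cold_start` optionally inflates the noise of the very first acquisition of
#' a run, emulating an instrument not yet thermally stable.
#'
#' @param sigma0 white-noise sd at `N = 1` scan (intensity units)
#' @param gamma scan exponent in `(0, 1]`
#' @param drift_sd per-acquisition baseline-wobble sd at `N = 1`
#' @param session_sd per-session (per sample-and-setting) drift sd, in
#'   intensity units, not scaled by `N`
#' @param cold_start if `TRUE`, the first acquisition generated in a run gets
#'   its noise inflated by `cold_start_factor`
#' @param cold_start_factor multiplier applied under `cold_start`
#' @return a list of class `noise_model`
#' @export
noise_model <- function(sigma0 = 0.02, gamma = 0.5, drift_sd = 0.008,
                        session_sd = 0.022, cold_start = FALSE,
                        cold_start_factor = 5) {
  assert_that(sigma0 >= 0, "sigma0 must be >= 0")
  assert_that(gamma > 0 && gamma <= 1, "gamma must be in (0, 1]")
  assert_that(drift_sd >= 0, "drift_sd must be >= 0")
  assert_that(session_sd >= 0, "session_sd must be >= 0")
  structure(list(sigma0 = sigma0, gamma = gamma, drift_sd = drift_sd,
                 session_sd = session_sd, cold_start = cold_start,
                 cold_start_factor = cold_start_factor),
            class = "noise_model")
}

## Unit-sd smooth random cubic over p channels (drawn from the current RNG
## state); the shared shape vocabulary of drift and session components.
smooth_random_curve <- function(p) {
  coefs <- stats::rnorm(4)
  u <- seq(-1, 1, length.out = p)
  curve <- coefs[1] + coefs[2] * u + coefs[3] * u^2 + coefs[4] * u^3
  sdc <- stats::sd(curve)
  if (sdc > 0) (curve - mean(curve)) / sdc else curve * 0
}

## Session drift curve for one (sample, setting) acquisition session.
session_drift <- function(noise, p, seed, sample_id, setting) {
  if (noise$session_sd == 0) return(numeric(p))
  with_substream(seed, paste("session", sample_id, setting, sep = "|"),
                 noise$session_sd * smooth_random_curve(p))
}

#' Noise-free spectrum of a soil composition
#'
#' Renders `baseline(v) + sum_k conc_k * sum_{peaks of k} a * exp(-(v - c)^2 /
#' (2 w^2))` on the grid: a fixed gentle quadratic baseline plus Gaussian bands
#' scaled linearly by component concentrations.  Deterministic given inputs.
#'
#' @param concentrations named numeric vector over
#'   `c("clay", "organics", "carbonate", "quartz")`, all >= 0
#' @param grid ascending wavenumber vector covering the peak centers
#' @param peaks peak library as from [default_peak_table()]
#' @return numeric intensity vector on `grid`
#' @export
render_true_spectrum <- function(concentrations, grid = default_grid(),
                                 peaks = default_peak_table()) {
  assert_that(all(soil_components %in% names(concentrations)),
              paste("concentrations must be named over:",
                    paste(soil_components, collapse = ", ")))
  assert_that(all(concentrations[soil_components] >= 0),
              "concentrations must be >= 0")
  assert_that(all(peaks$center >= min(grid) & peaks$center <= max(grid)),
              "peak center outside the wavenumber grid", "scanstab_config_error")
  assert_that(all(peaks$width > 0) && all(peaks$amplitude > 0),
              "peak widths and amplitudes must be > 0", "scanstab_config_error")
  y <- spectral_baseline(grid)
  for (i in seq_len(nrow(peaks))) {
    cc <- concentrations[[peaks$component[i]]]
    if (cc > 0)
      y <- y + cc * peaks$amplitude[i] *
        exp(-(grid - peaks$center[i])^2 / (2 * peaks$width[i]^2))
  }
  y
}

#' Fixed baseline under the synthetic spectra
#' @param grid wavenumber vector
#' @return baseline intensity vector
#' @export
spectral_baseline <- function(grid) {
  u <- (grid - 2300) / 1700
  0.15 + 0.05 * u + 0.04 * u^2
}

#' Simulate one stored acquisition at a scan setting
#'
#' Adds to the true spectrum (a) white noise with per-channel sd
#' `sigma0 * N^-gamma` and (b) a smooth random cubic drift curve with sd
#' `drift_sd * N^-gamma` across channels.  The random draw is taken from a
#' substream determined by `(seed, key)`, so any single acquisition is
#' bit-reproducible independently of the rest of its dataset.
#'
#' @param true_intensity noise-free intensity vector
#' @param n_scans scan setting `N >= 1`
#' @param noise a [noise_model()]
#' @param seed master integer seed
#' @param key acquisition key string (e.g. `"S01|10|3"`)
#' @param inflate extra noise multiplier (used for cold-start emulation)
#' @return observed intensity vector
#' @export
acquire <- function(true_intensity, n_scans, noise = noise_model(),
                    seed = 1, key = "acq", inflate = 1) {
  assert_that(is.numeric(n_scans) && n_scans >= 1, "n_scans must be >= 1")
  p <- length(true_intensity)
  scale <- n_scans^(-noise$gamma) * inflate
  with_substream(seed, key, {
    eps <- stats::rnorm(p, sd = 1)
    drift <- smooth_random_curve(p)
    true_intensity + noise$sigma0 * scale * eps +
      noise$drift_sd * scale * drift
  })
}

## Draw a component-concentration vector for one sample of a given soil type.
## The dominant component is set by the type; the rest are minor admixtures.
draw_composition <- function(soil_type) {
  r <- function(lo, hi) stats::runif(1, lo, hi)
  switch(soil_type,
    sandy   = c(clay = r(0.10, 0.40), organics = r(0.05, 0.25),
                carbonate = r(0.00, 0.30), quartz = r(1.00, 1.50)),
    clay    = c(clay = r(1.00, 1.50), organics = r(0.05, 0.30),
                carbonate = r(0.00, 0.40), quartz = r(0.20, 0.60)),
    organic = c(clay = r(0.10, 0.50), organics = r(1.00, 1.50),
                carbonate = r(0.00, 0.20), quartz = r(0.20, 0.60)),
    stop_scanstab(paste("unknown soil type:", soil_type), "scanstab_config_error"))
}

#' Generate the replicate-stability dataset
#'
#' Emulates the scan-number stability design: `n_samples` reference soils
#' (types cycled sandy/clay/organic), each acquired at every scan setting with
#' `replicates` replications -- by default 12 samples x settings
#' \{10, 20, ..., 100\} x 5 replicates = 600 acquisitions of 50 per sample.
#' All spectra share one grid; metadata is fully populated.  Bit-reproducible
#' from `(seed, design, noise)`.
#'
#' @param n_samples number of soil samples (default 12: 4 per soil type)
#' @param settings integer vector of scan settings
#' @param replicates replicates per (sample, setting); must be >= 2 so that a
#'   spread is defined
#' @param seed master integer seed
#' @param noise a [noise_model()]
#' @param grid wavenumber grid
#' @param peaks peak library
#' @return a [spectra_collection()] with `n_samples * length(settings) *
#'   replicates` acquisitions
#' @export
generate_stability_dataset <- function(n_samples = 12,
                                       settings = seq(10, 100, by = 10),
                                       replicates = 5, seed = 1,
                                       noise = noise_model(),
                                       grid = default_grid(),
                                       peaks = default_peak_table()) {
  assert_that(length(settings) >= 1 && all(settings >= 1),
              "settings must be positive", "scanstab_config_error")
  assert_that(replicates >= 2, "need >= 2 replicates (spread undefined otherwise)",
              "scanstab_config_error")
  assert_that(n_samples >= 1, "need >= 1 sample", "scanstab_config_error")

  # blocks of equal size per soil type (12 samples -> 4 sandy, 4 clay, 4 organic)
  types <- rep(c("sandy", "clay", "organic"), each = ceiling(n_samples / 3))[
    seq_len(n_samples)]
  ids <- sprintf("S%02d", seq_len(n_samples))

  truth <- matrix(0, nrow = length(grid), ncol = n_samples)
  for (s in seq_len(n_samples)) {
    comp <- with_substream(seed, paste0("composition|", ids[s]),
                           draw_composition(types[s]))
    truth[, s] <- render_true_spectrum(comp, grid, peaks)
  }

  design <- expand.grid(replicate = seq_len(replicates),
                        scan_setting = as.integer(settings),
                        sample = seq_len(n_samples))
  design <- design[, c("sample", "scan_setting", "replicate")]
  intensity <- matrix(0, nrow = length(grid), ncol = nrow(design))
  first_key <- paste(ids[1], min(settings), 1, sep = "|")
  sess <- list()
  for (a in seq_len(nrow(design))) {
    s <- design$sample[a]; N <- design$scan_setting[a]
    skey <- paste(ids[s], N)
    if (is.null(sess[[skey]]))
      sess[[skey]] <- session_drift(noise, length(grid), seed, ids[s], N)
    key <- paste(ids[s], N, design$replicate[a], sep = "|")
    inflate <- if (noise$cold_start && key == first_key) noise$cold_start_factor else 1
    intensity[, a] <- acquire(truth[, s] + sess[[skey]], N, noise,
                              seed = seed, key = key, inflate = inflate)
  }
  meta <- data.frame(
    acquisition_id = paste(ids[design$sample], design$scan_setting,
                           design$replicate, sep = "_"),
    sample_id = ids[design$sample],
    scan_setting = design$scan_setting,
    replicate = design$replicate,
    soil_type = types[design$sample],
    stringsAsFactors = FALSE)
  spectra_collection(grid, intensity, meta)
}

#' Default linear linkage from composition to soil properties
#'
#' Linear maps from component concentrations to the five measured properties,
#' with per-property measurement noise and the physically plausible ranges the
#' generated values are kept inside (pH 4.5-8.5, TOC 0.2-8 %, TN from TOC via
#' a C:N ratio in 8-15, CEC 2-45 cmol(+)/kg, Olsen P 2-60 mg/kg).  Olsen P is
#' deliberately given the weakest signal-to-noise of the five, making it the
#' hardest property to calibrate.
#'
#' @return list with per-property intercepts, coefficient matrix over
#'   components, noise sds, clamping ranges, and the C:N band
#' @export
default_property_linkage <- function() {
  coef <- rbind(  #            clay organics carbonate quartz
    pH     = c(5.30,  0.55, -0.45,  1.90, 0.00),
    TOC    = c(0.30,  0.00,  4.20,  0.00, 0.00),
    CEC    = c(3.50, 14.00,  9.00,  0.00, 0.00),
    OlsenP = c(9.00,  0.00, 13.00, 11.00, 0.00))
  colnames(coef) <- c("intercept", "clay", "organics", "carbonate", "quartz")
  list(coef = coef,
       noise_sd = c(pH = 0.12, TOC = 0.15, TN = 0, CEC = 1.2, OlsenP = 5.0),
       ranges = list(pH = c(4.5, 8.5), TOC = c(0.2, 8), TN = c(0.01, 1),
                     CEC = c(2, 45), OlsenP = c(2, 60)),
       cn_range = c(8, 15))
}

## Properties for one sample (substream-reproducible); TN derived from TOC
## through a per-sample C:N ratio so the C:N invariant holds by construction.
draw_properties <- function(comp, linkage, seed, sample_id) {
  with_substream(seed, paste0("properties|", sample_id), {
    cf <- linkage$coef
    lin <- as.numeric(cf[, "intercept"] +
                        cf[, soil_components, drop = FALSE] %*% comp[soil_components])
    names(lin) <- rownames(cf)
    clamp <- function(v, rng) min(max(v, rng[1]), rng[2])
    pH  <- clamp(lin["pH"]  + stats::rnorm(1, sd = linkage$noise_sd["pH"]),
                 linkage$ranges$pH)
    TOC <- clamp(lin["TOC"] + stats::rnorm(1, sd = linkage$noise_sd["TOC"]),
                 linkage$ranges$TOC)
    cn  <- stats::runif(1, linkage$cn_range[1], linkage$cn_range[2])
    TN  <- clamp(TOC / cn, linkage$ranges$TN)
    CEC <- clamp(lin["CEC"] + stats::rnorm(1, sd = linkage$noise_sd["CEC"]),
                 linkage$ranges$CEC)
    P   <- clamp(lin["OlsenP"] + stats::rnorm(1, sd = linkage$noise_sd["OlsenP"]),
                 linkage$ranges$OlsenP)
    c(pH = as.numeric(pH), TOC = as.numeric(TOC), TN = as.numeric(TN),
      CEC = as.numeric(CEC), OlsenP = as.numeric(P))
  })
}

#' Generate the calibration dataset: spectra + soil properties
#'
#' Emulates the scan-number calibration design: `n_samples` soils spanning the
#' property ranges (types cycled), each acquired once per scan setting, with
#' the five soil properties measured once per sample (independent of setting).
#' Defaults: 40 samples at settings \{10, 20, 40, 60, 80\} -> 200 spectra and a
#' 40-row property table.
#'
#' @inheritParams generate_stability_dataset
#' @param linkage property linkage as from [default_property_linkage()]
#' @return list with elements `spectra` (a [spectra_collection()]) and
#'   `properties` (data.frame: sample_id, soil_type, pH, TOC, TN, CEC, OlsenP)
#' @export
generate_calibration_dataset <- function(n_samples = 40,
                                         settings = c(10, 20, 40, 60, 80),
                                         seed = 1, noise = noise_model(),
                                         grid = default_grid(),
                                         peaks = default_peak_table(),
                                         linkage = default_property_linkage()) {
  assert_that(n_samples >= 10, "calibration needs >= 10 samples",
              "scanstab_config_error")
  assert_that(length(settings) >= 1 && all(settings >= 1),
              "settings must be positive", "scanstab_config_error")
  types <- rep(c("sandy", "clay", "organic"), length.out = n_samples)
  ids <- sprintf("C%02d", seq_len(n_samples))

  truth <- matrix(0, nrow = length(grid), ncol = n_samples)
  props <- matrix(0, nrow = n_samples, ncol = 5,
                  dimnames = list(NULL, c("pH", "TOC", "TN", "CEC", "OlsenP")))
  for (s in seq_len(n_samples)) {
    comp <- with_substream(seed, paste0("composition|", ids[s]),
                           draw_composition(types[s]))
    truth[, s] <- render_true_spectrum(comp, grid, peaks)
    props[s, ] <- draw_properties(comp, linkage, seed, ids[s])
  }

  design <- expand.grid(scan_setting = as.integer(settings),
                        sample = seq_len(n_samples))
  intensity <- matrix(0, nrow = length(grid), ncol = nrow(design))
  for (a in seq_len(nrow(design))) {
    s <- design$sample[a]; N <- design$scan_setting[a]
    key <- paste(ids[s], N, 1, sep = "|")
    intensity[, a] <- acquire(
      truth[, s] + session_drift(noise, length(grid), seed, ids[s], N),
      N, noise, seed = seed, key = key)
  }
  meta <- data.frame(
    acquisition_id = paste(ids[design$sample], design$scan_setting, 1, sep = "_"),
    sample_id = ids[design$sample],
    scan_setting = design$scan_setting,
    replicate = 1L,
    soil_type = types[design$sample],
    stringsAsFactors = FALSE)
  list(spectra = spectra_collection(grid, intensity, meta),
       properties = data.frame(sample_id = ids, soil_type = types,
                               as.data.frame(props),
                               stringsAsFactors = FALSE))
}
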