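test_that("rendered spectra are baseline plus concentration-linear bands", {
  grid <- default_grid()
  zero <- c(clay = 0, organics = 0, carbonate = 0, quartz = 0)
  expect_equal(render_true_spectrum(zero, grid), spectral_baseline(grid))

  one <- c(clay = 0.7, organics = 0.3, carbonate = 0.2, quartz = 0.9)
  y1 <- render_true_spectrum(one, grid) - spectral_baseline(grid)
  y2 <- render_true_spectrum(2 * one, grid) - spectral_baseline(grid)
  expect_equal(y2, 2 * y1, tolerance = 1e-12)
})

test_that("a clay-dominated composition peaks in the O-H stretching region", {
  grid <- default_grid()
  comp <- c(clay = 1.25, organics = 0.15, carbonate = 0.2, quartz = 0.4)
  y <- render_true_spectrum(comp, grid) - spectral_baseline(grid)
  peak_at <- grid[which.max(y)]
  expect_gt(peak_at, 3500)
  expect_lt(peak_at, 3700)
})

test_that("peaks outside the grid are a config error", {
  bad <- default_peak_table()
  bad$center[1] <- 5000
  expect_error(render_true_spectrum(c(clay = 1, organics = 0, carbonate = 0,
                                      quartz = 0), default_grid(), bad),
               class = "scanstab_config_error")
})

test_that("acquisition noise follows the closed-form scan-averaging law", {
  truth <- rep(0, 200)
  nm <- noise_model(sigma0 = 0.02, gamma = 0.5, drift_sd = 0, session_sd = 0)
  # sigma(N) = sigma0 / sqrt(N): empirical sd over many draws at N = 25
  draws <- vapply(1:10000, function(i)
    acquire(truth, 25, nm, seed = 3, key = paste0("k", i))[7], numeric(1))
  expect_equal(sd(draws), 0.02 / 5, tolerance = 0.03)
  # and at N = 100 the per-channel sd parameter is sigma0/10 by construction
  big <- acquire(rep(0, 20000), 100, nm, seed = 3, key = "wide")
  expect_equal(sd(big), 0.002, tolerance = 0.05)
})

test_that("acquisitions are bit-reproducible from (seed, key) and differ across keys", {
  truth <- render_true_spectrum(c(clay = 1, organics = 0.2, carbonate = 0.1,
                                  quartz = 0.4))
  a <- acquire(truth, 40, seed = 9, key = "S01|40|2")
  b <- acquire(truth, 40, seed = 9, key = "S01|40|2")
  expect_identical(a, b)
  expect_false(identical(a, acquire(truth, 40, seed = 9, key = "S01|40|3")))
  expect_false(identical(a, acquire(truth, 40, seed = 10, key = "S01|40|2")))
  expect_error(acquire(truth, 0, seed = 1, key = "x"),
               class = "scanstab_usage_error")
})

test_that("averaging N unit-scan draws matches one draw at sd sigma0/sqrt(N)", {
  nm <- noise_model(sigma0 = 0.05, gamma = 0.5, drift_sd = 0, session_sd = 0)
  truth <- rep(1, 400)
  N <- 16
  set.seed(99)
  avg <- replicate(600, {
    draws <- vapply(1:N, function(i)
      truth[1] + rnorm(1, sd = nm$sigma0), numeric(1))
    mean(draws)
  })
  direct <- vapply(1:600, function(i)
    acquire(truth, N, nm, seed = 5, key = paste0("d", i))[1], numeric(1))
  expect_equal(mean(avg), mean(direct), tolerance = 0.005)
  expect_equal(sd(avg), sd(direct), tolerance = 0.15)
})

test_that("the stability dataset has the full acquisition design", {
  coll <- generate_stability_dataset(seed = 5)
  expect_equal(n_spectra(coll), 600)
  expect_equal(length(unique(coll$meta$sample_id)), 12)
  expect_equal(sort(unique(coll$meta$scan_setting)), seq(10L, 100L, by = 10L))
  expect_equal(as.integer(table(coll$meta$soil_type)), c(200L, 200L, 200L))
  counts <- table(coll$meta$sample_id, coll$meta$scan_setting)
  expect_true(all(counts == 5))

  # same seed reproduces bitwise; different seed changes intensities only
  again <- generate_stability_dataset(seed = 5)
  expect_identical(coll$intensity, again$intensity)
  other <- generate_stability_dataset(seed = 6)
  expect_identical(coll$meta, other$meta)
  expect_false(identical(coll$intensity, other$intensity))

  expect_error(generate_stability_dataset(replicates = 1),
               class = "scanstab_config_error")
})

test_that("the calibration dataset links spectra and in-range properties", {
  ds <- generate_calibration_dataset(seed = 3)
  expect_equal(n_spectra(ds$spectra), 200)
  expect_equal(nrow(ds$properties), 40)
  rng <- default_property_linkage()$ranges
  with(ds$properties, {
    expect_true(all(pH >= rng$pH[1] & pH <= rng$pH[2]))
    expect_true(all(TOC >= rng$TOC[1] & TOC <= rng$TOC[2]))
    expect_true(all(CEC >= rng$CEC[1] & CEC <= rng$CEC[2]))
    expect_true(all(OlsenP >= rng$OlsenP[1] & OlsenP <= rng$OlsenP[2]))
    expect_true(all(is.finite(TN) & TN > 0))
  })
  # C:N ratio inside the configured band wherever TOC was not clamped
  cn <- ds$properties$TOC / ds$properties$TN
  expect_true(all(cn >= 7.99 & cn <= 15.01))
})

test_that("a noiseless generator renders spectra linear in concentrations", {
  nm <- noise_model(sigma0 = 1e-12, gamma = 0.5, drift_sd = 0, session_sd = 0)
  ds <- generate_calibration_dataset(n_samples = 10, settings = c(10, 80),
                                     seed = 2, noise = nm)
  # identical across settings when there is no noise to average away
  m <- ds$spectra$meta
  i10 <- which(m$scan_setting == 10); i80 <- which(m$scan_setting == 80)
  expect_equal(ds$spectra$intensity[, i10], ds$spectra$intensity[, i80],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("replicate sd at a fixed channel recovers the -gamma noise-law slope", {
  slopes <- vapply(1:40, function(rep) {
    coll <- generate_stability_dataset(n_samples = 1, replicates = 5,
                                       seed = 1000 + rep)
    ch <- 200
    sds <- vapply(split(seq_len(n_spectra(coll)), coll$meta$scan_setting),
                  function(ix) sd(coll$intensity[ch, ix]), numeric(1))
    N <- as.numeric(names(sds))
    unname(coef(lm(log(sds) ~ log(N)))[2])
  }, numeric(1))
  expect_lt(abs(mean(slopes) + 0.5), 0.1)
})
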