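test_that("moment distances match the hand-worked three-channel example", {
  rho <- c(1, 2, 3)
  # independent per-term summation: 1 + sqrt(5) + sqrt(13), sqrt5+sqrt5+3
  expect_equal(moment_distance_left(rho), brute_md(rho, 0:2), tolerance = 1e-14)
  expect_equal(moment_distance_right(rho), brute_md(rho, 2:0), tolerance = 1e-14)
  expect_equal(moment_distance_left(rho), 6.8416192, tolerance = 1e-7)
  expect_equal(moment_distance_right(rho), 7.4721360, tolerance = 1e-7)
  expect_equal(mdi_value(rho), 0.6305167, tolerance = 1e-6)

  # zero intensity reduces to the sum of offsets
  expect_equal(moment_distance_left(c(0, 0, 0)), 3)
  expect_equal(moment_distance_right(c(0, 0, 0)), 3)

  # reversal swaps the pivots, negating the index
  expect_equal(mdi_value(c(3, 2, 1)), -0.6305167, tolerance = 1e-6)
})

test_that("flat spectra give MDI 0 and mirror reversal negates MDI", {
  for (n in c(2, 5, 17, 301)) {
    expect_equal(mdi_value(rep(2.7, n)), 0, tolerance = 1e-12)
  }
  set.seed(42)
  for (i in 1:50) {
    n <- sample(2:60, 1)
    rho <- runif(n, 0, 3)
    m <- mdi_value(rho)
    expect_equal(mdi_value(rev(rho)), -m, tolerance = 1e-10 * max(1, abs(m)))
  }
})

test_that("vectorized batch MDI equals the per-channel loop oracle", {
  coll <- small_stability()
  res <- batch_mdi(coll)
  set.seed(1)
  for (a in sample(n_spectra(coll), 8)) {
    rho <- coll$intensity[, a]
    i <- which(res$acquisition_id == coll$meta$acquisition_id[a])
    expect_equal(res$md_lp[i], brute_md(rho, seq_along(rho) - 1),
                 tolerance = 1e-10)
    expect_equal(res$md_rp[i], brute_md(rho, rev(seq_along(rho)) - 1),
                 tolerance = 1e-10)
    # the index is a small difference of two large sums; summation-order
    # effects are bounded relative to the sums, not the difference
    expect_lt(abs(res$mdi[i] - brute_mdi(rho)), 1e-12 * res$md_rp[i])
  }
  # on short windows (no cancellation) the index itself matches tightly
  set.seed(2)
  for (i in 1:200) {
    rho <- runif(sample(2:50, 1), 0, 3)
    m <- mdi_value(rho)
    expect_lt(abs(m - brute_mdi(rho)), 1e-10 * max(1, abs(m)))
  }
})

test_that("axis-value offsets scale the metric by the channel spacing geometry", {
  rho <- c(0.5, 1.5, 0.25, 2)
  x <- c(600, 604, 608, 612)
  expect_equal(moment_distance_left(rho, x), brute_md(rho, x - 600),
               tolerance = 1e-12)
  expect_equal(mdi_value(rho, x), brute_mdi(rho, x), tolerance = 1e-12)
  # index and axis units are genuinely different metrics on a 4 cm-1 grid
  expect_false(isTRUE(all.equal(mdi_value(rho), mdi_value(rho, x))))
})

test_that("degenerate windows and non-finite intensities are rejected", {
  expect_error(moment_distance_left(3), class = "scanstab_window_error")
  expect_error(mdi_value(c(1, NA, 2)), class = "scanstab_data_error")
})

test_that("SMDI standardization maps each group onto [0, 1] with 0 and 1 attained", {
  df <- data.frame(sample_id = rep(c("A", "B"), each = 3),
                   mdi = c(2, 4, 6, 10, 11, 15))
  out <- smdi_standardize(df)
  expect_equal(out$smdi[1:3], c(0, 0.5, 1))
  expect_equal(min(out$smdi[4:6]), 0)
  expect_equal(max(out$smdi[4:6]), 1)
  # extremes recorded per group, never shared
  expect_equal(unique(out$group_min_mdi[1:3]), 2)
  expect_equal(unique(out$group_max_mdi[4:6]), 15)
})

test_that("SMDI is invariant under positive affine maps and flips under negation", {
  set.seed(7)
  df <- data.frame(sample_id = "A", mdi = rnorm(20))
  base <- smdi_standardize(df)$smdi
  aff <- df; aff$mdi <- 3.7 * df$mdi + 11
  expect_equal(smdi_standardize(aff)$smdi, base, tolerance = 1e-12)
  neg <- df; neg$mdi <- -df$mdi
  flipped <- smdi_standardize(neg)$smdi
  expect_equal(flipped, 1 - base, tolerance = 1e-12)
  # spread statistics downstream are orientation-immune
  expect_equal(max(flipped) - min(flipped), max(base) - min(base))
  expect_equal(sd(flipped), sd(base), tolerance = 1e-12)
})

test_that("degenerate standardization groups raise identifiable errors", {
  expect_error(smdi_standardize(data.frame(sample_id = "A", mdi = 5)),
               class = "scanstab_degenerate_group_error")
  expect_error(smdi_standardize(data.frame(sample_id = c("A", "A", "A"),
                                           mdi = c(5, 5, 5))),
               class = "scanstab_degenerate_group_error")
  err <- tryCatch(smdi_standardize(data.frame(sample_id = c("grpX", "grpX"),
                                              mdi = c(1, 1))),
                  error = identity)
  expect_match(conditionMessage(err), "grpX")
})

test_that("batch MDI on a stability design has full cardinality and per-sample scaling", {
  coll <- small_stability()
  res <- batch_mdi(coll)
  expect_equal(nrow(res), 3 * 3 * 4)
  expect_equal(length(unique(res$sample_id)), 3)
  for (s in unique(res$sample_id)) {
    v <- res$smdi[res$sample_id == s]
    expect_equal(min(v), 0)
    expect_equal(max(v), 1)
  }
  # deterministic ordering: sample, setting, replicate
  expect_identical(res$sample_id, sort(res$sample_id))
  # identical input spectra get identical index values
  dup <- spectra_collection(coll$wavenumber,
                            cbind(coll$intensity, coll$intensity[, 1]),
                            rbind(coll$meta,
                                  data.frame(acquisition_id = "dup",
                                             sample_id = coll$meta$sample_id[1],
                                             scan_setting = 999L, replicate = 1L,
                                             soil_type = coll$meta$soil_type[1])))
  res2 <- batch_mdi(dup)
  expect_equal(res2$mdi[res2$acquisition_id == "dup"],
               res2$mdi[res2$acquisition_id == coll$meta$acquisition_id[1]])
})
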