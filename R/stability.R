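#' Replicate SMDI spread per (sample, scan setting)
#'
#' The stability signal: for each sample and scan setting, the spread
#' (max - min, the difference between the two extreme replicate values) and
#' the standard deviation of the replicate SMDIs.
#'
#' @param smdi data.frame from [batch_mdi()] (needs `sample_id`,
#'   `scan_setting`, `replicate`, `smdi`, optionally `soil_type`)
#' @return data.frame: `sample_id, soil_type, scan_setting, spread, sd,
#'   n_replicates`, ordered by sample then setting
#' @export
setting_spread <- function(smdi) {
  assert_that(all(c("sample_id", "scan_setting", "smdi") %in% names(smdi)),
              "smdi table must have sample_id, scan_setting, smdi columns")
  key <- interaction(smdi$sample_id, smdi$scan_setting, drop = TRUE)
  pieces <- split(smdi, key)
  out <- do.call(rbind, lapply(pieces, function(g) {
    if (nrow(g) < 2)
      stop_scanstab(sprintf("sample %s at %d scans has %d replicate(s); need >= 2",
                            g$sample_id[1], g$scan_setting[1], nrow(g)),
                    "scanstab_usage_error")
    data.frame(sample_id = g$sample_id[1],
               soil_type = if ("soil_type" %in% names(g)) g$soil_type[1] else NA,
               scan_setting = g$scan_setting[1],
               spread = max(g$smdi) - min(g$smdi),
               sd = stats::sd(g$smdi),
               n_replicates = nrow(g),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$sample_id, out$scan_setting), ]
  rownames(out) <- NULL
  out
}

## Spearman correlation robust to constant input (all-equal -> 0, not NA).
spearman0 <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b, method = "spearman")
}

#' Convergence (funnel) curve of one sample
#'
#' Orders the per-setting spreads of a sample by scan number and reports the
#' Spearman rank correlation of spread versus N -- negative when replicate
#' agreement improves with more scans (the funnel closing).
#'
#' @param spreads [setting_spread()] rows for a single sample (>= 2 settings)
#' @return data.frame `scan_setting, spread` sorted ascending, with attributes
#'   `spearman` and `sample_id`
#' @export
convergence_curve <- function(spreads) {
  assert_that(length(unique(spreads$sample_id)) == 1,
              "convergence_curve expects rows of one sample")
  assert_that(length(unique(spreads$scan_setting)) >= 2,
              "need >= 2 scan settings for a curve")
  cur <- spreads[order(spreads$scan_setting), c("scan_setting", "spread")]
  rownames(cur) <- NULL
  attr(cur, "spearman") <- spearman0(cur$spread, cur$scan_setting)
  attr(cur, "sample_id") <- spreads$sample_id[1]
  cur
}

#' Recommend the minimum scan number from a convergence curve
#'
#' With `sustained = TRUE` (default): the smallest tested setting `N` whose
#' spread, and the spread of every larger tested setting, is at or below the
#' threshold -- an isolated lucky dip at a low setting does not qualify.
#' Otherwise the first crossing is taken.
#'
#' @param curve data.frame with `scan_setting` and `spread` (e.g. a pooled
#'   curve or [convergence_curve()] output)
#' @param threshold spread tolerance in SMDI units (> 0); default 0.05, between
#'   the ~0.2 spreads typical of unstable low-scan acquisition and the ~0.02 of
#'   a converged setting
#' @param sustained require the threshold to hold for all larger settings too
#' @return the recommended setting (integer), or `NA_integer_` if no tested
#'   setting meets the rule ("not reached")
#' @export
recommend_min_scans <- function(curve, threshold = 0.05, sustained = TRUE) {
  assert_that(is.numeric(threshold) && threshold > 0, "threshold must be > 0")
  assert_that(nrow(curve) >= 1, "empty convergence curve")
  cur <- curve[order(curve$scan_setting), ]
  ok <- cur$spread <= threshold
  if (sustained) ok <- rev(cumprod(rev(ok))) > 0   # TRUE only if all above hold
  if (!any(ok)) return(NA_integer_)
  as.integer(cur$scan_setting[which(ok)[1]])
}

#' Reproducibility summary across samples by soil type
#'
#' Pools the per-sample spreads within each soil type: median and interquartile
#' range of spread per setting, plus a flag for any sample whose spread at a
#' given setting exceeds 3x the type median there (an acquisition-session
#' outlier, e.g. an instrument still warming up).
#'
#' @param spreads [setting_spread()] table with `soil_type` populated
#' @return list with `by_type` (data.frame: soil_type, scan_setting, median,
#'   iqr, n_samples) and `flags` (data.frame of outlying (sample, setting)
#'   rows; zero rows when none)
#' @export
reproducibility_summary <- function(spreads) {
  assert_that("soil_type" %in% names(spreads) && !anyNA(spreads$soil_type),
              "spreads must carry soil_type")
  key <- interaction(spreads$soil_type, spreads$scan_setting, drop = TRUE)
  by_type <- do.call(rbind, lapply(split(spreads, key), function(g)
    data.frame(soil_type = g$soil_type[1], scan_setting = g$scan_setting[1],
               median = stats::median(g$spread), iqr = stats::IQR(g$spread),
               n_samples = nrow(g), stringsAsFactors = FALSE)))
  by_type <- by_type[order(by_type$soil_type, by_type$scan_setting), ]
  rownames(by_type) <- NULL

  med <- by_type$median[match(interaction(spreads$soil_type, spreads$scan_setting),
                              interaction(by_type$soil_type, by_type$scan_setting))]
  bad <- spreads$spread > 3 * med & med > 0
  flags <- spreads[bad, c("sample_id", "soil_type", "scan_setting", "spread")]
  flags$type_median <- med[bad]
  rownames(flags) <- NULL
  list(by_type = by_type, flags = flags)
}

#' Full stability report from an SMDI table
#'
#' Assembles the stability analysis: per-(sample, setting) spreads, per-sample
#' convergence curves with their Spearman trends, the pooled per-setting curve
#' (median spread across samples, robust to a single outlying session), the
#' soil-type reproducibility summary, and the recommended minimum scan number
#' under the sustained-threshold rule.
#'
#' @param smdi data.frame from [batch_mdi()]
#' @param threshold spread tolerance in SMDI units (see [recommend_min_scans()])
#' @param sustained passed to [recommend_min_scans()]
#' @return object of class `stability_report`: `spreads`, `curves` (named list
#'   per sample), `pooled` (scan_setting, spread), `by_type`, `flags`,
#'   `recommended_min_scans` (integer or `NA`), `threshold`, `sustained`
#' @export
stability_report <- function(smdi, threshold = 0.05, sustained = TRUE) {
  spreads <- setting_spread(smdi)
  assert_that(length(unique(spreads$scan_setting)) >= 2,
              "need >= 2 scan settings for a stability report",
              "scanstab_config_error")
  curves <- lapply(split(spreads, spreads$sample_id), convergence_curve)
  pooled <- do.call(rbind, lapply(split(spreads, spreads$scan_setting),
                                  function(g) data.frame(
                                    scan_setting = g$scan_setting[1],
                                    spread = stats::median(g$spread))))
  pooled <- pooled[order(pooled$scan_setting), ]
  rownames(pooled) <- NULL
  repro <- if (!anyNA(spreads$soil_type)) reproducibility_summary(spreads)
           else list(by_type = NULL, flags = spreads[0, ])
  structure(list(spreads = spreads, curves = curves, pooled = pooled,
                 by_type = repro$by_type, flags = repro$flags,
                 recommended_min_scans =
                   recommend_min_scans(pooled, threshold, sustained),
                 threshold = threshold, sustained = sustained),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report>\n")
  cat(sprintf("  samples: %d | settings: %s\n", length(x$curves),
              paste(x$pooled$scan_setting, collapse = ",")))
  cat("  pooled median spread per setting (SMDI units):\n")
  cat(sprintf("    %s\n", paste(sprintf("%d:%.3f", x$pooled$scan_setting,
                                        x$pooled$spread), collapse = "  ")))
  rec <- x$recommended_min_scans
  cat(sprintf("  recommended minimum scans (spread <= %.3g%s): %s\n",
              x$threshold, if (x$sustained) ", sustained" else "",
              if (is.na(rec)) "not reached" else rec))
  if (!is.null(x$flags) && nrow(x$flags))
    cat(sprintf("  flagged outlier sessions: %s\n",
                paste(sprintf("%s@%d", x$flags$sample_id, x$flags$scan_setting),
                      collapse = ", ")))
  invisible(x)
}

#' @export
summary.stability_report <- function(object, ...) {
  spear <- vapply(object$curves, attr, numeric(1), "spearman")
  out <- list(pooled = object$pooled,
              spearman_by_sample = spear,
              recommended_min_scans = object$recommended_min_scans,
              n_flags = if (is.null(object$flags)) 0L else nrow(object$flags))
  class(out) <- "summary.stability_report"
  out
}

#' @export
print.summary.stability_report <- function(x, ...) {
  cat("Pooled spread by scan setting:\n"); print(x$pooled)
  cat("\nSpearman(spread, N) per sample:\n"); print(round(x$spearman_by_sample, 3))
  cat(sprintf("\nRecommended minimum scans: %s | outlier flags: %d\n",
              if (is.na(x$recommended_min_scans)) "not reached"
              else x$recommended_min_scans, x$n_flags))
  invisible(x)
}

#' Funnel plot of replicate SMDI values versus scan setting
#'
#' One panel per sample: replicate SMDI plotted against the scan setting, the
#' visual form in which convergence shows as a lying funnel narrowing to the
#' right.
#'
#' @param x a [stability_report()] -- plotted from its `spreads`; pass the
#'   SMDI table via `smdi` for per-replicate points
#' @param smdi optional [batch_mdi()] table for per-replicate points
#' @param samples subset of sample ids to draw (default: up to 12)
#' @param ... passed to [graphics::plot()]
#' @export
plot.stability_report <- function(x, smdi = NULL, samples = NULL, ...) {
  ids <- names(x$curves)
  if (!is.null(samples)) ids <- intersect(ids, samples)
  ids <- utils::head(ids, 12)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(ids)),
                       mar = c(3, 3, 2, 0.5), mgp = c(1.8, 0.6, 0))
  on.exit(graphics::par(old))
  for (s in ids) {
    if (!is.null(smdi)) {
      g <- smdi[smdi$sample_id == s, ]
      graphics::plot(g$scan_setting, g$smdi, pch = 16, cex = 0.6,
                     xlab = "scan number", ylab = "SMDI", main = s,
                     ylim = c(0, 1), ...)
    } else {
      cur <- x$curves[[s]]
      graphics::plot(cur$scan_setting, cur$spread, type = "b", pch = 16,
                     xlab = "scan number", ylab = "SMDI spread", main = s, ...)
      graphics::abline(h = x$threshold, lty = 2)
    }
  }
  invisible(x)
}
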