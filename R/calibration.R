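soil_properties <- c("pH", "TOC", "TN", "CEC", "OlsenP")

#' PLS figures of merit per soil property and scan setting
#'
#' Builds one PLS1 calibration with leave-one-out cross-validation for every
#' (property, scan setting) cell: predictors are the spectra acquired at that
#' setting (optionally first-difference preprocessed), the response is the
#' property value of each sample.  Every sample must be present at every
#' requested setting.
#'
#' @param spectra a [spectra_collection()] with one acquisition per
#'   (sample, setting)
#' @param properties data.frame keyed by `sample_id` with the property columns
#' @param settings scan settings to evaluate (default: all present)
#' @param property_names property columns to calibrate (default: the five
#'   standard soil properties present in `properties`)
#' @param preprocess `"first_difference"` (default) or `"none"`
#' @param max_lv largest PLS component count tried in cross-validation
#' @return data.frame with one row per (property, setting), ordered by property
#'   then setting: `property, scan_setting, n, n_lv, r2, r2_pearson, rmsecv`.
#'   The per-sample CV predictions are attached as attribute `cv_predictions`
#'   (data.frame: sample_id, property, scan_setting, y, y_cv, outlier).
#' @export
evaluate_by_setting <- function(spectra, properties, settings = NULL,
                                property_names = NULL,
                                preprocess = c("first_difference", "none"),
                                max_lv = 10) {
  preprocess <- match.arg(preprocess)
  assert_that(inherits(spectra, "spectra_collection"),
              "spectra must be a spectra_collection")
  if (is.null(settings)) settings <- sort(unique(spectra$meta$scan_setting))
  if (is.null(property_names))
    property_names <- intersect(soil_properties, names(properties))
  assert_that(length(property_names) >= 1, "no property columns found")
  assert_that(!anyDuplicated(properties$sample_id),
              "properties must have one row per sample_id")
  samples <- properties$sample_id

  gaps <- character(0)
  for (N in settings) for (s in samples)
    if (!any(spectra$meta$sample_id == s & spectra$meta$scan_setting == N))
      gaps <- c(gaps, sprintf("(%s, %d)", s, N))
  if (length(gaps))
    stop_scanstab(paste("missing (sample, setting) acquisitions:",
                        paste(gaps, collapse = " ")), "scanstab_data_error")

  rows <- list(); preds <- list()
  for (prop in property_names) {
    y <- properties[[prop]]
    for (N in settings) {
      idx <- vapply(samples, function(s)
        which(spectra$meta$sample_id == s & spectra$meta$scan_setting == N)[1],
        integer(1))
      X <- t(spectra$intensity[, idx, drop = FALSE])
      if (preprocess == "first_difference") X <- first_difference(X)
      cv <- pls_loocv(X, y, max_lv = max_lv)
      rows[[length(rows) + 1]] <- data.frame(
        property = prop, scan_setting = as.integer(N), n = cv$n,
        n_lv = cv$n_lv, r2 = cv$r2, r2_pearson = cv$r2_pearson,
        rmsecv = cv$rmsecv, stringsAsFactors = FALSE)
      preds[[length(preds) + 1]] <- data.frame(
        sample_id = samples, property = prop, scan_setting = as.integer(N),
        y = y, y_cv = cv$cv_pred, outlier = cv$outlier,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$property, out$scan_setting), ]
  rownames(out) <- NULL
  attr(out, "cv_predictions") <- do.call(rbind, preds)
  out
}

#' Monotone-trend summary of calibration metrics versus scan number
#'
#' For each property, the Spearman rank correlation of `R2` and of `RMSECV`
#' with the scan setting, plus a plain verdict on whether the expected
#' direction (R2 improving, RMSECV shrinking as scans increase) is observed.
#'
#' @param metrics data.frame from [evaluate_by_setting()]
#' @return data.frame: `property, spearman_r2_vs_n, spearman_rmsecv_vs_n,
#'   r2_improves, rmsecv_shrinks`
#' @export
trend_summary <- function(metrics) {
  props <- unique(metrics$property)
  out <- do.call(rbind, lapply(props, function(prop) {
    m <- metrics[metrics$property == prop, ]
    s_r2 <- stats::cor(m$r2, m$scan_setting, method = "spearman")
    s_rm <- stats::cor(m$rmsecv, m$scan_setting, method = "spearman")
    data.frame(property = prop,
               spearman_r2_vs_n = s_r2, spearman_rmsecv_vs_n = s_rm,
               r2_improves = s_r2 > 0, rmsecv_shrinks = s_rm < 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
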