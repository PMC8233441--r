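#' Spectra collection on a shared wavenumber grid
#'
#' A `spectra_collection` holds a set of FTIR acquisitions sampled on one
#' common, strictly ascending wavenumber grid (cm^-1), together with the
#' acquisition metadata: which sample each spectrum belongs to, the scan
#' setting `N` (number of interferometer sweeps averaged into the stored
#' spectrum) and the replicate index.  All pairwise operations in the package
#' (moment distances, calibration matrices) require an identical grid and fail
#' loudly otherwise.
#'
#' @param wavenumber numeric vector of channel positions in cm^-1; may be given
#'   descending (instrument order) and is canonicalized to ascending with the
#'   intensities kept aligned.
#' @param intensity numeric matrix, one row per channel and one column per
#'   acquisition; all values must be finite.  Units are whatever the instrument
#'   exported (absorbance or reflectance) -- see `intensity_unit`.
#' @param meta data.frame with columns `acquisition_id`, `sample_id`,
#'   `scan_setting`, `replicate` and optionally `soil_type`; one row per
#'   intensity column, in column order.  `(sample_id, scan_setting, replicate)`
#'   must be unique.
#' @param intensity_unit label carried along untouched, `"absorbance"` or
#'   `"reflectance"`; the moment-distance machinery operates on whichever is
#'   supplied and never converts.
#'
#' @return An object of class `spectra_collection`.
#' @export
spectra_collection <- function(wavenumber, intensity,
                               meta, intensity_unit = "absorbance") {
  wavenumber <- as.numeric(wavenumber)
  if (is.vector(intensity)) intensity <- matrix(intensity, ncol = 1)
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"

  assert_that(length(wavenumber) >= 2, "wavenumber grid needs at least 2 channels",
              "scanstab_format_error")
  d <- diff(wavenumber)
  if (all(d < 0)) {            # descending instrument order: flip, keep aligned
    wavenumber <- rev(wavenumber)
    intensity <- intensity[rev(seq_len(nrow(intensity))), , drop = FALSE]
    d <- diff(wavenumber)
  }
  assert_that(all(d > 0), "wavenumber axis must be strictly monotone",
              "scanstab_format_error")
  assert_that(nrow(intensity) == length(wavenumber),
              sprintf("intensity has %d rows for %d grid channels",
                      nrow(intensity), length(wavenumber)),
              "scanstab_format_error")
  assert_that(all(is.finite(intensity)), "non-finite intensity values",
              "scanstab_data_error")

  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  req <- c("acquisition_id", "sample_id", "scan_setting", "replicate")
  assert_that(all(req %in% names(meta)),
              paste("metadata must have columns:", paste(req, collapse = ", ")),
              "scanstab_format_error")
  if (!"soil_type" %in% names(meta)) meta$soil_type <- NA_character_
  meta$scan_setting <- as.integer(meta$scan_setting)
  meta$replicate <- as.integer(meta$replicate)
  assert_that(nrow(meta) == ncol(intensity),
              "one metadata row required per acquisition column",
              "scanstab_format_error")
  assert_that(all(meta$scan_setting >= 1) && all(meta$replicate >= 1),
              "scan_setting and replicate must be positive integers",
              "scanstab_format_error")
  key <- paste(meta$sample_id, meta$scan_setting, meta$replicate, sep = "\r")
  assert_that(!anyDuplicated(key),
              "duplicate (sample_id, scan_setting, replicate) keys in metadata",
              "scanstab_format_error")
  assert_that(!anyDuplicated(meta$acquisition_id),
              "duplicate acquisition ids", "scanstab_format_error")
  colnames(intensity) <- meta$acquisition_id
  rownames(meta) <- NULL

  structure(list(wavenumber = wavenumber, intensity = intensity, meta = meta,
                 intensity_unit = intensity_unit,
                 resolution = stats::median(d)),
            class = "spectra_collection")
}

#' @export
print.spectra_collection <- function(x, ...) {
  cat(sprintf("<spectra_collection> %d acquisitions x %d channels (%.7g-%.7g cm-1, ~%g cm-1 step)\n",
              ncol(x$intensity), length(x$wavenumber),
              min(x$wavenumber), max(x$wavenumber), x$resolution))
  cat(sprintf("  samples: %d | scan settings: %s | unit: %s\n",
              length(unique(x$meta$sample_id)),
              paste(sort(unique(x$meta$scan_setting)), collapse = ","),
              x$intensity_unit))
  invisible(x)
}

#' Number of acquisitions in a collection
#' @param x a `spectra_collection`
#' @export
n_spectra <- function(x) ncol(x$intensity)

#' Subset a collection by acquisition
#'
#' @param x a `spectra_collection`
#' @param i acquisition selector: integer/logical index into the columns, or
#'   character acquisition ids
#' @param ... ignored
#' @export
`[.spectra_collection` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$meta$acquisition_id)
  assert_that(!anyNA(i), "unknown acquisition id", "scanstab_usage_error")
  spectra_collection(x$wavenumber, x$intensity[, i, drop = FALSE],
                     x$meta[i, , drop = FALSE], x$intensity_unit)
}

## Shared-grid check used by every operation combining two spectra objects.
assert_same_grid <- function(a, b) {
  assert_that(length(a) == length(b) && all(a == b),
              "spectra are not on an identical wavenumber grid",
              "scanstab_grid_error")
}

#' Restrict spectra to a wavenumber window
#'
#' Keeps the channels with `lo <= wavenumber <= hi` (closed interval on axis
#' values, not indices, so a window specification is resolution-independent).
#'
#' @param x a `spectra_collection`
#' @param lo,hi window bounds in cm^-1, `lo < hi`
#' @return a `spectra_collection` on the windowed grid
#' @export
select_window <- function(x, lo, hi) {
  assert_that(is.numeric(lo) && is.numeric(hi) && lo < hi,
              "window requires lo < hi", "scanstab_window_error")
  keep <- which(x$wavenumber >= lo & x$wavenumber <= hi)
  assert_that(length(keep) >= 2,
              sprintf("window [%g, %g] contains %d channel(s); need >= 2",
                      lo, hi, length(keep)),
              "scanstab_window_error")
  spectra_collection(x$wavenumber[keep], x$intensity[keep, , drop = FALSE],
                     x$meta, x$intensity_unit)
}
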