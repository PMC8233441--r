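#' Moment distances and the moment distance index (MDI)
#'
#' The moment distance of a curve from a pivot is the sum, over the channels of
#' a selected window, of the Euclidean distance from the pivot to each point
#' `(offset, intensity)`: `MD = sum_p sqrt(rho_p^2 + d_p^2)`, where `d_p` is the
#' offset of channel `p` from the pivot.  With the left pivot (LP) at the start
#' of the window and the right pivot (RP) at its end,
#' `MDI = MD_RP - MD_LP` is a scalar summary of curve shape: it is exactly zero
#' for a constant spectrum and changes sign when the curve is mirror-reversed.
#'
#' Offsets can be measured in channel index units (`x` omitted; `d_p = p` with
#' `p = 0` at the left pivot), the band-number convention of the original
#' remote-sensing formulation, or in axis units by passing the channel
#' positions `x` (e.g. wavenumber in cm^-1).
#'
#' @param rho numeric vector of intensities over the window (>= 2 channels,
#'   all finite)
#' @param x optional numeric vector of channel positions, strictly increasing,
#'   same length as `rho`; offsets become `x - x[1]` (left) / `x[n] - x` (right)
#' @return the moment distance (scalar, >= 0)
#' @seealso [batch_mdi()] for whole collections and SMDI standardization
#' @export
moment_distance_left <- function(rho, x = NULL) {
  d <- pivot_offsets(rho, x)
  sum(sqrt(rho^2 + d^2))
}

#' @rdname moment_distance_left
#' @export
moment_distance_right <- function(rho, x = NULL) {
  d <- pivot_offsets(rho, x)
  sum(sqrt(rho^2 + (d[length(d)] - d)^2))
}

pivot_offsets <- function(rho, x) {
  assert_that(length(rho) >= 2, "moment distance needs a window of >= 2 channels",
              "scanstab_window_error")
  assert_that(all(is.finite(rho)), "non-finite intensity in window",
              "scanstab_data_error")
  if (is.null(x)) return(seq_along(rho) - 1)
  assert_that(length(x) == length(rho) && all(diff(x) > 0),
              "x must be strictly increasing and match rho",
              "scanstab_window_error")
  x - x[1]
}

#' @rdname moment_distance_left
#' @return for `mdi_value()`: `MD_RP - MD_LP` (scalar, any sign)
#' @export
mdi_value <- function(rho, x = NULL) {
  moment_distance_right(rho, x) - moment_distance_left(rho, x)
}

#' Min-max standardization of MDI values to SMDI
#'
#' Standardizes MDI values to the `[0, 1]` SMDI scale within groups:
#' `SMDI = (MDI - min) / (max - min)`, extremes taken per group (by default all
#' acquisitions of one sample, across every scan setting and replicate).  The
#' individual SMDI values are not of interest; their spread across replicates
#' of one setting is the stability signal.
#'
#' @param results data.frame with an `mdi` column and the grouping column
#' @param group_by name of the grouping column (default `"sample_id"`)
#' @return `results` with columns `smdi`, `group_min_mdi`, `group_max_mdi` added
#' @export
smdi_standardize <- function(results, group_by = "sample_id") {
  assert_that(is.data.frame(results) && "mdi" %in% names(results),
              "results must be a data.frame with an 'mdi' column",
              "scanstab_usage_error")
  assert_that(group_by %in% names(results),
              sprintf("grouping column '%s' not found", group_by),
              "scanstab_usage_error")
  g <- as.character(results[[group_by]])
  smdi <- numeric(nrow(results))
  lo <- numeric(nrow(results)); hi <- numeric(nrow(results))
  for (grp in unique(g)) {
    idx <- which(g == grp)
    v <- results$mdi[idx]
    if (length(idx) < 2 || max(v) == min(v))
      stop_scanstab(sprintf(
        "degenerate standardization group '%s' (n = %d, all MDI equal: %s)",
        grp, length(idx), max(v) == min(v)), "scanstab_degenerate_group_error")
    lo[idx] <- min(v); hi[idx] <- max(v)
    smdi[idx] <- (v - min(v)) / (max(v) - min(v))
  }
  results$smdi <- smdi
  results$group_min_mdi <- lo
  results$group_max_mdi <- hi
  results
}

#' MDI and SMDI for every acquisition of a collection
#'
#' Computes `MD_LP`, `MD_RP` and `MDI` per acquisition over one pivot window,
#' then standardizes to SMDI within groups.  Note the pivot naming: the left
#' pivot is the window endpoint at the lower wavenumber on the canonical
#' ascending axis.  In wavelength terms that is the *longer*-wavelength end,
#' i.e. possibly mirrored relative to formulations written against wavelength;
#' this only flips the sign of every MDI in a group, which maps SMDI to
#' `1 - SMDI` and leaves all spread statistics unchanged.
#'
#' @param x a [spectra_collection()]
#' @param window `NULL` for the full acquired range, or `c(lo, hi)` in cm^-1
#' @param x_unit `"index"` (channel offsets 0..W within the window; default) or
#'   `"axis_value"` (offsets in cm^-1)
#' @param group_by metadata column defining the SMDI standardization groups
#' @return data.frame with one row per acquisition, ordered by
#'   (sample_id, scan_setting, replicate): acquisition metadata plus `md_lp`,
#'   `md_rp`, `mdi`, `smdi`, `group_min_mdi`, `group_max_mdi`.  The window and
#'   offset unit used are recorded as attributes `window` and `x_unit`.
#' @export
batch_mdi <- function(x, window = NULL, x_unit = c("index", "axis_value"),
                      group_by = "sample_id") {
  assert_that(inherits(x, "spectra_collection"),
              "x must be a spectra_collection", "scanstab_usage_error")
  x_unit <- match.arg(x_unit)
  if (!is.null(window)) x <- select_window(x, window[1], window[2])
  d <- if (x_unit == "index") seq_len(length(x$wavenumber)) - 1
       else x$wavenumber - x$wavenumber[1]
  W <- d[length(d)]
  I2 <- x$intensity^2
  md_lp <- colSums(sqrt(I2 + d^2))
  md_rp <- colSums(sqrt(I2 + (W - d)^2))
  res <- cbind(x$meta,
               data.frame(md_lp = md_lp, md_rp = md_rp, mdi = md_rp - md_lp,
                          row.names = NULL))
  res <- smdi_standardize(res, group_by = group_by)
  res <- res[order(res$sample_id, res$scan_setting, res$replicate), ]
  rownames(res) <- NULL
  attr(res, "window") <- range(x$wavenumber)
  attr(res, "x_unit") <- x_unit
  res
}

#' Write an SMDI table as CSV
#'
#' @param results data.frame from [batch_mdi()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_smdi_table <- function(results, path) {
  cols <- c("acquisition_id", "sample_id", "scan_setting", "replicate",
            "soil_type", "md_lp", "md_rp", "mdi", "smdi",
            "group_min_mdi", "group_max_mdi")
  out <- results[, intersect(cols, names(results)), drop = FALSE]
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], format_full)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
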