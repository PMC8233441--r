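#' Read spectra from a wide delimited table plus a metadata table
#'
#' The spectral file is comma-separated with first column `wavenumber_cm-1`
#' and one column per acquisition; the metadata file has columns
#' `acquisition_id, sample_id, scan_setting, replicate` and optionally
#' `soil_type`, with `acquisition_id` matching the spectral column headers.
#' A descending (4000 -> 600) axis is accepted and canonicalized to ascending.
#'
#' @param path path to the wide spectral CSV
#' @param meta_path path to the acquisition metadata CSV
#' @param intensity_unit unit tag to attach (`"absorbance"` or `"reflectance"`)
#' @return a [spectra_collection()]
#' @export
read_wide_table <- function(path, meta_path, intensity_unit = "absorbance") {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  assert_that(ncol(raw) >= 2, "spectral file needs a wavenumber column and at least one spectrum",
              "scanstab_format_error")
  for (j in seq_len(ncol(raw))) {
    col <- raw[[j]]
    if (!is.numeric(col))
      stop_scanstab(sprintf("column '%s' is not numeric (ragged or malformed input)",
                            names(raw)[j]), "scanstab_format_error")
    if (anyNA(col))
      stop_scanstab(sprintf("column '%s' has %d missing value(s) (ragged input?)",
                            names(raw)[j], sum(is.na(col))), "scanstab_format_error")
  }
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  ids <- names(raw)[-1]
  assert_that(setequal(ids, meta$acquisition_id),
              "spectral column headers and metadata acquisition_id do not match",
              "scanstab_format_error")
  meta <- meta[match(ids, meta$acquisition_id), , drop = FALSE]
  spectra_collection(raw[[1]], as.matrix(raw[, -1, drop = FALSE]), meta,
                     intensity_unit = intensity_unit)
}

#' Write a collection as wide spectral CSV + metadata CSV
#'
#' Values are written with 17 significant digits so that
#' `read_wide_table(write_wide_table(x))` reproduces `x` bit-identically.
#'
#' @param x a [spectra_collection()]
#' @param path output path for the spectral CSV
#' @param meta_path output path for the metadata CSV
#' @return `path`, invisibly
#' @export
write_wide_table <- function(x, path, meta_path) {
  assert_that(inherits(x, "spectra_collection") && n_spectra(x) >= 1,
              "need a non-empty spectra_collection", "scanstab_usage_error")
  out <- cbind(format_full(x$wavenumber),
               apply(x$intensity, 2, format_full))
  colnames(out) <- c("wavenumber_cm-1", x$meta$acquisition_id)
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  utils::write.csv(x$meta, meta_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a single-spectrum JCAMP-DX file
#'
#' Minimal importer for uncompressed single-block JCAMP-DX: `##XYDATA=(X++(Y..Y))`
#' with plain (AFFN) numbers, the common export dialect of FTIR instruments.
#' Compressed (SQZ/DIF/DUP) encodings and multi-block files are not supported.
#'
#' @param path path to the `.jdx` file
#' @param meta single-row data.frame of acquisition metadata; defaults to an
#'   id derived from the file name
#' @return a [spectra_collection()] with one spectrum
#' @export
read_jdx <- function(path, meta = NULL) {
  lines <- readLines(path, warn = FALSE)
  start <- grep("^##XYDATA=\\(X\\+\\+\\(Y\\.\\.Y\\)\\)", lines)
  assert_that(length(start) == 1,
              "need exactly one ##XYDATA=(X++(Y..Y)) block", "scanstab_format_error")
  stop_at <- grep("^##END", lines)
  stop_at <- min(stop_at[stop_at > start], length(lines) + 1)
  body <- lines[(start + 1):(stop_at - 1)]
  body <- body[!grepl("^##", body) & nzchar(trimws(body))]

  get_field <- function(name, default = NA_real_) {
    m <- grep(paste0("^##", name, "="), lines, value = TRUE)
    if (!length(m)) return(default)
    as.numeric(sub(paste0("^##", name, "="), "", m[1]))
  }
  xfactor <- get_field("XFACTOR", 1)
  yfactor <- get_field("YFACTOR", 1)

  xs <- numeric(0); ys <- numeric(0)
  for (ln in body) {
    vals <- as.numeric(strsplit(trimws(ln), "[ \t,]+")[[1]])
    assert_that(!anyNA(vals) && length(vals) >= 2,
                "unparseable XYDATA line (compressed dialects unsupported)",
                "scanstab_format_error")
    x0 <- vals[1]
    yv <- vals[-1]
    npt <- length(yv)
    ## per-line abscissa: x0 plus the nominal DELTAX step for following points
    dx <- get_field("DELTAX", NA_real_)
    if (is.na(dx)) {
      first <- get_field("FIRSTX"); last <- get_field("LASTX"); n <- get_field("NPOINTS")
      assert_that(!anyNA(c(first, last, n)),
                  "need DELTAX or FIRSTX/LASTX/NPOINTS", "scanstab_format_error")
      dx <- (last - first) / (n - 1)
    }
    xs <- c(xs, (x0 + dx * (seq_len(npt) - 1)) * xfactor)
    ys <- c(ys, yv * yfactor)
  }
  if (is.null(meta)) {
    id <- sub("\\.[^.]*$", "", basename(path))
    meta <- data.frame(acquisition_id = id, sample_id = id,
                       scan_setting = 1L, replicate = 1L,
                       stringsAsFactors = FALSE)
  }
  spectra_collection(xs, matrix(ys, ncol = 1), meta)
}
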