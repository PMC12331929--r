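#' Write / read a single trace as CSV
#'
#' Two-column CSV (`t_us`, `mv`) with the sampling rate recoverable from the
#' time axis; the plain-text exchange format for A-scans.
#'
#' @param tr a [raw_trace()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(tr, path) {
  utils::write.csv(data.frame(t_us = trace_time_us(tr), mv = tr$mv),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("t_us", "mv") %in% names(df)))
    stop("trace CSV needs columns `t_us` and `mv`")
  dt <- stats::median(diff(df$t_us))
  raw_trace(df$mv, fs_ghz = 1e-3 / dt, t0_us = df$t_us[1])
}

#' Write an experiment result
#'
#' Writes the condition table as CSV plus a JSON provenance sidecar
#' (kind, seed, fit estimates, floors/crossings where present).
#'
#' @param x a `"pam_experiment"`.
#' @param dir output directory (created if missing).
#' @param stem file stem; default the experiment kind.
#' @return the CSV path, invisibly.
#' @export
write_experiment <- function(x, dir, stem = x$kind) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(stem, ".csv"))
  utils::write.csv(x$table, csv, row.names = FALSE)
  meta <- list(kind = x$kind, seed = x$seed)
  if (!is.null(x$fit)) meta$fit <- as.list(x$fit$estimates)
  if (!is.null(x$floors)) meta$floors <- x$floors
  if (!is.null(x$crossings_um)) meta$crossings_um <- as.list(x$crossings_um)
  jsonlite::write_json(meta, file.path(dir, paste0(stem, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(csv)
}

#' Export an image (or phantom slices) as 32-bit TIFF
#'
#' Pixel values are scaled into `[0, 1]` for the TIFF container; the scale
#' and offset are recorded in a JSON sidecar so values round-trip.
#'
#' @param img a [pa_image()], numeric matrix, or 3D array (multi-page).
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(img, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF export")
  x <- if (inherits(img, "pa_image")) img$pixels else img
  rng <- range(x)
  span <- if (diff(rng) > 0) diff(rng) else 1
  scaled <- (x - rng[1]) / span
  if (length(dim(scaled)) == 3) {
    pages <- lapply(seq_len(dim(scaled)[3]), function(i) scaled[, , i])
    tiff::writeTIFF(pages, path, bits.per.sample = 32)
  } else {
    tiff::writeTIFF(scaled, path, bits.per.sample = 32)
  }
  meta <- list(offset = rng[1], scale = span)
  if (inherits(img, "pa_image")) {
    meta$pitch_um_per_px <- img$pitch_um_per_px
    meta$channel <- img$channel
    meta$provenance <- img$provenance
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read ROI fluorescence traces from CSV
#'
#' One column per ROI, one row per time sample (an optional leading `t` or
#' `time` column is dropped), for [dff_and_correlation()].
#'
#' @param path CSV file path.
#' @return numeric samples x ROI matrix.
#' @export
read_roi_csv <- function(path) {
  df <- utils::read.csv(path)
  tcol <- tolower(names(df)) %in% c("t", "time", "t_s", "t_us")
  as.matrix(df[, !tcol, drop = FALSE])
}
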