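# Result export: the workflow's deliverable is a ZIP archive holding one
# binary PNG per segmentation mask plus the area and attenuation
# measurements as CSV.

.format_csv_row <- function(r) {
  paste(
    r$marker_id,
    r$slice_ref$series_uid %||% "",
    r$slice_ref$instance %||% "",
    r$pixel_count,
    sprintf("%.2f", r$area_mm2),
    sprintf("%.2f", r$area_cm2),
    if (is.na(r$mean_hu)) "" else sprintf("%.1f", r$mean_hu),
    sprintf("%g", r$window$lo),
    sprintf("%g", r$window$hi),
    sep = ",")
}

#' Write measurement rows as CSV text
#'
#' Locale-independent: dot decimal separator, comma delimiter, UTF-8, LF
#' line endings; areas with 2 decimals, HU with 1. Byte-identical across
#' platforms for identical inputs.
#'
#' @param results list of `marker_result`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_measurements_csv <- function(results, path) {
  header <- "marker_id,slice_series_uid,slice_instance,pixel_count,area_mm2,area_cm2,mean_hu,window_lo_hu,window_hi_hu"
  rows <- vapply(results, .format_csv_row, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a measurements CSV
#' @param path CSV written by [write_measurements_csv].
#' @return data.frame with one row per marker.
#' @export
read_measurements_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(slice_series_uid = "character"))
}

#' Export markers and masks to a ZIP archive
#'
#' The archive contains `masks/<marker_id>.png` (8-bit binary PNG, values
#' 0/1) and `measurements.csv` with one row per marker result.
#'
#' @param results list of `marker_result` from [measure]/[combine].
#' @param masks list of [roi_mask], keyed consistently with `results` by
#'   marker id; defaults to the restricted masks carried by the results.
#' @param out_path output `.zip` path.
#' @param extra named list of extra text files to include (name -> character
#'   content), e.g. provenance.
#' @return invisibly, `out_path`.
#' @export
export_results <- function(results, masks = NULL, out_path, extra = list()) {
  if (is.null(masks)) masks <- lapply(results, function(r) r$mask)
  stopifnot(length(results) == length(masks))
  keys <- vapply(results, function(r) {
    paste(r$marker_id, r$slice_ref$series_uid %||% "",
          r$slice_ref$instance %||% "")
  }, character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate marker_id on the same slice", call. = FALSE)
  }
  stage <- tempfile("export")
  dir.create(file.path(stage, "masks"), recursive = TRUE)
  on.exit(unlink(stage, recursive = TRUE))
  for (i in seq_along(results)) {
    png::writePNG(masks[[i]]$grid / 255,
                  file.path(stage, "masks",
                            paste0(results[[i]]$marker_id, ".png")))
  }
  write_measurements_csv(results, file.path(stage, "measurements.csv"))
  for (nm in names(extra)) {
    writeLines(extra[[nm]], file.path(stage, nm), useBytes = TRUE)
  }
  out_path <- normalizePath(out_path, mustWork = FALSE)
  zip::zip(out_path,
           files = list.files(stage, recursive = TRUE),
           root = stage, mode = "mirror")
  invisible(out_path)
}

#' Import a mask PNG back as an ROI
#'
#' All non-zero pixels become 1. The PNG shape must match the slice.
#'
#' @param path PNG path.
#' @param slice the [ct_slice] the mask belongs to.
#' @param label region label.
#' @return a [roi_mask].
#' @export
import_mask_png <- function(path, slice, label = "") {
  mask <- .decode_png_mask(readBin(path, "raw", n = file.info(path)$size))
  if (nrow(mask) != slice$rows || ncol(mask) != slice$cols) {
    stop(sprintf("mask shape %dx%d does not match slice %dx%d",
                 nrow(mask), ncol(mask), slice$rows, slice$cols),
         call. = FALSE)
  }
  roi_mask(mask, label, slice)
}
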