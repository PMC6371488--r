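#' Assemble a CT volume from a series
#'
#' Stacks the HU-converted slices of a sorted series into a 3-D grid
#' (z, row, col). Requires at least two slices with uniform spacing:
#' consecutive projection gaps must agree with the median gap within 10%.
#'
#' @param series a `ct_series` from [sort_slices] or [read_dicom_dir].
#' @return a `ct_volume`: list with `hu_grid` (nz x rows x cols array),
#'   `spacing_mm` (dz, dy, dx), `origin_mm`, and `source` (the series).
#' @export
build_volume <- function(series) {
  stopifnot(inherits(series, "ct_series"))
  n <- length(series$slices)
  if (n < 2) stop("need at least 2 slices to build a volume", call. = FALSE)
  proj <- vapply(series$slices, function(s) sum(s$position_mm * series$normal),
                 numeric(1))
  gaps <- diff(proj)
  med <- stats::median(gaps)
  if (any(abs(gaps - med) > 0.1 * med)) {
    stop(sprintf("irregular spacing: gaps (mm) = %s",
                 paste(signif(gaps, 6), collapse = ", ")), call. = FALSE)
  }
  s1 <- series$slices[[1]]
  grid <- array(NA_real_, dim = c(n, s1$rows, s1$cols))
  for (k in seq_len(n)) grid[k, , ] <- to_hu(series$slices[[k]])
  structure(list(
    hu_grid = grid,
    spacing_mm = c(med, s1$pixel_spacing_row_mm, s1$pixel_spacing_col_mm),
    origin_mm = s1$position_mm,
    source = series
  ), class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$hu_grid)
  cat(sprintf("<ct_volume> %d x %d x %d (z,row,col), spacing %.4g/%.4g/%.4g mm\n",
              d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  invisible(x)
}

#' Extract a sagittal plane for level selection
#'
#' Native-grid extraction: the returned plane is `hu_grid[, , x_index]` with
#' no interpolation; the `aspect` field (dz/dy) lets a renderer correct for
#' anisotropic voxels.
#'
#' @param volume a `ct_volume`.
#' @param x_index column index (1-based).
#' @return list of class `sagittal_view` with `plane` (nz x rows matrix,
#'   row k = column `x_index` of slice k), `aspect`, and `x_index`.
#' @export
sagittal_view <- function(volume, x_index) {
  d <- dim(volume$hu_grid)
  if (x_index < 1 || x_index > d[3]) {
    stop(sprintf("x_index %d out of range [1, %d]", x_index, d[3]),
         call. = FALSE)
  }
  structure(list(
    plane = volume$hu_grid[, , x_index, drop = TRUE],
    aspect = volume$spacing_mm[1] / volume$spacing_mm[2],
    x_index = x_index
  ), class = "sagittal_view")
}

#' Write a sagittal view to PNG for visual QC
#'
#' 8-bit window/level mapping; pixels are not resampled, so the image is
#' anisotropic unless the viewer applies `aspect`.
#'
#' @param view a `sagittal_view`.
#' @param path output PNG path.
#' @param window_center,window_width display window in HU.
#' @export
write_sagittal_png <- function(view, path, window_center = 40,
                               window_width = 400) {
  lo <- window_center - window_width / 2
  img <- (view$plane - lo) / window_width
  img[img < 0] <- 0; img[img > 1] <- 1
  png::writePNG(img, path)
  invisible(path)
}

#' Select the working axial slice at a chosen level
#'
#' Returns the original slice (never an interpolated plane) nearest the
#' requested position. The z axis runs from the most-negative projection
#' along the stack normal (slice 1) upward; when a position in mm falls
#' exactly midway between two slices, the lower index wins.
#'
#' @param volume a `ct_volume`.
#' @param index 1-based slice index, or
#' @param mm position in mm as a projection along the stack normal.
#'   Exactly one of `index` and `mm` must be given.
#' @return the chosen `ct_slice`, with a `level` attribute recording the
#'   chosen index and the request.
#' @export
select_level <- function(volume, index = NULL, mm = NULL) {
  series <- volume$source
  n <- length(series$slices)
  if (is.null(index) == is.null(mm)) {
    stop("give exactly one of `index` or `mm`", call. = FALSE)
  }
  if (!is.null(index)) {
    if (index < 1 || index > n) {
      stop(sprintf("level index %s out of range [1, %d]", index, n),
           call. = FALSE)
    }
    k <- as.integer(index)
  } else {
    proj <- vapply(series$slices, function(s) sum(s$position_mm * series$normal),
                   numeric(1))
    if (mm < min(proj) - volume$spacing_mm[1] ||
        mm > max(proj) + volume$spacing_mm[1]) {
      stop(sprintf("level %g mm outside volume extent [%g, %g]",
                   mm, min(proj), max(proj)), call. = FALSE)
    }
    k <- which.min(abs(proj - mm))  # which.min takes the first (lower) index
  }
  out <- series$slices[[k]]
  attr(out, "level") <- list(index = k, requested_index = index,
                             requested_mm = mm)
  out
}
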