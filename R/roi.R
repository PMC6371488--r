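#' Hounsfield-unit window
#'
#' An inclusive attenuation interval defining a tissue class.
#'
#' @param lo,hi inclusive HU bounds, `lo <= hi`.
#' @param name label for reports.
#' @return object of class `hu_window`.
#' @export
hu_window <- function(lo, hi, name = "") {
  stopifnot(lo <= hi)
  structure(list(lo = lo, hi = hi, name = name), class = "hu_window")
}

#' @export
print.hu_window <- function(x, ...) {
  cat(sprintf("<hu_window> %s [%g, %g] HU\n", x$name, x$lo, x$hi))
  invisible(x)
}

#' Preset tissue windows
#'
#' The standard single-slice morphomics attenuation ranges: fat
#' -190..-30 HU, lumbar skeletal muscle -29..+150 HU, thoracic muscle
#' -129..+150 HU. Bounds are inclusive on both ends.
#'
#' @return named list of [hu_window] objects: `FAT`, `MUSCLE_LUMBAR`,
#'   `MUSCLE_THORACIC`.
#' @export
preset_windows <- function() {
  list(FAT = hu_window(-190, -30, "FAT"),
       MUSCLE_LUMBAR = hu_window(-29, 150, "MUSCLE_LUMBAR"),
       MUSCLE_THORACIC = hu_window(-129, 150, "MUSCLE_THORACIC"))
}

#' Binary region-of-interest mask
#'
#' @param grid 0/1 matrix, same shape as its slice.
#' @param label marker or region label.
#' @param slice_ref provenance list (`series_uid`, `instance`), or a
#'   [ct_slice] from which it is taken.
#' @return object of class `roi_mask`.
#' @export
roi_mask <- function(grid, label = "", slice_ref = NULL) {
  stopifnot(is.matrix(grid), all(grid %in% c(0L, 1L)))
  if (inherits(slice_ref, "ct_slice")) {
    slice_ref <- list(series_uid = slice_ref$series_uid,
                      instance = slice_ref$instance_number)
  }
  structure(list(grid = matrix(as.integer(grid), nrow(grid), ncol(grid)),
                 label = label, slice_ref = slice_ref),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> '%s' %dx%d, %d px set\n", x$label,
              nrow(x$grid), ncol(x$grid), sum(x$grid)))
  invisible(x)
}

#' An empty mask matching a slice or HU grid
#' @param x a [ct_slice] or an HU matrix.
#' @param label region label.
#' @return an all-zero [roi_mask].
#' @export
empty_mask <- function(x, label = "") {
  if (inherits(x, "ct_slice")) {
    roi_mask(matrix(0L, x$rows, x$cols), label, x)
  } else {
    roi_mask(matrix(0L, nrow(x), ncol(x)), label)
  }
}

# 0/1 logical disc of pixel centers within radius_px of center (row, col),
# Euclidean distance in pixel units.
.disc <- function(dim, center, radius_px) {
  r <- .row(dim); cc <- .col(dim)
  (r - center[1])^2 + (cc - center[2])^2 <= radius_px^2
}

.check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("shape mismatch: %s vs %s",
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")),
         call. = FALSE)
  }
}

#' Threshold brush: paint in-window pixels under a disc
#'
#' Sets to 1 every pixel whose center lies within `radius_px` (Euclidean,
#' pixel units) of `center` and whose HU falls inside `window`; all other
#' pixels are left unchanged. The brush is monotone: it never clears pixels
#' and can never add an out-of-window pixel.
#'
#' @param mask a [roi_mask].
#' @param hu HU matrix, same shape.
#' @param center (row, col) of the brush center.
#' @param radius_px brush radius in pixels, > 0.
#' @param window a [hu_window].
#' @return the updated [roi_mask].
#' @export
threshold_brush <- function(mask, hu, center, radius_px, window) {
  stopifnot(radius_px > 0)
  .check_same_shape(mask$grid, hu)
  if (center[1] < 1 || center[1] > nrow(hu) ||
      center[2] < 1 || center[2] > ncol(hu)) {
    stop("brush center outside the grid", call. = FALSE)
  }
  hit <- .disc(dim(hu), center, radius_px) & hu >= window$lo & hu <= window$hi
  g <- mask$grid
  g[hit] <- 1L
  roi_mask(g, mask$label, mask$slice_ref)
}

#' Eraser: clear all pixels under a disc
#'
#' Removes every pixel within the disc regardless of HU (monotone
#' decreasing, idempotent).
#'
#' @inheritParams threshold_brush
#' @return the updated [roi_mask].
#' @export
eraser <- function(mask, center, radius_px) {
  g <- mask$grid
  g[.disc(dim(g), center, radius_px)] <- 0L
  roi_mask(g, mask$label, mask$slice_ref)
}

#' Intersect a mask with an HU window
#'
#' `mask AND (lo <= hu <= hi)`; guarantees marker arithmetic only counts
#' in-window pixels.
#'
#' @inheritParams threshold_brush
#' @return the restricted [roi_mask].
#' @export
restrict_to_window <- function(mask, hu, window) {
  .check_same_shape(mask$grid, hu)
  g <- mask$grid
  g[!(hu >= window$lo & hu <= window$hi)] <- 0L
  roi_mask(g, mask$label, mask$slice_ref)
}
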