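# Computer-assisted segmentation of abdominal fat and muscle compartments.
#
# Strategy: extract the body as the largest 8-connected above-air component
# with interior holes filled, then locate the muscular abdominal wall in
# pseudo-polar coordinates: HU profiles are sampled along rays from the body
# centroid, and on each ray the wall is the first sufficiently long run of
# muscle-window samples encountered when moving inward from the skin. The
# per-angle radii split the body into a subcutaneous compartment (outside
# the wall), the wall band itself, and a visceral compartment (inside the
# wall); fat-window pixels in the first and last give SFA and VFA.

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that
# touch diagonally are merged with a union-find pass.
.label8 <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  parent <- seq_len(nlab)
  find <- function(x) { while (parent[x] != x) x <- parent[x] <<- parent[parent[x]]; x }
  if (nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  map <- vapply(seq_len(nlab), find, integer(1))
  lab[lab > 0L] <- map[lab[lab > 0L]]
  lab
}

#' Extract the body from an axial CT slice
#'
#' Pixels above the air threshold (-500 HU) are candidate foreground; the
#' largest 8-connected component is kept and its interior holes (e.g. bowel
#' gas) are filled, yielding a single connected body region.
#'
#' @param hu HU matrix.
#' @param air_threshold_hu foreground threshold; default -500 HU, midway
#'   between air/lung and fat.
#' @return a [roi_mask] labelled `"body"`.
#' @export
body_mask <- function(hu, air_threshold_hu = -500) {
  fg <- hu > air_threshold_hu
  if (!any(fg)) stop("no body found: image is entirely air", call. = FALSE)
  lab <- .label8(fg)
  counts <- tabulate(lab[lab > 0L])
  keep <- which.max(counts)
  body <- lab == keep
  body <- as.matrix(EBImage::fillHull(EBImage::Image(body * 1))) > 0
  roi_mask(body * 1L, "body")
}

#' Detect the muscular abdominal wall in pseudo-polar coordinates
#'
#' For each of `n_rays` angles (evenly spaced over the circle), HU values
#' are sampled every `step_px` pixels along the ray from the body centroid,
#' by nearest-pixel lookup. Moving inward from the skin (the outermost body
#' pixel on the ray), the wall's outer edge is the first position starting a
#' run of at least `min_run_px` consecutive pixels inside the lumbar muscle
#' window, and the wall's inner edge is where that run ends. Rays on which
#' no run is found (e.g. through a wall defect) get both wall radii
#' interpolated circularly from their neighbours, and all per-angle radii
#' are finally smoothed with a circular median filter.
#'
#' @param hu HU matrix.
#' @param body body mask from [body_mask]; its centroid is the ray origin.
#' @param n_rays number of rays (>= 36).
#' @param min_run_px minimum muscle run length, in pixels, to accept a wall
#'   crossing.
#' @param window muscle window; default MUSCLE_LUMBAR.
#' @param smooth_width circular median filter width (rays; odd).
#' @param step_px radial sampling step in pixels.
#' @return object of class `polar_boundary`: `center`, `angles`, and
#'   per-angle radii `outer_radius_px` (skin), `wall_outer_radius_px` and
#'   `inner_radius_px` (wall outer/inner edges).
#' @export
detect_wall <- function(hu, body, n_rays = 360L, min_run_px = 3L,
                        window = preset_windows()$MUSCLE_LUMBAR,
                        smooth_width = 5L, step_px = 0.5) {
  stopifnot(n_rays >= 36L, min_run_px >= 1L, smooth_width %% 2L == 1L)
  .check_same_shape(body$grid, hu)
  bpix <- which(body$grid == 1L, arr.ind = TRUE)
  center <- c(mean(bpix[, 1]), mean(bpix[, 2]))
  angles <- 2 * pi * (seq_len(n_rays) - 1L) / n_rays

  nr <- nrow(hu); nc <- ncol(hu)
  rmax <- sqrt(max((c(1, nr) - center[1])^2) + max((c(1, nc) - center[2])^2))
  radii <- seq(0, rmax, by = step_px)
  ns <- length(radii)

  # sample grids for all rays at once: ns x n_rays matrices of pixel indices
  rowm <- round(outer(radii, sin(angles)) + center[1])
  colm <- round(outer(radii, cos(angles)) + center[2])
  ok <- rowm >= 1 & rowm <= nr & colm >= 1 & colm <= nc
  idx <- (colm - 1L) * nr + rowm
  idx[!ok] <- 1L
  body_s <- matrix(body$grid[idx] == 1L & ok, ns, n_rays)
  musc_s <- matrix(hu[idx] >= window$lo & hu[idx] <= window$hi & ok, ns, n_rays)

  outer_r <- apply(body_s, 2, function(v) if (any(v)) radii[max(which(v))] else NA_real_)
  if (mean(outer_r, na.rm = TRUE) < 10) {
    stop("body too small to trace (< 10 px mean radius)", call. = FALSE)
  }

  run_min <- max(1L, ceiling(min_run_px / step_px))
  wall_out <- rep(NA_real_, n_rays)
  wall_in <- rep(NA_real_, n_rays)
  for (j in seq_len(n_rays)) {
    if (is.na(outer_r[j])) next
    i_skin <- max(which(body_s[, j]))
    m <- musc_s[seq_len(i_skin), j]
    # walk inward: reverse so index 1 = skin
    mr <- rev(m)
    r <- rle(mr)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= run_min)
    if (length(hit) == 0L) next
    h <- hit[1L]
    # positions (1-based from skin) back to radii: sample i from skin maps to
    # radius index i_skin - pos + 1
    wall_out[j] <- radii[i_skin - starts[h] + 1L]
    wall_in[j] <- radii[i_skin - ends[h] + 1L]
  }

  wall_out <- .circ_fill(wall_out)
  wall_in <- .circ_fill(wall_in)
  if (all(is.na(wall_in))) {
    stop("no muscle wall found on any ray", call. = FALSE)
  }
  wall_out <- .circ_median(wall_out, smooth_width)
  wall_in <- .circ_median(wall_in, smooth_width)
  outer_r <- .circ_median(outer_r, smooth_width)
  wall_in <- pmin(wall_in, wall_out)

  structure(list(center = center, angles = angles,
                 outer_radius_px = outer_r,
                 wall_outer_radius_px = wall_out,
                 inner_radius_px = wall_in,
                 n_rays = n_rays), class = "polar_boundary")
}

# Circular linear interpolation of NA entries from the nearest valid
# neighbours on each side.
.circ_fill <- function(x) {
  n <- length(x)
  na <- which(is.na(x))
  if (length(na) == 0L || length(na) == n) return(x)
  valid <- which(!is.na(x))
  for (i in na) {
    d_prev <- (i - valid) %% n
    d_next <- (valid - i) %% n
    p <- valid[which.min(replace(d_prev, d_prev == 0, n))]
    q <- valid[which.min(replace(d_next, d_next == 0, n))]
    dp <- (i - p) %% n; dq <- (q - i) %% n
    x[i] <- (x[p] * dq + x[q] * dp) / (dp + dq)
  }
  x
}

# Circular median filter of odd width w.
.circ_median <- function(x, w) {
  n <- length(x)
  h <- (w - 1L) %/% 2L
  xx <- c(x[(n - h + 1L):n], x, x[1L:h])
  vapply(seq_len(n), function(i) stats::median(xx[i:(i + 2L * h)], na.rm = TRUE),
         numeric(1))
}

# Interpolate per-angle radii at arbitrary angles (circular, linear).
.interp_circular <- function(angles, values, theta) {
  n <- length(angles)
  stats::approx(x = c(angles, angles[1] + 2 * pi), y = c(values, values[1]),
                xout = theta %% (2 * pi), rule = 2)$y
}

#' Segment abdominal fat and muscle compartments
#'
#' Runs [body_mask] and [detect_wall], then partitions the body by pixel
#' radius relative to the per-angle wall radii: the subcutaneous compartment
#' lies outside the wall's outer edge, the visceral compartment inside the
#' wall's inner edge (the wall band itself belongs to neither, so
#' intramuscular fat is excluded from both SFA and VFA). Fat-window pixels
#' in each compartment give `sfa` and `vfa`; `tama` collects all
#' muscle-window pixels in the body.
#'
#' @param hu HU matrix.
#' @param n_rays,min_run_px passed to [detect_wall].
#' @param windows preset windows list (FAT and MUSCLE_LUMBAR are used).
#' @return list with [roi_mask] elements `sfa`, `vfa`, `tama`, plus `body`
#'   and the `boundary` (`polar_boundary`).
#' @export
segment_compartments <- function(hu, n_rays = 360L, min_run_px = 3L,
                                 windows = preset_windows()) {
  body <- body_mask(hu)
  pb <- detect_wall(hu, body, n_rays = n_rays, min_run_px = min_run_px,
                    window = windows$MUSCLE_LUMBAR)
  nr <- nrow(hu); nc <- ncol(hu)
  dr <- .row(c(nr, nc)) - pb$center[1]
  dc <- .col(c(nr, nc)) - pb$center[2]
  rad <- sqrt(dr^2 + dc^2)
  theta <- atan2(dr, dc)
  wall_out_t <- matrix(.interp_circular(pb$angles, pb$wall_outer_radius_px, theta),
                       nr, nc)
  wall_in_t <- matrix(.interp_circular(pb$angles, pb$inner_radius_px, theta),
                      nr, nc)
  bodyg <- body$grid == 1L
  fat <- hu >= windows$FAT$lo & hu <= windows$FAT$hi
  musc <- hu >= windows$MUSCLE_LUMBAR$lo & hu <= windows$MUSCLE_LUMBAR$hi
  subcut <- bodyg & rad > wall_out_t
  visceral <- bodyg & rad < wall_in_t
  list(sfa = roi_mask((subcut & fat) * 1L, "SFA"),
       vfa = roi_mask((visceral & fat) * 1L, "VFA"),
       tama = roi_mask((bodyg & musc) * 1L, "TAMA"),
       body = body, boundary = pb)
}

#' Segment total abdominal fat
#'
#' All fat-window pixels inside the body mask. Unlike [segment_compartments]
#' no wall partition is applied, so intramuscular fat is included — matching
#' the total abdominal fat definition (visceral + subcutaneous +
#' intramuscular).
#'
#' @param hu HU matrix.
#' @param windows preset windows list.
#' @return a [roi_mask] labelled `"TAA"`.
#' @export
segment_tat <- function(hu, windows = preset_windows()) {
  body <- body_mask(hu)
  fat <- hu >= windows$FAT$lo & hu <= windows$FAT$hi
  roi_mask((body$grid == 1L & fat) * 1L, "TAA")
}

#' Registry of the built-in segmenters
#'
#' Named list of segmentation functions (`hu matrix -> 0/1 matrix`) exposed
#' by the reference plugin server: `sfa`, `vfa`, `taa`, `muscle`.
#' @return named list of functions.
#' @export
autoseg_registry <- function() {
  list(
    sfa = function(hu) segment_compartments(hu)$sfa$grid,
    vfa = function(hu) segment_compartments(hu)$vfa$grid,
    taa = function(hu) segment_tat(hu)$grid,
    muscle = function(hu) segment_compartments(hu)$tama$grid
  )
}
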