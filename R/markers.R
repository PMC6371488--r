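#' Measure one morphomic marker from a mask
#'
#' The mask is first restricted to the marker's tissue window, so stray
#' out-of-window pixels in a manually drawn ROI never contribute to either
#' the area or the mean attenuation. Area follows directly from the pixel
#' count and the pixel spacing; the mean HU is taken over the restricted
#' mask and is absent (`NA`) when no pixel survives.
#'
#' @param mask a [roi_mask].
#' @param hu HU matrix, same shape as the mask.
#' @param window the marker's [hu_window].
#' @param spacing (row, col) pixel spacing in mm.
#' @param marker_id marker identifier (defaults to the mask label).
#' @return object of class `marker_result` with fields `marker_id`,
#'   `pixel_count`, `area_mm2`, `area_cm2`, `mean_hu`, `window`,
#'   `slice_ref`, plus the restricted mask and HU grid (used by [combine]).
#' @export
measure <- function(mask, hu, window, spacing, marker_id = mask$label) {
  stopifnot(length(spacing) == 2, all(spacing > 0))
  .check_same_shape(mask$grid, hu)
  restricted <- restrict_to_window(mask, hu, window)
  n <- sum(restricted$grid)
  area_mm2 <- n * spacing[1] * spacing[2]
  structure(list(
    marker_id = marker_id,
    pixel_count = n,
    area_mm2 = area_mm2,
    area_cm2 = area_mm2 / 100,
    mean_hu = if (n > 0) mean(hu[restricted$grid == 1L]) else NA_real_,
    window = window,
    slice_ref = mask$slice_ref,
    mask = restricted,
    hu = hu
  ), class = "marker_result")
}

#' @export
print.marker_result <- function(x, ...) {
  cat(sprintf("<marker_result> %s: %d px, %.2f cm^2, mean %s HU\n",
              x$marker_id, x$pixel_count, x$area_cm2,
              if (is.na(x$mean_hu)) "--" else sprintf("%.1f", x$mean_hu)))
  invisible(x)
}

#' Combine marker results over the union of their masks
#'
#' For markers defined as the combination of several regions (e.g. left and
#' right psoas). Pixel counts and areas are computed over the union of the
#' restricted masks, so overlapping pixels are counted once; the mean HU is
#' the mean over the union (equal to the count-weighted mean of the parts
#' when the parts are disjoint).
#'
#' @param results list of `marker_result` from [measure], sharing a slice
#'   and window.
#' @param target_id marker id of the combined result.
#' @return a `marker_result` for the union.
#' @export
combine <- function(results, target_id) {
  stopifnot(length(results) >= 1)
  w <- results[[1]]$window
  ref <- results[[1]]$slice_ref
  for (r in results) {
    if (r$window$lo != w$lo || r$window$hi != w$hi) {
      stop("window mismatch: cannot combine markers of different tissue classes",
           call. = FALSE)
    }
    if (!identical(r$slice_ref, ref)) {
      stop("slice mismatch: cannot combine markers across slices", call. = FALSE)
    }
  }
  u <- results[[1]]$mask$grid
  for (r in results[-1]) u <- pmax(u, r$mask$grid)
  sp_area <- results[[1]]$area_mm2 /
    max(results[[1]]$pixel_count, 1L)  # mm^2 per pixel
  # recover spacing product robustly even when the first part is empty
  if (results[[1]]$pixel_count == 0) {
    nz <- Filter(function(r) r$pixel_count > 0, results)
    sp_area <- if (length(nz)) nz[[1]]$area_mm2 / nz[[1]]$pixel_count else 0
  }
  n <- sum(u)
  hu <- results[[1]]$hu
  structure(list(
    marker_id = target_id,
    pixel_count = n,
    area_mm2 = n * sp_area,
    area_cm2 = n * sp_area / 100,
    mean_hu = if (n > 0) mean(hu[u == 1L]) else NA_real_,
    window = w,
    slice_ref = ref,
    mask = roi_mask(u, target_id, ref),
    hu = hu
  ), class = "marker_result")
}

#' Catalog of single-slice morphomic markers
#'
#' The sixteen marker identifiers covered by this package: paired area
#' (mm^2) and mean-attenuation (HU) markers for psoas, lumbar dorsal, total
#' lumbar and total thoracic muscle, and for visceral, subcutaneous, total
#' abdominal and epicardial fat. Each entry records its tissue window:
#' lumbar muscle markers use MUSCLE_LUMBAR, thoracic muscle MUSCLE_THORACIC,
#' and all fat markers FAT.
#'
#' @return named list: marker id -> list(definition, category, window).
#' @export
marker_catalog <- function() {
  w <- preset_windows()
  entry <- function(def, cat, win) list(definition = def, category = cat,
                                        window = win)
  list(
    PMA = entry("Psoas muscle area: combined area of the right and left psoas muscles, mm^2",
                "muscle(lumbar)", w$MUSCLE_LUMBAR),
    PMA_HU = entry("Psoas muscle attenuation: mean HU within the psoas muscles",
                   "muscle(lumbar)", w$MUSCLE_LUMBAR),
    LDMA = entry("Lumbar dorsal muscle area: muscle posterior to the spine and ribs, mm^2",
                 "muscle(lumbar)", w$MUSCLE_LUMBAR),
    LDMA_HU = entry("Lumbar dorsal muscle attenuation: mean HU within the dorsal muscles",
                    "muscle(lumbar)", w$MUSCLE_LUMBAR),
    TLMA = entry("Total lumbar muscle area: abdominal-wall plus psoas plus dorsal muscle, mm^2",
                 "muscle(lumbar)", w$MUSCLE_LUMBAR),
    TLMA_HU = entry("Total lumbar muscle attenuation: mean HU within the lumbar muscles",
                    "muscle(lumbar)", w$MUSCLE_LUMBAR),
    TTLMA = entry("Total thoracic muscle area: pectoralis, intercostal and paraspinal muscle, mm^2",
                  "muscle(thoracic)", w$MUSCLE_THORACIC),
    TTLMA_HU = entry("Total thoracic muscle attenuation: mean HU within the thoracic muscles",
                     "muscle(thoracic)", w$MUSCLE_THORACIC),
    VFA = entry("Visceral fat area: total intraperitoneal fat, mm^2",
                "fat(lumbar)", w$FAT),
    VFA_HU = entry("Visceral fat attenuation: mean HU within the visceral fat",
                   "fat(lumbar)", w$FAT),
    SFA = entry("Subcutaneous fat area: fat between the skin and the abdominal/back wall, mm^2",
                "fat(lumbar)", w$FAT),
    SFA_HU = entry("Subcutaneous fat attenuation: mean HU within the subcutaneous fat",
                   "fat(lumbar)", w$FAT),
    TAA = entry("Total abdominal fat area: visceral plus subcutaneous plus intramuscular fat, mm^2",
                "fat(lumbar)", w$FAT),
    TAA_HU = entry("Total abdominal fat attenuation: mean HU within the abdominal fat",
                   "fat(lumbar)", w$FAT),
    EFA = entry("Epicardial fat area: fat between the heart and the pericardium, mm^2",
                "fat(thoracic)", w$FAT),
    EFA_HU = entry("Epicardial fat attenuation: mean HU within the epicardial fat",
                   "fat(thoracic)", w$FAT)
  )
}
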