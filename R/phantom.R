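#' Parametric abdominal CT phantom
#'
#' Builds a synthetic axial slice at the L4 level with analytically known
#' geometry: an air background, an elliptical body whose outer band is a
#' subcutaneous fat ring, a muscular abdominal wall (elliptical annulus,
#' optionally with an angular gap), a visceral compartment containing a fat
#' lining along the wall plus scattered fat blobs over a soft-organ
#' background, two psoas-like muscle ellipses and a vertebral body at bone
#' attenuation. Each tissue class has a fixed HU value (chosen mid-window so
#' moderate Gaussian noise does not cross the Table-style HU class bounds),
#' and every class mask is exact ground truth.
#'
#' Geometry is parameterized as fractions of the body ellipse so a spec
#' scales cleanly to smaller grids for fast tests.
#'
#' @param size grid side in pixels (rows = cols = size).
#' @param pixel_spacing_mm (row, col) spacing in mm.
#' @param n_slices,slice_gap_mm stack depth and inter-slice gap.
#' @param body_semi_px body ellipse semi-axes (row, col) in px; default
#'   `round(c(0.47, 0.66) * size / 2)`.
#' @param wall_outer_frac,wall_inner_frac muscle wall annulus as fractions of
#'   the body semi-axes.
#' @param lining_frac inner edge of the visceral fat lining, as a fraction of
#'   the body semi-axes; must be < `wall_inner_frac`.
#' @param wall_gap_deg optional angular gap (degrees) in the muscle wall,
#'   centered on the +column axis; the gap is filled with fat.
#' @param visceral_fat_fraction fraction of the eligible visceral core
#'   assigned fat blobs (smoothed thresholded noise).
#' @param include_psoas,include_vertebra toggles for the interior organs.
#' @param hu named list of class attenuations (air, fat, muscle, organ, bone).
#' @param noise_sigma_hu per-pixel Gaussian HU noise SD (0 = noiseless).
#' @param blob_smooth_px Gaussian smoothing sigma for the blob field.
#' @param seed RNG seed; generation is deterministic given the spec.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 512L,
                         pixel_spacing_mm = c(0.7, 0.7),
                         n_slices = 20L,
                         slice_gap_mm = 2.5,
                         body_semi_px = NULL,
                         wall_outer_frac = 0.82,
                         wall_inner_frac = 0.70,
                         lining_frac = 0.64,
                         wall_gap_deg = 0,
                         visceral_fat_fraction = 0.30,
                         include_psoas = TRUE,
                         include_vertebra = TRUE,
                         hu = list(air = -1000, fat = -95, muscle = 45,
                                   organ = 35, bone = 700),
                         noise_sigma_hu = 0,
                         blob_smooth_px = size / 64,
                         seed = 1L) {
  if (is.null(body_semi_px)) body_semi_px <- round(c(0.47, 0.66) * size / 2)
  stopifnot(size >= 64, all(pixel_spacing_mm > 0), n_slices >= 1,
            slice_gap_mm > 0, length(body_semi_px) == 2,
            wall_inner_frac < wall_outer_frac, wall_outer_frac < 1,
            lining_frac < wall_inner_frac,
            visceral_fat_fraction >= 0, visceral_fat_fraction <= 1,
            noise_sigma_hu >= 0)
  if (hu$fat < -190 || hu$fat > -30) stop("fat HU must lie in [-190, -30]")
  if (hu$muscle < -29 || hu$muscle > 150) stop("muscle HU must lie in [-29, 150]")
  if (hu$air > -900) stop("air HU must be <= -900")
  if (max(body_semi_px) > size / 2 - 2) stop("body ellipse exceeds the grid")
  structure(as.list(environment()), class = "phantom_spec")
}

.ellipse_mask <- function(size, center, semi) {
  r <- .row(c(size, size)); cc <- .col(c(size, size))
  ((r - center[1]) / semi[1])^2 + ((cc - center[2]) / semi[2])^2 <= 1
}

# Restore the caller's RNG state on exit so generation is a pure function
# of the spec.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a phantom CT series with ground truth
#'
#' @param spec a [phantom_spec].
#' @return list with elements
#'   \describe{
#'     \item{series}{a `ct_series` of `n_slices` identical-geometry slices
#'       (independent noise per slice).}
#'     \item{hu}{the noiseless HU matrix shared by all slices.}
#'     \item{truth}{list of exact class masks (`body`, `sfa`, `vfa`, `wall`,
#'       `psoas`, `vertebra`, `tat`, `tama`) as 0/1 integer matrices,
#'       pixel-count areas in mm^2 (`areas_mm2`), and closed-form ellipse
#'       areas (`analytic_mm2`) for regions with an analytic formula.}
#'     \item{spec}{the input spec.}
#'   }
#' @export
phantom_generate <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  s <- spec
  size <- s$size
  center <- c((size + 1) / 2, (size + 1) / 2)
  body <- .ellipse_mask(size, center, s$body_semi_px)
  wall_o <- .ellipse_mask(size, center, s$body_semi_px * s$wall_outer_frac)
  wall_i <- .ellipse_mask(size, center, s$body_semi_px * s$wall_inner_frac)
  core_o <- .ellipse_mask(size, center, s$body_semi_px * s$lining_frac)

  ring <- body & !wall_o                # subcutaneous fat
  wall <- wall_o & !wall_i              # abdominal muscle wall
  lining <- wall_i & !core_o            # visceral fat lining the wall
  core <- core_o

  if (s$wall_gap_deg > 0) {
    r <- .row(c(size, size)); cc <- .col(c(size, size))
    theta <- atan2(r - center[1], cc - center[2]) * 180 / pi
    gap <- abs(theta) <= s$wall_gap_deg / 2
    lining <- lining | (wall & gap)     # gap filled with fat
    wall <- wall & !gap
  }

  psoas <- matrix(FALSE, size, size)
  vertebra <- matrix(FALSE, size, size)
  if (s$include_psoas) {
    semi <- round(c(0.17, 0.13) * s$body_semi_px)
    dy <- round(0.35 * s$body_semi_px[1]); dx <- round(0.33 * s$body_semi_px[2])
    psoas <- .ellipse_mask(size, center + c(dy, -dx), semi) |
      .ellipse_mask(size, center + c(dy, dx), semi)
  }
  if (s$include_vertebra) {
    semi <- round(c(0.20, 0.13) * s$body_semi_px)
    vertebra <- .ellipse_mask(size, center + c(round(0.42 * s$body_semi_px[1]), 0),
                              semi)
  }
  if (any(psoas & vertebra)) {
    stop("overlapping mandatory regions: psoas and vertebra intersect")
  }
  # tolerate rasterization spill at coarse grids, but reject genuine overlap
  for (nm in c("psoas", "vertebra")) {
    m <- get(nm)
    if (sum(m & !core) > 0.2 * sum(m)) {
      stop("overlapping mandatory regions: ", nm,
           " extends beyond the visceral core")
    }
  }
  psoas <- psoas & core
  vertebra <- vertebra & core

  eligible <- core & !psoas & !vertebra
  blobs <- matrix(FALSE, size, size)
  if (s$visceral_fat_fraction > 0 && any(eligible)) {
    blobs <- .with_seed(s$seed, {
      field <- matrix(stats::rnorm(size * size), size, size)
      sm <- as.matrix(EBImage::gblur(EBImage::Image(field), sigma = s$blob_smooth_px))
      thr <- stats::quantile(sm[eligible], 1 - s$visceral_fat_fraction)
      eligible & (sm >= thr)
    })
  }
  organ <- eligible & !blobs
  vfat <- lining | blobs

  hu <- matrix(s$hu$air, size, size)
  hu[ring] <- s$hu$fat
  hu[wall] <- s$hu$muscle
  hu[vfat] <- s$hu$fat
  hu[organ] <- s$hu$organ
  hu[psoas] <- s$hu$muscle
  hu[vertebra] <- s$hu$bone

  sp <- prod(s$pixel_spacing_mm)
  px_area <- function(m) sum(m) * sp
  a <- s$body_semi_px[1]; b <- s$body_semi_px[2]
  truth <- list(
    body = body * 1L, sfa = ring * 1L, vfa = vfat * 1L, wall = wall * 1L,
    psoas = psoas * 1L, vertebra = vertebra * 1L,
    tat = (ring | vfat) * 1L, tama = (wall | psoas) * 1L,
    areas_mm2 = list(
      body = px_area(body), SFA = px_area(ring), VFA = px_area(vfat),
      TAA = px_area(ring | vfat), TAMA = px_area(wall | psoas)),
    analytic_mm2 = list(
      body = pi * a * b * sp,
      SFA = pi * a * b * (1 - s$wall_outer_frac^2) * sp,
      wall = pi * a * b * (s$wall_outer_frac^2 - s$wall_inner_frac^2) * sp)
  )

  uid <- make_uid(s$seed, 1)
  slices <- .with_seed(s$seed + 1L, lapply(seq_len(s$n_slices), function(k) {
    hu_k <- hu
    if (s$noise_sigma_hu > 0) {
      hu_k <- hu_k + matrix(stats::rnorm(size * size, 0, s$noise_sigma_hu),
                            size, size)
    }
    stored <- round(hu_k) + 1024
    stored[stored < 0] <- 0
    ct_slice(matrix(as.integer(stored), size, size),
             pixel_spacing_mm = s$pixel_spacing_mm,
             rescale_slope = 1, rescale_intercept = -1024,
             position_mm = c(0, 0, (k - 1) * s$slice_gap_mm),
             orientation = c(1, 0, 0, 0, 1, 0),
             series_uid = uid, instance_number = k)
  }))

  list(series = sort_slices(slices), hu = hu, truth = truth, spec = s)
}

# Encode one ct_slice as Part 10 explicit-VR-LE bytes. Identifying fields
# are synthetic placeholders so the de-identification pipeline has material
# to strip in tests.
.encode_slice_dicom <- function(slice, study_uid, sop_uid,
                                patient_name = "PHANTOM^SYNTHETIC",
                                patient_id = "PHANTOM-0000") {
  stored <- t(slice$pixel_grid)            # serialize row-major
  px <- writeBin(as.integer(stored), raw(), size = 2L, endian = "little")
  data <- list(
    dcm_make(0x0008L, 0x0016L, "UI", SOP_CT_IMAGE),
    dcm_make(0x0008L, 0x0018L, "UI", sop_uid),
    dcm_make(0x0008L, 0x0060L, "CS", "CT"),
    dcm_make(0x0010L, 0x0010L, "PN", patient_name),
    dcm_make(0x0010L, 0x0020L, "LO", patient_id),
    dcm_make(0x0020L, 0x000DL, "UI", study_uid),
    dcm_make(0x0020L, 0x000EL, "UI", slice$series_uid),
    dcm_make(0x0020L, 0x0013L, "IS", as.character(slice$instance_number)),
    dcm_make(0x0020L, 0x0032L, "DS",
             formatC(slice$position_mm, format = "fg", digits = 10)),
    dcm_make(0x0020L, 0x0037L, "DS",
             formatC(slice$orientation, format = "fg", digits = 10)),
    dcm_make(0x0028L, 0x0002L, "US", 1L),
    dcm_make(0x0028L, 0x0004L, "CS", "MONOCHROME2"),
    dcm_make(0x0028L, 0x0010L, "US", slice$rows),
    dcm_make(0x0028L, 0x0011L, "US", slice$cols),
    dcm_make(0x0028L, 0x0030L, "DS",
             formatC(c(slice$pixel_spacing_row_mm, slice$pixel_spacing_col_mm),
                     format = "fg", digits = 10)),
    dcm_make(0x0028L, 0x0100L, "US", 16L),
    dcm_make(0x0028L, 0x0101L, "US", 16L),
    dcm_make(0x0028L, 0x0102L, "US", 15L),
    dcm_make(0x0028L, 0x0103L, "US", 0L),
    dcm_make(0x0028L, 0x1052L, "DS", as.character(slice$rescale_intercept)),
    dcm_make(0x0028L, 0x1053L, "DS", as.character(slice$rescale_slope)),
    dcm_element(0x7FE0L, 0x0010L, "OW", px)
  )
  meta <- list(
    dcm_make(0x0002L, 0x0001L, "OB", c(0L, 1L)),
    dcm_make(0x0002L, 0x0002L, "UI", SOP_CT_IMAGE),
    dcm_make(0x0002L, 0x0003L, "UI", sop_uid),
    dcm_make(0x0002L, 0x0010L, "UI", TS_EXPLICIT_LE),
    dcm_make(0x0002L, 0x0012L, "UI", make_uid(0))
  )
  dcm_serialize(meta, data, TS_EXPLICIT_LE)
}

#' Write a phantom to disk as DICOM plus ground truth
#'
#' Writes one Part 10 file per slice (explicit VR little endian, stored value
#' = HU + 1024 with RescaleIntercept -1024), each class mask as an 8-bit PNG,
#' and the area ground truth as `truth.json`.
#'
#' @param phantom result of [phantom_generate].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `dicom_dir` and `truth_dir` paths.
#' @export
phantom_write_dicom <- function(phantom, out_dir) {
  dicom_dir <- file.path(out_dir, "dicom")
  truth_dir <- file.path(out_dir, "truth")
  dir.create(dicom_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(truth_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dicom_dir)) stop("cannot create output directory")
  seed <- phantom$spec$seed
  study_uid <- make_uid(seed, 0)
  for (i in seq_along(phantom$series$slices)) {
    sl <- phantom$series$slices[[i]]
    bytes <- .encode_slice_dicom(sl, study_uid, make_uid(seed, 2, i),
                                 patient_id = sprintf("PHANTOM-%04d", seed))
    writeBin(bytes, file.path(dicom_dir, sprintf("slice_%03d.dcm", i)))
  }
  for (nm in c("body", "sfa", "vfa", "wall", "psoas", "vertebra", "tat", "tama")) {
    png::writePNG(phantom$truth[[nm]] / 255,
                  file.path(truth_dir, paste0(nm, ".png")))
  }
  jsonlite::write_json(
    list(areas_mm2 = phantom$truth$areas_mm2,
         analytic_mm2 = phantom$truth$analytic_mm2,
         pixel_spacing_mm = phantom$spec$pixel_spacing_mm,
         seed = seed),
    file.path(truth_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(dicom_dir = dicom_dir, truth_dir = truth_dir))
}
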