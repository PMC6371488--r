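#' @title CT slice and series containers
#' @description
#' A `ct_slice` holds one axial CT image: the stored pixel grid (pre-rescale
#' integers), acquisition geometry (pixel spacing, patient position and
#' orientation cosines), the HU rescale coefficients, and the original
#' encapsulated file bytes (kept so plugin calls can transmit the anonymized
#' original). A `ct_series` is an ordered stack of slices sharing geometry.
#' @name ct_containers
NULL

#' Construct a CT slice
#'
#' @param pixel_grid integer matrix (rows x cols) of stored pixel values.
#' @param pixel_spacing_mm numeric length-2, (row, col) spacing in mm/pixel.
#' @param rescale_slope,rescale_intercept HU transform: HU = stored * slope + intercept.
#' @param position_mm ImagePositionPatient, length-3 (mm).
#' @param orientation ImageOrientationPatient, 6 direction cosines
#'   (row axis then column axis).
#' @param series_uid,instance_number series membership and instance index.
#' @param source_bytes raw vector with the original DICOM file content
#'   (may be `NULL` for slices built in memory).
#' @param file originating path, used in diagnostics.
#' @return an object of class `ct_slice`.
#' @export
ct_slice <- function(pixel_grid, pixel_spacing_mm, rescale_slope = 1,
                     rescale_intercept = 0, position_mm = c(0, 0, 0),
                     orientation = c(1, 0, 0, 0, 1, 0),
                     series_uid = "", instance_number = NA_integer_,
                     source_bytes = NULL, file = NA_character_) {
  stopifnot(is.matrix(pixel_grid), nrow(pixel_grid) > 0, ncol(pixel_grid) > 0,
            length(pixel_spacing_mm) == 2, all(pixel_spacing_mm > 0),
            length(position_mm) == 3, length(orientation) == 6)
  r <- orientation[1:3]; cvec <- orientation[4:6]
  if (abs(sqrt(sum(r^2)) - 1) > 1e-3 || abs(sqrt(sum(cvec^2)) - 1) > 1e-3) {
    stop("orientation axes must be unit vectors", call. = FALSE)
  }
  if (abs(sum(r * cvec)) > 1e-3) {
    stop("orientation axes must be orthogonal", call. = FALSE)
  }
  structure(list(
    pixel_grid = pixel_grid,
    rows = nrow(pixel_grid), cols = ncol(pixel_grid),
    pixel_spacing_row_mm = pixel_spacing_mm[1],
    pixel_spacing_col_mm = pixel_spacing_mm[2],
    rescale_slope = rescale_slope, rescale_intercept = rescale_intercept,
    position_mm = as.numeric(position_mm),
    orientation = as.numeric(orientation),
    series_uid = series_uid, instance_number = instance_number,
    source_bytes = source_bytes, file = file
  ), class = "ct_slice")
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("<ct_slice> %dx%d px, spacing %.4gx%.4g mm, instance %s\n",
              x$rows, x$cols, x$pixel_spacing_row_mm, x$pixel_spacing_col_mm,
              x$instance_number))
  invisible(x)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

slice_normal <- function(slice) {
  .cross3(slice$orientation[1:3], slice$orientation[4:6])
}

#' Order slices by position along the stack normal
#'
#' Slices are ordered by the scalar projection of ImagePositionPatient onto
#' the normal of the image plane (the cross product of the row and column
#' direction cosines). InstanceNumber is ignored: spatial position wins, so
#' the ordering survives missing or duplicated instance numbers.
#'
#' @param slices list of [ct_slice] with a shared orientation.
#' @return a `ct_series`: list with `slices` (ordered), `slice_spacing_mm`
#'   (median gap between consecutive projections; `NA` for a single slice)
#'   and `normal`.
#' @export
sort_slices <- function(slices) {
  stopifnot(length(slices) >= 1)
  ori <- slices[[1]]$orientation
  for (s in slices) {
    if (max(abs(s$orientation - ori)) > 1e-3) {
      stop("slices do not share an orientation; cannot order the stack",
           call. = FALSE)
    }
  }
  normal <- slice_normal(slices[[1]])
  proj <- vapply(slices, function(s) sum(s$position_mm * normal), numeric(1))
  o <- order(proj)
  gaps <- diff(proj[o])
  if (length(gaps) && any(gaps < 1e-6)) {
    i <- which(gaps < 1e-6)[1]
    a <- slices[[o[i]]]; b <- slices[[o[i + 1]]]
    stop(sprintf(
      "duplicate slice position (projection %.6f mm): '%s' and '%s'",
      proj[o[i]], a$file, b$file), call. = FALSE)
  }
  structure(list(
    slices = slices[o],
    slice_spacing_mm = if (length(gaps)) stats::median(gaps) else NA_real_,
    normal = normal
  ), class = "ct_series")
}

#' @export
print.ct_series <- function(x, ...) {
  cat(sprintf("<ct_series> %d slices, spacing %.4g mm, uid %s\n",
              length(x$slices), x$slice_spacing_mm, x$slices[[1]]$series_uid))
  invisible(x)
}

#' Convert stored pixel values to Hounsfield units
#'
#' Applies the DICOM rescale transform elementwise:
#' HU = stored * RescaleSlope + RescaleIntercept.
#'
#' @param slice a [ct_slice].
#' @return numeric matrix of HU values, same shape as the pixel grid.
#' @export
to_hu <- function(slice) {
  slice$pixel_grid * slice$rescale_slope + slice$rescale_intercept
}

# Build a ct_slice from parsed DICOM structures.
.slice_from_parsed <- function(parsed, bytes, file = NA_character_) {
  d <- parsed$data
  rows <- dcm_us(dcm_find(d, 0x0028L, 0x0010L))
  cols <- dcm_us(dcm_find(d, 0x0028L, 0x0011L))
  px <- dcm_find(d, 0x7FE0L, 0x0010L)
  if (is.na(rows) || is.na(cols) || is.null(px)) return(NULL)  # not an image
  bits <- dcm_us(dcm_find(d, 0x0028L, 0x0100L))
  if (is.na(bits)) bits <- 16L
  if (bits != 16L) stop("only 16-bit pixel data is supported", call. = FALSE)
  signed <- identical(dcm_us(dcm_find(d, 0x0028L, 0x0103L)), 1L)
  vals <- readBin(px$bytes, "integer", n = rows * cols, size = 2L,
                  signed = signed, endian = "little")
  grid <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)

  spacing <- dcm_ds(dcm_find(d, 0x0028L, 0x0030L))
  if (length(spacing) != 2) spacing <- c(1, 1)
  slope_el <- dcm_find(d, 0x0028L, 0x1053L)
  inter_el <- dcm_find(d, 0x0028L, 0x1052L)
  if (is.null(slope_el) || is.null(inter_el)) {
    warning("missing RescaleSlope/Intercept; assuming slope 1, intercept 0",
            call. = FALSE)
  }
  slope <- if (is.null(slope_el)) 1 else dcm_ds(slope_el)
  inter <- if (is.null(inter_el)) 0 else dcm_ds(inter_el)
  pos <- dcm_ds(dcm_find(d, 0x0020L, 0x0032L))
  if (length(pos) != 3) pos <- c(0, 0, 0)
  ori <- dcm_ds(dcm_find(d, 0x0020L, 0x0037L))
  if (length(ori) != 6) ori <- c(1, 0, 0, 0, 1, 0)
  uid <- dcm_str(dcm_find(d, 0x0020L, 0x000EL))
  inst <- suppressWarnings(as.integer(dcm_str(dcm_find(d, 0x0020L, 0x0013L))))

  ct_slice(grid, pixel_spacing_mm = spacing, rescale_slope = slope,
           rescale_intercept = inter, position_mm = pos, orientation = ori,
           series_uid = uid, instance_number = inst,
           source_bytes = bytes, file = file)
}

#' Read one DICOM file as a CT slice
#'
#' @param path file path.
#' @return a [ct_slice], or `NULL` (with a message) when the file holds no
#'   image data.
#' @export
read_dicom_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  parsed <- dcm_parse(bytes)
  .slice_from_parsed(parsed, bytes, file = path)
}

#' Read a directory of DICOM files into CT series
#'
#' Files are parsed, grouped by SeriesInstanceUID, and each group is ordered
#' spatially with [sort_slices]. Unparsable or non-image files are skipped
#' with a warning; a series whose slices disagree on grid shape is rejected
#' with a diagnostic.
#'
#' @param path directory containing DICOM files (searched recursively).
#' @return list of `ct_series`, named by series UID.
#' @export
read_dicom_dir <- function(path) {
  if (!dir.exists(path)) stop(sprintf("no input: '%s' is not a directory", path),
                              call. = FALSE)
  files <- list.files(path, recursive = TRUE, full.names = TRUE)
  files <- files[!dir.exists(files)]
  slices <- list()
  for (f in files) {
    s <- tryCatch(read_dicom_file(f), error = function(e) {
      warning(sprintf("skipping '%s': %s", f, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (!is.null(s)) slices[[length(slices) + 1L]] <- s
  }
  if (length(slices) == 0L) {
    stop("no input: directory contains no readable DICOM image files",
         call. = FALSE)
  }
  uids <- vapply(slices, function(s) s$series_uid, character(1))
  out <- list()
  for (uid in unique(uids)) {
    group <- slices[uids == uid]
    shapes <- vapply(group, function(s) paste(s$rows, s$cols), character(1))
    if (length(unique(shapes)) > 1L) {
      warning(sprintf(
        "series %s rejected: mixed pixel grid shapes (%s)",
        uid, paste(unique(shapes), collapse = " vs ")), call. = FALSE)
      next
    }
    out[[uid]] <- sort_slices(group)
  }
  if (length(out) == 0L) {
    stop("no input: all series were rejected", call. = FALSE)
  }
  out
}

#' Tags treated as protected health information
#'
#' The fixed de-identification list applied by [anonymize]: direct patient,
#' institution, physician and study identifiers, plus every private
#' (odd-group) element. Keys are "GGGG,EEEE" hex tag strings.
#'
#' @return named character vector, tag -> attribute name.
#' @export
dicom_phi_tags <- function() {
  c("0010,0010" = "PatientName",
    "0010,0020" = "PatientID",
    "0010,0030" = "PatientBirthDate",
    "0010,1040" = "PatientAddress",
    "0010,1000" = "OtherPatientIDs",
    "0008,0080" = "InstitutionName",
    "0008,0081" = "InstitutionAddress",
    "0008,0090" = "ReferringPhysicianName",
    "0008,1050" = "PerformingPhysicianName",
    "0008,1070" = "OperatorsName",
    "0008,0050" = "AccessionNumber",
    "0020,0010" = "StudyID")
}

.is_phi_element <- function(el) {
  if (el$group %% 2L == 1L) return(TRUE)  # private groups
  tag_key(el$group, el$element) %in% names(dicom_phi_tags())
}

#' Strip identifying information from a DICOM file
#'
#' Removes the [dicom_phi_tags] set and all private (odd-group) elements
#' from the dataset, leaving pixel data, geometry and rescale elements
#' untouched, and re-serializes in the original transfer syntax. Idempotent.
#'
#' @param dicom_bytes raw vector with a Part 10 file.
#' @return raw vector with the de-identified file.
#' @export
anonymize <- function(dicom_bytes) {
  parsed <- dcm_parse(dicom_bytes)
  keep <- Filter(function(el) !.is_phi_element(el), parsed$data)
  dcm_serialize(parsed$meta, keep, parsed$transfer_syntax)
}

#' Check a DICOM file for absence of identifying tags
#'
#' @param dicom_bytes raw vector with a Part 10 file.
#' @return `TRUE` when none of the [dicom_phi_tags] (nor any private
#'   element) carries a non-empty value.
#' @export
is_anonymized <- function(dicom_bytes) {
  parsed <- tryCatch(dcm_parse(dicom_bytes), error = function(e) NULL)
  if (is.null(parsed)) return(FALSE)
  for (el in parsed$data) {
    if (.is_phi_element(el) && length(el$bytes) > 0L) return(FALSE)
  }
  TRUE
}
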