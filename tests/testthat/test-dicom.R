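test_that("a written phantom volume round-trips exactly through DICOM", {
  ph <- small_phantom(seed = 11, size = 96, n_slices = 4, noise = 5)
  d <- withr::local_tempdir()
  res <- phantom_write_dicom(ph, d)
  series_list <- read_dicom_dir(res$dicom_dir)
  expect_length(series_list, 1L)
  series <- series_list[[1]]
  expect_length(series$slices, 4L)
  expect_equal(series$slice_spacing_mm, 2.5)
  for (k in 1:4) {
    expect_identical(series$slices[[k]]$pixel_grid,
                     ph$series$slices[[k]]$pixel_grid)
    expect_equal(series$slices[[k]]$position_mm,
                 ph$series$slices[[k]]$position_mm)
    expect_equal(to_hu(series$slices[[k]]), to_hu(ph$series$slices[[k]]))
  }
})

test_that("files from two series are grouped into two series", {
  d <- withr::local_tempdir()
  p1 <- phantom_write_dicom(small_phantom(seed = 1, size = 64, n_slices = 3), d)
  # second phantom with a different seed gets different UIDs
  d2 <- file.path(d, "other")
  p2 <- phantom_write_dicom(small_phantom(seed = 2, size = 64, n_slices = 2), d2)
  file.copy(list.files(p2$dicom_dir, full.names = TRUE),
            file.path(p1$dicom_dir, paste0("b_", 1:2, ".dcm")))
  series_list <- read_dicom_dir(p1$dicom_dir)
  expect_length(series_list, 2L)
  expect_setequal(vapply(series_list, function(s) length(s$slices), integer(1)),
                  c(3L, 2L))
})

test_that("unreadable files are skipped with a warning; empty dir errors", {
  d <- withr::local_tempdir()
  res <- phantom_write_dicom(small_phantom(seed = 3, size = 64, n_slices = 2), d)
  writeLines("not dicom at all", file.path(res$dicom_dir, "junk.txt"))
  expect_warning(series_list <- read_dicom_dir(res$dicom_dir), "skipping")
  expect_length(series_list[[1]]$slices, 2L)
  empty <- withr::local_tempdir()
  writeLines("nope", file.path(empty, "a.txt"))
  suppressWarnings(expect_error(read_dicom_dir(empty), "no input"))
})

test_that("slices are ordered by spatial position, not instance number", {
  mk <- function(z, inst) {
    ct_slice(matrix(0L, 4, 4), c(1, 1), position_mm = c(0, 0, z),
             instance_number = inst)
  }
  s <- sort_slices(list(mk(5, 1), mk(1, 2), mk(3, 3)))
  expect_equal(vapply(s$slices, function(x) x$position_mm[3], numeric(1)),
               c(1, 3, 5))

  # permutation invariance on a phantom stack
  ph <- small_phantom(seed = 4, size = 64, n_slices = 6)
  base <- sort_slices(ph$series$slices)
  set.seed(42)
  for (i in 1:5) {
    perm <- sample(ph$series$slices)
    expect_identical(sort_slices(perm)$slices, base$slices)
  }
  # idempotence
  expect_identical(sort_slices(base$slices)$slices, base$slices)
})

test_that("ordering with a flipped row axis matches a brute-force oracle", {
  # row axis negated: normal flips, so ordering by projection reverses
  mk <- function(z) {
    ct_slice(matrix(0L, 4, 4), c(1, 1), position_mm = c(0.5, -2, z),
             orientation = c(-1, 0, 0, 0, 1, 0))
  }
  zs <- c(2.0, -1.5, 0.25, 3.75, 1.0)
  slices <- lapply(zs, mk)
  got <- sort_slices(slices)
  got_z <- vapply(got$slices, function(s) s$position_mm[3], numeric(1))

  # oracle: enumerate all orderings, keep the one whose projections onto the
  # recomputed normal increase strictly
  cross_oracle <- function(a, b) {
    c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1])
  }
  normal <- cross_oracle(c(-1, 0, 0), c(0, 1, 0))
  proj <- vapply(slices, function(s) sum(s$position_mm * normal), numeric(1))
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 5L), ]
  increasing <- apply(perms, 1, function(p) all(diff(proj[p]) > 0))
  oracle_order <- perms[which(increasing)[1], ]
  expect_equal(got_z, zs[oracle_order])
})

test_that("duplicate spatial positions are rejected naming both files", {
  mk <- function(z, f) {
    ct_slice(matrix(0L, 4, 4), c(1, 1), position_mm = c(0, 0, z), file = f)
  }
  expect_error(sort_slices(list(mk(1, "a.dcm"), mk(1, "b.dcm"))),
               "duplicate slice position.*a\\.dcm.*b\\.dcm")
})

test_that("HU conversion applies the rescale transform", {
  s <- ct_slice(matrix(c(0L, 1024L, 2048L, 512L), 2, 2), c(1, 1),
                rescale_slope = 1, rescale_intercept = -1024)
  expect_equal(to_hu(s), matrix(c(-1024, 0, 1024, -512), 2, 2))
  # phantom fat pixel written at -100 HU comes back as -100 HU
  ph <- small_phantom(seed = 5, size = 64,
                      hu = list(air = -1000, fat = -100, muscle = 45,
                                organ = 35, bone = 700))
  d <- withr::local_tempdir()
  res <- phantom_write_dicom(ph, d)
  sl <- read_dicom_dir(res$dicom_dir)[[1]]$slices[[1]]
  expect_true(any(to_hu(sl) == -100))
  expect_equal(to_hu(sl)[ph$truth$sfa == 1L][1], -100)
})

test_that("anonymization removes PHI but preserves pixels and geometry", {
  ph <- small_phantom(seed = 6, size = 64, n_slices = 1)
  d <- withr::local_tempdir()
  res <- phantom_write_dicom(ph, d)
  f <- list.files(res$dicom_dir, full.names = TRUE)[1]
  bytes <- readBin(f, "raw", n = file.info(f)$size)

  expect_false(is_anonymized(bytes))  # phantom writer embeds placeholder PHI
  anon <- anonymize(bytes)
  expect_true(is_anonymized(anon))
  expect_identical(anonymize(anon), anon)  # idempotent

  before <- read_dicom_file(f)
  tmp <- withr::local_tempfile(fileext = ".dcm")
  writeBin(anon, tmp)
  after <- read_dicom_file(tmp)
  expect_identical(after$pixel_grid, before$pixel_grid)
  expect_equal(after$position_mm, before$position_mm)
  expect_equal(after$orientation, before$orientation)
  expect_equal(after$pixel_spacing_row_mm, before$pixel_spacing_row_mm)
  expect_equal(after$rescale_intercept, before$rescale_intercept)

  # pipeline invariance: VFA measured before and after anonymization agrees
  w <- preset_windows()
  vfa_of <- function(slice) {
    seg <- segment_compartments(to_hu(slice))
    measure(seg$vfa, to_hu(slice), w$FAT,
            c(slice$pixel_spacing_row_mm, slice$pixel_spacing_col_mm))$area_mm2
  }
  expect_equal(vfa_of(after), vfa_of(before))
})

test_that("unsupported transfer syntaxes raise a named error", {
  ph <- small_phantom(seed = 7, size = 64)
  d <- withr::local_tempdir()
  res <- phantom_write_dicom(ph, d)
  f <- list.files(res$dicom_dir, full.names = TRUE)[1]
  bytes <- readBin(f, "raw", n = file.info(f)$size)
  # rewrite the transfer syntax UID to a JPEG-compressed one
  jpeg <- charToRaw("1.2.840.10008.1.2.4.90")
  plain <- c(charToRaw("1.2.840.10008.1.2.1"), as.raw(0))
  hit <- grepRaw(plain, bytes, fixed = TRUE)[1]
  mangled <- c(bytes[1:(hit - 3)],
               writeBin(length(jpeg), raw(), size = 2, endian = "little"),
               jpeg, bytes[(hit + length(plain)):length(bytes)])
  expect_error(ctmorph:::dcm_parse(mangled), "unsupported transfer syntax")
})

test_that("series with mixed grid shapes are rejected with a diagnostic", {
  d <- withr::local_tempdir()
  ph <- small_phantom(seed = 8, size = 64, n_slices = 2)
  res <- phantom_write_dicom(ph, d)
  # forge a third slice with a different shape but the same series UID
  odd <- ph$series$slices[[1]]
  odd2 <- ct_slice(matrix(0L, 32, 32), c(1, 1), rescale_intercept = -1024,
                   position_mm = c(0, 0, 99), series_uid = odd$series_uid,
                   instance_number = 9L)
  bytes <- ctmorph:::.encode_slice_dicom(odd2, "1.2.3", "1.2.4")
  writeBin(bytes, file.path(res$dicom_dir, "odd.dcm"))
  expect_warning(expect_error(read_dicom_dir(res$dicom_dir), "no input"),
                 "mixed pixel grid shapes")
})
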