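test_that("body extraction recovers the analytic ellipse and drops satellites", {
  ph <- small_phantom(seed = 51, size = 256)
  hu <- phantom_hu(ph)
  b <- body_mask(hu)
  area <- mask_area_mm2(b, c(0.7, 0.7))
  expect_lt(pct_err(area, ph$truth$analytic_mm2$body), 1)

  # all-air image
  expect_error(body_mask(matrix(-1000, 32, 32)), "no body found")

  # a small disconnected blob is discarded, keeping only the body
  hu2 <- hu; hu2[5:10, 5:10] <- 40
  b2 <- body_mask(hu2)
  expect_equal(sum(b2$grid), sum(b$grid))
  expect_true(all(b2$grid[5:10, 5:10] == 0L))
})

test_that("interior air pockets are filled into the body", {
  ph <- small_phantom(seed = 52, size = 160)
  hu <- phantom_hu(ph)
  ctr <- round(dim(hu) / 2)
  hu[ctr[1]:(ctr[1] + 4), ctr[2]:(ctr[2] + 4)] <- -1000  # bowel gas pocket
  b <- body_mask(hu)
  expect_true(all(b$grid[ctr[1]:(ctr[1] + 4), ctr[2]:(ctr[2] + 4)] == 1L))
})

test_that("wall detection finds the annulus radii on a concentric phantom", {
  ph <- concentric_phantom()
  hu <- phantom_hu(ph)
  b <- body_mask(hu)
  pb <- detect_wall(hu, b)
  expect_true(all(abs(pb$inner_radius_px - 60) <= 2))
  expect_true(all(abs(pb$wall_outer_radius_px - 70) <= 2))
  expect_true(all(abs(pb$outer_radius_px - 85) <= 2))
  expect_true(all(pb$inner_radius_px <= pb$wall_outer_radius_px))
  expect_error(detect_wall(hu, b, n_rays = 10), "n_rays")
})

test_that("rays through a wall gap get circularly interpolated radii", {
  ph <- concentric_phantom(wall_gap_deg = 30)
  hu <- phantom_hu(ph)
  pb <- detect_wall(hu, body_mask(hu))
  expect_true(all(abs(pb$inner_radius_px - 60) <= 2.5))
})

test_that("a too-small body cannot be traced", {
  hu <- matrix(-1000, 64, 64); hu[30:34, 30:34] <- 40
  expect_error(detect_wall(hu, body_mask(hu)), "too small")
})

test_that("compartment segmentation recovers the phantom fat areas", {
  ph <- small_phantom(seed = 53, size = 256, noise = 5)
  hu <- phantom_hu(ph)
  seg <- segment_compartments(hu)
  taa <- segment_tat(hu)
  sp <- c(0.7, 0.7)
  expect_lt(pct_err(mask_area_mm2(seg$sfa, sp), ph$truth$areas_mm2$SFA), 3)
  expect_lt(pct_err(mask_area_mm2(seg$vfa, sp), ph$truth$areas_mm2$VFA), 3)
  expect_lt(pct_err(mask_area_mm2(taa, sp), ph$truth$areas_mm2$TAA), 3)
  # compartments are disjoint and nested in the fat class of the body
  expect_equal(sum(seg$sfa$grid & seg$vfa$grid), 0L)
  w <- preset_windows()
  fat_in_body <- restrict_to_window(seg$body, hu, w$FAT)
  expect_true(all(seg$sfa$grid <= fat_in_body$grid))
  expect_true(all(seg$vfa$grid <= fat_in_body$grid))
  expect_true(all(taa$grid <= fat_in_body$grid))
  expect_true(all((seg$sfa$grid | seg$vfa$grid) <= taa$grid))
  musc_in_body <- restrict_to_window(seg$body, hu, w$MUSCLE_LUMBAR)
  expect_true(all(seg$tama$grid <= musc_in_body$grid))
})

test_that("a phantom without visceral fat yields an essentially empty VFA", {
  ph <- small_phantom(seed = 54, size = 200, visceral_fat_fraction = 0,
                      lining_frac = 0.699,  # no fat lining either
                      hu = list(air = -1000, fat = -95, muscle = 45,
                                organ = 30, bone = 700))
  seg <- segment_compartments(phantom_hu(ph))
  expect_lt(sum(seg$vfa$grid), 0.005 * sum(seg$body$grid))
})

test_that("total abdominal fat adds subcutaneous, visceral and intramuscular fat", {
  ph <- small_phantom(seed = 55, size = 256)
  hu <- phantom_hu(ph)
  seg <- segment_compartments(hu)
  taa <- segment_tat(hu)
  # no intramuscular fat in the phantom: TAA = SFA + VFA within 1%
  expect_lt(100 * abs(sum(taa$grid) - sum(seg$sfa$grid) - sum(seg$vfa$grid)) /
              sum(taa$grid), 1)

  # inject single-pixel fat flecks at mid-wall radius of a concentric phantom:
  # the circular median filter keeps the wall boundary put, so total fat grows
  # by exactly the fleck count while the compartments do not
  phc <- concentric_phantom(size = 256, body_r = 110, wall_radii = c(78, 91))
  huc <- phantom_hu(phc)
  ctr <- (256 + 1) / 2
  idx <- t(vapply(c(0, 90, 170, 260) * pi / 180, function(a) {
    round(c(ctr + 84.5 * sin(a), ctr + 84.5 * cos(a)))
  }, numeric(2)))
  hu2 <- huc
  hu2[idx] <- -95
  expect_true(all(huc[idx] == 45))  # all four sat on muscle
  segc <- segment_compartments(huc); taac <- segment_tat(huc)
  seg2 <- segment_compartments(hu2); taa2 <- segment_tat(hu2)
  extra <- sum(taa2$grid) - sum(seg2$sfa$grid) - sum(seg2$vfa$grid)
  base <- sum(taac$grid) - sum(segc$sfa$grid) - sum(segc$vfa$grid)
  expect_equal(extra - base, 4L)
})

test_that("segmented areas are stable to ray count, noise and rotation", {
  ph <- concentric_phantom(size = 256, body_r = 110, wall_radii = c(78, 91))
  hu <- phantom_hu(ph)
  a360 <- sum(segment_compartments(hu, n_rays = 360)$sfa$grid)
  a720 <- sum(segment_compartments(hu, n_rays = 720)$sfa$grid)
  expect_lt(100 * abs(a360 - a720) / a360, 1)

  # sigma = 10 HU noise moves areas by < 5%
  phn <- small_phantom(seed = 56, size = 256, noise = 0)
  phn10 <- small_phantom(seed = 56, size = 256, noise = 10)
  s0 <- segment_compartments(phantom_hu(phn))
  s10 <- segment_compartments(phantom_hu(phn10))
  expect_lt(100 * abs(sum(s0$sfa$grid) - sum(s10$sfa$grid)) / sum(s0$sfa$grid), 5)
  expect_lt(100 * abs(sum(s0$vfa$grid) - sum(s10$vfa$grid)) / sum(s0$vfa$grid), 5)

  # rotating the image by 90 degrees preserves each compartment area to < 1%
  hu_rot <- rot90(phantom_hu(phn))
  sr <- segment_compartments(hu_rot)
  expect_lt(100 * abs(sum(s0$sfa$grid) - sum(sr$sfa$grid)) / sum(s0$sfa$grid), 1)
  expect_lt(100 * abs(sum(s0$vfa$grid) - sum(sr$vfa$grid)) / sum(s0$vfa$grid), 1)
  expect_lt(100 * abs(sum(segment_tat(phantom_hu(phn))$grid) -
                        sum(segment_tat(hu_rot)$grid)) /
              sum(segment_tat(phantom_hu(phn))$grid), 1)
})
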