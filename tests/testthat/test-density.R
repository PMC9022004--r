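test_that("calibration maps anchor points and midpoints exactly", {
  curve <- default_calibration_curve()
  vol <- water_volume(c(4, 4, 4), hu = 0)
  expect_true(all(hu_to_red(vol)$values == 1.0))
  vol$values[] <- -1000
  expect_true(all(hu_to_red(vol)$values == 0.001))
  # clamped beyond both ends
  vol$values[] <- -1400
  expect_true(all(hu_to_red(vol)$values == 0.001))
  vol$values[] <- 3000
  expect_true(all(hu_to_red(vol)$values == 1.72))
  # midpoint of adjacent nodes -> arithmetic mean of their rED
  nodes <- curve$nodes
  for (i in seq_len(nrow(nodes) - 1)) {
    vol$values[] <- (nodes$hu[i] + nodes$hu[i + 1]) / 2
    expect_equal(hu_to_red(vol)$values[1, 1, 1],
                 (nodes$red[i] + nodes$red[i + 1]) / 2, tolerance = 1e-12)
  }
})

test_that("hu_to_red is monotone non-decreasing in HU", {
  set.seed(11)
  hu <- sort(runif(500, -1500, 2000))
  vol <- image_volume(array(hu, c(500, 1, 1)), spacing = c(1, 1, 1),
                      unit = "HU")
  red <- as.vector(hu_to_red(vol)$values)
  expect_true(all(diff(red) >= 0))
})

test_that("calibration curve validation catches bad inputs", {
  expect_error(calibration_curve(data.frame(hu = 0, red = 1)), "2 nodes")
  expect_error(calibration_curve(data.frame(hu = c(0, 0), red = c(1, 1))),
               "increasing")
  expect_error(calibration_curve(data.frame(hu = c(-100, 0),
                                            red = c(1.2, 1.0))),
               "non-decreasing")
  expect_error(calibration_curve(data.frame(hu = c(-100, 100),
                                            red = c(0.9, 1.1))), "water")
  f <- tempfile(fileext = ".yaml")
  write_calibration_curve(default_calibration_curve(), f)
  expect_equal(read_calibration_curve(f)$nodes,
               default_calibration_curve()$nodes)
})

test_that("threshold segmentation matches its definition voxel by voxel", {
  # all-water volume: both masks empty
  vol <- water_volume(c(6, 6, 6), hu = 0)
  body <- array(TRUE, c(6, 6, 6))
  seg <- segment_bone_air(vol, body)
  expect_equal(sum(seg$bone), 0)
  expect_equal(sum(seg$air), 0)

  # single hot voxel with cleanup disabled is segmented exactly
  vol$values[2, 2, 2] <- 300
  vol$values[4, 4, 4] <- -500
  cfg <- threshold_config(min_component_cm3 = 0, closing_radius = 0)
  seg <- segment_bone_air(vol, body, cfg)
  expect_identical(which(seg$bone), which(vol$values > 250))
  expect_identical(which(seg$air), which(vol$values < -300))

  expect_error(segment_bone_air(vol, body & FALSE), "empty")
  expect_error(threshold_config(bone_hu = -400, air_hu = -300), "below")
})

test_that("segmentation on a phantom equals a brute-force recount", {
  ph <- build_phantom(small_npc_spec(7))
  body <- roi_mask(ph$structures, "body")
  cfg <- threshold_config(min_component_cm3 = 0, closing_radius = 0)
  seg <- segment_bone_air(ph$ct, body, cfg)
  expect_identical(seg$bone, ph$ct$values > 250 & body)
  expect_identical(seg$air, ph$ct$values < -300 & body)

  # with morphology on: masks stay disjoint and inside the body
  seg2 <- segment_bone_air(ph$ct, body)
  expect_equal(sum(seg2$bone & seg2$air), 0)

  # raising the bone threshold never enlarges the bone mask
  seg_hi <- segment_bone_air(ph$ct, body, threshold_config(bone_hu = 400,
                                                           min_component_cm3 = 0,
                                                           closing_radius = 0))
  expect_true(all(which(seg_hi$bone) %in% which(seg$bone)))
})

test_that("small components are removed and closing fills gaps", {
  vol <- water_volume(c(12, 12, 12), hu = 0) # 2 mm voxels, 0.008 cm3 each
  body <- array(TRUE, c(12, 12, 12))
  vol$values[2, 2, 2] <- 400 # isolated: 0.008 cm3 < 0.5 cm3
  vol$values[6:10, 6:10, 6:10] <- 400 # 125 voxels = 1 cm3
  seg <- segment_bone_air(vol, body, threshold_config(closing_radius = 0))
  expect_false(seg$bone[2, 2, 2])
  expect_equal(sum(seg$bone), 125)

  # closing fills a one-voxel hole in a slab
  vol2 <- water_volume(c(12, 12, 12), hu = 0)
  vol2$values[3:9, 3:9, 3:9] <- 400
  vol2$values[6, 6, 6] <- 0
  seg2 <- segment_bone_air(vol2, body,
                           threshold_config(min_component_cm3 = 0))
  expect_true(seg2$bone[6, 6, 6])
})

test_that("ROI density summary equals the brute-force mean and flags empties", {
  ph <- build_phantom(small_npc_spec(8))
  red <- hu_to_red(ph$ct)
  ss <- segmented_structures(ph)
  s <- summarize_roi_red(red, ss, hu = ph$ct)
  for (roi in c("ptv_nx", "bone", "air")) {
    m <- roi_mask(ss, roi)
    expect_equal(s$mean_red[s$roi == roi],
                 sum(red$values * m) / sum(m), tolerance = 1e-12)
  }
  expect_true(all(s$mean_red[!s$empty] >= 0))

  # constant region: mean is exact
  g <- ss$geometry
  uni <- image_volume(array(1.05, g$dims), spacing = g$spacing,
                      origin = g$origin, unit = "rED")
  s2 <- summarize_roi_red(uni, ss)
  expect_equal(s2$mean_red[s2$roi == "ptv_nx"], 1.05)

  # empty ROI: flagged with count 0, not dropped
  rois <- ss$rois
  rois$ghost <- list(role = "oar", mask = array(FALSE, g$dims))
  s3 <- summarize_roi_red(red, structure_set(g, rois))
  expect_true("ghost" %in% s3$roi)
  expect_true(s3$empty[s3$roi == "ghost"])
  expect_equal(s3$n_voxels[s3$roi == "ghost"], 0L)
})
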