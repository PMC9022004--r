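test_that("radiological depth matches closed forms", {
  # uniform water: axis-aligned ray through N voxels of 2 mm at rED 1
  red <- image_volume(array(1, c(10, 10, 10)), spacing = c(2, 2, 2),
                      origin = c(0, 0, 0), unit = "rED")
  p0 <- c(-10, 8, 8); p1 <- c(30, 8, 8) # crosses the full 20 mm extent
  expect_equal(radiological_depth(red, p0, p1), 2.0, tolerance = 1e-12)

  # vacuum path
  red0 <- image_volume(array(0, c(10, 10, 10)), spacing = c(2, 2, 2),
                       origin = c(0, 0, 0), unit = "rED")
  expect_equal(radiological_depth(red0, p0, p1), 0)

  # oblique ray through a uniform block: Euclidean chord times rED
  redb <- image_volume(array(0.7, c(2, 2, 2)), spacing = c(2, 2, 2),
                       origin = c(0, 0, 0), unit = "rED")
  # voxel-boundary box spans [-1, 3]^3; a main diagonal chord
  a <- c(-2, -2, -2); b <- c(4, 4, 4)
  chord <- sqrt(3) * 4 # mm inside the box
  expect_equal(radiological_depth(redb, a, b), 0.7 * chord / 10,
               tolerance = 1e-9)
  # symmetry in endpoint order and zero-length segment
  expect_equal(radiological_depth(redb, a, b), radiological_depth(redb, b, a),
               tolerance = 1e-12)
  expect_equal(radiological_depth(redb, a, a), 0)
})

test_that("partial voxel crossings use exact intersection lengths", {
  red <- image_volume(array(rep(c(1, 2), each = 4), c(2, 2, 2)),
                      spacing = c(2, 2, 2), origin = c(0, 0, 0), unit = "rED")
  # ray along +z at (x, y) = (0, 0): crosses 2 mm of rED 1 and 2 mm of rED 2
  expect_equal(radiological_depth(red, c(0, 0, -5), c(0, 0, 9)),
               (2 * 1 + 2 * 2) / 10, tolerance = 1e-12)
  # stop halfway inside the second voxel
  expect_equal(radiological_depth(red, c(0, 0, -1), c(0, 0, 2)),
               (2 * 1 + 1 * 2) / 10, tolerance = 1e-12)
})

single_beam_plan <- function(iso, field = c(80, 80), angle = 0) {
  plan <- plan_spec(gantry_angles = angle, isocenter = iso, weights = 1,
                    field_size = field)
  resolve_plan(plan, structures = NULL)
}

test_that("central-axis dose in water decreases beyond the buildup depth", {
  red <- image_volume(array(1, c(40, 40, 40)), spacing = c(2, 2, 2),
                      origin = -c(39, 39, 39), unit = "rED")
  plan <- single_beam_plan(c(0, 0, 0))
  model <- beam_model(b_on = FALSE)
  d <- compute_dose(red, plan, model, norm_factor = NA)
  # beam from anterior (-y): central axis runs along y at x = z = 0
  profile <- d$dose$values[20, , 20]
  y <- red$origin[2] + (seq_len(40) - 1) * 2
  depth_cm <- (y - (-39)) / 10 # water depth from entry, cm
  beyond <- which(depth_cm > model$buildup_cm + 0.2)
  expect_true(all(diff(profile[beyond]) < 0))
  # and the buildup region rises
  rising <- which(depth_cm < model$buildup_cm - 0.2)
  expect_true(all(diff(profile[rising]) > 0))
})

test_that("dose is linear in beam weight before normalization", {
  red <- image_volume(array(1, c(20, 20, 20)), spacing = c(2, 2, 2),
                      origin = -c(19, 19, 19), unit = "rED")
  p1 <- plan_spec(gantry_angles = c(0, 90), isocenter = c(0, 0, 0),
                  weights = c(1, 1), field_size = c(60, 60))
  p2 <- plan_spec(gantry_angles = c(0, 90), isocenter = c(0, 0, 0),
                  weights = c(2, 1), field_size = c(60, 60))
  p0 <- plan_spec(gantry_angles = 90, isocenter = c(0, 0, 0), weights = 1,
                  field_size = c(60, 60))
  m <- beam_model(b_on = FALSE)
  d1 <- compute_dose(red, resolve_plan(p1, NULL), m, norm_factor = NA)
  d2 <- compute_dose(red, resolve_plan(p2, NULL), m, norm_factor = NA)
  d0 <- compute_dose(red, resolve_plan(p0, NULL), m, norm_factor = NA)
  beam0 <- d1$dose$values - d0$dose$values # contribution of beam at 0 deg
  expect_equal(d2$dose$values, d1$dose$values + beam0, tolerance = 1e-9)
})

test_that("an upstream air slab raises the downstream primary dose", {
  dims <- c(20, 20, 20)
  water <- image_volume(array(1, dims), spacing = c(2, 2, 2),
                        origin = -c(19, 19, 19), unit = "rED")
  slab <- water
  slab$values[, 5:8, ] <- 0.001 # upstream of the isocenter for a 0-deg beam
  plan <- single_beam_plan(c(0, 10, 0))
  m <- beam_model(b_on = FALSE)
  dw <- compute_dose(water, plan, m, norm_factor = NA)
  ds <- compute_dose(slab, plan, m, norm_factor = NA)
  expect_gt(ds$dose$values[10, 16, 10], dw$dose$values[10, 16, 10])
})

test_that("the engine is deterministic and produces finite non-negative dose", {
  ph <- build_phantom(small_npc_spec(1))
  ss <- segmented_structures(ph)
  red <- hu_to_red(ph$ct)
  plan <- resolve_plan(plan_spec(), ss)
  d1 <- compute_dose(red, plan, beam_model(), ss)
  d2 <- compute_dose(red, plan, beam_model(), ss)
  expect_identical(d1$dose$values, d2$dose$values)
  expect_true(all(is.finite(d1$dose$values)))
  expect_true(all(d1$dose$values >= 0))
  # normalization: the PTV_nx reference point receives its prescription
  rp <- roi_reference_point(ss, "ptv_nx")
  expect_equal(d1$dose$values[rp$index[1] + 1, rp$index[2] + 1,
                              rp$index[3] + 1], 70, tolerance = 1e-9)
})

test_that("ERE perturbation is conserving, directional, and gated by the field", {
  dose <- rep(1, 60)
  red <- c(rep(1, 30), rep(0.2, 30)) # tissue -> air step at sample 30
  kernel <- list(threshold = 0.3, fraction = 0.15, range_mm = 10)
  out <- ere_perturbation(dose, red, step_mm = 1, kernel = kernel)
  expect_equal(sum(out), sum(dose), tolerance = 1e-9)
  expect_gt(out[30], dose[30]) # proximal voxel rises
  expect_lt(out[31], dose[31]) # distal side falls
  # identity cases
  expect_identical(ere_perturbation(dose, red, b_on = FALSE), dose)
  expect_identical(ere_perturbation(dose, rep(1, 60)), dose)
  expect_identical(ere_perturbation(dose, c(rep(1, 30), rep(0.9, 30))), dose)
})

test_that("with the field on, dose shifts to the proximal side of an air cavity", {
  dims <- c(20, 20, 20)
  vol <- image_volume(array(1, dims), spacing = c(2, 2, 2),
                      origin = -c(19, 19, 19), unit = "rED")
  vol$values[, 11:14, ] <- 0.001 # cavity downstream of entry, 0-deg beam
  plan <- single_beam_plan(c(0, 0, 0))
  d_off <- compute_dose(vol, plan, beam_model(b_on = FALSE), norm_factor = NA)
  d_on <- compute_dose(vol, plan, beam_model(b_on = TRUE), norm_factor = NA)
  # proximal tissue voxel just before the cavity gains dose
  expect_gt(d_on$dose$values[10, 10, 10], d_off$dose$values[10, 10, 10])
  # voxel inside the cavity loses dose
  expect_lt(d_on$dose$values[10, 12, 10], d_off$dose$values[10, 12, 10])
})
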