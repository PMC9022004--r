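random_dose_pair <- function(dims = c(7, 7, 7), spacing = c(2, 2, 2),
                             sd = 2, seed = 1) {
  set.seed(seed)
  base <- array(60 + 10 * sin(seq_len(prod(dims)) / 7), dim = dims)
  ref <- image_volume(base + rnorm(prod(dims), 0, sd), spacing = spacing,
                      origin = -(dims - 1) / 2 * spacing, unit = "Gy")
  ev <- image_volume(base + rnorm(prod(dims), 0, sd), spacing = spacing,
                     origin = ref$origin, unit = "Gy")
  list(ref = ref, ev = ev)
}

test_that("gamma of a dose against itself is zero with a 100% pass rate", {
  p <- random_dose_pair(seed = 2)
  g <- gamma_index(p$ref, p$ref, gamma_criteria(1, 1))
  expect_equal(g$pass_rate, 100)
  expect_true(all(g$gamma_map$values[!is.na(g$gamma_map$values)] == 0))
  # only voxels at or above the 10% threshold are evaluated
  thr <- 0.1 * max(p$ref$values)
  expect_equal(g$n_evaluated, sum(p$ref$values >= thr))
})

test_that("a 2% global scaling passes 3%/3 mm everywhere", {
  p <- random_dose_pair(seed = 3)
  ev <- p$ref
  ev$values <- ev$values * 1.02
  g <- gamma_index(p$ref, ev, gamma_criteria(3, 3))
  expect_equal(g$pass_rate, 100)
})

test_that("the optimized gamma equals exhaustive brute force", {
  for (case in list(list(dims = c(5, 5, 5), crit = gamma_criteria(1, 1),
                         sd = 1.5, seed = 4),
                    list(dims = c(7, 7, 7), crit = gamma_criteria(3, 3),
                         sd = 3, seed = 5),
                    list(dims = c(9, 9, 9), crit = gamma_criteria(3, 3),
                         sd = 1, seed = 6))) {
    p <- random_dose_pair(case$dims, sd = case$sd, seed = case$seed)
    fast <- gamma_index(p$ref, p$ev, case$crit)
    slow <- gamma_oracle(p$ref, p$ev, case$crit)
    expect_equal(fast$gamma_map$values, slow$gamma, tolerance = 1e-9)
    expect_equal(fast$pass_rate, slow$pass_rate, tolerance = 1e-9)
  }
})

test_that("gamma requires a common grid and rejects bad criteria", {
  p <- random_dose_pair()
  shifted <- p$ev
  shifted$origin <- shifted$origin + 1
  expect_error(gamma_index(p$ref, shifted), "share a grid")
  expect_error(gamma_criteria(0, 1), "> 0")
  expect_error(gamma_criteria(3, 3, threshold = 100), "threshold")
  expect_error(gamma_criteria(3, 3, normalization = "prescription"),
               "norm_dose")
})

test_that("point dose differences follow their definition and snap to the mask", {
  ph <- build_phantom(small_npc_spec(1))
  ss <- ph$structures
  g <- grid_geometry(ph$ct)
  ref <- image_volume(array(50, g$dims), spacing = g$spacing,
                      origin = g$origin, unit = "Gy")
  expect_equal(point_dose_difference(ref, ref, ss), 0)
  ev <- ref; ev$values <- ev$values * 1.05
  expect_equal(point_dose_difference(ref, ev, ss), 5, tolerance = 1e-12)

  # C-shaped ROI: centroid falls outside; the snapped point is in-mask
  dims <- c(12, 12, 12)
  cg <- list(dims = dims, spacing = c(2, 2, 2), origin = c(0, 0, 0))
  cmask <- array(FALSE, dims)
  cmask[3:10, 3:10, 5:7] <- TRUE
  cmask[3:8, 4:9, 5:7] <- FALSE # carve the interior: a C in each slice
  body <- array(TRUE, dims)
  css <- structure_set(cg, list(body = list(role = "body", mask = body),
                                c_roi = list(role = "oar", mask = cmask)))
  rp <- roi_reference_point(css, "c_roi")
  expect_true(cmask[rp$index[1] + 1, rp$index[2] + 1, rp$index[3] + 1])

  # zero reference dose at the point is an error
  zero <- ref; zero$values[] <- 0
  expect_error(point_dose_difference(zero, ev, ss), "zero")
})

test_that("DVH metrics match closed forms on uniform and ramp doses", {
  dims <- c(12, 12, 12)
  g <- list(dims = dims, spacing = c(2, 2, 2), origin = c(0, 0, 0))
  body <- array(TRUE, dims)
  ptv <- array(FALSE, dims); ptv[3:8, 3:8, 3:8] <- TRUE
  ss <- structure_set(g, list(body = list(role = "body", mask = body),
                              ptv_nx = list(role = "target", mask = ptv)))
  uni <- image_volume(array(70, dims), spacing = g$spacing,
                      origin = g$origin, unit = "Gy")
  m <- dvh_metrics(uni, ss, prescriptions = c(ptv_nx = 70))
  row <- m[m$roi == "ptv_nx", ]
  expect_equal(row$d_mean, 70)
  expect_equal(row$d98, 70)
  expect_equal(row$d2, 70)
  expect_equal(row$d_max, 70)
  expect_equal(row$v100, 100)

  # 1000-voxel ROI with doses 1..1000: D2% is the interpolated 98th
  # percentile order statistic
  dims2 <- c(10, 10, 10)
  g2 <- list(dims = dims2, spacing = c(2, 2, 2), origin = c(0, 0, 0))
  dose2 <- image_volume(array(as.double(1:1000), dims2),
                        spacing = g2$spacing, origin = g2$origin, unit = "Gy")
  ss2 <- structure_set(g2, list(body = list(role = "body",
                                            mask = array(TRUE, dims2))))
  m2 <- dvh_metrics(dose2, ss2, rois = "body")
  expect_equal(m2$d2, as.numeric(quantile(1:1000, 0.98, type = 7)),
               tolerance = 1e-9)
  expect_equal(m2$d98, as.numeric(quantile(1:1000, 0.02, type = 7)),
               tolerance = 1e-9)
  # 0.008 cm3 voxels: D1cc sits at the 125-voxel exceedance level
  expect_equal(m2$d1cc, dvh_scan_oracle(1:1000, 1 / 0.008), tolerance = 1e-9)
  expect_equal(m2$d_max, 1000)
})

test_that("DVH order statistics match the cumulative-volume scan on random ROIs", {
  set.seed(9)
  for (i in 1:100) {
    n <- sample(30:400, 1)
    doses <- rlnorm(n, log(50), 0.4)
    d <- sort(doses, decreasing = TRUE)
    for (x in c(98, 2)) {
      mine <- sctdosim:::dose_at_volume(d, x / 100 * n)
      expect_equal(mine, dvh_scan_oracle(doses, x / 100 * n),
                   tolerance = 1e-9)
      expect_equal(mine, as.numeric(quantile(doses, 1 - x / 100, type = 7)),
                   tolerance = 1e-9)
    }
    # ordering invariant
    q <- c(d98 = sctdosim:::dose_at_volume(d, 0.98 * n),
           mean = mean(d),
           d2 = sctdosim:::dose_at_volume(d, 0.02 * n),
           max = d[1])
    expect_true(q["d98"] <= q["mean"] + 1e-12)
    expect_true(q["mean"] <= q["d2"] + 1e-12)
    expect_true(q["d2"] <= q["max"] + 1e-12)
  }
})

test_that("tiny ROIs report D1cc as D_max with a flag", {
  dims <- c(8, 8, 8)
  g <- list(dims = dims, spacing = c(2, 2, 2), origin = c(0, 0, 0))
  tiny <- array(FALSE, dims); tiny[4:5, 4:5, 4] <- TRUE # 4 voxels = 0.032 cm3
  ss <- structure_set(g, list(body = list(role = "body",
                                          mask = array(TRUE, dims)),
                              spot = list(role = "oar", mask = tiny)))
  dose <- image_volume(array(runif(512, 10, 20), dims), spacing = g$spacing,
                       origin = g$origin, unit = "Gy")
  m <- dvh_metrics(dose, ss, rois = "spot")
  expect_true(m$d1cc_is_dmax)
  expect_equal(m$d1cc, m$d_max)
})

test_that("comparing identical strategy doses gives all-pass, all-zero reports", {
  ph <- build_phantom(small_npc_spec(2))
  ss <- segmented_structures(ph)
  red <- hu_to_red(ph$ct)
  plan <- resolve_plan(plan_spec(), ss)
  ref <- compute_dose(red, plan, beam_model(), ss)
  rep <- compare_strategies(ref, list(tailor = ref, icru = ref), ss,
                            criteria_list = list(gamma_criteria(3, 3)))
  expect_true(all(rep$gamma$pass_rate == 100))
  expect_true(all(rep$point$diff_pct == 0))
  expect_true(all(rep$dvh$diff == 0))
  # one row per strategy x criteria
  expect_equal(nrow(rep$gamma), 2)

  f <- tempfile(fileext = ".json")
  write_comparison_report(rep, f)
  back <- read_comparison_report(f)
  expect_equal(back$gamma$pass_rate, rep$gamma$pass_rate)
  expect_equal(back$dvh$diff, rep$dvh$diff)
})

test_that("tightening gamma criteria never raises the pass rate", {
  set.seed(12)
  for (i in 1:4) {
    p <- random_dose_pair(c(8, 8, 8), sd = runif(1, 0.5, 3), seed = 100 + i)
    g11 <- gamma_index(p$ref, p$ev, gamma_criteria(1, 1))
    g33 <- gamma_index(p$ref, p$ev, gamma_criteria(3, 3))
    expect_lte(g11$pass_rate, g33$pass_rate)
  }
})
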