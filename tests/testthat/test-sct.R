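test_that("assignment tables encode the three strategies", {
  ph <- build_phantom(small_npc_spec(1))
  ss <- segmented_structures(ph)
  s <- summarize_roi_red(hu_to_red(ph$ct), ss, hu = ph$ct)

  hom <- make_assignment_table("homogeneity", s)
  expect_equal(nrow(hom$entries), 1L)
  expect_equal(hom$entries$roi, "body")
  expect_identical(hom$entries$red, 1.0)

  icru <- make_assignment_table("icru", s)
  expect_identical(icru$entries$red[icru$entries$roi == "air"], 0.001)
  expect_identical(icru$entries$red[icru$entries$roi == "bone"], 1.61)
  # every other ROI keeps its patient-specific mean
  for (roi in setdiff(icru$entries$roi, c("air", "bone")))
    expect_equal(icru$entries$red[icru$entries$roi == roi],
                 s$mean_red[s$roi == roi])

  tail <- make_assignment_table("tailor", s)
  for (roi in tail$entries$roi)
    expect_equal(tail$entries$red[tail$entries$roi == roi],
                 s$mean_red[s$roi == roi])

  # missing required ROI is a config error naming the ROI
  s_nobone <- s[s$roi != "bone", ]
  expect_error(make_assignment_table("icru", s_nobone), "bone")

  f <- tempfile(fileext = ".yaml")
  write_assignment_table(icru, f)
  back <- read_assignment_table(f)
  expect_equal(back$entries$red, icru$entries$red)
  expect_equal(back$strategy, "icru")
})

test_that("assignment table invariants are enforced", {
  e <- data.frame(roi = c("body", "air"), red = c(1, 0.001),
                  precedence = c(0, 1))
  expect_s3_class(assignment_table("homogeneity",
                                   e[e$roi == "body", , drop = FALSE]),
                  "assignment_table")
  expect_error(assignment_table("homogeneity",
                                data.frame(roi = "body", red = 0.98,
                                           precedence = 0)), "1.0")
  expect_error(assignment_table("icru", e), "bone")
  e2 <- data.frame(roi = c("body", "x"), red = c(1, 1), precedence = c(0, 0))
  expect_error(assignment_table("tailor", e2), "total order")
  e3 <- data.frame(roi = "body", red = -1, precedence = 0)
  expect_error(assignment_table("tailor", e3), ">= 0")
})

test_that("bulk maps are piecewise constant with air winning inside PTVs", {
  ph <- build_phantom(small_npc_spec(2))
  ss <- segmented_structures(ph)
  s <- summarize_roi_red(hu_to_red(ph$ct), ss, hu = ph$ct)
  sct <- build_sct(ss, make_assignment_table("tailor", s))

  # bulk property: at most one distinct value per table entry inside the body
  body <- roi_mask(ss, "body")
  expect_lte(length(unique(sct$red_map$values[body])),
             nrow(sct$table$entries))

  # air cavity voxels inside ptv_nx take the air value, not the PTV value
  overlap <- roi_mask(ss, "air") & roi_mask(ss, "ptv_nx")
  expect_gt(sum(overlap), 0)
  expect_true(all(sct$red_map$values[overlap] ==
                    s$mean_red[s$roi == "air"]))

  # outside the body: background
  expect_true(all(sct$red_map$values[!body] == sct$table$background))

  expect_error(build_sct(ph$structures,
                         make_assignment_table("tailor", s)),
               "missing from structures")
})

test_that("disjoint ROIs take exactly their own value and equal-precedence order is irrelevant", {
  g <- list(dims = c(8, 8, 8), spacing = c(2, 2, 2), origin = c(0, 0, 0))
  body <- array(TRUE, c(8, 8, 8))
  a <- array(FALSE, c(8, 8, 8)); a[1:3, , ] <- TRUE
  b <- array(FALSE, c(8, 8, 8)); b[6:8, , ] <- TRUE
  ss <- structure_set(g, list(body = list(role = "body", mask = body),
                              a = list(role = "oar", mask = a),
                              b = list(role = "oar", mask = b)))
  e <- data.frame(roi = c("body", "a", "b"), red = c(1, 1.2, 0.8),
                  precedence = c(0, 1, 2))
  m1 <- build_sct(ss, assignment_table("tailor", e))$red_map$values
  expect_true(all(m1[a] == 1.2))
  expect_true(all(m1[b] == 0.8))
  expect_true(all(m1[!a & !b] == 1))
  # swapping the ranks of the two disjoint ROIs changes nothing
  e2 <- e; e2$precedence <- c(0, 2, 1)
  m2 <- build_sct(ss, assignment_table("tailor", e2))$red_map$values
  expect_identical(m1, m2)
})

test_that("tailored bulk assignment conserves ROI means under identity registration", {
  ph <- build_phantom(small_npc_spec(3))
  ss <- segmented_structures(ph)
  red <- hu_to_red(ph$ct)
  s <- summarize_roi_red(red, ss, hu = ph$ct)
  sct <- build_sct(ss, make_assignment_table("tailor", s))
  # ROIs not overlapped by any higher-precedence ROI keep their CT mean
  for (roi in c("brainstem", "parotid_l", "bone", "air")) {
    m <- roi_mask(ss, roi)
    expect_equal(mean(sct$red_map$values[m]), s$mean_red[s$roi == roi],
                 tolerance = 1e-12)
  }
})

test_that("the tailored strategy is the most faithful bulk map", {
  # body-wide mean absolute rED error against the true CT-derived map,
  # across several seeds
  for (seed in 1:5) {
    ph <- build_phantom(small_npc_spec(seed))
    ss <- segmented_structures(ph)
    red <- hu_to_red(ph$ct)
    s <- summarize_roi_red(red, ss, hu = ph$ct)
    body <- roi_mask(ss, "body")
    mae <- vapply(c("tailor", "icru", "homogeneity"), function(st) {
      m <- build_sct(ss, make_assignment_table(st, s))$red_map$values
      mean(abs(m[body] - red$values[body]))
    }, numeric(1))
    expect_lte(mae[["tailor"]], min(mae[["icru"]], mae[["homogeneity"]]))
  }
})
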