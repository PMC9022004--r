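# Independent oracles and small fixtures shared across the suite.

# vectorized trilinear interpolation mirroring the engine's edge clamping;
# returns NA outside the voxel-centre hull
tri_interp_oracle <- function(vals, g, P) {
  n <- g$dims
  ci <- sweep(sweep(P, 2, g$origin, "-"), 2, g$spacing, "/")
  ok <- rep(TRUE, nrow(P))
  for (a in 1:3) ok <- ok & ci[, a] >= -1e-9 & ci[, a] <= n[a] - 1 + 1e-9
  out <- rep(NA_real_, nrow(P))
  if (!any(ok)) return(out)
  ci <- pmin(pmax(ci, 0), rep(n - 1, each = nrow(ci)))
  lo <- pmin(floor(ci), rep(n - 2, each = nrow(ci)))
  f <- ci - lo
  acc <- 0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (dx * f[, 1] + (1 - dx) * (1 - f[, 1])) *
      (dy * f[, 2] + (1 - dy) * (1 - f[, 2])) *
      (dz * f[, 3] + (1 - dz) * (1 - f[, 3]))
    idx <- (lo[, 1] + dx) + n[1] * ((lo[, 2] + dy) + n[2] * (lo[, 3] + dz))
    acc <- acc + w * vals[idx + 1]
  }
  out[ok] <- acc[ok]
  out
}

# exhaustive brute-force gamma: every lattice sample within the search ball,
# no pruning; feasible only on tiny grids
gamma_oracle <- function(reference, evaluated, criteria) {
  ref <- reference$values
  ev <- evaluated$values
  g <- list(dims = dim(ref), spacing = reference$spacing,
            origin = reference$origin)
  dnorm_val <- max(ref)
  thr <- criteria$threshold / 100 * dnorm_val
  h <- criteria$dta / criteria$step_divisor
  kmax <- criteria$search_radius * criteria$step_divisor
  ks <- -kmax:kmax
  offs <- as.matrix(expand.grid(x = ks, y = ks, z = ks)) * h
  d2 <- rowSums(offs^2)
  keep <- d2 <= (criteria$search_radius * criteria$dta)^2 + 1e-12
  offs <- offs[keep, , drop = FALSE]
  d2 <- d2[keep]
  invd <- 1 / (criteria$delta / 100 * dnorm_val)
  invdta2 <- 1 / criteria$dta^2
  gam <- array(NA_real_, dim = dim(ref))
  idx <- which(ref >= thr, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    xr <- g$origin + (idx[r, ] - 1) * g$spacing
    P <- sweep(offs, 2, xr, "+")
    vals <- tri_interp_oracle(as.vector(ev), g, P)
    okv <- !is.na(vals)
    g2 <- d2[okv] * invdta2 + ((vals[okv] - ref[idx[r, , drop = FALSE]]) *
                                 invd)^2
    gam[idx[r, , drop = FALSE]] <- sqrt(min(g2))
  }
  list(gamma = gam,
       pass_rate = 100 * sum(gam <= 1, na.rm = TRUE) / sum(!is.na(gam)))
}

# cumulative-volume scan for the dose-at-volume level: walks the descending
# order statistics accumulating volume until the target is bracketed
dvh_scan_oracle <- function(doses, v_voxels) {
  d <- sort(doses, decreasing = TRUE)
  n <- length(d)
  if (n == 1) return(d[1])
  target <- 1 + (v_voxels / n) * (n - 1)
  target <- min(max(target, 1), n)
  k <- 1
  while (k + 1 <= n && k + 1 <= target) k <- k + 1
  if (k >= n) return(d[n])
  d[k] + (target - k) * (d[k + 1] - d[k])
}

# small uniform water phantom: body box with soft HU everywhere
water_volume <- function(dims = c(24, 24, 24), spacing = c(2, 2, 2),
                         hu = 0) {
  org <- -(dims - 1) / 2 * spacing
  image_volume(array(hu, dim = dims), spacing = spacing, origin = org,
               unit = "HU")
}

# a small fast phantom spec for tests that need the full pipeline shape but
# not the default grid size
small_npc_spec <- function(seed = 1L) {
  phantom_spec(
    grid_shape = c(48L, 48L, 40L), spacing = c(4, 4, 4),
    head = list(center = c(0, 0, 0), semiaxes = c(70, 85, 72)),
    air_cavities = list(nasopharynx = list(center = c(0, 10, 0),
                                           semiaxes = c(16, 12, 12))),
    targets = list(
      ptv_nx = list(center = c(0, 14, 0), semiaxes = c(22, 20, 18)),
      ptv_nd = list(center = c(30, 10, -30), semiaxes = c(12, 12, 14)),
      ptv1 = list(center = c(0, 14, 0), semiaxes = c(30, 27, 24)),
      ptv2 = list(center = c(0, 14, 0), semiaxes = c(38, 34, 30))),
    oars = list(brainstem = list(center = c(0, 35, 18),
                                 semiaxes = c(10, 10, 20)),
                parotid_l = list(center = c(45, 10, -15),
                                 semiaxes = c(11, 14, 16))),
    seed = seed)
}

# structure set with bone/air contours appended, as the pipeline builds it
segmented_structures <- function(ph, cfg = threshold_config()) {
  seg <- segment_bone_air(ph$ct, roi_mask(ph$structures, "body"), cfg)
  rois <- ph$structures$rois
  rois$bone <- list(role = "bone", mask = seg$bone)
  rois$air <- list(role = "air", mask = seg$air)
  structure_set(ph$structures$geometry, rois)
}

expect_volumes_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$values, b$values, tolerance = tol)
  expect_equal(a$spacing, b$spacing, tolerance = tol)
  expect_equal(a$origin, b$origin, tolerance = tol)
}
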