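#' Digital head-and-neck phantom specification
#'
#' Describes a seeded synthetic head phantom: an ellipsoidal head with a
#' cranial bone shell, internal air cavities (nasopharynx and paranasal
#' sinuses), nested planning target volumes with the nasopharyngeal PTV
#' abutting the air cavity, a representative OAR subset (brainstem, spinal
#' cord, parotids), additive CT noise, and a paired pseudo-MRI offset by a
#' known rigid transform. All primitives are ellipsoids given as
#' `list(center =, semiaxes =)` in mm (LPS world frame).
#'
#' @param grid_shape index triplet (voxels).
#' @param spacing mm triplet.
#' @param head head ellipsoid (doubles as the body mask).
#' @param cranium `list(outer_scale =, thickness_mm =, hu_mean =, hu_sd =)`:
#'   bone shell between `head * outer_scale` and that ellipsoid shrunk by
#'   `thickness_mm`.
#' @param air_cavities list of ellipsoids sharing `air_hu` statistics.
#' @param air_hu,soft_hu `list(mean =, sd =)` HU of cavity air and soft tissue
#'   (the sd components are reserved; voxel noise is governed by `noise_sd`).
#' @param targets named list of ellipsoids `ptv_nx`, `ptv_nd`, `ptv1`, `ptv2`
#'   with `ptv_nx` inside `ptv1` inside `ptv2`.
#' @param oars named list of OAR ellipsoids.
#' @param noise_sd additive Gaussian CT noise, HU.
#' @param mri_transform `rigid_transform` mapping CT world coordinates to
#'   pseudo-MRI world coordinates (the simulated set-up difference).
#' @param seed integer RNG seed; the phantom is a pure function of the spec.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(128L, 128L, 96L),
                         spacing = c(2, 2, 2),
                         head = list(center = c(0, 0, 0),
                                     semiaxes = c(70, 85, 88)),
                         cranium = list(outer_scale = 0.96,
                                        thickness_mm = 6,
                                        hu_mean = 565, hu_sd = 0),
                         air_cavities = list(
                           nasopharynx = list(center = c(0, 10, 0),
                                              semiaxes = c(16, 12, 12)),
                           sinus_l = list(center = c(22, -18, 8),
                                          semiaxes = c(8, 8, 8)),
                           sinus_r = list(center = c(-22, -18, 8),
                                          semiaxes = c(8, 8, 8))),
                         air_hu = list(mean = -745, sd = 0),
                         soft_hu = list(mean = 30, sd = 0),
                         targets = list(
                           ptv_nx = list(center = c(0, 14, 0),
                                         semiaxes = c(22, 20, 18)),
                           ptv_nd = list(center = c(30, 10, -40),
                                         semiaxes = c(12, 12, 16)),
                           ptv1 = list(center = c(0, 14, 0),
                                       semiaxes = c(30, 27, 24)),
                           ptv2 = list(center = c(0, 14, 0),
                                       semiaxes = c(38, 34, 30))),
                         oars = list(
                           brainstem = list(center = c(0, 35, 18),
                                            semiaxes = c(10, 10, 24)),
                           cord = list(center = c(0, 38, -40),
                                       semiaxes = c(7, 7, 28)),
                           parotid_l = list(center = c(45, 10, -15),
                                            semiaxes = c(11, 14, 17)),
                           parotid_r = list(center = c(-45, 10, -15),
                                            semiaxes = c(11, 14, 17))),
                         noise_sd = 20,
                         mri_transform = axis_rotation(3, 2,
                                                       translation = c(3, 0, 0)),
                         seed = 1L) {
  spec <- structure(
    list(grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
         head = head, cranium = cranium, air_cavities = air_cavities,
         air_hu = air_hu, soft_hu = soft_hu, targets = targets, oars = oars,
         noise_sd = noise_sd, mri_transform = mri_transform,
         seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

phantom_geometry <- function(spec) {
  dims <- spec$grid_shape
  # grid centred on the world origin
  origin <- -(dims - 1) / 2 * spec$spacing
  list(dims = dims, spacing = spec$spacing, origin = origin)
}

validate_phantom_spec <- function(spec) {
  g <- phantom_geometry(spec)
  lo <- g$origin
  hi <- g$origin + (g$dims - 1) * g$spacing
  prims <- c(list(head = spec$head), spec$air_cavities, spec$targets,
             spec$oars)
  for (nm in names(prims)) {
    p <- prims[[nm]]
    if (any(p$center - p$semiaxes < lo) || any(p$center + p$semiaxes > hi))
      stop("spec error: primitive `", nm, "` extends outside the grid",
           call. = FALSE)
  }
  # nested targets
  for (pair in list(c("ptv_nx", "ptv1"), c("ptv1", "ptv2"))) {
    a <- spec$targets[[pair[1]]]; b <- spec$targets[[pair[2]]]
    # ellipsoid containment check on the axis extremes (same centres in the
    # default; a conservative necessary condition otherwise)
    if (any(a$center - a$semiaxes < b$center - b$semiaxes) ||
        any(a$center + a$semiaxes > b$center + b$semiaxes))
      stop("spec error: targets must nest ", pair[1], " within ", pair[2],
           call. = FALSE)
  }
  invisible(spec)
}

#' Default nasopharyngeal phantom specification for a given seed
#'
#' Returns the documented default spec (128 x 128 x 96 voxels at 2 mm). The
#' seed fixes the noise realisation and also draws the subject's cavity-air
#' and cranium-bone HU levels from narrow cohort bands, chosen so that after
#' the default HU-to-rED calibration the segmented air-cavity ROI mean rED
#' falls in the 0.196--0.327 band and the cranium ROI mean in the
#' 1.280--1.362 band -- the patient-to-patient spread reported for NPC
#' cohorts.
#'
#' @param seed integer seed identifying the synthetic subject.
#' @export
default_npc_spec <- function(seed = 1L) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  rng <- local({
    set.seed(as.integer(seed))
    list(air = runif(1, -785, -700), bone = runif(1, 520, 610),
         soft = runif(1, 20, 45))
  })
  phantom_spec(air_hu = list(mean = rng$air, sd = 0),
               cranium = list(outer_scale = 0.96, thickness_mm = 6,
                              hu_mean = rng$bone, hu_sd = 0),
               soft_hu = list(mean = rng$soft, sd = 0),
               seed = seed)
}

ellipsoid_field <- function(X, Y, Z, prim) {
  ((X - prim$center[1]) / prim$semiaxes[1])^2 +
    ((Y - prim$center[2]) / prim$semiaxes[2])^2 +
    ((Z - prim$center[3]) / prim$semiaxes[3])^2
}

# class map evaluated at arbitrary world coordinates:
# 0 outside body, 1 soft tissue, 2 bone shell, 3 cavity air
phantom_class_at <- function(spec, X, Y, Z) {
  cls <- array(0L, dim = dim(X))
  head_q <- ellipsoid_field(X, Y, Z, spec$head)
  cls[head_q <= 1] <- 1L
  outer <- list(center = spec$head$center,
                semiaxes = spec$head$semiaxes * spec$cranium$outer_scale)
  inner <- list(center = spec$head$center,
                semiaxes = pmax(outer$semiaxes - spec$cranium$thickness_mm, 1))
  qo <- ellipsoid_field(X, Y, Z, outer)
  qi <- ellipsoid_field(X, Y, Z, inner)
  cls[cls == 1L & qo <= 1 & qi > 1] <- 2L
  for (cav in spec$air_cavities)
    cls[cls > 0L & ellipsoid_field(X, Y, Z, cav) <= 1] <- 3L
  cls
}

world_coordinate_arrays <- function(g) {
  xs <- g$origin[1] + (seq_len(g$dims[1]) - 1) * g$spacing[1]
  ys <- g$origin[2] + (seq_len(g$dims[2]) - 1) * g$spacing[2]
  zs <- g$origin[3] + (seq_len(g$dims[3]) - 1) * g$spacing[3]
  list(
    X = array(rep(xs, times = g$dims[2] * g$dims[3]), dim = g$dims),
    Y = array(rep(rep(ys, each = g$dims[1]), times = g$dims[3]),
              dim = g$dims),
    Z = array(rep(zs, each = g$dims[1] * g$dims[2]), dim = g$dims)
  )
}

#' Build a phantom from a specification
#'
#' Deterministic for a fixed spec (including its seed). Returns the pseudo-CT
#' in HU, the pseudo-MRI on its own grid offset by the known rigid transform,
#' the structure set on the CT grid, and a `truth` table with the generative
#' per-ROI mean HU and rED (the soft-tissue rED values are water-adjacent
#' assumptions, flagged as such).
#'
#' @param spec a `phantom_spec`.
#' @return object of class `phantom`: list with `ct`, `mri`, `structures`,
#'   `mri_transform`, `truth`, `spec`.
#' @export
build_phantom <- function(spec) {
  validate_phantom_spec(spec)
  g <- phantom_geometry(spec)
  co <- world_coordinate_arrays(g)
  cls <- phantom_class_at(spec, co$X, co$Y, co$Z)

  hu <- array(-1000, dim = g$dims)
  hu[cls == 1L] <- spec$soft_hu$mean
  hu[cls == 2L] <- spec$cranium$hu_mean
  hu[cls == 3L] <- spec$air_hu$mean
  set.seed(spec$seed)
  if (spec$noise_sd > 0) {
    inside <- cls > 0L
    hu[inside] <- hu[inside] + rnorm(sum(inside), 0, spec$noise_sd)
  }
  ct <- image_volume(hu, spacing = g$spacing, origin = g$origin, unit = "HU")

  masks <- list(body = list(role = "body", mask = cls > 0L))
  for (nm in names(spec$targets))
    masks[[nm]] <- list(role = "target",
                        mask = ellipsoid_field(co$X, co$Y, co$Z,
                                               spec$targets[[nm]]) <= 1)
  for (nm in names(spec$oars))
    masks[[nm]] <- list(role = "oar",
                        mask = ellipsoid_field(co$X, co$Y, co$Z,
                                               spec$oars[[nm]]) <= 1)
  structures <- structure_set(g, masks)
  if (!any(roi_mask(structures, "ptv_nx") & cls == 3L))
    stop("spec error: ptv_nx must intersect an air cavity", call. = FALSE)

  # pseudo-MRI: evaluate the anatomy at the inverse-transformed coordinates,
  # then apply a monotone intensity remap of the tissue class plus noise
  inv <- invert_transform(spec$mri_transform)
  q <- apply_transform(inv, cbind(as.vector(co$X), as.vector(co$Y),
                                  as.vector(co$Z)))
  mcls <- phantom_class_at(spec,
                           array(q[, 1], g$dims),
                           array(q[, 2], g$dims),
                           array(q[, 3], g$dims))
  mr_levels <- c(5, 420, 60, 30) # background, soft, bone, air
  mri_vals <- array(mr_levels[mcls + 1L], dim = g$dims)
  if (spec$noise_sd > 0)
    mri_vals <- mri_vals + rnorm(length(mri_vals), 0, spec$noise_sd / 2)
  mri <- image_volume(mri_vals, spacing = g$spacing, origin = g$origin,
                      unit = "MR")

  curve <- default_calibration_curve()
  truth_rows <- list()
  add_truth <- function(name, role, mask, hu_mean, assumed) {
    truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
      roi = name, role = role, n_voxels = sum(mask), true_hu = hu_mean,
      true_red = interp_curve(curve, hu_mean), assumed_soft = assumed)
  }
  add_truth("body", "body", cls > 0L, spec$soft_hu$mean, TRUE)
  add_truth("cranium", "bone", cls == 2L, spec$cranium$hu_mean, FALSE)
  add_truth("air_cavity", "air", cls == 3L, spec$air_hu$mean, FALSE)
  for (nm in names(spec$targets))
    add_truth(nm, "target", masks[[nm]]$mask, spec$soft_hu$mean, TRUE)
  for (nm in names(spec$oars))
    add_truth(nm, "oar", masks[[nm]]$mask, spec$soft_hu$mean, TRUE)

  structure(list(ct = ct, mri = mri, structures = structures,
                 mri_transform = spec$mri_transform,
                 truth = do.call(rbind, truth_rows), spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> seed %d, grid %s at (%g, %g, %g) mm\n", x$spec$seed,
              paste(x$spec$grid_shape, collapse = " x "), x$spec$spacing[1],
              x$spec$spacing[2], x$spec$spacing[3]))
  invisible(x)
}

#' Write a phantom to a directory
#'
#' Writes `ct.nii.gz`, `mri.nii.gz`, the structure-set manifest,
#' `transform.json` (the known CT-to-MRI rigid transform) and `truth.json`.
#'
#' @param phantom a `phantom`.
#' @param dir output directory.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(phantom$ct, file.path(dir, "ct.nii.gz"))
  write_volume(phantom$mri, file.path(dir, "mri.nii.gz"))
  write_structure_set(phantom$structures, file.path(dir, "structures"))
  jsonlite::write_json(
    list(rotation = phantom$mri_transform$rotation,
         translation = phantom$mri_transform$translation),
    file.path(dir, "transform.json"), digits = NA, matrix = "rowmajor")
  jsonlite::write_json(phantom$truth, file.path(dir, "truth.json"),
                       digits = NA, dataframe = "rows")
  invisible(dir)
}
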