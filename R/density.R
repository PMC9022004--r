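#' Piecewise-linear HU to relative-electron-density calibration curve
#'
#' Nodes must be strictly increasing in HU with non-decreasing rED, and must
#' contain the water node (0 HU, 1.0 rED). Conversion interpolates linearly
#' between nodes and clamps at both ends.
#'
#' @param nodes data frame (or 2-column matrix) with columns `hu`, `red`.
#' @return object of class `calibration_curve`.
#' @export
calibration_curve <- function(nodes) {
  nodes <- as.data.frame(nodes)
  names(nodes) <- c("hu", "red")
  if (nrow(nodes) < 2)
    stop("config error: a calibration curve needs at least 2 nodes",
         call. = FALSE)
  if (any(diff(nodes$hu) <= 0))
    stop("calibration HU nodes must be strictly increasing", call. = FALSE)
  if (any(diff(nodes$red) < 0))
    stop("calibration rED nodes must be non-decreasing", call. = FALSE)
  if (any(nodes$red < 0))
    stop("calibration rED values must be >= 0", call. = FALSE)
  if (!any(nodes$hu == 0 & nodes$red == 1))
    stop("calibration curve must contain the water node (0 HU, 1.0 rED)",
         call. = FALSE)
  structure(list(nodes = nodes), class = "calibration_curve")
}

#' Default HU to rED calibration
#'
#' A generic scanner-agnostic curve: air (-1000, 0.001), lung-like
#' (-300, 0.71), water (0, 1.0), trabecular transition (250, 1.12), dense
#' bone (1200, 1.72). Scanner-specific curves can be loaded from YAML with
#' [read_calibration_curve()].
#'
#' @export
default_calibration_curve <- function() {
  calibration_curve(data.frame(
    hu = c(-1000, -300, 0, 250, 1200),
    red = c(0.001, 0.71, 1.0, 1.12, 1.72)))
}

interp_curve <- function(curve, hu) {
  approx(curve$nodes$hu, curve$nodes$red, xout = hu, rule = 2)$y
}

#' @rdname default_calibration_curve
#' @param path YAML file holding a list of `[HU, rED]` pairs.
#' @export
read_calibration_curve <- function(path) {
  pairs <- yaml::read_yaml(path)
  m <- do.call(rbind, lapply(pairs, as.numeric))
  calibration_curve(data.frame(hu = m[, 1], red = m[, 2]))
}

#' @rdname default_calibration_curve
#' @param curve a `calibration_curve`.
#' @export
write_calibration_curve <- function(curve, path) {
  pairs <- lapply(seq_len(nrow(curve$nodes)),
                  function(i) c(curve$nodes$hu[i], curve$nodes$red[i]))
  yaml::write_yaml(pairs, path, precision = 15)
  invisible(path)
}

#' Convert an HU volume to relative electron density
#'
#' Voxelwise piecewise-linear interpolation on the calibration curve, clamped
#' to the end nodes; monotone non-decreasing in HU.
#'
#' @param vol `image_volume` with unit `"HU"`.
#' @param curve a `calibration_curve`.
#' @return `image_volume` with unit `"rED"`.
#' @export
hu_to_red <- function(vol, curve = default_calibration_curve()) {
  stopifnot(inherits(vol, "image_volume"))
  if (vol$unit != "HU") stop("`vol` must be HU-tagged", call. = FALSE)
  stopifnot(inherits(curve, "calibration_curve"))
  red <- array(interp_curve(curve, as.vector(vol$values)),
               dim = dim(vol$values))
  image_volume(red, spacing = vol$spacing, origin = vol$origin, unit = "rED")
}

#' Threshold-segmentation configuration for bone and air
#'
#' Bone is `HU > bone_hu`, air is `HU < air_hu`, both restricted to the body.
#' The manual contour clean-up of clinical practice is replaced by a
#' deterministic morphological closing plus removal of small connected
#' components.
#'
#' @param bone_hu bone threshold, HU (rule: HU strictly above).
#' @param air_hu air threshold, HU (rule: HU strictly below); must be below
#'   `bone_hu`.
#' @param min_component_cm3 connected components smaller than this are
#'   dropped (cm^3); 0 disables.
#' @param closing_radius morphological closing ball radius in voxels; 0
#'   disables.
#' @export
threshold_config <- function(bone_hu = 250, air_hu = -300,
                             min_component_cm3 = 0.5, closing_radius = 1) {
  if (air_hu >= bone_hu)
    stop("air threshold must be below the bone threshold", call. = FALSE)
  structure(list(bone_hu = bone_hu, air_hu = air_hu,
                 min_component_cm3 = min_component_cm3,
                 closing_radius = closing_radius),
            class = "threshold_config")
}

clean_mask <- function(mask, dims, spacing, cfg) {
  if (cfg$closing_radius > 0)
    mask <- array(cpp_close_mask(as.vector(mask), as.integer(dims),
                                 cfg$closing_radius), dim = dims)
  if (cfg$min_component_cm3 > 0 && any(mask)) {
    lab <- cpp_label_components(as.vector(mask), as.integer(dims))
    voxel_cm3 <- prod(spacing) / 1000
    keep <- which(tabulate(lab) * voxel_cm3 >= cfg$min_component_cm3)
    mask <- array(lab %in% keep, dim = dims)
  }
  mask
}

#' Threshold segmentation of bone and air on a planning CT
#'
#' Returns disjoint bone and air masks restricted to the body (exterior air is
#' excluded: the air ROI means internal cavities). Where closing makes the two
#' masks touch, bone wins.
#'
#' @param ct `image_volume`, HU.
#' @param body logical body mask on the CT grid.
#' @param cfg a `threshold_config`.
#' @return list with logical `bone` and `air` masks.
#' @export
segment_bone_air <- function(ct, body, cfg = threshold_config()) {
  stopifnot(inherits(ct, "image_volume"))
  if (ct$unit != "HU") stop("`ct` must be HU-tagged", call. = FALSE)
  if (!is.logical(body) || !all(dim(body) == dim(ct$values)))
    stop("`body` must be a logical mask on the CT grid", call. = FALSE)
  if (!any(body)) stop("input error: body mask is empty", call. = FALSE)
  dims <- dim(ct$values)
  bone <- clean_mask(ct$values > cfg$bone_hu & body, dims, ct$spacing, cfg)
  air <- clean_mask(ct$values < cfg$air_hu & body, dims, ct$spacing, cfg)
  air <- air & !bone
  list(bone = bone, air = air)
}

#' Per-ROI electron-density statistics
#'
#' Arithmetic mean over mask voxels, the quantity a planning system derives
#' from the planning CT for bulk assignment. Empty ROIs are recorded with
#' count 0 and flagged, never dropped.
#'
#' @param red `image_volume`, rED.
#' @param structures `structure_set` on the same grid.
#' @param hu optional HU `image_volume` to also report per-ROI mean HU.
#' @return data frame of class `roi_density_summary`: columns `roi`, `role`,
#'   `n_voxels`, `mean_hu`, `mean_red`, `sd_red`, `empty`.
#' @export
summarize_roi_red <- function(red, structures, hu = NULL) {
  stopifnot(inherits(red, "image_volume"), inherits(structures,
                                                    "structure_set"))
  if (red$unit != "rED") stop("`red` must be rED-tagged", call. = FALSE)
  if (!same_grid(red, structures))
    stop("`red` and the structure set must share a grid", call. = FALSE)
  if (!is.null(hu) && !same_grid(hu, structures))
    stop("`hu` must share the structure-set grid", call. = FALSE)
  rows <- lapply(names(structures$rois), function(nm) {
    m <- structures$rois[[nm]]$mask
    n <- sum(m)
    data.frame(
      roi = nm, role = structures$rois[[nm]]$role, n_voxels = n,
      mean_hu = if (!is.null(hu) && n > 0) mean(hu$values[m]) else NA_real_,
      mean_red = if (n > 0) mean(red$values[m]) else NA_real_,
      sd_red = if (n > 1) sd(red$values[m]) else NA_real_,
      empty = n == 0L)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("roi_density_summary", "data.frame")
  out
}

#' @rdname summarize_roi_red
#' @param summary an `roi_density_summary`.
#' @param path output CSV path.
#' @export
write_density_summary <- function(summary, path) {
  write.csv(summary, path, row.names = FALSE)
  invisible(path)
}
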