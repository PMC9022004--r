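#' Treatment plan specification
#'
#' A nine-field equidistant co-planar beam arrangement is the default, with
#' the standard head-and-neck prescription levels (70/70/60/54 Gy to
#' PTV_nx/PTV_nd/PTV_1/PTV_2 in 33 fractions). The isocenter defaults to the
#' PTV_nx centroid and the per-beam rectangular apertures default to the
#' projection of PTV_2 plus a margin; both are resolved against the reference
#' structure set when the plan is first used ([resolve_plan()]) and then
#' frozen.
#'
#' @param gantry_angles degrees in `[0, 360)`; 0 is anterior, 90 the
#'   patient's left (IEC convention, LPS frame).
#' @param isocenter mm triplet, or `NULL` to use the PTV_nx centroid.
#' @param weights per-beam weights, all `>= 0` with at least one positive.
#' @param field_size `NULL` (auto: bounding rectangle of the projected
#'   PTV_2 plus `field_margin`), a single `c(u, v)` mm pair used for every
#'   beam, or an n x 2 matrix.
#' @param field_margin mm added around the projected PTV_2 when `field_size`
#'   is automatic.
#' @param prescriptions named Gy vector for the V100% targets.
#' @param fractions positive integer (doses are reported as totals).
#' @param dose_grid_spacing mm; the engine computes on the rED grid, which is
#'   the comparison grid.
#' @export
plan_spec <- function(gantry_angles = c(0, 40, 80, 110, 160, 200, 250, 280,
                                        320),
                      isocenter = NULL,
                      weights = rep(1, length(gantry_angles)),
                      field_size = NULL, field_margin = 5,
                      prescriptions = c(ptv_nx = 70, ptv_nd = 70, ptv1 = 60,
                                        ptv2 = 54),
                      fractions = 33L, dose_grid_spacing = 2) {
  gantry_angles <- as.numeric(gantry_angles)
  if (any(gantry_angles < 0 | gantry_angles >= 360))
    stop("gantry angles must lie in [0, 360)", call. = FALSE)
  if (length(weights) != length(gantry_angles) || any(weights < 0) ||
      !any(weights > 0))
    stop("weights must be >= 0 with at least one > 0", call. = FALSE)
  if (any(prescriptions <= 0)) stop("prescriptions must be positive",
                                    call. = FALSE)
  if (fractions <= 0 || fractions != round(fractions))
    stop("fractions must be a positive integer", call. = FALSE)
  structure(list(gantry_angles = gantry_angles, isocenter = isocenter,
                 weights = as.numeric(weights), field_size = field_size,
                 field_margin = field_margin, prescriptions = prescriptions,
                 fractions = as.integer(fractions),
                 dose_grid_spacing = dose_grid_spacing),
            class = "plan_spec")
}

#' Simplified beam model
#'
#' Parameters of the analytic divergent-beam engine: effective linear
#' attenuation in water, a linear buildup ramp over the first stretch of
#' radiological depth, an error-function penumbra, inverse-square divergence
#' from a Unity-like source-axis distance, and an optional magnetic-boundary
#' (electron-return-effect) kernel that moves dose from the far side of a
#' sharp rED drop back to the near side.
#'
#' @param mu_eff effective linear attenuation, 1/cm in water (7 MV FFF-like).
#' @param buildup_cm buildup ramp length, cm of radiological depth.
#' @param penumbra_sigma Gaussian penumbra sigma at the isocenter plane, mm.
#' @param sad source-axis distance, mm.
#' @param b_on magnetic field on/off; gates the ERE kernel.
#' @param ere `list(threshold =, fraction =, range_mm =)`: interfaces are rED
#'   drops larger than `threshold` between consecutive voxels along a ray;
#'   `fraction` (in `[0, 1)`) scales the redistributed dose; `range_mm` is
#'   the exponential range of the kernel.
#' @export
beam_model <- function(mu_eff = 0.049, buildup_cm = 1.5, penumbra_sigma = 5,
                       sad = 1435, b_on = TRUE,
                       ere = list(threshold = 0.3, fraction = 0.15,
                                  range_mm = 10)) {
  if (mu_eff <= 0) stop("mu_eff must be > 0", call. = FALSE)
  if (penumbra_sigma <= 0) stop("penumbra sigma must be > 0", call. = FALSE)
  if (ere$fraction < 0 || ere$fraction >= 1)
    stop("ERE enhancement fraction must be in [0, 1)", call. = FALSE)
  structure(list(mu_eff = mu_eff, buildup_cm = buildup_cm,
                 penumbra_sigma = penumbra_sigma, sad = sad, b_on = b_on,
                 ere = ere),
            class = "beam_model")
}

#' Radiological depth along a segment
#'
#' Exact Siddon-style traversal: the integral of rED over the segment using
#' per-voxel intersection lengths, in cm. Symmetric in the endpoint order;
#' zero for a zero-length segment.
#'
#' @param red `image_volume`, rED.
#' @param p0,p1 mm triplets (world coordinates).
#' @export
radiological_depth <- function(red, p0, p1) {
  stopifnot(inherits(red, "image_volume"))
  if (any(!is.finite(p0)) || any(!is.finite(p1)))
    stop("endpoints must be finite", call. = FALSE)
  cpp_radiological_depth(as.vector(red$values), as.integer(dim(red$values)),
                         red$origin, red$spacing, as.numeric(p0),
                         as.numeric(p1))
}

beam_axes <- function(angle_deg) {
  th <- angle_deg * pi / 180
  # source direction from isocenter; 0 deg anterior (-y in LPS), 90 deg left
  sdir <- c(sin(th), -cos(th), 0)
  d <- -sdir # beam axis points from source towards isocenter
  u <- c(cos(th), sin(th), 0) # in-plane, perpendicular to the axis
  v <- c(0, 0, 1)
  list(sdir = sdir, d = d, u = u, v = v)
}

#' Resolve a plan against a reference structure set
#'
#' Fills in the isocenter (PTV_nx centroid) and the per-beam rectangular
#' apertures (bounding box of the projected PTV_2 plus the field margin) and
#' freezes them, so that recalculations on synthetic CTs reuse exactly the
#' reference-plan geometry.
#'
#' @param plan a `plan_spec`.
#' @param structures reference `structure_set` (planning-CT grid).
#' @param model a `beam_model` (for the source-axis distance).
#' @return a `plan_spec` with `isocenter` and `field_size` concrete and
#'   `resolved = TRUE`.
#' @export
resolve_plan <- function(plan, structures, model = beam_model()) {
  if (isTRUE(plan$resolved)) return(plan)
  if (is.null(plan$isocenter)) {
    if (!"ptv_nx" %in% names(structures$rois) ||
        !any(structures$rois$ptv_nx$mask))
      stop("config error: empty ptv_nx while the isocenter is defaulted",
           call. = FALSE)
    m <- roi_mask(structures, "ptv_nx")
    idx <- which(m, arr.ind = TRUE) - 1
    plan$isocenter <- colMeans(index_to_world(structures, idx))
  }
  nb <- length(plan$gantry_angles)
  if (is.null(plan$field_size)) {
    if (!"ptv2" %in% names(structures$rois))
      stop("config error: automatic field sizes require a ptv2 ROI",
           call. = FALSE)
    m <- roi_mask(structures, "ptv2")
    pts <- index_to_world(structures, which(m, arr.ind = TRUE) - 1)
    fs <- matrix(0, nb, 2)
    for (b in seq_len(nb)) {
      ax <- beam_axes(plan$gantry_angles[b])
      src <- plan$isocenter + model$sad * ax$sdir
      rel <- sweep(pts, 2, src, "-")
      tax <- as.vector(rel %*% ax$d)
      uo <- as.vector(rel %*% ax$u) * model$sad / tax
      vo <- as.vector(rel %*% ax$v) * model$sad / tax
      fs[b, ] <- c(max(abs(uo)), max(abs(vo))) + plan$field_margin
    }
    plan$field_size <- fs
  } else if (is.null(dim(plan$field_size))) {
    plan$field_size <- matrix(rep(plan$field_size / 2, each = nb), nb, 2)
  }
  plan$resolved <- TRUE
  plan
}

beam_matrix <- function(plan, model) {
  nb <- length(plan$gantry_angles)
  beams <- matrix(0, nb, 15)
  for (b in seq_len(nb)) {
    ax <- beam_axes(plan$gantry_angles[b])
    src <- plan$isocenter + model$sad * ax$sdir
    beams[b, ] <- c(src, ax$d, ax$u, ax$v, plan$field_size[b, ],
                    plan$weights[b])
  }
  beams
}

#' Compute dose with the simplified divergent-beam engine
#'
#' Per beam, the primary dose at a voxel is `weight x inverse-square x
#' exp(-mu_eff x radiological depth) x lateral penumbra profile`, with a
#' linear buildup ramp over the first `buildup_cm` of radiological depth;
#' beams are summed. With the magnetic field on, an exponential kernel adds
#' dose on the dense (proximal) side of every sharp along-ray rED drop and
#' removes it on the far side, emulating the electron return effect at
#' tissue--air interfaces. The total is optionally renormalized so the PTV_nx
#' reference point receives its prescription; the returned factor can be
#' reused unchanged for recalculations on synthetic CTs.
#'
#' @param red `image_volume`, rED (the CT-derived map or a synthetic CT).
#' @param plan a resolved `plan_spec` (see [resolve_plan()]); an unresolved
#'   plan is resolved against `structures`.
#' @param model a `beam_model`.
#' @param structures reference `structure_set`; needed to resolve the plan
#'   and/or normalize at the PTV_nx reference point.
#' @param norm_factor `NULL` to renormalize at the PTV_nx reference point
#'   (reference run), a number to reuse a frozen factor (sCT runs), or
#'   `NA` to skip normalization.
#' @return object of class `dose_grid`: `dose` (`image_volume`, Gy), `plan`,
#'   `model`, `norm_factor`, `norm_point`.
#' @export
compute_dose <- function(red, plan, model = beam_model(), structures = NULL,
                         norm_factor = NULL) {
  stopifnot(inherits(red, "image_volume"))
  if (red$unit != "rED") stop("`red` must be rED-tagged", call. = FALSE)
  if (!isTRUE(plan$resolved)) {
    if (is.null(structures))
      stop("an unresolved plan needs `structures`", call. = FALSE)
    plan <- resolve_plan(plan, structures, model)
  }
  beams <- beam_matrix(plan, model)
  vals <- cpp_compute_dose(as.vector(red$values),
                           as.integer(dim(red$values)), red$origin,
                           red$spacing, beams, model$mu_eff,
                           model$buildup_cm, model$penumbra_sigma, model$sad,
                           model$b_on, model$ere$threshold,
                           model$ere$fraction, model$ere$range_mm)
  dose <- array(vals, dim = dim(red$values))
  norm_point <- NULL
  if (is.null(norm_factor)) {
    if (is.null(structures))
      stop("normalization at the PTV_nx point needs `structures`",
           call. = FALSE)
    norm_point <- roi_reference_point(structures, "ptv_nx")
    raw <- dose[norm_point$index[1] + 1, norm_point$index[2] + 1,
                norm_point$index[3] + 1]
    if (raw <= 0)
      stop("reference-point dose is zero; cannot normalize", call. = FALSE)
    rx <- plan$prescriptions[["ptv_nx"]]
    norm_factor <- rx / raw
  }
  if (!is.na(norm_factor)) dose <- dose * norm_factor
  structure(list(dose = image_volume(dose, spacing = red$spacing,
                                     origin = red$origin, unit = "Gy"),
                 plan = plan, model = model, norm_factor = norm_factor,
                 norm_point = norm_point),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> max %.2f Gy, %d beams, norm factor %s\n",
              max(x$dose$values), length(x$plan$gantry_angles),
              format(x$norm_factor)))
  invisible(x)
}

#' Electron-return-effect perturbation along a ray
#'
#' Operates on uniformly sampled dose and rED profiles along one ray
#' (proximal to distal). At every sharp rED drop, dose is removed on the far
#' (low-density) side with an exponential kernel and the identical integral
#' is added back on the near (dense) side, so the ray total is conserved
#' exactly. Identity when the field is off or no interface crosses the drop
#' threshold.
#'
#' @param dose numeric vector, dose samples along the ray.
#' @param red numeric vector, rED at the same samples.
#' @param step_mm sample spacing, mm.
#' @param kernel `list(threshold =, fraction =, range_mm =)`.
#' @param b_on logical; `FALSE` returns `dose` unchanged.
#' @return perturbed dose vector with `sum(out) == sum(dose)` per ray.
#' @export
ere_perturbation <- function(dose, red, step_mm = 1,
                             kernel = list(threshold = 0.3, fraction = 0.15,
                                           range_mm = 10),
                             b_on = TRUE) {
  stopifnot(length(dose) == length(red))
  if (!b_on || length(dose) < 2) return(dose)
  n <- length(dose)
  out <- dose
  drops <- which(red[-n] - red[-1] > kernel$threshold & red[-n] > 0)
  for (i in drops) {
    # distal side: samples i+1 .. n; proximal side: 1 .. i
    wd <- exp(-(seq(i + 1, n) - (i + 1)) * step_mm / kernel$range_mm)
    rel <- 1 - red[i + 1] / red[i]
    removed <- kernel$fraction * rel * dose[i + 1] * wd
    removed <- pmin(removed, out[(i + 1):n]) # never drive dose negative
    wp <- exp(-(i - seq_len(i)) * step_mm / kernel$range_mm)
    add <- wp / sum(wp) * sum(removed)
    out[(i + 1):n] <- out[(i + 1):n] - removed
    out[seq_len(i)] <- out[seq_len(i)] + add
  }
  out
}
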