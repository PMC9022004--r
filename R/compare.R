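#' Gamma-analysis criteria
#'
#' Global gamma with a dose tolerance in percent of the normalization dose, a
#' distance-to-agreement in mm, and a low-dose threshold below which reference
#' voxels are not evaluated. The evaluated dose is trilinearly interpolated on
#' a sub-voxel lattice (step `dta / step_divisor`) inside a ball of radius
#' `search_radius x dta`.
#'
#' @param delta dose-difference tolerance, % (e.g. 1 or 3).
#' @param dta distance-to-agreement, mm (e.g. 1 or 3).
#' @param threshold low-dose threshold, % of the normalization dose.
#' @param normalization `"global-max"` (reference-dose maximum) or
#'   `"prescription"` (supply `norm_dose`).
#' @param norm_dose normalization dose in Gy when `normalization =
#'   "prescription"`.
#' @param search_radius search radius in multiples of `dta`.
#' @param step_divisor sub-voxel search step is `dta / step_divisor`.
#' @export
gamma_criteria <- function(delta = 3, dta = 3, threshold = 10,
                           normalization = c("global-max", "prescription"),
                           norm_dose = NULL, search_radius = 3,
                           step_divisor = 10) {
  normalization <- match.arg(normalization)
  if (delta <= 0 || dta <= 0) stop("delta and dta must be > 0", call. = FALSE)
  if (threshold < 0 || threshold >= 100)
    stop("threshold must be in [0, 100)", call. = FALSE)
  if (normalization == "prescription" &&
      (is.null(norm_dose) || norm_dose <= 0))
    stop("prescription normalization needs a positive `norm_dose`",
         call. = FALSE)
  structure(list(delta = delta, dta = dta, threshold = threshold,
                 normalization = normalization, norm_dose = norm_dose,
                 search_radius = as.integer(search_radius),
                 step_divisor = as.integer(step_divisor)),
            class = "gamma_criteria")
}

as_dose_volume <- function(x) {
  if (inherits(x, "dose_grid")) x$dose
  else if (inherits(x, "image_volume")) x
  else stop("expected a dose_grid or image_volume", call. = FALSE)
}

#' 3D global gamma index
#'
#' For every reference voxel at or above the low-dose threshold, the gamma
#' index is the minimum over nearby evaluated positions of
#' `sqrt(dist^2/dta^2 + dose_diff^2/(delta% of D_norm)^2)`, searched on an
#' interpolated sub-voxel lattice. Both doses must already live on the same
#' (reference) grid.
#'
#' @param reference,evaluated `dose_grid` or Gy `image_volume` objects on a
#'   common grid.
#' @param criteria a `gamma_criteria`.
#' @return object of class `gamma_result`: `gamma_map` (`image_volume`,
#'   dimensionless, `NA` below threshold), `pass_rate` (%), `n_evaluated`,
#'   `criteria`, `norm_dose`.
#' @export
gamma_index <- function(reference, evaluated, criteria = gamma_criteria()) {
  ref <- as_dose_volume(reference)
  ev <- as_dose_volume(evaluated)
  if (!same_grid(ref, ev))
    stop("usage error: doses must share a grid; resample first",
         call. = FALSE)
  dnorm_val <- if (criteria$normalization == "global-max") max(ref$values)
               else criteria$norm_dose
  if (dnorm_val <= 0) stop("normalization dose must be positive",
                           call. = FALSE)
  thr_abs <- criteria$threshold / 100 * dnorm_val
  res <- cpp_gamma(as.vector(ref$values), as.vector(ev$values),
                   as.integer(dim(ref$values)), ref$origin, ref$spacing,
                   criteria$delta, criteria$dta, dnorm_val, thr_abs,
                   criteria$search_radius, criteria$step_divisor)
  structure(list(gamma_map = image_volume(array(res$gamma,
                                                dim = dim(ref$values)),
                                          spacing = ref$spacing,
                                          origin = ref$origin, unit = "MR"),
                 pass_rate = res$pass_rate, n_evaluated = res$n_evaluated,
                 criteria = criteria, norm_dose = dnorm_val),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %g%%/%g mm: pass rate %.2f%% (%d voxels)\n",
              x$criteria$delta, x$criteria$dta, x$pass_rate,
              as.integer(x$n_evaluated)))
  invisible(x)
}

#' Reference point of an ROI: centroid snapped into the mask
#'
#' The mask centroid may fall outside a non-convex ROI; the reference point
#' is the in-mask voxel centre nearest to the centroid.
#'
#' @param structures a `structure_set`.
#' @param roi ROI name.
#' @return list with `point` (mm) and `index` (0-based voxel triplet).
#' @export
roi_reference_point <- function(structures, roi) {
  m <- roi_mask(structures, roi)
  if (!any(m)) stop("ROI `", roi, "` is empty", call. = FALSE)
  idx <- which(m, arr.ind = TRUE) - 1
  pts <- index_to_world(structures, idx)
  centroid <- colMeans(pts)
  d2 <- rowSums(sweep(pts, 2, centroid, "-")^2)
  i <- which.min(d2)
  list(point = pts[i, ], index = as.integer(idx[i, ]))
}

#' Point-dose difference at an ROI reference point
#'
#' Percent difference of the evaluated dose relative to the reference dose at
#' the ROI's snapped centroid (the PTV_nx high-dose point in the standard
#' workflow): `100 * (D_eval - D_ref) / D_ref`.
#'
#' @param reference,evaluated doses on a common grid.
#' @param structures `structure_set` on the same grid.
#' @param roi ROI name (default `"ptv_nx"`).
#' @export
point_dose_difference <- function(reference, evaluated, structures,
                                  roi = "ptv_nx") {
  ref <- as_dose_volume(reference)
  ev <- as_dose_volume(evaluated)
  if (!same_grid(ref, ev) || !same_grid(ref, structures))
    stop("doses and structures must share a grid", call. = FALSE)
  rp <- roi_reference_point(structures, roi)
  i <- rp$index + 1
  dr <- ref$values[i[1], i[2], i[3]]
  if (dr == 0)
    stop("undefined-reference error: reference dose is zero at the point",
         call. = FALSE)
  100 * (ev$values[i[1], i[2], i[3]] - dr) / dr
}

# dose at a (possibly fractional) cumulative-volume level, voxels, on the
# descending order statistics with linear interpolation (type-7 convention)
dose_at_volume <- function(sorted_desc, v_voxels) {
  n <- length(sorted_desc)
  if (n == 1L) return(sorted_desc[1])
  r <- 1 + (v_voxels / n) * (n - 1)
  r <- min(max(r, 1), n)
  lo <- floor(r)
  hi <- ceiling(r)
  sorted_desc[lo] + (r - lo) * (sorted_desc[hi] - sorted_desc[lo])
}

#' DVH metrics per ROI
#'
#' Computes D_mean, D_max, D98%, D2%, D1cc and (for ROIs with a prescription)
#' V100% from the voxel doses inside each mask. Dx% is the dose level such
#' that x% of the ROI volume receives at least that dose, interpolated
#' between the sorted order statistics; D1cc is the dose exceeded by exactly
#' 1 cm^3 of the ROI. For ROIs smaller than 1 cm^3, D1cc is reported as D_max
#' and flagged.
#'
#' @param dose a `dose_grid` or Gy `image_volume`.
#' @param structures `structure_set` on the dose grid.
#' @param prescriptions named Gy vector; V100% is the percent of ROI volume
#'   at or above the ROI's prescription (NA without one).
#' @param rois ROI names to evaluate (default: all except body).
#' @return data frame of class `dvh_metrics`: `roi`, `role`, `n_voxels`,
#'   `d_mean`, `d_max`, `d98`, `d2`, `d1cc`, `v100`, `d1cc_is_dmax`.
#' @export
dvh_metrics <- function(dose, structures, prescriptions = NULL,
                        rois = NULL) {
  dv <- as_dose_volume(dose)
  if (!same_grid(dv, structures))
    stop("dose and structures must share a grid", call. = FALSE)
  if (is.null(rois))
    rois <- setdiff(names(structures$rois),
                    names(which(roi_roles(structures) == "body")))
  voxel_cm3 <- prod(grid_geometry(structures)$spacing) / 1000
  rows <- lapply(rois, function(nm) {
    m <- roi_mask(structures, nm)
    d <- sort(dv$values[m], decreasing = TRUE)
    n <- length(d)
    if (n == 0)
      return(data.frame(roi = nm, role = structures$rois[[nm]]$role,
                        n_voxels = 0L, d_mean = NA_real_, d_max = NA_real_,
                        d98 = NA_real_, d2 = NA_real_, d1cc = NA_real_,
                        v100 = NA_real_, d1cc_is_dmax = NA))
    small <- n * voxel_cm3 < 1
    d1cc <- if (small) d[1] else dose_at_volume(d, 1 / voxel_cm3)
    rx <- if (!is.null(prescriptions) && nm %in% names(prescriptions))
      prescriptions[[nm]] else NA_real_
    data.frame(
      roi = nm, role = structures$rois[[nm]]$role, n_voxels = n,
      d_mean = mean(d), d_max = d[1],
      d98 = dose_at_volume(d, 0.98 * n),
      d2 = dose_at_volume(d, 0.02 * n),
      d1cc = d1cc,
      v100 = if (is.na(rx)) NA_real_ else 100 * sum(d >= rx) / n,
      d1cc_is_dmax = small)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("dvh_metrics", "data.frame")
  out
}

#' Compare synthetic-CT dose recalculations against the reference dose
#'
#' Runs the full evaluation battery for each strategy: gamma analysis at every
#' requested criteria, the PTV_nx point-dose difference, and per-ROI DVH
#' metric differences (sCT minus CT).
#'
#' @param reference reference `dose_grid` (planning-CT rED).
#' @param evaluated named list of `dose_grid`s, one per strategy, on the
#'   reference grid.
#' @param structures reference `structure_set`.
#' @param criteria_list list of `gamma_criteria`.
#' @param prescriptions named Gy vector for V100%.
#' @param point_roi ROI for the point-dose comparison.
#' @param keep_gamma_maps retain the gamma maps in the result (memory-heavy).
#' @return object of class `comparison_report` with data frames `gamma`
#'   (strategy, delta, dta, pass_rate, n_evaluated), `point` (strategy,
#'   roi, diff_pct), and `dvh` (strategy, roi, metric, reference, evaluated,
#'   diff).
#' @export
compare_strategies <- function(reference, evaluated, structures,
                               criteria_list = list(gamma_criteria(1, 1),
                                                    gamma_criteria(3, 3)),
                               prescriptions = c(ptv_nx = 70, ptv_nd = 70,
                                                 ptv1 = 60, ptv2 = 54),
                               point_roi = "ptv_nx",
                               keep_gamma_maps = FALSE) {
  stopifnot(is.list(evaluated), length(evaluated) > 0,
            !is.null(names(evaluated)))
  ref_dvh <- dvh_metrics(reference, structures, prescriptions)
  gamma_rows <- list(); point_rows <- list(); dvh_rows <- list()
  gamma_maps <- list()
  metrics <- c("d_mean", "d_max", "d98", "d2", "d1cc", "v100")
  for (st in names(evaluated)) {
    for (cr in criteria_list) {
      gr <- gamma_index(reference, evaluated[[st]], cr)
      gamma_rows[[length(gamma_rows) + 1L]] <- data.frame(
        strategy = st, delta = cr$delta, dta = cr$dta,
        pass_rate = gr$pass_rate, n_evaluated = gr$n_evaluated)
      if (keep_gamma_maps)
        gamma_maps[[paste(st, cr$delta, cr$dta, sep = "_")]] <- gr$gamma_map
    }
    point_rows[[length(point_rows) + 1L]] <- data.frame(
      strategy = st, roi = point_roi,
      diff_pct = point_dose_difference(reference, evaluated[[st]],
                                       structures, point_roi))
    ev_dvh <- dvh_metrics(evaluated[[st]], structures, prescriptions)
    for (met in metrics) {
      keep <- !is.na(ref_dvh[[met]])
      dvh_rows[[length(dvh_rows) + 1L]] <- data.frame(
        strategy = st, roi = ref_dvh$roi[keep], metric = met,
        reference = ref_dvh[[met]][keep], evaluated = ev_dvh[[met]][keep],
        diff = ev_dvh[[met]][keep] - ref_dvh[[met]][keep])
    }
  }
  structure(list(gamma = do.call(rbind, gamma_rows),
                 point = do.call(rbind, point_rows),
                 dvh = do.call(rbind, dvh_rows),
                 gamma_maps = if (keep_gamma_maps) gamma_maps else NULL,
                 criteria = criteria_list),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n gamma pass rates (%):\n")
  print(x$gamma, row.names = FALSE)
  cat(" point-dose differences (%):\n")
  print(x$point, row.names = FALSE)
  invisible(x)
}

#' Serialize a comparison report to JSON (and back)
#'
#' @param report a `comparison_report`.
#' @param path JSON path.
#' @export
write_comparison_report <- function(report, path) {
  jsonlite::write_json(list(gamma = report$gamma, point = report$point,
                            dvh = report$dvh),
                       path, dataframe = "rows", digits = NA)
  invisible(path)
}

#' @rdname write_comparison_report
#' @export
read_comparison_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(gamma = x$gamma, point = x$point, dvh = x$dvh,
                 gamma_maps = NULL, criteria = NULL),
            class = "comparison_report")
}
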