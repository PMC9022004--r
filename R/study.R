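#' Study configuration for a synthetic cohort run
#'
#' Bundles every tunable of the end-to-end workflow: the cohort of phantom
#' seeds, the HU-to-rED calibration, the bone/air segmentation thresholds,
#' the bulk-assignment strategies and precedence, the plan and beam model,
#' and the gamma criteria.
#'
#' @param seeds integer vector of phantom seeds (one synthetic subject each).
#' @param calibration a `calibration_curve`.
#' @param thresholds a `threshold_config`.
#' @param plan a `plan_spec`.
#' @param model a `beam_model`.
#' @param criteria list of `gamma_criteria` (default 1%/1 mm and 3%/3 mm at a
#'   10% threshold).
#' @param strategies character subset of `c("tailor", "icru",
#'   "homogeneity")`.
#' @param prescriptions named Gy vector for the V100% metrics.
#' @param out_dir optional output directory for the report files.
#' @param verbose print per-stage progress.
#' @export
study_config <- function(seeds = 1:10,
                         calibration = default_calibration_curve(),
                         thresholds = threshold_config(),
                         plan = plan_spec(),
                         model = beam_model(),
                         criteria = list(gamma_criteria(1, 1),
                                         gamma_criteria(3, 3)),
                         strategies = c("tailor", "icru", "homogeneity"),
                         prescriptions = c(ptv_nx = 70, ptv_nd = 70,
                                           ptv1 = 60, ptv2 = 54),
                         out_dir = NULL, verbose = FALSE) {
  if (length(seeds) < 1) stop("cohort must be non-empty", call. = FALSE)
  if (length(criteria) < 1) stop("criteria list must be non-empty",
                                 call. = FALSE)
  strategies <- match.arg(strategies,
                          c("tailor", "icru", "homogeneity"),
                          several.ok = TRUE)
  structure(list(seeds = as.integer(seeds), calibration = calibration,
                 thresholds = thresholds, plan = plan, model = model,
                 criteria = criteria, strategies = strategies,
                 prescriptions = prescriptions, out_dir = out_dir,
                 verbose = isTRUE(verbose)),
            class = "study_config")
}

study_log <- function(config, ...) {
  if (config$verbose) message(sprintf(...))
}

#' Run the full evaluation for one synthetic subject
#'
#' Builds the phantom, derives the rED map and the bone/air contours on the
#' planning CT, propagates all contours to the pseudo-MRI through the known
#' rigid transform, builds each synthetic CT on the MRI grid and resamples it
#' back to the CT grid, computes the reference dose (normalized at the PTV_nx
#' point) and recalculates the frozen plan on every synthetic CT, then runs
#' the comparison battery on the reference grid.
#'
#' @param seed phantom seed identifying the subject.
#' @param config a `study_config`.
#' @return list with `seed`, `report` (a `comparison_report`), `summary`
#'   (ROI density summary), `provenance` (frozen plan geometry, weights and
#'   normalization factor).
#' @export
run_subject <- function(seed, config = study_config()) {
  study_log(config, "[seed %d] building phantom", seed)
  ph <- build_phantom(default_npc_spec(seed))
  ct <- ph$ct
  red_ct <- hu_to_red(ct, config$calibration)
  body <- roi_mask(ph$structures, "body")
  seg <- segment_bone_air(ct, body, config$thresholds)
  rois <- ph$structures$rois
  rois$bone <- list(role = "bone", mask = seg$bone)
  rois$air <- list(role = "air", mask = seg$air)
  structures_ct <- structure_set(ph$structures$geometry, rois)
  summary <- summarize_roi_red(red_ct, structures_ct, hu = ct)

  study_log(config, "[seed %d] propagating contours to MRI", seed)
  mr_geom <- grid_geometry(ph$mri)
  structures_mr <- propagate_structures(structures_ct, mr_geom,
                                        ph$mri_transform)
  back <- invert_transform(ph$mri_transform)

  scts <- list()
  for (st in config$strategies) {
    tab <- make_assignment_table(st, summary)
    sct_mr <- build_sct(structures_mr, tab, summary)
    scts[[st]] <- resample_to_grid(sct_mr$red_map,
                                   grid_geometry(ct), back,
                                   mode = "linear")
  }

  study_log(config, "[seed %d] reference dose", seed)
  plan <- resolve_plan(config$plan, structures_ct, config$model)
  ref_dose <- compute_dose(red_ct, plan, config$model, structures_ct,
                           norm_factor = NULL)
  doses <- list()
  for (st in config$strategies) {
    study_log(config, "[seed %d] recalculating on sCT_%s", seed, st)
    doses[[st]] <- compute_dose(scts[[st]], plan, config$model,
                                structures_ct,
                                norm_factor = ref_dose$norm_factor)
  }

  study_log(config, "[seed %d] comparing", seed)
  report <- compare_strategies(ref_dose, doses, structures_ct,
                               criteria_list = config$criteria,
                               prescriptions = config$prescriptions)
  list(seed = seed, report = report, summary = summary,
       provenance = list(
         isocenter = plan$isocenter,
         field_size = plan$field_size,
         weights = plan$weights,
         norm_factor = ref_dose$norm_factor))
}

#' Run a full synthetic-cohort study
#'
#' Executes [run_subject()] for every seed (a failing subject is recorded as
#' failed and never aborts the cohort), assembles the per-subject rows, and
#' adds cohort-level statistics: mean and sample SD per strategy x metric
#' cell, plus Wilcoxon signed-rank contrasts of the tailored strategy against
#' the other two.
#'
#' @param config a `study_config`.
#' @return object of class `study_report`: data frames `gamma` (subject x
#'   strategy x criteria pass rates), `point`, `dvh`, `cohort` (summary
#'   cells), `tests` (paired contrasts), plus `failed` seeds and
#'   `provenance`.
#' @export
run_study <- function(config = study_config()) {
  results <- list(); failed <- list()
  for (seed in config$seeds) {
    res <- tryCatch(run_subject(seed, config), error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("subject %d failed: %s", seed, conditionMessage(res)))
      failed[[length(failed) + 1L]] <- data.frame(
        seed = seed, error = conditionMessage(res))
    } else {
      results[[length(results) + 1L]] <- res
    }
  }
  if (length(results) == 0) stop("every subject failed", call. = FALSE)

  gamma <- do.call(rbind, lapply(results, function(r)
    cbind(subject = r$seed, r$report$gamma)))
  point <- do.call(rbind, lapply(results, function(r)
    cbind(subject = r$seed, r$report$point)))
  dvh <- do.call(rbind, lapply(results, function(r)
    cbind(subject = r$seed, r$report$dvh)))
  summaries <- do.call(rbind, lapply(results, function(r) {
    s <- as.data.frame(r$summary)
    cbind(subject = r$seed, s)
  }))

  cohort_rows <- list()
  add_cell <- function(metric, strategy, values, extra = list()) {
    if (length(values) >= 2) {
      s <- summarize_values(values)
      cohort_rows[[length(cohort_rows) + 1L]] <<- data.frame(
        metric = metric, strategy = strategy, mean = s$mean, sd = s$sd,
        n = length(values))
    }
  }
  for (st in unique(gamma$strategy)) {
    for (i in seq_len(nrow(unique(gamma[, c("delta", "dta")])))) {
      cd <- unique(gamma[, c("delta", "dta")])[i, ]
      v <- gamma$pass_rate[gamma$strategy == st & gamma$delta == cd$delta &
                             gamma$dta == cd$dta]
      add_cell(sprintf("gpr_%g_%g", cd$delta, cd$dta), st, v)
    }
    add_cell("point_diff", st, point$diff_pct[point$strategy == st])
  }
  cohort <- do.call(rbind, cohort_rows)

  tests <- list()
  if (length(results) >= 5 && "tailor" %in% config$strategies) {
    for (other in intersect(c("icru", "homogeneity"), config$strategies)) {
      for (i in seq_len(nrow(unique(gamma[, c("delta", "dta")])))) {
        cd <- unique(gamma[, c("delta", "dta")])[i, ]
        sel <- gamma$delta == cd$delta & gamma$dta == cd$dta
        a <- gamma$pass_rate[sel & gamma$strategy == "tailor"]
        b <- gamma$pass_rate[sel & gamma$strategy == other]
        wt <- wilcoxon_signed_rank(paired_sample(a, b))
        tests[[length(tests) + 1L]] <- data.frame(
          metric = sprintf("gpr_%g_%g", cd$delta, cd$dta),
          contrast = paste0("tailor_vs_", other), W = wt$W, z = wt$z,
          p = wt$p, n = wt$n_effective)
      }
      a <- point$diff_pct[point$strategy == "tailor"]
      b <- point$diff_pct[point$strategy == other]
      wt <- wilcoxon_signed_rank(paired_sample(a, b))
      tests[[length(tests) + 1L]] <- data.frame(
        metric = "point_diff", contrast = paste0("tailor_vs_", other),
        W = wt$W, z = wt$z, p = wt$p, n = wt$n_effective)
    }
  }
  tests <- if (length(tests)) do.call(rbind, tests) else NULL

  report <- structure(list(
    gamma = gamma, point = point, dvh = dvh, summaries = summaries,
    cohort = cohort, tests = tests,
    failed = if (length(failed)) do.call(rbind, failed) else NULL,
    provenance = lapply(results, function(r)
      c(list(seed = r$seed), r$provenance)),
    config_seeds = config$seeds), class = "study_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_study_report(report, config$out_dir)
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d subjects (%d failed)\n",
              length(unique(x$gamma$subject)),
              if (is.null(x$failed)) 0L else nrow(x$failed)))
  cat(" cohort summary:\n")
  print(x$cohort, row.names = FALSE)
  if (!is.null(x$tests)) {
    cat(" paired contrasts:\n")
    print(x$tests, row.names = FALSE)
  }
  invisible(x)
}

#' Write a study report as JSON plus flat CSV tables
#'
#' The JSON is written atomically (temp file + rename).
#'
#' @param report a `study_report`.
#' @param dir output directory.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".json")
  jsonlite::write_json(
    list(gamma = report$gamma, point = report$point, dvh = report$dvh,
         cohort = report$cohort, tests = report$tests,
         failed = report$failed),
    tmp, dataframe = "rows", digits = NA, null = "null")
  file.rename(tmp, file.path(dir, "study_report.json"))
  write.csv(report$gamma, file.path(dir, "gamma.csv"), row.names = FALSE)
  write.csv(report$point, file.path(dir, "point_dose.csv"),
            row.names = FALSE)
  write.csv(report$dvh, file.path(dir, "dvh.csv"), row.names = FALSE)
  write.csv(report$cohort, file.path(dir, "cohort_summary.csv"),
            row.names = FALSE)
  invisible(dir)
}
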