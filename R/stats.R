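#' Mean and sample standard deviation of a cohort column
#'
#' @param values numeric vector, length >= 2, no missing entries.
#' @return list with `mean` and `sd` (n-1 denominator).
#' @export
summarize_values <- function(values) {
  if (length(values) < 2 || anyNA(values))
    stop("input error: need >= 2 non-missing values", call. = FALSE)
  list(mean = mean(values), sd = sd(values))
}

#' Paired cohort sample
#'
#' @param a,b equal-length numeric vectors (one value per subject under each
#'   condition).
#' @param labels subject identifiers.
#' @export
paired_sample <- function(a, b, labels = seq_along(a)) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b) || length(a) < 2)
    stop("paired sample needs equal lengths >= 2", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("missing entries are not allowed",
                                 call. = FALSE)
  structure(list(labels = labels, a = a, b = b), class = "paired_sample")
}

# exact null distribution of the positive-rank sum via sign-flip convolution;
# ranks may be midranks (half-integers), handled on a doubled integer lattice
exact_signed_rank_p <- function(ranks, w_obs) {
  r2 <- as.integer(round(2 * ranks))
  tot <- sum(r2)
  dist <- numeric(tot + 1) # index i -> probability of doubled-W = i - 1
  dist[1] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), dist[seq_len(tot + 1 - r)])
    dist <- (dist + shifted) / 2
  }
  w2 <- round(2 * w_obs)
  p_le <- sum(dist[seq_len(w2 + 1)])
  p_ge <- sum(dist[seq(w2 + 1, tot + 1)])
  min(1, 2 * min(p_le, p_ge))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' The default is the normal approximation as used by common statistical
#' packages: zero differences are dropped, ties are mid-ranked, the variance
#' carries the tie correction, and no continuity correction is applied:
#' `z = (W - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24 - sum(t^3 - t)/48)` with `W`
#' the positive-rank sum. The exact method enumerates all `2^n` sign
#' assignments (n <= 20 after dropping zeros).
#'
#' @param sample a `paired_sample`, or a numeric vector of values `a` when
#'   `b` is given.
#' @param b optional second vector when `sample` is a plain vector.
#' @param method `"normal"` (asymptotic) or `"exact"`.
#' @return list with `W`, `z`, `p`, `method`, `n_effective`.
#' @export
wilcoxon_signed_rank <- function(sample, b = NULL,
                                 method = c("normal", "exact")) {
  method <- match.arg(method)
  if (!inherits(sample, "paired_sample")) sample <- paired_sample(sample, b)
  d <- sample$a - sample$b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    stop("degenerate-sample error: all paired differences are zero",
         call. = FALSE)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / 48
  mu <- n * (n + 1) / 4
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - tie_corr)
  z <- if (sigma > 0) (W - mu) / sigma else NA_real_
  if (method == "exact") {
    if (n > 20)
      stop("exact method supports at most 20 non-zero pairs", call. = FALSE)
    p <- exact_signed_rank_p(r, W)
  } else {
    if (n < 5)
      warning("normal approximation with fewer than 5 non-zero pairs")
    if (sigma == 0)
      stop("degenerate-sample error: zero variance", call. = FALSE)
    p <- 2 * pnorm(-abs(z))
  }
  list(W = W, z = z, p = p, method = method, n_effective = n)
}

#' Published reference cohort tables
#'
#' Per-patient results for a published 10-patient nasopharyngeal-carcinoma
#' cohort evaluated on a 1.5 T MR-Linac, shipped with the package as
#' plain-text fixtures: gamma passing rates (1%/1 mm and 3%/3 mm) and PTV_nx
#' point-dose differences for the three bulk-assignment strategies against
#' the planning CT. Only the per-patient rows are stored; summary statistics
#' are always recomputed.
#'
#' @return data frame with a `patient` column and one column per strategy x
#'   criterion (`reference_gpr`) or per strategy (`reference_point_dose`).
#' @export
reference_gpr <- function() {
  read.csv(system.file("extdata", "cohort_gpr.csv", package = "sctdosim"))
}

#' @rdname reference_gpr
#' @export
reference_point_dose <- function() {
  read.csv(system.file("extdata", "cohort_point_dose.csv",
                       package = "sctdosim"))
}
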