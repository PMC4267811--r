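#' Exact expected PD of m planning units drawn without replacement
#'
#' The rarefaction null model: planning units are drawn uniformly at random
#' without replacement, and the expected PD follows from the per-branch
#' probability of occurring in the draw. A branch present in `n_b` of `N`
#' units is missed by an `m`-subset with probability
#' `choose(N - n_b, m) / choose(N, m)`, so
#' `E[PD(m)] = sum_b l_b * (1 - choose(N - n_b, m) / choose(N, m))`.
#' Binomial ratios are computed in log space ([lchoose()]), so there is no
#' factorial overflow even for thousands of planning units.
#'
#' @param incidence a `branch_incidence` object.
#' @param m number of planning units drawn, `0 <= m <= N`.
#' @return expected PD in branch-length units.
#' @export
expected_pd_exact <- function(incidence, m) {
  stopifnot(inherits(incidence, "branch_incidence"))
  N <- incidence$n_pu
  m <- as.integer(m)
  if (is.na(m) || m < 0L || m > N) {
    stop("m must be between 0 and the number of planning units (", N, ")",
         call. = FALSE)
  }
  if (m == 0L) return(0)
  # lchoose(a, b) is -Inf for a < b, so impossible misses contribute prob 1
  p_miss <- exp(lchoose(N - incidence$n_b, m) - lchoose(N, m))
  contrib <- incidence$length * (1 - p_miss)
  # clamp to [0, l_b] against negative-zero round-off
  contrib <- pmin(pmax(contrib, 0), incidence$length)
  sum(contrib)
}

#' Monte-Carlo expected PD (validation cross-check)
#'
#' Estimates the rarefaction expectation by repeatedly sampling uniform
#' m-subsets of planning units without replacement and averaging their PD.
#'
#' @param incidence a `branch_incidence` object.
#' @param m number of planning units drawn.
#' @param samples number of random subsets (default 1000).
#' @param seed optional integer seed.
#' @return list with `mean`, `se` (standard error of the mean), `samples`.
#' @export
expected_pd_montecarlo <- function(incidence, m, samples = 1000L, seed = NULL) {
  stopifnot(inherits(incidence, "branch_incidence"))
  N <- incidence$n_pu
  m <- as.integer(m)
  samples <- as.integer(samples)
  if (is.na(m) || m < 0L || m > N) {
    stop("m must be between 0 and the number of planning units (", N, ")",
         call. = FALSE)
  }
  if (is.na(samples) || samples < 1L) stop("samples must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  vals <- vapply(seq_len(samples), function(i) {
    compute_pd(incidence, incidence$pu_ids[sample.int(N, m)])
  }, numeric(1))
  list(mean = mean(vals),
       se = if (samples > 1L) stats::sd(vals) / sqrt(samples) else 0,
       samples = samples)
}

#' PD rarefaction curve
#'
#' @param incidence a `branch_incidence` object.
#' @param m integer vector of subset sizes (default `0:N`).
#' @param method `"exact"` (closed form) or `"monte-carlo"`.
#' @param samples,seed Monte-Carlo settings (ignored for `"exact"`).
#' @return data frame with columns `m`, `expected_pd`,
#'   `expected_pd_fraction`, `method`, `samples`, `seed`. Fractions use
#'   total represented PD, so the curve ends at 1.
#' @export
pd_rarefaction <- function(incidence, m = NULL, method = c("exact", "monte-carlo"),
                           samples = 1000L, seed = NULL) {
  stopifnot(inherits(incidence, "branch_incidence"))
  method <- match.arg(method)
  if (is.null(m)) m <- 0:incidence$n_pu
  total <- pd_total(incidence)
  epd <- vapply(m, function(mi) {
    if (method == "exact") expected_pd_exact(incidence, mi)
    else expected_pd_montecarlo(incidence, mi, samples, seed)$mean
  }, numeric(1))
  data.frame(m = m, expected_pd = epd,
             expected_pd_fraction = if (total > 0) epd / total else 0,
             method = method,
             samples = if (method == "monte-carlo") samples else NA_integer_,
             seed = if (method == "monte-carlo" && !is.null(seed)) seed else NA_integer_)
}
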