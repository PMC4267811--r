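#' Annealing schedule for the minimum-set selector
#'
#' @param iterations iterations per run (default 100000).
#' @param runs number of repeat runs feeding the selection frequency
#'   (default 500, the standard usage for irreplaceability estimates).
#' @param t_init initial temperature, or `"adaptive"` to set it per run from
#'   the spread of 100 sampled random-move score deltas.
#' @param t_final_frac final temperature as a fraction of the initial one;
#'   cooling is geometric per iteration.
#' @param beta penalty scale, or `"auto"` (see [anneal_minimum_set()]).
#' @param seed optional integer seed.
#' @return an `anneal_schedule` list.
#' @export
anneal_schedule <- function(iterations = 100000L, runs = 500L,
                            t_init = "adaptive", t_final_frac = 1e-4,
                            beta = "auto", seed = NULL) {
  iterations <- as.integer(iterations)
  runs <- as.integer(runs)
  if (is.na(iterations) || iterations < 1L) stop("iterations must be >= 1", call. = FALSE)
  if (is.na(runs) || runs < 1L) stop("runs must be >= 1", call. = FALSE)
  if (!identical(t_init, "adaptive") && (!is.numeric(t_init) || t_init <= 0)) {
    stop("t_init must be positive or \"adaptive\"", call. = FALSE)
  }
  if (!is.numeric(t_final_frac) || t_final_frac <= 0 || t_final_frac >= 1) {
    stop("t_final_frac must be in (0, 1)", call. = FALSE)
  }
  if (!identical(beta, "auto") && (!is.numeric(beta) || beta <= 0)) {
    stop("beta must be positive or \"auto\"", call. = FALSE)
  }
  structure(list(iterations = iterations, runs = runs, t_init = t_init,
                 t_final_frac = t_final_frac, beta = beta, seed = seed),
            class = "anneal_schedule")
}

#' Marxan-style simulated-annealing minimum-set site selection
#'
#' Minimises, per run, the objective
#' `Score(S) = sum of selected PU costs + beta * sum of weights of unmet
#' branches`, where a branch is unmet while no selected planning unit
#' contains it. The boundary-length term of the full Marxan objective is
#' not modelled (planning units here are sampling points). Every branch has
#' an implicit representation target of one.
#'
#' The cost cap is enforced as a hard constraint: proposed additions that
#' would exceed it become swap moves, so reserves never cost more than
#' `cost_cap`. Each run ends with a deterministic steepest-descent pass, so
#' every reported solution is locally optimal under single adds, removes and
#' swaps. Best-per-run solutions are tallied into a selection frequency per
#' planning unit — the fraction of runs whose best solution contains it,
#' analogous to irreplaceability.
#'
#' With `beta = "auto"` the penalty scale is `10 * max(costs) / min positive
#' weight`, which makes any strictly positive PD gain worth more than any
#' single PU's cost; under equal costs and a cap the annealer then behaves
#' as PD maximisation over sets within the cap.
#'
#' @param incidence a `branch_incidence` object.
#' @param weights a [normalize_weights()] result aligned with `incidence`
#'   rows, or `NULL` to use raw branch lengths as weights.
#' @param costs per-PU positive costs; a single value is recycled
#'   (default 1 for every PU).
#' @param cost_cap maximum total cost of a reserve (e.g. 2..10 with unit
#'   costs caps the number of selected PUs).
#' @param schedule an [anneal_schedule()].
#' @return an object of class `anneal_result`: a list with `solutions` (data
#'   frame: run, n_selected, cost, pd, pd_fraction, penalty, score, pus),
#'   `selected` (runs x PU 0/1 matrix), `freq` (a `selection_frequency`),
#'   `best` (index of the best-scoring run) and the call parameters.
#' @export
anneal_minimum_set <- function(incidence, weights = NULL, costs = 1,
                               cost_cap, schedule = anneal_schedule()) {
  stopifnot(inherits(incidence, "branch_incidence"),
            inherits(schedule, "anneal_schedule"))
  n <- incidence$n_pu
  if (length(costs) == 1L) costs <- rep(costs, n)
  if (length(costs) != n) stop("costs must have one value per planning unit", call. = FALSE)
  if (any(costs <= 0)) stop("all planning-unit costs must be positive", call. = FALSE)
  if (missing(cost_cap) || !is.numeric(cost_cap) || length(cost_cap) != 1L) {
    stop("cost_cap must be a single positive number", call. = FALSE)
  }
  if (cost_cap < min(costs)) {
    stop("cost_cap (", cost_cap, ") is below the cheapest planning unit (",
         min(costs), "): no feasible non-empty reserve", call. = FALSE)
  }

  w <- if (is.null(weights)) incidence$length else {
    stopifnot(inherits(weights, "feature_weights"))
    if (length(weights$w) != length(incidence$length)) {
      stop("weights and incidence describe different numbers of branches",
           call. = FALSE)
    }
    weights$w
  }

  beta <- schedule$beta
  if (identical(beta, "auto")) {
    pos <- w[w > 0]
    if (length(pos) == 0L) stop("all branch weights are zero", call. = FALSE)
    beta <- 10 * max(costs) / min(pos)
  }
  t_init <- if (identical(schedule$t_init, "adaptive")) -1 else schedule$t_init

  if (!is.null(schedule$seed)) set.seed(schedule$seed)
  res <- anneal_runs_cpp(incidence$matrix, w, costs, cost_cap,
                         schedule$iterations, schedule$runs, beta,
                         t_init, schedule$t_final_frac)

  sel <- res$selected
  colnames(sel) <- incidence$pu_ids
  total <- pd_total(incidence)
  pd <- apply(sel, 1, function(row) compute_pd(incidence, incidence$pu_ids[row == 1L]))
  solutions <- data.frame(
    run = seq_len(schedule$runs),
    n_selected = rowSums(sel),
    cost = res$cost,
    pd = pd,
    pd_fraction = if (total > 0) pd / total else 0,
    penalty = res$penalty,
    score = res$score,
    pus = vapply(seq_len(nrow(sel)), function(i) {
      paste(incidence$pu_ids[sel[i, ] == 1L], collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  freq <- selection_frequency_matrix(sel)
  structure(list(
    solutions = solutions,
    selected = sel,
    freq = freq,
    best = which.min(res$score),
    beta = beta,
    cost_cap = cost_cap,
    schedule = schedule
  ), class = "anneal_result")
}

#' @export
print.anneal_result <- function(x, ...) {
  cat("Simulated-annealing minimum-set selection: ", nrow(x$solutions),
      " runs, cost cap ", x$cost_cap, "\n", sep = "")
  b <- x$solutions[x$best, ]
  cat("  best run: PD ", signif(b$pd, 6), " (fraction ",
      sprintf("%.3f", b$pd_fraction), "), cost ", b$cost, ", PUs {",
      b$pus, "}\n", sep = "")
  invisible(x)
}

selection_frequency_matrix <- function(sel) {
  counts <- colSums(sel)
  structure(list(
    pu_ids = colnames(sel),
    count = counts,
    frequency = counts / nrow(sel),
    n_runs = nrow(sel)
  ), class = "selection_frequency")
}

#' Selection frequency of planning units across solver runs
#'
#' The fraction of runs whose best solution contains each planning unit;
#' an indication of how useful a PU is for creating an efficient reserve
#' system, analogous to irreplaceability.
#'
#' @param solutions list of per-run selected PU id vectors, or an
#'   `anneal_result`.
#' @param pu_ids the full planning-unit id universe (required for lists).
#' @return a `selection_frequency` object with `pu_ids`, `count`,
#'   `frequency`, `n_runs`.
#' @export
selection_frequency <- function(solutions, pu_ids = NULL) {
  if (inherits(solutions, "anneal_result")) return(solutions$freq)
  if (!is.list(solutions) || length(solutions) == 0L) {
    stop("solutions must be a non-empty list of PU id vectors", call. = FALSE)
  }
  if (is.null(pu_ids)) pu_ids <- sort(unique(unlist(solutions)))
  sel <- t(vapply(solutions, function(s) as.integer(pu_ids %in% s),
                  integer(length(pu_ids))))
  colnames(sel) <- pu_ids
  selection_frequency_matrix(sel)
}

#' @export
print.selection_frequency <- function(x, ...) {
  cat("Selection frequency over ", x$n_runs, " runs\n", sep = "")
  ord <- order(-x$frequency)
  top <- ord[seq_len(min(5, length(ord)))]
  for (i in top) {
    cat("  ", x$pu_ids[i], sprintf("%.3f", x$frequency[i]), "\n")
  }
  invisible(x)
}

#' Exact best PD subset by exhaustive enumeration
#'
#' Test oracle for the heuristics: enumerates all subsets of at most `k`
#' planning units (monotonicity means size-`k` subsets suffice) and returns
#' the one with maximum PD, ties broken by lexicographic PU order.
#'
#' @param incidence a `branch_incidence` object.
#' @param k subset size.
#' @return list with `pus`, `pd`, `pd_fraction`.
#' @export
optimal_subset_bruteforce <- function(incidence, k) {
  stopifnot(inherits(incidence, "branch_incidence"))
  n <- incidence$n_pu
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > n) stop("k must be in 1..n_pu", call. = FALSE)
  if (choose(n, k) > 1e6) {
    stop("choose(", n, ", ", k, ") exceeds the enumeration guard (1e6); ",
         "use anneal_minimum_set() instead", call. = FALSE)
  }
  ord <- order(incidence$pu_ids)  # lexicographic enumeration => lexicographic ties
  combos <- utils::combn(ord[seq_len(n)], k)
  best_pd <- -Inf
  best <- NULL
  for (j in seq_len(ncol(combos))) {
    idx <- combos[, j]
    covered <- rowSums(incidence$matrix[, idx, drop = FALSE]) > 0L
    v <- sum(incidence$length[covered])
    if (v > best_pd + 1e-12) {
      best_pd <- v
      best <- idx
    }
  }
  total <- pd_total(incidence)
  list(pus = incidence$pu_ids[best], pd = best_pd,
       pd_fraction = if (total > 0) best_pd / total else 0)
}
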