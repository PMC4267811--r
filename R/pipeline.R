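#' Compare annealer, greedy and rarefaction PD accumulation
#'
#' For each reserve size `k` in `[k_min, k_max]` this runs the
#' simulated-annealing selector with cost cap `k` (unit costs), reads the
#' greedy heuristic's mean accumulation at `k`, and evaluates the exact
#' rarefaction expectation at `k`. The three curves bracket each other:
#' annealer-best and greedy sit near the optimum, rarefaction is the
#' random-selection null.
#'
#' @param incidence a `branch_incidence` object.
#' @param weights optional [normalize_weights()] result for the annealer.
#' @param k_min,k_max reserve-size range, `1 <= k_min <= k_max <= N`.
#' @param schedule an [anneal_schedule()] (its `seed` is ignored here; use
#'   `seed`).
#' @param greedy_reps greedy replicates (default 100).
#' @param seed integer seed governing both the greedy and annealer runs.
#' @return an `accumulation_report` data frame with one row per `k`:
#'   `anneal_best_pd`, `greedy_mean_pd`, `rarefaction_pd` and the matching
#'   `_fraction` columns (denominator: total represented PD).
#' @export
compare_curves <- function(incidence, weights = NULL, k_min = 1L,
                           k_max = incidence$n_pu,
                           schedule = anneal_schedule(runs = 100L),
                           greedy_reps = 100L, seed = 1L) {
  stopifnot(inherits(incidence, "branch_incidence"))
  k_min <- as.integer(k_min)
  k_max <- as.integer(k_max)
  if (is.na(k_min) || is.na(k_max) || k_min < 1L || k_max < k_min ||
      k_max > incidence$n_pu) {
    stop("need 1 <= k_min <= k_max <= number of planning units", call. = FALSE)
  }
  total <- pd_total(incidence)
  greedy <- greedy_summed_pd(incidence, replicates = greedy_reps, seed = seed)
  gcurve <- greedy_mean_curve(greedy)
  ks <- k_min:k_max
  anneal_best <- vapply(ks, function(k) {
    sched <- schedule
    sched$seed <- seed + k  # independent, reproducible stream per cap
    res <- anneal_minimum_set(incidence, weights = weights, costs = 1,
                              cost_cap = k, schedule = sched)
    max(res$solutions$pd)
  }, numeric(1))
  rare <- vapply(ks, function(k) expected_pd_exact(incidence, k), numeric(1))
  out <- data.frame(
    k = ks,
    anneal_best_pd = anneal_best,
    anneal_best_fraction = anneal_best / total,
    greedy_mean_pd = gcurve$mean_pd[ks],
    greedy_mean_fraction = gcurve$mean_pd[ks] / total,
    rarefaction_pd = rare,
    rarefaction_fraction = rare / total
  )
  class(out) <- c("accumulation_report", "data.frame")
  attr(out, "seed") <- seed
  attr(out, "schedule") <- schedule
  attr(out, "greedy_reps") <- greedy_reps
  out
}

#' Plot an accumulation report
#'
#' Draws the three PD-fraction curves (solid black: greedy mean; dashed:
#' annealer best; grey: rarefaction) against reserve size.
#'
#' @param x an `accumulation_report`.
#' @param ... passed to [plot()].
#' @return the report, invisibly.
#' @export
plot.accumulation_report <- function(x, ...) {
  plot(x$k, x$greedy_mean_fraction, type = "l", lwd = 2, ylim = c(0, 1),
       xlab = "planning units selected", ylab = "fraction of total PD", ...)
  graphics::lines(x$k, x$anneal_best_fraction, lty = 2, lwd = 2, col = "red")
  graphics::lines(x$k, x$rarefaction_fraction, col = "grey50", lwd = 2)
  graphics::legend("bottomright", bty = "n",
                   legend = c("greedy summed PD", "annealer best", "rarefaction"),
                   col = c("black", "red", "grey50"), lty = c(1, 2, 1), lwd = 2)
  invisible(x)
}

#' Run the full planning pipeline on input files
#'
#' Parse tree -> read occurrence -> encode branches -> normalise weights ->
#' greedy ranking, annealing with selection frequency, rarefaction curve,
#' curve comparison and Marxan export, writing every table as CSV plus a
#' log and a run-metadata file into `out_dir`. Any stage failure aborts
#' with the stage name and cause.
#'
#' @param tree_file Newick tree path.
#' @param occurrence_file occurrence CSV/TSV path.
#' @param out_dir output directory (created if needed).
#' @param format occurrence layout, `"wide"` or `"long"`.
#' @param costs_file optional CSV with columns `pu_id,cost`.
#' @param cost_cap cost cap for the headline annealer run (default 2).
#' @param k_max top of the comparison range (default `min(10, N)`).
#' @param schedule an [anneal_schedule()].
#' @param greedy_reps greedy replicates.
#' @param seed integer seed for all stochastic stages.
#' @return invisibly, a list with all in-memory results.
#' @export
run_pipeline <- function(tree_file, occurrence_file, out_dir,
                         format = "wide", costs_file = NULL, cost_cap = 2,
                         k_max = NULL, schedule = anneal_schedule(runs = 100L),
                         greedy_reps = 100L, seed = 1L) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  log_lines <- character()
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    log_lines <<- c(log_lines, msg)
  }

  say("parse: ", tree_file)
  tree <- stage("parse", read_phylogeny(tree_file))
  say("occurrence: ", occurrence_file)
  occ <- stage("occurrence", read_occurrence(occurrence_file, format = format))
  say("encode: ", length(tree$tip.label), " tips x ", ncol(occ), " PUs")
  incidence <- stage("encode", build_incidence(tree, occ))
  weights <- stage("weights", normalize_weights(tree))
  costs <- if (!is.null(costs_file)) {
    cdf <- stage("costs", utils::read.table(costs_file, header = TRUE, sep = ",",
                                            stringsAsFactors = FALSE))
    as.numeric(cdf$cost[match(incidence$pu_ids, cdf$pu_id)])
  } else rep(1, incidence$n_pu)

  say("greedy: ", greedy_reps, " replicates")
  greedy <- stage("greedy", greedy_summed_pd(incidence, replicates = greedy_reps,
                                             seed = seed))
  say("anneal: cap ", cost_cap, ", ", schedule$runs, " runs")
  sched <- schedule
  sched$seed <- seed
  anneal <- stage("anneal", anneal_minimum_set(incidence, weights = weights,
                                               costs = costs, cost_cap = cost_cap,
                                               schedule = sched))
  say("rarefy")
  rare <- stage("rarefy", pd_rarefaction(incidence))
  kmax <- if (is.null(k_max)) min(10L, incidence$n_pu) else as.integer(k_max)
  say("compare: k in 1..", kmax)
  report <- stage("compare", compare_curves(incidence, weights = weights,
                                            k_min = 1L, k_max = kmax,
                                            schedule = schedule,
                                            greedy_reps = greedy_reps,
                                            seed = seed))
  say("export-marxan")
  stage("export-marxan", export_marxan(incidence, weights = weights,
                                       costs = costs,
                                       dir = file.path(out_dir, "marxan")))

  stage("write", {
    write_incidence_csv(incidence, file.path(out_dir, "incidence.csv"))
    utils::write.csv(data.frame(pu_id = names(greedy$avg_rank),
                                mean_rank = unname(greedy$avg_rank)),
                     file.path(out_dir, "greedy_ranking.csv"), row.names = FALSE)
    utils::write.csv(anneal$solutions, file.path(out_dir, "anneal_solutions.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(pu_id = anneal$freq$pu_ids,
                                count = unname(anneal$freq$count),
                                frequency = unname(anneal$freq$frequency)),
                     file.path(out_dir, "selection_frequency.csv"),
                     row.names = FALSE)
    utils::write.csv(rare, file.path(out_dir, "rarefaction.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(report), file.path(out_dir, "accumulation.csv"),
                     row.names = FALSE)
    writeLines(c(
      paste0("tree_file=", tree_file),
      paste0("occurrence_file=", occurrence_file),
      paste0("n_tips=", length(tree$tip.label)),
      paste0("n_pus=", incidence$n_pu),
      paste0("tree_depth=", format(weights$depth, digits = 12)),
      paste0("total_represented_pd=", format(pd_total(incidence), digits = 12)),
      paste0("seed=", seed),
      paste0("cost_cap=", cost_cap),
      paste0("anneal_iterations=", schedule$iterations),
      paste0("anneal_runs=", schedule$runs),
      paste0("greedy_reps=", greedy_reps)
    ), file.path(out_dir, "run_metadata.txt"))
    writeLines(log_lines, logf)
  })

  invisible(list(tree = tree, occ = occ, incidence = incidence,
                 weights = weights, greedy = greedy, anneal = anneal,
                 rarefaction = rare, report = report, out_dir = out_dir))
}
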