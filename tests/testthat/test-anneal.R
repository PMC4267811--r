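fast_schedule <- function(runs = 20L, seed = 1L, iterations = 10000L) {
  anneal_schedule(iterations = iterations, runs = runs, seed = seed)
}

test_that("annealer matches the brute-force optimum on a small instance", {
  ins <- random_instance(51, n_tips = 10, n_pus = 5, endemism = 0.2)
  res <- anneal_minimum_set(ins$incidence, ins$weights, cost_cap = 2,
                            schedule = fast_schedule(runs = 50, seed = 2))
  bf <- optimal_subset_bruteforce(ins$incidence, 2)
  expect_equal(max(res$solutions$pd), bf$pd, tolerance = 1e-9)
})

test_that("an unconstrained run meets every occupied branch", {
  ins <- random_instance(52, n_tips = 12, n_pus = 6, endemism = 0.15)
  res <- anneal_minimum_set(ins$incidence, ins$weights,
                            cost_cap = ins$incidence$n_pu,
                            schedule = fast_schedule(runs = 10, seed = 3))
  expect_equal(max(res$solutions$pd), pd_total(ins$incidence), tolerance = 1e-9)
})

test_that("the cost cap is a hard constraint", {
  ins <- random_instance(53)
  res <- anneal_minimum_set(ins$incidence, ins$weights, cost_cap = 3,
                            schedule = fast_schedule(runs = 30, seed = 4))
  expect_true(all(res$solutions$cost <= 3 + 1e-9))
  expect_true(all(res$solutions$n_selected <= 3))
})

test_that("a PU uniquely holding a dominant-weight branch is irreplaceable", {
  # p1 alone holds tip X on a very long pendant branch; other PUs share
  # short-branch tips
  tree <- parse_phylogeny("((A:0.1,B:0.1):0.1,X:10);")
  occ <- occ_matrix(c("A", "B", "X"), c("p1", "p2", "p3"),
                    list(c("X", "p1"), c("A", "p2"), c("B", "p3"),
                         c("A", "p3"), c("B", "p2")))
  inc <- build_incidence(tree, occ)
  w <- suppressWarnings(normalize_weights(tree))  # deliberately non-clock
  for (cap in c(1, 2)) {
    res <- anneal_minimum_set(inc, w, cost_cap = cap,
                              schedule = fast_schedule(runs = 40, seed = cap))
    expect_equal(unname(res$freq$frequency["p1"]), 1.0)
  }
})

test_that("identical seeds give bit-identical runs", {
  ins <- random_instance(54)
  r1 <- anneal_minimum_set(ins$incidence, ins$weights, cost_cap = 2,
                           schedule = fast_schedule(runs = 10, seed = 9))
  r2 <- anneal_minimum_set(ins$incidence, ins$weights, cost_cap = 2,
                           schedule = fast_schedule(runs = 10, seed = 9))
  expect_identical(r1$selected, r2$selected)
  expect_identical(r1$solutions, r2$solutions)
})

test_that("infeasible caps and bad costs are rejected", {
  ins <- random_instance(55)
  expect_error(anneal_minimum_set(ins$incidence, ins$weights, cost_cap = 0.5,
                                  schedule = fast_schedule()),
               "no feasible")
  expect_error(anneal_minimum_set(ins$incidence, ins$weights, costs = -1,
                                  cost_cap = 2, schedule = fast_schedule()),
               "positive")
})

test_that("selection frequency is the per-run membership fraction", {
  sols <- c(rep(list(c("p1", "p2")), 250), rep(list(c("p1", "p3")), 250))
  sf <- selection_frequency(sols, pu_ids = c("p1", "p2", "p3", "p4"))
  expect_equal(unname(sf$frequency), c(1, 0.5, 0.5, 0))
  expect_equal(sf$n_runs, 500L)
  expect_error(selection_frequency(list()), "non-empty")
})

test_that("brute force is exact, deterministic and guarded", {
  ins <- random_instance(56, n_tips = 12, n_pus = 8, endemism = 0.2)
  bf1 <- optimal_subset_bruteforce(ins$incidence, 1)
  singles <- vapply(ins$incidence$pu_ids,
                    function(p) compute_pd(ins$incidence, p), numeric(1))
  expect_equal(bf1$pd, max(singles))
  bfN <- optimal_subset_bruteforce(ins$incidence, ins$incidence$n_pu)
  expect_equal(bfN$pd, pd_total(ins$incidence))
  # dominance over the greedy heuristic's first two picks
  g <- greedy_summed_pd(ins$incidence, replicates = 20, seed = 8)
  bf2 <- optimal_subset_bruteforce(ins$incidence, 2)
  for (r in seq_len(nrow(g$order))) {
    expect_gte(bf2$pd + 1e-9, compute_pd(ins$incidence, g$order[r, 1:2]))
  }
  big <- branch_incidence(matrix(1L, 2, 40,
                                 dimnames = list(c("b1", "b2"), paste0("p", 1:40))),
                          c(1, 1))
  expect_error(optimal_subset_bruteforce(big, 20), "guard")
})
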