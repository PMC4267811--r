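basal_length_fraction <- function(tree) {
  # fraction of total branch length lying in the basal half of the depth
  age <- ape::node.depth.edgelength(tree)
  d <- max(age[seq_along(tree$tip.label)])
  from <- age[tree$edge[, 1]]
  to <- age[tree$edge[, 2]]
  basal <- pmax(0, pmin(to, d / 2) - from)
  sum(basal) / sum(to - from)
}

test_that("tree simulation is seeded and ultrametric for every shape", {
  for (shape in c("yule", "stemmy", "tippy")) {
    cfg <- sim_config(16, shape = shape, seed = 7)
    t1 <- simulate_tree(cfg)
    t2 <- simulate_tree(cfg)
    expect_identical(ape::write.tree(t1), ape::write.tree(t2))
    depths <- ape::node.depth.edgelength(t1)[1:16]
    expect_lt(max(depths) - min(depths), 1e-9)
    w <- normalize_weights(t1)
    expect_equal(unname(path_weight_sums(t1, w)), rep(1, 16), tolerance = 1e-9)
  }
})

test_that("stemmy trees concentrate length basally, tippy trees tipward", {
  pendant_fraction <- function(tree) {
    ntip <- length(tree$tip.label)
    sum(tree$edge.length[tree$edge[, 2] <= ntip]) / sum(tree$edge.length)
  }
  for (seed in 81:85) {
    yule <- simulate_tree(sim_config(24, shape = "yule", seed = seed))
    stemmy <- simulate_tree(sim_config(24, shape = "stemmy", gamma = 2,
                                       seed = seed))
    tippy <- simulate_tree(sim_config(24, shape = "tippy", gamma = 2,
                                      seed = seed))
    expect_gt(basal_length_fraction(stemmy), basal_length_fraction(yule))
    expect_lt(basal_length_fraction(tippy), basal_length_fraction(yule))
    # the same contrast in terms of where the length sits: terminal
    # branches carry more of a tippy tree, internal stems more of a stemmy
    expect_gt(pendant_fraction(tippy), pendant_fraction(yule))
    expect_lt(pendant_fraction(stemmy), pendant_fraction(yule))
  }
})

test_that("occupancy matches the endemism model", {
  cfg <- sim_config(1000, n_pus = 26, endemism = 0.05, seed = 13)
  tree <- simulate_tree(sim_config(1000, seed = 13))
  occ <- simulate_occupancy(tree, cfg)
  sizes <- rowSums(occ)
  expect_true(all(sizes >= 1))
  expect_lte(mean(sizes), 2.5)
  # shifted-geometric mean is endemism * n_pus = 1.3; allow 3 SE
  expect_lt(abs(mean(sizes) - 1.3), 3 * stats::sd(sizes) / sqrt(1000))
})

test_that("full endemism puts every tip in every planning unit", {
  cfg <- sim_config(8, n_pus = 5, endemism = 1, seed = 3)
  tree <- simulate_tree(cfg)
  occ <- simulate_occupancy(tree, cfg)
  expect_true(all(occ == 1L))
})

test_that("occupancy is reproducible and validates its config", {
  cfg <- sim_config(12, n_pus = 8, endemism = 0.2, seed = 4)
  tree <- simulate_tree(cfg)
  expect_identical(simulate_occupancy(tree, cfg), simulate_occupancy(tree, cfg))
  expect_error(sim_config(12, endemism = 0), "endemism")
  expect_error(sim_config(1), "n_tips")
  expect_error(sim_config(12, gamma = -1), "gamma")
})

test_that("generated instances satisfy the core encoding invariants", {
  for (seed in 86:88) {
    ins <- random_instance(seed, n_tips = 20, n_pus = 10, endemism = 0.1)
    expect_equal(unname(ins$incidence$n_b), unname(rowSums(ins$incidence$matrix)))
    expect_true(all(ins$incidence$length >= 0))
    expect_true(all(rowSums(ins$occ) >= 1))
    expect_equal(compute_pd(ins$incidence, ins$incidence$pu_ids),
                 pd_total(ins$incidence))
  }
})

test_that("matched pairs share occupancy and total tree length", {
  pair <- simulate_matched_pair(sim_config(20, n_pus = 12, gamma = 2,
                                           endemism = 0.1, seed = 19))
  expect_identical(pair$stemmy$occ, pair$tippy$occ)
  expect_equal(sum(pair$stemmy$tree$edge.length),
               sum(pair$tippy$tree$edge.length), tolerance = 1e-9)
  expect_gt(basal_length_fraction(pair$stemmy$tree),
            basal_length_fraction(pair$tippy$tree))
})
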