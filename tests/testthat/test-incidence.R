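test_that("a planning unit's branches are the union of its tips' root paths", {
  occ <- occ_matrix(c("A", "B", "C"), c("p1", "p2"),
                    list(c("A", "p1"), c("C", "p2")))
  inc <- build_incidence(toy_tree(), occ)
  # p1 = {A}: pendant A plus the internal edge to the (A,B) ancestor
  expect_equal(sum(inc$matrix[, "p1"]), 2L)
  expect_equal(unname(inc$matrix[, "p1"]), c(1L, 1L, 0L, 0L))
  expect_equal(inc$n_b, c(b0001 = 1, b0002 = 1, b0003 = 0, b0004 = 1))
})

test_that("a PU holding every tip carries every branch; unseen tips have n_b 0", {
  occ_all <- occ_matrix(c("A", "B", "C"), "p1",
                        list(c("A", "p1"), c("B", "p1"), c("C", "p1")))
  inc <- build_incidence(toy_tree(), occ_all)
  expect_true(all(inc$matrix[, "p1"] == 1L))

  occ_partial <- occ_matrix(c("A", "C"), c("p1", "p2"),
                            list(c("A", "p1"), c("C", "p2")))
  expect_warning(inc2 <- build_incidence(toy_tree(), occ_partial),
                 "globally absent: B")
  expect_equal(unname(inc2$n_b[3]), 0)  # pendant edge of B
})

test_that("occurrence tips missing from the tree are an error", {
  occ <- occ_matrix(c("A", "Z"), "p1", list(c("A", "p1"), c("Z", "p1")))
  expect_error(build_incidence(toy_tree(), occ), "not found in tree: Z")
})

test_that("PD sums covered branch lengths and always includes the root path", {
  occ <- occ_matrix(c("A", "B", "C"), c("p1", "p2", "p3"),
                    list(c("A", "p1"), c("B", "p2"), c("C", "p3")))
  inc <- build_incidence(toy_tree(), occ)
  expect_equal(compute_pd(inc, character(0)), 0)
  expect_equal(compute_pd(inc, c("p1", "p3")), 4)  # {A, C}: 1 + 1 + 2
  expect_equal(compute_pd(inc, c("p1", "p2", "p3")), 5)
  expect_error(compute_pd(inc, "nope"), "unknown planning unit")
})

test_that("pd_gain matches differences of PD and rejects reselection", {
  occ <- occ_matrix(c("A", "B", "C"), c("p1", "p2", "p3"),
                    list(c("A", "p1"), c("B", "p2"), c("C", "p3")))
  inc <- build_incidence(toy_tree(), occ)
  expect_equal(pd_gain(inc, character(0), "p3"), compute_pd(inc, "p3"))
  expect_equal(pd_gain(inc, "p1", "p2"),
               compute_pd(inc, c("p1", "p2")) - compute_pd(inc, "p1"))
  expect_error(pd_gain(inc, "p1", "p1"), "already selected")
  # duplicate PU adds nothing
  occ2 <- occ_matrix(c("A", "B", "C"), c("p1", "p2"),
                     list(c("A", "p1"), c("A", "p2")))
  inc2 <- build_incidence(toy_tree(), occ2)
  expect_equal(pd_gain(inc2, "p1", "p2"), 0)
})

test_that("incidence PD equals direct tree-traversal PD on random subsets", {
  for (seed in 1:5) {
    ins <- random_instance(seed)
    set.seed(seed + 1000)
    for (rep in 1:40) {
      k <- sample.int(ins$incidence$n_pu, 1)
      pus <- sample(ins$incidence$pu_ids, k)
      expect_equal(compute_pd(ins$incidence, pus),
                   pd_oracle_pus(ins$tree, ins$occ, pus), tolerance = 1e-9)
    }
  }
})

test_that("PD is monotone and pd_gain is submodular", {
  for (seed in 6:9) {
    ins <- random_instance(seed)
    ids <- ins$incidence$pu_ids
    set.seed(seed)
    for (rep in 1:25) {
      t_set <- sample(ids, sample.int(length(ids) - 1L, 1))
      s_set <- t_set[seq_len(sample.int(length(t_set), 1))]
      expect_lte(compute_pd(ins$incidence, s_set),
                 compute_pd(ins$incidence, t_set) + 1e-12)
      cand <- sample(setdiff(ids, t_set), 1)
      expect_gte(pd_gain(ins$incidence, s_set, cand),
                 pd_gain(ins$incidence, t_set, cand) - 1e-12)
    }
  }
})

test_that("ancestral branches dominate descendant incidence rows", {
  for (seed in 10:12) {
    ins <- random_instance(seed, endemism = 0.2)
    tree <- ins$tree
    m <- ins$incidence$matrix
    child_of_edge <- tree$edge[, 2]
    for (e in seq_len(nrow(tree$edge))) {
      parent_edge <- match(tree$edge[e, 1], child_of_edge)
      if (!is.na(parent_edge)) {
        expect_true(all(m[parent_edge, ] >= m[e, ]))
      }
      expect_equal(unname(ins$incidence$n_b[e]), sum(m[e, ]))
    }
  }
})
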