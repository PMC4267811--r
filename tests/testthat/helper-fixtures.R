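# Shared fixtures and the independent PD oracle used across the suite.

toy_newick <- "((A:1,B:1):1,C:2);"

toy_tree <- function() parse_phylogeny(toy_newick)

occ_matrix <- function(tips, pus, presences) {
  m <- matrix(0, length(tips), length(pus), dimnames = list(tips, pus))
  for (pr in presences) m[pr[1], pr[2]] <- 1
  tip_occurrence(m)
}

# A 3-site instance with the structure of a worked complementarity example:
# site s1 has the strictly highest PD, s2 adds strictly more new branch
# length to s1 than s3 does (s3's tips are a subset of a clade s2 covers).
fig2_instance <- function() {
  tree <- parse_phylogeny("((A:3,B:3):1,(C:2,D:2):1);")
  occ <- occ_matrix(c("A", "B", "C", "D"), c("s1", "s2", "s3"),
                    list(c("A", "s1"), c("B", "s1"),
                         c("C", "s2"), c("D", "s2"),
                         c("C", "s3")))
  list(tree = tree, occ = occ, incidence = build_incidence(tree, occ))
}

# Independent PD oracle: direct traversal of root-to-tip paths with
# ape::nodepath, never touching the incidence encoding.
pd_oracle <- function(tree, tips) {
  if (length(tips) == 0) return(0)
  root <- length(tree$tip.label) + 1L
  nodes <- unique(unlist(lapply(match(tips, tree$tip.label), function(t) {
    ape::nodepath(tree, root, t)
  })))
  sum(tree$edge.length[tree$edge[, 2] %in% setdiff(nodes, root)])
}

# PD of a PU set straight from tree + occurrence via the oracle
pd_oracle_pus <- function(tree, occ, pus) {
  if (length(pus) == 0) return(0)
  present <- rownames(occ)[rowSums(occ[, pus, drop = FALSE]) > 0]
  pd_oracle(tree, present)
}

random_instance <- function(seed, n_tips = 16L, n_pus = 8L, shape = "yule",
                            endemism = 0.15) {
  simulate_instance(sim_config(n_tips, n_pus, shape = shape,
                               endemism = endemism, seed = seed))
}
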