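#' Simulation configuration for synthetic planning instances
#'
#' Bundles the generator settings: tree size and shape, number of planning
#' units, and the endemism level of the occupancy model.
#'
#' @param n_tips number of tips (>= 2).
#' @param n_pus number of planning units (default 26, a typical bore-field
#'   survey size).
#' @param shape tree shape: `"yule"` (pure birth, ultrametric), `"stemmy"`
#'   (branch length concentrated near the root: long unbranched stems
#'   subtending compact groups) or `"tippy"` (long internodes towards the
#'   tips).
#' @param gamma shape intensity (> 0); larger values exaggerate the stemmy
#'   or tippy character. Ignored for `"yule"`.
#' @param endemism mean fraction of PUs occupied per tip, in (0, 1]. Small
#'   values emulate narrow-endemic faunas where most tips occur in 1-2
#'   units.
#' @param seed optional integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_tips, n_pus = 26L, shape = c("yule", "stemmy", "tippy"),
                       gamma = 2, endemism = 0.06, seed = NULL) {
  shape <- match.arg(shape)
  n_tips <- as.integer(n_tips)
  n_pus <- as.integer(n_pus)
  if (is.na(n_tips) || n_tips < 2L) stop("n_tips must be >= 2", call. = FALSE)
  if (is.na(n_pus) || n_pus < 1L) stop("n_pus must be >= 1", call. = FALSE)
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  if (!is.numeric(endemism) || endemism <= 0 || endemism > 1) {
    stop("endemism must be in (0, 1]", call. = FALSE)
  }
  structure(list(n_tips = n_tips, n_pus = n_pus, shape = shape,
                 gamma = gamma, endemism = endemism, seed = seed),
            class = "sim_config")
}

#' Simulate an ultrametric tree (Yule, stemmy or tippy)
#'
#' The base tree is a pure-birth (Yule) tree from [ape::rphylo()], which is
#' ultrametric by construction, rescaled to unit depth. Stemmy and tippy
#' variants re-time the divergences with the monotone sigmoid map
#' `t -> t^g / (t^g + (1-t)^g)` applied to node ages (time from the root,
#' scaled to `[0, 1]`). With `g = gamma > 1` deep divergences move towards
#' the root and shallow ones towards the tips, stretching the unbranched
#' stem that subtends each clade while its crown stays compact — the
#' stemmy shape, with branch length concentrated basally on internal
#' edges. With `g = 1/gamma` divergences bunch at mid-depth, transferring
#' length into the terminal branches (tippy). The endpoints are fixed
#' points of the map, so ultrametricity is preserved exactly.
#'
#' @param config a [sim_config()].
#' @return a validated `phylo` of depth 1.
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  tree <- ape::rphylo(config$n_tips, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree)[seq_len(config$n_tips)])
  tree$edge.length <- tree$edge.length / depth
  if (config$shape != "yule") {
    g <- if (config$shape == "stemmy") config$gamma else 1 / config$gamma
    tree <- warp_node_ages(tree, g)
  }
  validate_phylogeny(tree)
}

# Re-time every node with the sigmoid age map t -> t^g / (t^g + (1-t)^g)
# (age = time from root, scaled to unit depth) and rebuild edge lengths;
# tips sit at age 1, a fixed point, so the tree stays ultrametric.
warp_node_ages <- function(tree, g) {
  age <- ape::node.depth.edgelength(tree)  # time from root per node
  ntip <- length(tree$tip.label)
  d <- max(age[seq_len(ntip)])
  t <- age / d
  new_age <- d * t^g / (t^g + (1 - t)^g)
  new_age[seq_len(ntip)] <- d  # guard tips against round-off
  tree$edge.length <- new_age[tree$edge[, 2]] - new_age[tree$edge[, 1]]
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Simulate narrow-endemic occupancy of tips across planning units
#'
#' Each tip's range size (number of occupied PUs) is a shifted geometric
#' variate on `{1, 2, ...}` capped at `n_pus`, with the success probability
#' solved so that the mean of the *capped* distribution equals
#' `endemism * n_pus`. Every tip therefore occurs somewhere, small endemism
#' values put most tips in one or two units, and `endemism = 1` degenerates
#' to every tip occupying every unit. The occupied units themselves are
#' drawn uniformly without replacement.
#'
#' @param tree a `phylo` whose tips are the taxa.
#' @param config a [sim_config()]; `n_tips` must match the tree.
#' @return a [tip_occurrence()] matrix, tips x `n_pus`, with PU ids
#'   `pu01`, `pu02`, ...
#' @export
simulate_occupancy <- function(tree, config) {
  stopifnot(inherits(config, "sim_config"))
  tree <- validate_phylogeny(tree)
  ntip <- length(tree$tip.label)
  if (ntip != config$n_tips) {
    stop("config$n_tips (", config$n_tips, ") does not match the tree (",
         ntip, " tips)", call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  n_pus <- config$n_pus
  target_mean <- config$endemism * n_pus
  sizes <- if (target_mean <= 1) {
    rep(1L, ntip)
  } else if (target_mean >= n_pus) {
    rep(n_pus, ntip)
  } else {
    # shifted geometric on {1, 2, ...} capped at n_pus; solve p so that
    # E[min(X, n_pus)] = (1 - (1-p)^n_pus) / p equals the target mean
    p <- stats::uniroot(function(p) {
      (1 - (1 - p)^n_pus) / p - target_mean
    }, interval = c(1e-12, 1), tol = 1e-12)$root
    pmin(1L + stats::rgeom(ntip, prob = p), n_pus)
  }
  m <- matrix(0L, ntip, n_pus,
              dimnames = list(tree$tip.label, sprintf("pu%02d", seq_len(n_pus))))
  for (i in seq_len(ntip)) {
    m[i, sample.int(n_pus, sizes[i])] <- 1L
  }
  tip_occurrence(m)
}

#' Simulate a complete planning instance
#'
#' Convenience wrapper chaining [simulate_tree()], [simulate_occupancy()],
#' [build_incidence()] and [normalize_weights()] under one seed.
#'
#' @param config a [sim_config()].
#' @return list with `tree`, `occ`, `incidence`, `weights`, `config`.
#' @export
simulate_instance <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  sub <- config
  sub$seed <- NULL  # one stream: seed set once above
  tree <- simulate_tree(sub)
  occ <- simulate_occupancy(tree, sub)
  incidence <- build_incidence(tree, occ)
  list(tree = tree, occ = occ, incidence = incidence,
       weights = normalize_weights(tree), config = config)
}

#' Paired stemmy/tippy instances matched for length and occupancy
#'
#' Generates one Yule base tree, derives its stemmy and tippy warps (each
#' rescaled to the base tree's total branch length) and applies one shared
#' occupancy matrix to both, so the pair differs only in where branch
#' length sits on the tree — the comparison behind marker-resolution
#' contrasts (conserved, stemmy markers vs fast, tippy ones).
#'
#' @param config a [sim_config()]; its `shape` field is ignored.
#' @return list with `stemmy` and `tippy` (each as [simulate_instance()]
#'   output) sharing `occ`.
#' @export
simulate_matched_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  sub <- config
  sub$seed <- NULL
  sub$shape <- "yule"
  base <- simulate_tree(sub)
  total <- sum(base$edge.length)
  occ <- simulate_occupancy(base, sub)
  one <- function(shape) {
    tr <- if (shape == "stemmy") warp_node_ages(base, config$gamma)
          else warp_node_ages(base, 1 / config$gamma)  # sigmoid map, see above
    tr$edge.length <- tr$edge.length * (total / sum(tr$edge.length))
    tr <- validate_phylogeny(tr)
    list(tree = tr, occ = occ, incidence = build_incidence(tr, occ),
         weights = normalize_weights(tr), config = config)
  }
  list(stemmy = one("stemmy"), tippy = one("tippy"))
}
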