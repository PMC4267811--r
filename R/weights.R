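#' Normalise branch lengths into species penalty factors
#'
#' Divides every branch length by the depth of the tree (maximum root-to-tip
#' path length), so that on an ultrametric tree the weights along any
#' root-to-tip path sum to exactly one. These relative lengths are the
#' species penalty factors (SPF) attached to each branch feature: the
#' penalty incurred by a reserve scenario that fails to represent the
#' branch, emphasising long branches (large PD gains) in site selection.
#'
#' For non-ultrametric input the depth is the maximum root-to-tip distance —
#' the unique choice keeping all path sums at most one — and a warning is
#' emitted; path sums then equal one only for the deepest tip.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param tol relative tolerance for the ultrametricity check.
#' @return an object of class `feature_weights`: a list with `depth`,
#'   `branch_id`, `w` (per-branch weight, preorder, aligned with
#'   [build_incidence()] rows) and `ultrametric` (logical).
#' @examples
#' w <- normalize_weights(parse_phylogeny("((A:1,B:1):2,C:3);"))
#' w$depth   # 3
#' w$w[1]    # internal branch 2/3
#' @export
normalize_weights <- function(tree, tol = 1e-6) {
  tree <- validate_phylogeny(tree)
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  d <- max(depths)
  if (d <= 0) {
    stop("tree depth is zero (all branch lengths zero); cannot normalise",
         call. = FALSE)
  }
  ultra <- (d - min(depths)) / d <= tol
  if (!ultra) {
    warning("tree is not ultrametric; using maximum root-to-tip distance (",
            signif(d, 6), ") as depth", call. = FALSE)
  }
  structure(list(
    depth = d,
    branch_id = sprintf("b%04d", seq_len(nrow(tree$edge))),
    w = tree$edge.length / d,
    ultrametric = ultra
  ), class = "feature_weights")
}

#' @export
print.feature_weights <- function(x, ...) {
  cat("Feature weights (SPF): ", length(x$w), " branches, tree depth ",
      signif(x$depth, 6), if (!x$ultrametric) " (non-ultrametric)", "\n",
      sep = "")
  invisible(x)
}

#' Root-to-tip sums of branch weights
#'
#' Diagnostic for the SPF normalisation: on an ultrametric tree every
#' root-to-tip path of weights sums to one.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param weights a [normalize_weights()] result for the same tree.
#' @return named numeric vector of per-tip path sums.
#' @export
path_weight_sums <- function(tree, weights) {
  tree <- validate_phylogeny(tree)
  stopifnot(inherits(weights, "feature_weights"),
            length(weights$w) == nrow(tree$edge))
  desc <- edge_tip_matrix(tree)
  sums <- as.numeric(crossprod(desc, weights$w))
  names(sums) <- tree$tip.label
  sums
}
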