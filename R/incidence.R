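#' Encode tree branches as conservation features across planning units
#'
#' Builds the branch x planning-unit presence table: branch `b` is present in
#' PU `p` iff at least one tip descending from `b` occurs in `p`. A tip's
#' presence therefore implies presence of every branch on its path to the
#' root, so the incidence of an ancestral branch dominates the incidence of
#' each of its descendants elementwise.
#'
#' @param tree a rooted `phylo` with branch lengths (see [parse_phylogeny()]).
#' @param occ a [tip_occurrence()] matrix. Every tip label in `occ` must
#'   exist in the tree; tips in the tree but absent from `occ` are treated as
#'   globally absent, with a warning.
#' @return an object of class `branch_incidence`: a list with elements
#'   `branch_id`, `length` (branch lengths, preorder), `matrix` (integer 0/1,
#'   branches x PUs), `n_b` (per-branch PU occupancy), `pu_ids`, `n_pu`.
#' @examples
#' tr <- parse_phylogeny("((A:1,B:1):1,C:2);")
#' occ <- tip_occurrence(matrix(c(1, 0, 0, 0, 0, 1), 3, 2,
#'   dimnames = list(c("A", "B", "C"), c("p1", "p2"))))
#' inc <- build_incidence(tr, occ)
#' compute_pd(inc, c("p1", "p2"))  # 4: A and C plus their shared root paths
#' @export
build_incidence <- function(tree, occ) {
  tree <- validate_phylogeny(tree)
  stopifnot(inherits(occ, "tip_occurrence"))
  missing_in_tree <- setdiff(rownames(occ), tree$tip.label)
  if (length(missing_in_tree)) {
    stop("occurrence tips not found in tree: ",
         paste(missing_in_tree, collapse = ", "), call. = FALSE)
  }
  unobserved <- setdiff(tree$tip.label, rownames(occ))
  if (length(unobserved)) {
    warning("tree tips absent from the occurrence table are treated as ",
            "globally absent: ", paste(unobserved, collapse = ", "),
            call. = FALSE)
  }
  # align occurrence rows to tree tip order, zero-filling unobserved tips
  full <- matrix(0L, length(tree$tip.label), ncol(occ),
                 dimnames = list(tree$tip.label, colnames(occ)))
  full[rownames(occ), ] <- occ
  desc <- edge_tip_matrix(tree)
  inc <- (desc %*% full) > 0
  mat <- matrix(as.integer(inc), nrow(inc), ncol(inc), dimnames = dimnames(inc))
  structure(list(
    branch_id = rownames(mat),
    length = tree$edge.length,
    matrix = mat,
    n_b = rowSums(mat),
    pu_ids = colnames(mat),
    n_pu = ncol(mat)
  ), class = "branch_incidence")
}

#' Assemble a branch incidence object from raw tables
#'
#' Used when a feature table does not come from a tree (e.g. read back from
#' Marxan files). No ancestral-dominance structure is assumed.
#'
#' @param mat integer 0/1 matrix, branches x PUs, with dimnames.
#' @param lengths per-branch lengths (feature amounts), non-negative.
#' @return a `branch_incidence` object.
#' @export
branch_incidence <- function(mat, lengths) {
  stopifnot(is.matrix(mat), length(lengths) == nrow(mat), all(lengths >= 0))
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("incidence matrix needs branch ids as rownames and PU ids as colnames",
         call. = FALSE)
  }
  mat <- matrix(as.integer(mat > 0), nrow(mat), ncol(mat), dimnames = dimnames(mat))
  structure(list(
    branch_id = rownames(mat),
    length = as.numeric(lengths),
    matrix = mat,
    n_b = rowSums(mat),
    pu_ids = colnames(mat),
    n_pu = ncol(mat)
  ), class = "branch_incidence")
}

#' @export
print.branch_incidence <- function(x, ...) {
  cat("Branch incidence: ", length(x$branch_id), " branches x ", x$n_pu,
      " planning units\n", sep = "")
  cat("  total represented PD: ", signif(pd_total(x), 6),
      " (of ", signif(sum(x$length), 6), " total branch length)\n", sep = "")
  invisible(x)
}

resolve_pus <- function(incidence, pus) {
  if (is.numeric(pus)) pus <- incidence$pu_ids[pus]
  unknown <- setdiff(pus, incidence$pu_ids)
  if (length(unknown)) {
    stop("unknown planning unit id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  unique(pus)
}

#' Phylogenetic diversity of a set of planning units
#'
#' PD is the sum of the lengths of all branches present in at least one
#' selected planning unit. Because incidence rows already include every
#' branch on the root path of each present tip, the path to the root is
#' always included: PD of any non-empty set counts the basal branches
#' connecting its represented tips to the root.
#'
#' @param incidence a `branch_incidence` object.
#' @param pus character vector of PU ids (or numeric indices). May be empty.
#' @return PD in branch-length units; 0 for the empty set.
#' @export
compute_pd <- function(incidence, pus) {
  stopifnot(inherits(incidence, "branch_incidence"))
  pus <- resolve_pus(incidence, pus)
  if (length(pus) == 0L) return(0)
  covered <- rowSums(incidence$matrix[, pus, drop = FALSE]) > 0L
  sum(incidence$length[covered])
}

#' Total represented PD
#'
#' Sum of lengths over branches present in at least one planning unit.
#' Branches whose tips were never observed contribute nothing; this is the
#' denominator used for all PD fractions, so accumulation curves plateau
#' at 1.
#'
#' @param incidence a `branch_incidence` object.
#' @return total represented PD in branch-length units.
#' @export
pd_total <- function(incidence) {
  stopifnot(inherits(incidence, "branch_incidence"))
  sum(incidence$length[incidence$n_b > 0L])
}

#' Marginal PD gain of a candidate planning unit (complementarity)
#'
#' @param incidence a `branch_incidence` object.
#' @param selected character vector of already-selected PU ids (may be empty).
#' @param candidate a single PU id not in `selected`.
#' @return `compute_pd(selected + candidate) - compute_pd(selected)`, always
#'   non-negative.
#' @export
pd_gain <- function(incidence, selected, candidate) {
  stopifnot(inherits(incidence, "branch_incidence"), length(candidate) == 1L)
  selected <- resolve_pus(incidence, selected)
  candidate <- resolve_pus(incidence, candidate)
  if (candidate %in% selected) {
    stop("candidate '", candidate, "' is already selected", call. = FALSE)
  }
  uncovered <- if (length(selected) == 0L) {
    rep(TRUE, length(incidence$branch_id))
  } else {
    rowSums(incidence$matrix[, selected, drop = FALSE]) == 0L
  }
  sum(incidence$length[uncovered & incidence$matrix[, candidate] > 0L])
}

#' Write an incidence matrix (with lengths and occupancy) to CSV
#'
#' @param incidence a `branch_incidence` object.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_incidence_csv <- function(incidence, path) {
  stopifnot(inherits(incidence, "branch_incidence"))
  df <- data.frame(branch_id = incidence$branch_id,
                   length = incidence$length,
                   n_b = incidence$n_b,
                   incidence$matrix,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
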