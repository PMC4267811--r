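#' Parse a rooted phylogeny from a Newick string
#'
#' Thin wrapper around [ape::read.tree()] that adds syntax pre-checks with
#' position reporting and validates the result as a usable rooted phylogeny:
#' branch lengths on every edge, all lengths non-negative, tip labels unique.
#' Multifurcations are permitted. A root edge, if present in the string, is
#' ignored: the root node carries no branch.
#'
#' @param text a single Newick string, terminated by `;`.
#' @return an object of class `phylo` (see [ape::read.tree()]), rooted, with
#'   an `edge.length` entry for every edge.
#' @examples
#' tr <- parse_phylogeny("((A:1,B:1):1,C:2);")
#' sum(tr$edge.length)  # total branch length, 5
#' @seealso [read_phylogeny()] to read from a file.
#' @export
parse_phylogeny <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) {
    stop("empty Newick string", call. = FALSE)
  }
  check_newick_syntax(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse failed: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) {
    stop("Newick parse failed: unreadable tree string", call. = FALSE)
  }
  validate_phylogeny(tree)
}

#' Read a rooted phylogeny from a Newick file
#'
#' @param path path to a file whose first tree is read.
#' @return a validated `phylo` object.
#' @export
read_phylogeny <- function(path) {
  if (!file.exists(path)) {
    stop("tree file not found: ", path, call. = FALSE)
  }
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  parse_phylogeny(txt)
}

# Balanced-parenthesis and terminator checks, reporting 1-based character
# positions; ape's own parser is lenient about both.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("malformed Newick: unmatched ')' at position ", i, call. = FALSE)
      }
    }
  }
  if (depth > 0L) {
    stop("malformed Newick: ", depth, " unclosed '(' at end of string", call. = FALSE)
  }
  if (!endsWith(text, ";")) {
    stop("malformed Newick: missing terminating ';' at position ",
         nchar(text), call. = FALSE)
  }
  invisible(text)
}

#' Validate a phylogeny for use as a feature universe
#'
#' @param tree a `phylo` object.
#' @return the tree, invisibly reordered into canonical (cladewise) edge
#'   order so that branch identifiers are reproducible.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) {
    stop("not a 'phylo' object", call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; lengths are required on every edge",
         call. = FALSE)
  }
  if (anyNA(tree$edge.length)) {
    stop("tree has NA branch lengths", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch length(s): ",
         paste(signif(tree$edge.length[tree$edge.length < 0], 6), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(tree$tip.label) >= 3L && !ape::is.rooted(tree)) {
    stop("tree must be rooted", call. = FALSE)
  }
  stats::reorder(tree, "cladewise")
}

#' Branch table of a phylogeny
#'
#' Enumerates the edges of a rooted tree in deterministic preorder
#' (cladewise) traversal and assigns stable branch identifiers `b0001`,
#' `b0002`, ... in that order. Every edge is one conservation feature.
#'
#' @param tree a validated `phylo` object.
#' @return a data frame with columns `branch_id`, `parent`, `child` (ape node
#'   numbers) and `length`.
#' @export
branch_table <- function(tree) {
  tree <- validate_phylogeny(tree)
  ne <- nrow(tree$edge)
  data.frame(
    branch_id = sprintf("b%04d", seq_len(ne)),
    parent = tree$edge[, 1],
    child = tree$edge[, 2],
    length = tree$edge.length,
    stringsAsFactors = FALSE
  )
}

#' Tree depth (maximum root-to-tip path length)
#'
#' @param tree a validated `phylo` object.
#' @return a single non-negative number in the tree's branch-length units.
#' @export
tree_depth <- function(tree) {
  tree <- validate_phylogeny(tree)
  max(ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)])
}

# tips x edges is the wrong orientation for PD sums; build edges x tips:
# M[e, t] is TRUE iff tip t descends from edge e (through its child node).
edge_tip_matrix <- function(tree) {
  tree <- validate_phylogeny(tree)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  under <- matrix(FALSE, nnode, ntip)
  under[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  post <- stats::reorder(tree, "postorder")$edge
  for (i in seq_len(nrow(post))) {
    under[post[i, 1], ] <- under[post[i, 1], ] | under[post[i, 2], ]
  }
  m <- under[tree$edge[, 2], , drop = FALSE]
  colnames(m) <- tree$tip.label
  rownames(m) <- sprintf("b%04d", seq_len(nrow(m)))
  m
}
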