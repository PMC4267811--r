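#' Export a branch-feature problem as Marxan input files
#'
#' Writes the three core Marxan tables with branches as conservation
#' features: `pu.dat` (`id,cost`), `spec.dat` (`id,target,spf,name`; every
#' branch gets a representation target of 1 and its normalised length as
#' species penalty factor) and `puvspr.dat` (`species,pu,amount`; amount 1
#' for every present branch x PU pair, sorted by pu id then species id).
#' Integer ids are assigned deterministically — branches in preorder
#' traversal order, planning units in input column order — and the id maps
#' are written alongside as `branch_ids.csv` and `pu_ids.csv`. Identical
#' inputs give byte-identical files.
#'
#' @param incidence a `branch_incidence` object.
#' @param weights a [normalize_weights()] result aligned with `incidence`,
#'   or `NULL` to write raw branch lengths as spf.
#' @param costs per-PU positive costs; single values are recycled
#'   (default 1).
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the three tables (`pu`, `spec`, `puvspr`)
#'   and the id maps.
#' @export
export_marxan <- function(incidence, weights = NULL, costs = 1, dir) {
  stopifnot(inherits(incidence, "branch_incidence"))
  n <- incidence$n_pu
  nb <- length(incidence$branch_id)
  if (length(costs) == 1L) costs <- rep(costs, n)
  if (length(costs) != n) {
    stop("costs must have one value per planning unit (", n, ")", call. = FALSE)
  }
  spf <- if (is.null(weights)) incidence$length else {
    stopifnot(inherits(weights, "feature_weights"))
    if (length(weights$w) != nb) {
      stop("weights and incidence describe different numbers of branches",
           call. = FALSE)
    }
    weights$w
  }
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir, call. = FALSE)
  }

  pu <- data.frame(id = seq_len(n), cost = costs)
  spec <- data.frame(id = seq_len(nb), target = 1L,
                     spf = formatC(spf, digits = 10, format = "g"),
                     name = incidence$branch_id, stringsAsFactors = FALSE)
  present <- which(incidence$matrix > 0L, arr.ind = TRUE)
  puvspr <- data.frame(species = present[, 1], pu = present[, 2], amount = 1L)
  puvspr <- puvspr[order(puvspr$pu, puvspr$species), , drop = FALSE]

  write_dat <- function(df, file) {
    con <- file(file.path(dir, file), open = "wb")  # binary: stable newlines
    on.exit(close(con))
    writeLines(paste(colnames(df), collapse = ","), con)
    writeLines(do.call(paste, c(unname(df), sep = ",")), con)
  }
  write_dat(pu, "pu.dat")
  write_dat(spec, "spec.dat")
  write_dat(puvspr, "puvspr.dat")
  write_dat(data.frame(id = seq_len(nb), branch_id = incidence$branch_id,
                       length = formatC(incidence$length, digits = 10, format = "g"),
                       stringsAsFactors = FALSE), "branch_ids.csv")
  write_dat(data.frame(id = seq_len(n), pu_id = incidence$pu_ids,
                       stringsAsFactors = FALSE), "pu_ids.csv")

  invisible(list(pu = pu, spec = spec, puvspr = puvspr,
                 branch_map = incidence$branch_id, pu_map = incidence$pu_ids))
}

read_dat <- function(dir, file, required_cols) {
  path <- file.path(dir, file)
  if (!file.exists(path)) stop("missing Marxan file: ", path, call. = FALSE)
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  unknown <- setdiff(colnames(df), required_cols)
  missing <- setdiff(required_cols, colnames(df))
  if (length(missing)) {
    stop(file, ": missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(unknown)) {
    stop(file, ": unknown column(s) ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Import a Marxan dataset back into a branch-feature problem
#'
#' Reads `pu.dat`, `spec.dat` and `puvspr.dat` (comma or tab delimited,
#' header row) and reconstructs the incidence matrix, feature weights and
#' costs. Arbitrary feature tables are legal here — the ancestral-dominance
#' structure that tree-derived tables have is not enforced; instead the
#' returned object records whether it holds (`dominance`: TRUE iff for
#' every pair of features one incidence row dominates the other whenever
#' they are nested).
#'
#' @param dir directory holding the three files (and optionally the id
#'   maps written by [export_marxan()], used to restore original ids).
#' @return list with `incidence` (a `branch_incidence`), `spf` (numeric,
#'   per feature), `costs`, `dominance` (logical flag).
#' @export
import_marxan <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir, call. = FALSE)
  pu <- read_dat(dir, "pu.dat", c("id", "cost"))
  spec <- read_dat(dir, "spec.dat", c("id", "target", "spf", "name"))
  puvspr <- read_dat(dir, "puvspr.dat", c("species", "pu", "amount"))
  if (anyDuplicated(pu$id) || any(pu$id <= 0)) {
    stop("pu.dat ids must be unique positive integers", call. = FALSE)
  }
  if (anyDuplicated(spec$id) || any(spec$id <= 0)) {
    stop("spec.dat ids must be unique positive integers", call. = FALSE)
  }
  bad_pu <- setdiff(puvspr$pu, pu$id)
  if (length(bad_pu)) {
    stop("puvspr.dat references unknown pu id(s): ",
         paste(bad_pu, collapse = ", "), call. = FALSE)
  }
  bad_sp <- setdiff(puvspr$species, spec$id)
  if (length(bad_sp)) {
    stop("puvspr.dat references unknown species id(s): ",
         paste(bad_sp, collapse = ", "), call. = FALSE)
  }

  pu_names <- as.character(pu$id)
  br_names <- as.character(spec$name)
  pmap <- file.path(dir, "pu_ids.csv")
  if (file.exists(pmap)) {
    m <- utils::read.table(pmap, header = TRUE, sep = ",",
                           stringsAsFactors = FALSE)
    pu_names <- m$pu_id[match(pu$id, m$id)]
  }
  bmap <- file.path(dir, "branch_ids.csv")
  lengths <- spec$spf
  if (file.exists(bmap)) {
    m <- utils::read.table(bmap, header = TRUE, sep = ",",
                           stringsAsFactors = FALSE)
    lengths <- m$length[match(spec$id, m$id)]
  }

  mat <- matrix(0L, nrow(spec), nrow(pu), dimnames = list(br_names, pu_names))
  mat[cbind(match(puvspr$species, spec$id), match(puvspr$pu, pu$id))] <- 1L
  inc <- branch_incidence(mat, as.numeric(lengths))
  list(incidence = inc,
       spf = as.numeric(spec$spf),
       costs = pu$cost,
       dominance = incidence_dominance(inc))
}

# Laminarity diagnostic: whenever two feature rows overlap in some PU, one
# must contain the other. Tree-derived tables restricted to a root-to-tip
# path are always nested, but tables from trees whose separate clades share
# PUs can legitimately fail this; the flag is informational, mainly useful
# for spotting hand-built tables with no nesting structure at all.
incidence_dominance <- function(incidence) {
  m <- incidence$matrix > 0L
  nb <- nrow(m)
  if (nb < 2L) return(TRUE)
  for (i in seq_len(nb - 1L)) {
    for (j in seq(i + 1L, nb)) {
      both <- m[i, ] & m[j, ]
      if (any(both)) {
        if (!(all(m[j, ] | !m[i, ]) || all(m[i, ] | !m[j, ]))) return(FALSE)
      }
    }
  }
  TRUE
}
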