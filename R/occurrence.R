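#' Construct a tip-by-planning-unit occurrence table
#'
#' Planning units (PUs) are the elementary spatial units of a conservation
#' plan — in the groundwater setting, individual monitoring bores. Counts are
#' binarised: any positive abundance records presence.
#'
#' @param mat numeric matrix, tips in rows, PUs in columns; rownames are tip
#'   labels and colnames PU identifiers (both mandatory and unique).
#' @return an object of class `tip_occurrence`: an integer 0/1 matrix with
#'   the same dimnames.
#' @export
tip_occurrence <- function(mat) {
  stopifnot(is.matrix(mat))
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("occurrence matrix needs tip labels as rownames and PU ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(mat))) {
    stop("duplicate tip labels in occurrence table", call. = FALSE)
  }
  if (anyDuplicated(colnames(mat))) {
    stop("duplicate planning-unit identifiers", call. = FALSE)
  }
  if (!is.numeric(mat) || anyNA(mat)) {
    stop("occurrence entries must be numeric and non-missing", call. = FALSE)
  }
  out <- matrix(as.integer(mat > 0), nrow(mat), ncol(mat), dimnames = dimnames(mat))
  empty <- colnames(out)[colSums(out) == 0L]
  if (length(empty)) {
    message("planning unit(s) with no recorded tips retained: ",
            paste(empty, collapse = ", "))
  }
  structure(out, class = c("tip_occurrence", "matrix"))
}

#' Read an occurrence table from CSV/TSV
#'
#' Two layouts are accepted. `wide`: first column holds tip labels, remaining
#' columns are planning units, cells are numeric abundances (binarised on
#' read). `long`: two columns `(tip, pu)`, one row per record; duplicate
#' records are collapsed with a warning. A header row is mandatory; the
#' delimiter (comma or tab) is sniffed from the header line.
#'
#' @param path path to a delimited text file.
#' @param format `"wide"` or `"long"`.
#' @return a [tip_occurrence()] matrix.
#' @export
read_occurrence <- function(path, format = c("wide", "long")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("occurrence file not found: ", path, call. = FALSE)
  }
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (format == "wide") {
    tips <- as.character(df[[1]])
    vals <- df[, -1, drop = FALSE]
    num <- vapply(vals, is.numeric, logical(1))
    if (!all(num)) {
      stop("non-numeric entries in wide occurrence columns: ",
           paste(names(vals)[!num], collapse = ", "), call. = FALSE)
    }
    m <- as.matrix(vals)
    rownames(m) <- tips
    tip_occurrence(m)
  } else {
    if (ncol(df) < 2L) {
      stop("long format needs two columns (tip, pu)", call. = FALSE)
    }
    tip <- as.character(df[[1]])
    pu <- as.character(df[[2]])
    if (anyDuplicated(paste(tip, pu, sep = "\r"))) {
      warning("duplicate (tip, pu) records collapsed", call. = FALSE)
    }
    tips <- unique(tip)
    pus <- unique(pu)
    m <- matrix(0, length(tips), length(pus), dimnames = list(tips, pus))
    m[cbind(match(tip, tips), match(pu, pus))] <- 1
    tip_occurrence(m)
  }
}

#' @export
print.tip_occurrence <- function(x, ...) {
  cat("Tip occurrence: ", nrow(x), " tips x ", ncol(x), " planning units; ",
      sum(x), " presences\n", sep = "")
  invisible(x)
}
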