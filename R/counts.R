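#' Validated count matrix
#'
#' A count matrix is a base integer-valued matrix of non-negative counts with
#' unique uppercase gene symbols as row names and unique sample (or cell)
#' identifiers as column names. `as_count_matrix()` normalizes and validates
#' an arbitrary numeric matrix into this form: gene symbols are uppercased and
#' rows sharing a symbol are collapsed by summation (so per-cell totals used
#' by downstream UMI-fraction scores are preserved).
#'
#' @param x numeric matrix with row names (gene symbols) and column names
#'   (sample or cell ids).
#' @return an integer matrix of class `count_matrix`.
#' @examples
#' m <- matrix(c(1, 2, 0, 5, 3, 3), nrow = 3, byrow = TRUE,
#'             dimnames = list(c("TP53", "Actb", "EGFR"), c("s1", "s2")))
#' cm <- as_count_matrix(m)
#' rownames(cm)
#' @export
as_count_matrix <- function(x) {
  if (!is.matrix(x) && !methods::is(x, "Matrix")) {
    stop("count input must be a matrix")
  }
  if (methods::is(x, "Matrix")) x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("count matrix must have gene row names and sample column names")
  }
  bad <- which(!is.finite(x) | x < 0 | abs(x - round(x)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "counts must be non-negative integers; first offending entry at gene '%s', sample '%s'",
      rownames(x)[bad[1L, 1L]], colnames(x)[bad[1L, 2L]]
    ))
  }
  rownames(x) <- toupper(rownames(x))
  if (anyDuplicated(colnames(x))) {
    stop("duplicate sample/cell identifiers in count matrix")
  }
  if (anyDuplicated(rownames(x))) {
    x <- rowsum(x, group = rownames(x), reorder = FALSE)
  }
  storage.mode(x) <- "double"   # keeps >2^31 totals safe; values remain integral
  class(x) <- c("count_matrix", class(x))
  x
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples/cells\n", nrow(x), ncol(x)))
  cat(sprintf("total counts: %.0f\n", sum(x)))
  invisible(x)
}

is_count_matrix <- function(x) inherits(x, "count_matrix")

# accept either a validated count_matrix or a plain matrix (validated on entry)
ensure_counts <- function(x) {
  if (is_count_matrix(x)) x else as_count_matrix(x)
}
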