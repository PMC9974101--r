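#' Gene-by-unit count matrix
#'
#' A light container for non-negative integer counts with genes on rows and
#' observation units (cells or samples) on columns. Counts are stored as a
#' sparse [Matrix::dgCMatrix-class]; `unit_kind` records whether columns are
#' individual cells or (pseudo)bulk samples.
#'
#' @param counts A matrix or sparse Matrix of non-negative counts with unique
#'   rownames (gene symbols) and unique colnames (unit identifiers).
#' @param unit_kind Either `"cell"` or `"sample"`.
#' @return An object of class `count_matrix` with elements `counts`
#'   (dgCMatrix), `genes`, `units` and `unit_kind`.
#' @examples
#' m <- matrix(c(0, 1, 2, 3, 0, 4), nrow = 3,
#'             dimnames = list(c("A", "B", "C"), c("u1", "u2")))
#' cm <- count_matrix(m, "cell")
#' dim(cm)
#' @export
count_matrix <- function(counts, unit_kind = c("cell", "sample")) {
  unit_kind <- match.arg(unit_kind)
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) ||
      (is.null(colnames(counts)) && ncol(counts) > 0)) {
    stop("count matrix must have gene rownames and unit colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- unique(rownames(counts)[duplicated(rownames(counts))])
    stop("duplicate gene symbols: ", paste(head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate unit identifiers", call. = FALSE)
  }
  if (any(counts@x < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(counts@x != round(counts@x))) {
    stop("counts must be integer-valued", call. = FALSE)
  }
  structure(
    list(counts = counts,
         genes = rownames(counts),
         units = colnames(counts) %||% character(0),
         unit_kind = unit_kind),
    class = "count_matrix"
  )
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d %ss (%.1f%% nonzero)\n",
              nrow(x$counts), ncol(x$counts), x$unit_kind,
              100 * Matrix::nnzero(x$counts) / prod(dim(x$counts))))
  invisible(x)
}

#' Subset a count matrix
#'
#' @param x A [count_matrix].
#' @param genes,units Optional character or index vectors selecting rows /
#'   columns; `NULL` keeps all.
#' @return A `count_matrix` restricted to the selection.
#' @export
subset_counts <- function(x, genes = NULL, units = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  m <- x$counts
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  if (!is.null(units)) m <- m[, units, drop = FALSE]
  count_matrix(m, x$unit_kind)
}
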