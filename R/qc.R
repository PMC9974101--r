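# Cell-level QC, log-CPM normalization, marker-score segment assignment and
# pseudobulk aggregation.

#' QC thresholds
#'
#' Cells are kept when the number of detected genes lies in
#' `[min_genes, max_genes]` (inclusive) and the mitochondrial count fraction
#' is strictly below `max_mito_fraction`.
#'
#' @param min_genes,max_genes Inclusive bounds on detected genes per cell.
#' @param max_mito_fraction Strict upper bound on the mitochondrial fraction.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 500, max_genes = 5000,
                          max_mito_fraction = 0.5) {
  if (!(min_genes > 0 && min_genes <= max_genes)) {
    stop("need 0 < min_genes <= max_genes", call. = FALSE)
  }
  if (!(max_mito_fraction > 0 && max_mito_fraction <= 1)) {
    stop("max_mito_fraction must be in (0,1]", call. = FALSE)
  }
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_mito_fraction = max_mito_fraction),
            class = "qc_thresholds")
}

#' Filter cells on detected genes and mitochondrial fraction
#'
#' @param x A [count_matrix] with `unit_kind = "cell"`.
#' @param thresholds A [qc_thresholds()].
#' @param mito_prefix Prefix identifying mitochondrial genes (default
#'   `"MT-"`, use `"mt-"` for mouse).
#' @return The filtered `count_matrix`; retained/removed tallies are reported
#'   via `message()`.
#' @export
qc_filter <- function(x, thresholds = qc_thresholds(), mito_prefix = "MT-") {
  stopifnot(inherits(x, "count_matrix"))
  if (x$unit_kind != "cell") stop("qc_filter expects cell-level counts", call. = FALSE)
  if (ncol(x$counts) == 0) {
    warning("qc_filter: empty input", call. = FALSE)
    return(x)
  }
  detected <- Matrix::colSums(x$counts > 0)
  total <- Matrix::colSums(x$counts)
  is_mito <- startsWith(x$genes, mito_prefix)
  mito <- if (any(is_mito)) {
    Matrix::colSums(x$counts[is_mito, , drop = FALSE])
  } else {
    rep(0, ncol(x$counts))
  }
  mito_frac <- ifelse(total > 0, mito / total, 0)
  keep <- detected >= thresholds$min_genes &
    detected <= thresholds$max_genes &
    mito_frac < thresholds$max_mito_fraction
  message(sprintf("qc_filter: retained %d / %d cells (%d removed)",
                  sum(keep), length(keep), sum(!keep)))
  subset_counts(x, units = which(keep))
}

#' Log2 counts-per-scale normalization
#'
#' `value = log2(1 + scale * count / unit_total)`; with the default
#' `scale = 1e4` this is log2(1 + CP10K).
#'
#' @param x A [count_matrix].
#' @param scale Positive scaling constant.
#' @return A dense numeric matrix of the same shape and dimnames.
#' @export
normalize_log_cpm <- function(x, scale = 1e4) {
  stopifnot(inherits(x, "count_matrix"), scale > 0)
  total <- Matrix::colSums(x$counts)
  if (any(total == 0)) {
    stop("unit(s) with zero total count: ",
         paste(head(x$units[total == 0], 5), collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(x$counts)
  log2(1 + sweep(m, 2, scale / total, "*"))
}

#' Marker panel
#'
#' @param panel Named list mapping segment label to its marker genes (each
#'   segment needs at least one marker; panels may overlap).
#' @return The validated panel, class `marker_panel`.
#' @export
marker_panel <- function(panel) {
  if (is.null(names(panel)) || any(!nzchar(names(panel)))) {
    stop("marker panel segments must be named", call. = FALSE)
  }
  if (any(lengths(panel) == 0)) {
    stop("every segment needs at least one marker", call. = FALSE)
  }
  structure(lapply(panel, as.character), class = "marker_panel")
}

#' Assign segments by marker score
#'
#' Per cell, each segment's score is the mean z-scored expression of its
#' marker genes (z across cells per gene; zero-variance genes contribute 0);
#' the assigned segment is the argmax, ties broken by panel declaration
#' order. Stands in for graph clustering plus manual marker annotation.
#'
#' @param expr Normalized expression matrix (genes x cells), e.g. from
#'   [normalize_log_cpm()].
#' @param panel A [marker_panel()].
#' @param metadata Optional metadata tibble whose `segment` column is filled
#'   (matched on `unit_id`).
#' @return If `metadata` is `NULL`, a tibble `unit_id`, `segment`; otherwise
#'   `metadata` with `segment` filled.
#' @export
assign_segments <- function(expr, panel, metadata = NULL) {
  stopifnot(inherits(panel, "marker_panel"), is.matrix(expr))
  z <- expr
  mu <- rowMeans(z)
  sdv <- apply(z, 1, sd)
  nz <- sdv > 0
  z[nz, ] <- (z[nz, , drop = FALSE] - mu[nz]) / sdv[nz]
  z[!nz, ] <- 0
  scores <- matrix(NA_real_, ncol(expr), length(panel),
                   dimnames = list(colnames(expr), names(panel)))
  for (s in names(panel)) {
    present <- intersect(panel[[s]], rownames(expr))
    if (!length(present)) {
      stop("segment '", s, "': no marker genes present in expression matrix",
           call. = FALSE)
    }
    if (length(present) < length(panel[[s]])) {
      warning(sprintf("segment '%s': %d marker(s) absent, dropped",
                      s, length(panel[[s]]) - length(present)), call. = FALSE)
    }
    scores[, s] <- colMeans(z[present, , drop = FALSE])
  }
  # argmax with ties broken by panel declaration (column) order
  assigned <- names(panel)[max.col(scores, ties.method = "first")]
  out <- tibble::tibble(unit_id = colnames(expr), segment = assigned)
  if (is.null(metadata)) return(out)
  metadata$segment <- NULL
  dplyr::left_join(metadata, out, by = "unit_id")
}

#' Aggregate cells to pseudobulk profiles
#'
#' Counts are summed across cells within each combination of the `by`
#' metadata columns (default sample and segment). The grand total of the
#' retained cells is conserved exactly.
#'
#' @param x A [count_matrix] with `unit_kind = "cell"`.
#' @param metadata Metadata tibble covering the cells of `x` (`unit_id`,
#'   `sample_id`, `group`, and `segment` when aggregating by segment).
#' @param by Metadata columns defining the aggregation units.
#' @return A list: `counts` (a sample-level [count_matrix], one column per
#'   observed `by` combination) and `metadata` (one row per pseudobulk unit,
#'   with `n_cells`).
#' @export
pseudobulk <- function(x, metadata, by = c("sample_id", "segment")) {
  stopifnot(inherits(x, "count_matrix"))
  if (x$unit_kind != "cell") stop("pseudobulk expects cell-level counts", call. = FALSE)
  miss <- setdiff(by, names(metadata))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  md <- metadata[match(x$units, metadata$unit_id), , drop = FALSE]
  if (anyNA(md$unit_id)) stop("metadata does not cover all cells", call. = FALSE)
  key <- do.call(paste, c(md[by], sep = "."))
  levels_key <- unique(key)
  # sparse indicator (cells x units) so aggregation is one matrix product
  ind <- Matrix::sparseMatrix(i = seq_along(key),
                              j = match(key, levels_key),
                              x = 1,
                              dims = c(length(key), length(levels_key)),
                              dimnames = list(NULL, levels_key))
  agg <- x$counts %*% ind
  pb_md <- md[match(levels_key, key), c("sample_id", "group", by[by != "sample_id"]),
              drop = FALSE]
  pb_md <- tibble::as_tibble(pb_md)
  pb_md$unit_id <- levels_key
  pb_md$n_cells <- as.integer(table(key)[levels_key])
  pb_md <- dplyr::relocate(pb_md, "unit_id")
  # combinations of by-levels present in metadata but with zero cells
  expected <- do.call(paste, c(unique(metadata[by]), sep = "."))
  dropped <- setdiff(expected, levels_key)
  if (length(dropped)) {
    warning("pseudobulk: ", length(dropped),
            " (sample, segment) combination(s) had no cells and were omitted",
            call. = FALSE)
  }
  list(counts = count_matrix(agg, "sample"), metadata = pb_md)
}

#' Fraction of cells expressing a gene, per stratum
#'
#' @param x A cell-level [count_matrix].
#' @param metadata Metadata tibble with `unit_id`, `group` and (optionally)
#'   `segment`.
#' @param gene Gene symbol (must be present).
#' @param group,segment Optional filters; when `NULL` the fraction is
#'   reported for every observed stratum.
#' @return A tibble `group`, `segment`, `n_cells`, `n_expressing`,
#'   `fraction`; empty strata are absent (no cells means the fraction is
#'   undefined).
#' @export
fraction_expressing <- function(x, metadata, gene, group = NULL, segment = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  if (!gene %in% x$genes) stop("gene not present: ", gene, call. = FALSE)
  md <- metadata[match(x$units, metadata$unit_id), , drop = FALSE]
  if (!"segment" %in% names(md)) md$segment <- NA_character_
  md$expressing <- as.vector(x$counts[gene, ] > 0)
  if (!is.null(group)) md <- md[as.character(md$group) %in% group, , drop = FALSE]
  if (!is.null(segment)) md <- md[md$segment %in% segment, , drop = FALSE]
  md |>
    dplyr::group_by(.data$group, .data$segment) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     n_expressing = sum(.data$expressing),
                     fraction = mean(.data$expressing),
                     .groups = "drop")
}
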