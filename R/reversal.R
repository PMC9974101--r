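# The core classifier: a transcript is "reversed" by treatment when it is
# significant (FDR < alpha, strict) in both contrasts with opposite
# fold-change signs. Disease-up genes pushed back down are "suppressed";
# disease-down genes pushed back up are "enhanced". Everything else —
# including significant concordant changes — is "not_reversed".

#' Classify transcripts as suppressed / enhanced / not reversed
#'
#' @param result1 [run_contrasts()] rows for the disease-vs-control contrast
#'   (e.g. T2Di(-) vs HC).
#' @param result2 Rows for the treated-vs-untreated contrast (e.g. T2Di(+)
#'   vs T2Di(-)); must cover the same (gene, segment) universe as `result1`.
#' @param alpha Significance level; the FDR gate is strict (`fdr < alpha`, a
#'   gene at exactly `alpha` is not significant).
#' @return A tibble of class `reversal_table`: `gene`, `segment`, `class`
#'   (`suppressed` / `enhanced` / `not_reversed`), both contrasts' `log2FC`
#'   and `fdr`, and `concordant` flagging significant same-sign pairs.
#' @export
classify_reversal <- function(result1, result2, alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)", call. = FALSE)
  k1 <- paste(result1$gene, result1$segment, sep = "\r")
  k2 <- paste(result2$gene, result2$segment, sep = "\r")
  sym_diff <- length(setdiff(k1, k2)) + length(setdiff(k2, k1))
  if (sym_diff > 0) {
    stop("contrast results cover different (gene, segment) universes; ",
         "symmetric difference of size ", sym_diff, call. = FALSE)
  }
  r2 <- result2[match(k1, k2), , drop = FALSE]
  sig1 <- !is.na(result1$fdr) & result1$fdr < alpha
  sig2 <- !is.na(r2$fdr) & r2$fdr < alpha
  up1 <- result1$log2FC > 0
  dn1 <- result1$log2FC < 0
  up2 <- r2$log2FC > 0
  dn2 <- r2$log2FC < 0
  cls <- rep("not_reversed", nrow(result1))
  cls[sig1 & sig2 & up1 & dn2] <- "suppressed"
  cls[sig1 & sig2 & dn1 & up2] <- "enhanced"
  out <- tibble::tibble(
    gene = result1$gene,
    segment = result1$segment,
    class = cls,
    log2FC1 = result1$log2FC,
    fdr1 = result1$fdr,
    log2FC2 = r2$log2FC,
    fdr2 = r2$fdr,
    concordant = sig1 & sig2 & ((up1 & up2) | (dn1 & dn2))
  )
  class(out) <- c("reversal_table", class(out))
  out
}

#' Significant concordant (non-reversed) transcripts
#'
#' Side table of genes significant in both contrasts with the same
#' fold-change sign; these are not analyzed as reversals but are exported
#' for inspection.
#'
#' @param records A `reversal_table`.
#' @return The concordant subset of the table.
#' @export
concordant_records <- function(records) {
  dplyr::filter(records, .data$concordant)
}

#' Per-segment reversal counts
#'
#' @param records A `reversal_table`.
#' @return A tibble `segment`, `reversed`, `suppressed`, `enhanced` with
#'   `reversed = suppressed + enhanced`; empty input gives an empty table.
#' @export
count_by_segment <- function(records) {
  if (nrow(records) == 0) {
    return(tibble::tibble(segment = character(), reversed = integer(),
                          suppressed = integer(), enhanced = integer()))
  }
  records |>
    dplyr::group_by(.data$segment) |>
    dplyr::summarise(
      suppressed = sum(.data$class == "suppressed"),
      enhanced = sum(.data$class == "enhanced"),
      .groups = "drop"
    ) |>
    dplyr::mutate(reversed = .data$suppressed + .data$enhanced) |>
    dplyr::relocate("segment", "reversed", "suppressed", "enhanced")
}

#' Upset-style exclusive segment intersections
#'
#' Each gene carrying `class` in at least one segment is counted in exactly
#' the combination of segments where it does, so exclusive counts partition
#' the union of genes.
#'
#' @param records A `reversal_table`.
#' @param class `"suppressed"` or `"enhanced"`.
#' @return A list of class `intersection_summary`: `intersections` (tibble
#'   `combo`, `degree`, `n`, `genes` list-column, sorted by `n`),
#'   `per_segment` totals, and `n_union`.
#' @export
shared_sets <- function(records, class = c("suppressed", "enhanced")) {
  class <- match.arg(class)
  hits <- dplyr::filter(records, .data$class == !!class)
  if (nrow(hits) == 0) {
    inter <- tibble::tibble(combo = character(), degree = integer(),
                            n = integer(), genes = list())
    return(structure(list(intersections = inter,
                          per_segment = tibble::tibble(segment = character(),
                                                       n = integer()),
                          n_union = 0L, class = class),
                     class = "intersection_summary"))
  }
  seg_order <- unique(records$segment)
  combos <- hits |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      combo = paste(seg_order[sort(match(.data$segment, seg_order))],
                    collapse = "+"),
      degree = dplyr::n(), .groups = "drop")
  inter <- combos |>
    dplyr::group_by(.data$combo, .data$degree) |>
    dplyr::summarise(n = dplyr::n(), genes = list(sort(.data$gene)),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n))
  per_segment <- hits |>
    dplyr::count(.data$segment, name = "n")
  structure(list(intersections = inter, per_segment = per_segment,
                 n_union = dplyr::n_distinct(hits$gene), class = class),
            class = "intersection_summary")
}

#' @export
print.intersection_summary <- function(x, ...) {
  cat(sprintf("<intersection_summary> class = %s, %d gene(s) across %d combination(s)\n",
              x$class, x$n_union, nrow(x$intersections)))
  print(x$intersections[, c("combo", "degree", "n")])
  invisible(x)
}
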