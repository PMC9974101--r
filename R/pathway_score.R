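# Single-sample gene-set scoring. Per unit, genes are ranked by expression
# (average ranks on ties) and walked in decreasing rank; in-set steps add
# rank^alpha (normalized to sum 1 over in-set genes), out-of-set steps add
# 1/(G - |set|); the score is the sum over the walk of (cumulative in-set
# weight - cumulative out-of-set weight). This is the unnormalized ssGSEA
# enrichment statistic: rank-based, hence invariant to any strictly monotone
# transform of a unit's expression vector.

#' ssGSEA score per unit
#'
#' @param expr Numeric expression matrix (genes x units), at least 2 genes.
#' @param gene_set Character vector of gene symbols; must share at least one
#'   gene with `expr` and leave at least one gene outside the set.
#' @param alpha Rank-weight exponent (>= 0, default 0.25).
#' @return Named numeric vector: one score per unit (column).
#' @export
ssgsea_score <- function(expr, gene_set, alpha = 0.25) {
  drop(.ssgsea_multi(expr, list(set = gene_set), alpha))
}

# Shared scoring core: each unit is ranked once and the decreasing-rank
# ordering (gene name breaks ties deterministically) is reused across sets.
.ssgsea_multi <- function(expr, sets, alpha) {
  stopifnot(is.matrix(expr), nrow(expr) >= 2, alpha >= 0)
  genes <- rownames(expr)
  G <- nrow(expr)
  masks <- lapply(sets, function(members) genes %in% members)
  for (nm in names(masks)) {
    m <- sum(masks[[nm]])
    if (m == 0) {
      stop("gene set shares no genes with the expression matrix", call. = FALSE)
    }
    if (m == G) {
      stop("gene set covers the whole expression matrix; no out-of-set genes",
           call. = FALSE)
    }
  }
  out <- matrix(NA_real_, ncol(expr), length(sets),
                dimnames = list(colnames(expr), names(sets)))
  for (j in seq_len(ncol(expr))) {
    r <- rank(expr[, j], ties.method = "average")
    ord <- order(-r, genes)
    r_a <- r[ord]^alpha
    for (k in seq_along(masks)) {
      ins <- masks[[k]][ord]
      w_in <- numeric(G)
      w_in[ins] <- r_a[ins] / sum(r_a[ins])
      w_out <- (!ins) / (G - sum(ins))
      out[j, k] <- sum(cumsum(w_in) - cumsum(w_out))
    }
  }
  out
}

#' Pathway score table
#'
#' Scores every unit of an expression matrix against every set of a
#' collection and attaches unit metadata. Sets sharing no genes with the
#' matrix are skipped with a warning.
#'
#' @param expr Expression matrix (genes x units).
#' @param metadata Unit metadata (`unit_id`, `sample_id`, `group`, optional
#'   `segment`).
#' @param collection A [gene_set_collection()] (or a single character vector,
#'   scored as set `"set"`).
#' @param alpha Rank-weight exponent.
#' @return A tibble of class `pathway_score_table`: `unit_id`, `sample_id`,
#'   `group`, `segment`, `set_name`, `score`.
#' @export
score_table <- function(expr, metadata, collection, alpha = 0.25) {
  if (is.character(collection)) {
    collection <- gene_set_collection(list(set = collection))
  }
  stopifnot(inherits(collection, "gene_set_collection"))
  md <- metadata[match(colnames(expr), metadata$unit_id), , drop = FALSE]
  if (!"segment" %in% names(md)) md$segment <- NA_character_
  sets <- unclass(collection)
  scorable <- vapply(sets, function(m) any(rownames(expr) %in% m), logical(1))
  if (any(!scorable)) {
    warning("set(s) sharing no genes with the expression matrix skipped: ",
            paste(names(sets)[!scorable], collapse = ", "), call. = FALSE)
    sets <- sets[scorable]
  }
  if (!length(sets)) stop("no set shares genes with the expression matrix", call. = FALSE)
  scores <- .ssgsea_multi(expr, sets, alpha)
  out <- purrr::map_dfr(colnames(scores), function(nm) {
    tibble::tibble(
      unit_id = colnames(expr),
      sample_id = md$sample_id,
      group = md$group,
      segment = md$segment,
      set_name = nm,
      score = unname(scores[, nm])
    )
  })
  class(out) <- c("pathway_score_table", class(out))
  out
}

#' Group-delta pathway scores relative to a reference group
#'
#' Scores are first averaged within (sample, segment, set), then across
#' samples per (group, segment, set); the delta is the group mean minus the
#' reference-group mean, so the reference delta is 0 by construction.
#' Segments lacking the reference group are omitted with a warning.
#'
#' @param scores A `pathway_score_table` from [score_table()].
#' @param reference_group Reference group label (default `"HC"`).
#' @return A tibble of class `delta_score_table`: `set_name`, `segment`,
#'   `group`, `mean_score`, `delta`, `sd_sample_means`, `n_samples`.
#' @export
delta_pathway_score <- function(scores, reference_group = "HC") {
  if (!reference_group %in% as.character(scores$group)) {
    stop("reference group '", reference_group, "' absent from scores", call. = FALSE)
  }
  sample_means <- scores |>
    dplyr::group_by(.data$set_name, .data$segment, .data$group, .data$sample_id) |>
    dplyr::summarise(score = mean(.data$score), .groups = "drop")
  group_means <- sample_means |>
    dplyr::group_by(.data$set_name, .data$segment, .data$group) |>
    dplyr::summarise(mean_score = mean(.data$score),
                     sd_sample_means = sd(.data$score),
                     n_samples = dplyr::n(), .groups = "drop")
  ref <- group_means |>
    dplyr::filter(as.character(.data$group) == reference_group) |>
    dplyr::select("set_name", "segment", ref_mean = "mean_score")
  missing_ref <- dplyr::anti_join(
    dplyr::distinct(group_means, .data$set_name, .data$segment), ref,
    by = c("set_name", "segment"))
  if (nrow(missing_ref)) {
    warning("segment(s) without reference group omitted: ",
            paste(unique(missing_ref$segment), collapse = ", "), call. = FALSE)
  }
  out <- group_means |>
    dplyr::inner_join(ref, by = c("set_name", "segment")) |>
    dplyr::mutate(delta = .data$mean_score - .data$ref_mean) |>
    dplyr::select("set_name", "segment", "group", "mean_score", "delta",
                  "sd_sample_means", "n_samples")
  class(out) <- c("delta_score_table", class(out))
  out
}
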