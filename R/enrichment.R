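# Directional over-representation analysis: one-sided Fisher exact
# (hypergeometric tail) of suppressed / enhanced gene lists against a GMT
# collection, with the significance rule p < alpha and overlap >= 5.

#' One-sided Fisher over-representation test
#'
#' For each set in `collection` (intersected with `universe` first), tests
#' over-representation of `query` with the hypergeometric tail
#' `p = P(X >= k)` for the 2x2 table `(k, n-k, K-k, N-n-K+k)`; the odds
#' ratio is the sample odds ratio of the same table.
#'
#' @param query Character vector of genes (must be a subset of `universe`).
#' @param universe Background gene universe (non-empty).
#' @param collection A [gene_set_collection()].
#' @return A tibble of class `enrichment_result`: `pathway`, `overlap` (k),
#'   `set_size` (K within universe), `query_size` (n), `universe_size` (N),
#'   `odds_ratio`, `p_value`, sorted by `p_value`.
#' @export
fisher_enrich <- function(query, universe, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  extra <- setdiff(query, universe)
  if (length(extra)) {
    stop("query contains ", length(extra), " gene(s) outside the universe: ",
         paste(head(extra, 5), collapse = ", "), call. = FALSE)
  }
  N <- length(universe)
  n <- length(query)
  rows <- purrr::imap_dfr(unclass(collection), function(members, nm) {
    set <- intersect(members, universe)
    K <- length(set)
    k <- length(intersect(query, set))
    tibble::tibble(pathway = nm, overlap = k, set_size = K,
                   query_size = n, universe_size = N)
  })
  rows$p_value <- hypergeom_tail_p(rows$overlap, rows$set_size,
                                   rows$query_size, rows$universe_size)
  a <- rows$overlap
  b <- rows$query_size - a
  c_ <- rows$set_size - a
  d <- rows$universe_size - rows$query_size - rows$set_size + a
  rows$odds_ratio <- (a * d) / (b * c_)
  out <- dplyr::arrange(rows, .data$p_value)
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeom(N, K, n)` (number of set members in a
#' query of size `n` drawn from a universe of size `N` containing `K` set
#' members). `k = 0` gives 1 exactly.
#'
#' @param k,K,n,N Integer vectors (recycled).
#' @return Numeric vector of tail probabilities.
#' @export
hypergeom_tail_p <- function(k, K, n, N) {
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  pmin(pmax(p, 0), 1)
}

#' Apply the significance rule to enrichment results
#'
#' Keeps pathways with `p_value < alpha` and `overlap >= min_overlap`.
#'
#' @param results An `enrichment_result` tibble.
#' @param alpha Significance level (strict).
#' @param min_overlap Minimum overlapping transcripts (default 5).
#' @return The filtered tibble.
#' @export
filter_significant <- function(results, alpha = 0.05, min_overlap = 5) {
  dplyr::filter(results, .data$p_value < alpha, .data$overlap >= min_overlap)
}

#' Directional enrichment of reversal classes per segment
#'
#' Tests the suppressed and enhanced gene lists of each segment separately.
#' The universe is the set of genes tested in that segment
#' (`universe_mode = "tested"`, the default) or the union of collection
#' members (`"global"`). Queries smaller than `min_overlap` are skipped with
#' a logged note (too few transcripts for enrichment).
#'
#' @param records A `reversal_table` from [classify_reversal()].
#' @param collection A [gene_set_collection()].
#' @param universe_mode `"tested"` or `"global"`.
#' @param min_overlap Minimum query size / overlap.
#' @return An `enrichment_result` tibble with `segment` and `direction`
#'   columns (possibly empty).
#' @export
enrich_by_direction <- function(records, collection,
                                universe_mode = c("tested", "global"),
                                min_overlap = 5) {
  universe_mode <- match.arg(universe_mode)
  segs <- unique(records$segment)
  out <- purrr::map_dfr(segs, function(seg) {
    in_seg <- if (is.na(seg)) is.na(records$segment) else
      !is.na(records$segment) & records$segment == seg
    seg_rec <- records[in_seg, , drop = FALSE]
    universe <- if (universe_mode == "tested") {
      unique(seg_rec$gene)
    } else {
      unique(c(unlist(unclass(collection)), seg_rec$gene))
    }
    purrr::map_dfr(c("suppressed", "enhanced"), function(dir) {
      query <- seg_rec$gene[seg_rec$class == dir]
      if (length(query) < min_overlap) {
        message(sprintf(
          "enrich_by_direction: segment %s has %d %s transcript(s); too few for enrichment (min %d), skipped",
          seg, length(query), dir, min_overlap))
        return(NULL)
      }
      res <- fisher_enrich(query, universe, collection)
      res$segment <- seg
      res$direction <- dir
      res
    })
  })
  if (nrow(out)) {
    out <- dplyr::relocate(out, "segment", "direction")
  } else {
    out <- tibble::tibble(segment = character(), direction = character(),
                          pathway = character(), overlap = integer(),
                          set_size = integer(), query_size = integer(),
                          universe_size = integer(), p_value = numeric(),
                          odds_ratio = numeric())
  }
  class(out) <- c("enrichment_result", class(out))
  out
}
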