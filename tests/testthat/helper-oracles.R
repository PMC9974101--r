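# Independent oracles, written from first principles so they share no code
# with the implementation they check.

# Benjamini-Hochberg step-up, literal definition: sort ascending,
# q_(i) = min_{j >= i} m * p_(j) / j, clipped to 1, back in input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, m * ps[i:m] / (i:m))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Hypergeometric upper tail P(X >= k) as an explicit sum of point masses.
hyper_tail_oracle <- function(k, K, n, N) {
  if (k > min(K, n)) return(0)
  lo <- max(k, 0)
  hi <- min(K, n)
  sum(dhyper(lo:hi, K, N - K, n))
}

# Reversal truth table, written as an explicit case analysis.
reversal_oracle <- function(lfc1, fdr1, lfc2, fdr2, alpha = 0.05) {
  sig1 <- !is.na(fdr1) && fdr1 < alpha
  sig2 <- !is.na(fdr2) && fdr2 < alpha
  if (sig1 && sig2 && lfc1 > 0 && lfc2 < 0) return("suppressed")
  if (sig1 && sig2 && lfc1 < 0 && lfc2 > 0) return("enhanced")
  "not_reversed"
}

# ssGSEA running sum evaluated position by position with an explicit loop.
ssgsea_oracle <- function(x, genes, set_genes, alpha) {
  r <- rank(x, ties.method = "average")
  ord <- order(-r, genes)
  in_set <- genes[ord] %in% set_genes
  r_ord <- r[ord]
  w_in_total <- sum(r_ord[in_set]^alpha)
  G <- length(genes)
  m <- sum(in_set)
  cum_in <- 0
  cum_out <- 0
  score <- 0
  for (pos in seq_len(G)) {
    if (in_set[pos]) {
      cum_in <- cum_in + r_ord[pos]^alpha / w_in_total
    } else {
      cum_out <- cum_out + 1 / (G - m)
    }
    score <- score + (cum_in - cum_out)
  }
  unname(score)
}

# Minimal contrast_result-shaped tibble for classifier tests.
make_result <- function(gene, segment, log2FC, fdr, contrast = "c") {
  tibble::tibble(gene = gene, segment = segment, contrast = contrast,
                 log2FC = log2FC, t = NA_real_, p_value = fdr, fdr = fdr,
                 mean_a = NA_real_, mean_b = NA_real_, testable = TRUE)
}

# Tiny deterministic count matrix.
make_counts <- function(mat, unit_kind = "cell",
                        genes = sprintf("g%d", seq_len(nrow(mat))),
                        units = sprintf("u%d", seq_len(ncol(mat)))) {
  dimnames(mat) <- list(genes, units)
  count_matrix(mat, unit_kind)
}
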