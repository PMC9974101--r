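# Negative-binomial cohort simulator with planted reversal structure.
# Counts ~ NB(mean = lib * mu_g * segment_factor * group_factor, var = mu + phi mu^2).
# A "suppressed"-class gene is up 2^delta in untreated disease and back at
# 2^(delta * (1 - rho)) under treatment; "enhanced" is the mirror image. A
# designated pathway set receives its own coordinated suppressed-type shift,
# so single-sample pathway scores have a known group ordering.

#' Simulation configuration
#'
#' Defaults describe a three-group human cohort: 6 healthy controls, 6
#' untreated diabetic and 10 treated diabetic donors, five tubular segments
#' with 50 cells per donor per segment, 2,000 genes with log-normal baseline
#' means and NB dispersion 0.3, 100 planted suppressed and 50 enhanced genes
#' with a one-log2 disease shift fully restored by treatment, 10 markers per
#' segment at 8-fold enrichment, and a 39-gene pathway set carrying a
#' coordinated disease shift that treatment restores.
#'
#' @param n_genes Total genes simulated.
#' @param segments Tubular segment labels.
#' @param samples_per_group Named integer vector of donors per group; names
#'   define the group labels (first = reference).
#' @param cells_per_sample_per_segment Cells per donor per segment (>= 1).
#' @param mu_meanlog,mu_sdlog Log-normal parameters of the per-gene baseline
#'   mean count per cell.
#' @param dispersion NB dispersion phi (variance = mu + phi mu^2).
#' @param libsize_sdlog Log-normal spread of per-unit library-size factors.
#' @param n_suppressed,n_enhanced Planted gene counts per class.
#' @param delta Disease log2 shift (>= 0) for planted genes.
#' @param rho Treatment restoration fraction in [0,1] (1 = full reversal).
#' @param n_markers_per_segment,marker_fold Segment marker genes and their
#'   within-segment fold enrichment.
#' @param mito_fraction Fraction of genes renamed with `mito_prefix` so QC is
#'   exercised realistically.
#' @param mito_prefix Mitochondrial gene-name prefix.
#' @param pathway_size Size of the coordinated pathway set (0 disables).
#' @param pathway_name Name of that set in the emitted collection.
#' @param pathway_delta,pathway_rho Disease shift and restoration for the
#'   pathway set (suppressed-type direction).
#' @param bulk_samples_per_group Named integer vector for bulk mode (murine
#'   cortex layout: 5 per group).
#' @param bulk_depth_factor Multiplier taking per-cell means to per-sample
#'   bulk means.
#' @param bulk_dispersion NB dispersion for bulk samples. Bulk profiles
#'   average over very many cells, so their biological coefficient of
#'   variation is far below the single-cell dispersion; 0.05 is typical for
#'   replicated bulk RNA-seq.
#' @param seed Non-negative integer.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       segments = tubular_segments(),
                       samples_per_group = c(HC = 6, T2Di_minus = 6, T2Di_plus = 10),
                       cells_per_sample_per_segment = 50,
                       mu_meanlog = log(0.5), mu_sdlog = 1,
                       dispersion = 0.3, libsize_sdlog = 0.15,
                       n_suppressed = 100, n_enhanced = 50,
                       delta = 1, rho = 1,
                       n_markers_per_segment = 10, marker_fold = 8,
                       mito_fraction = 0.02, mito_prefix = "MT-",
                       pathway_size = 39,
                       pathway_name = "MTORC1_SIGNALING",
                       pathway_delta = 1, pathway_rho = 1,
                       bulk_samples_per_group = c(control = 5, diabetic = 5,
                                                  diabetic_sglt2i = 5),
                       bulk_depth_factor = 200,
                       bulk_dispersion = 0.05,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$delta < 0 || cfg$pathway_delta < 0) stop("delta must be >= 0", call. = FALSE)
  if (cfg$rho < 0 || cfg$rho > 1 || cfg$pathway_rho < 0 || cfg$pathway_rho > 1) {
    stop("rho must be in [0,1]", call. = FALSE)
  }
  if (cfg$cells_per_sample_per_segment < 1) {
    stop("cells_per_sample_per_segment must be >= 1", call. = FALSE)
  }
  if (cfg$dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  n_planted <- cfg$n_suppressed + cfg$n_enhanced + cfg$pathway_size +
    cfg$n_markers_per_segment * length(cfg$segments)
  if (n_planted > cfg$n_genes) {
    stop(sprintf("planted sets need %d genes but n_genes = %d",
                 n_planted, cfg$n_genes), call. = FALSE)
  }
  if (cfg$seed < 0 || cfg$seed != round(cfg$seed)) {
    stop("seed must be a non-negative integer", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# Draw gene-level structure shared by cohort and bulk modes: baseline means,
# disjoint planted sets, per-group log2 multipliers.
.sim_genes <- function(cfg, groups) {
  n <- cfg$n_genes
  genes <- sprintf("G%05d", seq_len(n))
  n_mito <- round(cfg$mito_fraction * n)
  # planted sets are drawn from the non-mito tail, disjoint by construction
  idx <- seq_len(n)
  mito_idx <- head(idx, n_mito)
  if (n_mito > 0) genes[mito_idx] <- paste0(cfg$mito_prefix, seq_len(n_mito))
  pool <- setdiff(idx, mito_idx)
  pool <- sample(pool)
  take <- function(k) {
    if (k == 0) return(integer(0))
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  suppressed <- take(cfg$n_suppressed)
  enhanced <- take(cfg$n_enhanced)
  pathway <- if (cfg$pathway_size > 0) take(cfg$pathway_size) else integer(0)
  markers <- lapply(seq_along(cfg$segments), function(i) take(cfg$n_markers_per_segment))
  names(markers) <- cfg$segments

  mu <- rlnorm(n, cfg$mu_meanlog, cfg$mu_sdlog)
  # per-gene log2 shift relative to reference, by group
  shift <- matrix(0, n, length(groups), dimnames = list(genes, groups))
  shift[suppressed, 2] <- cfg$delta
  shift[suppressed, 3] <- cfg$delta * (1 - cfg$rho)
  shift[enhanced, 2] <- -cfg$delta
  shift[enhanced, 3] <- -cfg$delta * (1 - cfg$rho)
  if (length(pathway)) {
    shift[pathway, 2] <- cfg$pathway_delta
    shift[pathway, 3] <- cfg$pathway_delta * (1 - cfg$pathway_rho)
  }
  class_vec <- rep("null", n)
  class_vec[suppressed] <- "suppressed"
  class_vec[enhanced] <- "enhanced"
  if (length(pathway)) class_vec[pathway] <- "suppressed"
  list(genes = genes, mu = mu, shift = shift, class = class_vec,
       suppressed = genes[suppressed], enhanced = genes[enhanced],
       pathway = genes[pathway],
       markers = lapply(markers, function(i) genes[i]),
       mito = genes[mito_idx])
}

.nb_draw <- function(mu, phi) {
  if (phi <= 0) return(stats::rpois(length(mu), mu))
  rnbinom(length(mu), size = 1 / phi, mu = mu)
}

#' Simulate a single-cell cohort with planted reversal structure
#'
#' @param cfg A [sim_config()].
#' @return A list with `counts` (a [count_matrix], genes x cells), `metadata`
#'   (tibble: unit_id, sample_id, group), and `truth` (a `ground_truth` list:
#'   per-(gene, segment) planted class, true segment per cell, the marker
#'   panel, the pathway gene set and its true per-group log2 activation).
#'   Deterministic given `cfg$seed`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    groups <- names(cfg$samples_per_group)
    gs <- .sim_genes(cfg, groups)
    samples <- tibble::tibble(
      sample_id = unlist(lapply(groups, function(g) {
        sprintf("%s.s%02d", g, seq_len(cfg$samples_per_group[[g]]))
      })),
      group = rep(groups, cfg$samples_per_group)
    )
    cells <- tidyr::expand_grid(samples,
                                segment = cfg$segments,
                                rep = seq_len(cfg$cells_per_sample_per_segment))
    cells$unit_id <- sprintf("%s.%s.c%03d", cells$sample_id, cells$segment, cells$rep)
    n_cells <- nrow(cells)
    lib <- rlnorm(n_cells, 0, cfg$libsize_sdlog)

    # segment factor matrix (genes x segments): markers enriched in their segment
    seg_fac <- matrix(1, cfg$n_genes, length(cfg$segments),
                      dimnames = list(gs$genes, cfg$segments))
    for (s in cfg$segments) seg_fac[gs$markers[[s]], s] <- cfg$marker_fold

    counts <- matrix(0L, cfg$n_genes, n_cells,
                     dimnames = list(gs$genes, cells$unit_id))
    group_mult <- 2^gs$shift  # genes x groups
    for (j in seq_len(n_cells)) {
      mu_j <- lib[j] * gs$mu * seg_fac[, cells$segment[j]] *
        group_mult[, cells$group[j]]
      counts[, j] <- .nb_draw(mu_j, cfg$dispersion)
    }
    cm <- count_matrix(counts, "cell")
    metadata <- tibble::tibble(unit_id = cells$unit_id,
                               sample_id = cells$sample_id,
                               group = factor(cells$group, levels = groups))
    truth <- .ground_truth(cfg, gs, cells)
    list(counts = cm, metadata = metadata, truth = truth)
  })
}

#' Simulate a bulk "mouse-cortex-like" dataset
#'
#' Gene-by-sample NB counts with the same planted effect structure and no
#' segment axis; defaults give 5 samples in each of three groups.
#'
#' @param cfg A [sim_config()].
#' @return As [simulate_cohort()], with `unit_kind = "sample"` counts and a
#'   truth table without a segment axis (`segment = NA`).
#' @export
simulate_bulk_cortex <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    groups <- names(cfg$bulk_samples_per_group)
    gs <- .sim_genes(cfg, groups)
    samples <- tibble::tibble(
      sample_id = unlist(lapply(groups, function(g) {
        sprintf("%s.s%02d", g, seq_len(cfg$bulk_samples_per_group[[g]]))
      })),
      group = rep(groups, cfg$bulk_samples_per_group)
    )
    n_samp <- nrow(samples)
    lib <- rlnorm(n_samp, 0, cfg$libsize_sdlog) * cfg$bulk_depth_factor
    counts <- matrix(0L, cfg$n_genes, n_samp,
                     dimnames = list(gs$genes, samples$sample_id))
    group_mult <- 2^gs$shift
    for (j in seq_len(n_samp)) {
      counts[, j] <- .nb_draw(lib[j] * gs$mu * group_mult[, samples$group[j]],
                              cfg$bulk_dispersion)
    }
    cm <- count_matrix(counts, "sample")
    metadata <- tibble::tibble(unit_id = samples$sample_id,
                               sample_id = samples$sample_id,
                               group = factor(samples$group, levels = groups))
    truth <- .ground_truth(cfg, gs, cells = NULL)
    list(counts = cm, metadata = metadata, truth = truth)
  })
}

.ground_truth <- function(cfg, gs, cells) {
  segs <- if (is.null(cells)) NA_character_ else cfg$segments
  gene_classes <- tidyr::expand_grid(gene = gs$genes, segment = segs)
  gene_classes$class <- rep(gs$class, each = length(segs))
  groups <- colnames(gs$shift)
  pathway_delta <- tibble::tibble(
    group = groups,
    delta_log2 = if (length(gs$pathway)) gs$shift[gs$pathway[1], ] else rep(0, length(groups))
  )
  structure(list(
    gene_classes = gene_classes,
    cell_segments = if (is.null(cells)) NULL else
      tibble::tibble(unit_id = cells$unit_id, segment = cells$segment),
    marker_panel = gs$markers,
    pathway_genes = gs$pathway,
    pathway_name = cfg$pathway_name,
    pathway_delta = pathway_delta,
    suppressed = gs$suppressed, enhanced = gs$enhanced, mito = gs$mito
  ), class = "ground_truth")
}
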