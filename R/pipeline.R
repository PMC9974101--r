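# End-to-end orchestration: (simulate ->) qc -> annotate -> pseudobulk ->
# differential expression -> reversal -> enrichment -> pathway score, with a
# machine-readable run summary. Identical config + seed gives an identical
# summary.

#' Build a gene-set collection around a simulated cohort's pathway set
#'
#' Combines the planted pathway set with seeded decoy sets drawn from the
#' simulated gene universe, so the enrichment stage has something realistic
#' to rank. Deterministic given `seed`.
#'
#' @param truth `ground_truth` from [simulate_cohort()].
#' @param genes The simulated gene universe.
#' @param n_decoys,decoy_size Number and size of decoy sets.
#' @param seed Integer seed.
#' @return A [gene_set_collection()].
#' @export
sim_collection <- function(truth, genes, n_decoys = 20, decoy_size = 39,
                           seed = 1L) {
  withr::with_seed(seed, {
    sets <- list()
    if (length(truth$pathway_genes)) sets[[truth$pathway_name]] <- truth$pathway_genes
    for (i in seq_len(n_decoys)) {
      sets[[sprintf("DECOY_%02d", i)]] <- sample(genes, decoy_size)
    }
    gene_set_collection(sets, source = "simulated")
  })
}

#' Run the full single-cell reversal pipeline
#'
#' @param config A [run_config()].
#' @param counts,metadata Cell-level [count_matrix] and metadata; when `NULL`
#'   a cohort is simulated from `sim`.
#' @param panel A [marker_panel()]; defaults to the simulation's planted
#'   panel when simulating.
#' @param collection Optional [gene_set_collection()] for enrichment and
#'   pathway scoring; defaults to [sim_collection()] when simulating.
#' @param sim A [sim_config()]; defaults to `sim_config(seed = config$seed)`.
#' @param do_enrichment,do_scoring Stage toggles; disable to stop after the
#'   reversal classification (e.g. calibration runs that only need reversal
#'   counts).
#' @return A list of class `run_summary`; see [write_run_summary()]. The
#'   element `results` holds the stage outputs (contrasts, reversal records,
#'   counts by segment, enrichment, delta scores, and the ground truth when
#'   simulated).
#' @export
run_pipeline <- function(config = run_config(), counts = NULL, metadata = NULL,
                         panel = NULL, collection = NULL, sim = NULL,
                         do_enrichment = TRUE, do_scoring = TRUE) {
  config <- validate_run_config(config)
  truth <- NULL
  if (is.null(counts)) {
    if (is.null(sim)) sim <- sim_config(seed = config$seed)
    simmed <- .stage("simulate", simulate_cohort(sim))
    counts <- simmed$counts
    metadata <- simmed$metadata
    truth <- simmed$truth
    if (is.null(panel)) panel <- marker_panel(truth$marker_panel)
    if (is.null(collection)) {
      collection <- sim_collection(truth, counts$genes, seed = config$seed)
    }
  }
  if (counts$unit_kind != "cell") {
    stop("run_pipeline expects cell-level counts; use run_mouse_mode for bulk",
         call. = FALSE)
  }
  if (is.null(panel)) stop("a marker panel is required to annotate segments",
                           call. = FALSE)
  metadata <- validate_metadata(metadata, levels(metadata$group) %||%
                                  unique(as.character(metadata$group)))
  n_cells_raw <- ncol(counts$counts)

  qc <- .stage("qc", qc_filter(counts,
                               qc_thresholds(config$min_genes, config$max_genes,
                                             config$max_mito_fraction),
                               mito_prefix = config$mito_prefix))
  expr_cells <- .stage("normalize", normalize_log_cpm(qc))
  metadata_qc <- metadata[metadata$unit_id %in% qc$units, , drop = FALSE]
  metadata_qc <- .stage("annotate", assign_segments(expr_cells, panel, metadata_qc))

  groups <- levels(metadata$group)
  specs <- list(
    contrast_spec(paste0(groups[2], "_vs_", groups[1]), groups[2], groups[1]),
    contrast_spec(paste0(groups[3], "_vs_", groups[2]), groups[3], groups[2])
  )
  if (config$de_mode == "pseudobulk") {
    pb <- .stage("pseudobulk", pseudobulk(qc, metadata_qc))
    # CP10K keeps an effective prior count of (library size / 1e4), which
    # stabilizes log-scale variances of low-count pseudobulk genes
    expr_de <- normalize_log_cpm(pb$counts)
    md_de <- pb$metadata
  } else {
    expr_de <- expr_cells
    md_de <- metadata_qc
  }
  results <- .stage("de", run_contrasts(expr_de, md_de, specs))
  r1 <- dplyr::filter(results, .data$contrast == specs[[1]]$name)
  r2 <- dplyr::filter(results, .data$contrast == specs[[2]]$name)
  records <- .stage("reversal", classify_reversal(r1, r2, alpha = config$alpha))
  seg_counts <- count_by_segment(records)

  enrichment <- NULL
  enrichment_sig <- NULL
  if (do_enrichment && !is.null(collection)) {
    enrichment <- .stage("enrichment",
                         enrich_by_direction(records, collection,
                                             min_overlap = config$min_overlap))
    enrichment_sig <- filter_significant(enrichment, config$alpha,
                                         config$min_overlap)
  }

  deltas <- NULL
  if (do_scoring && !is.null(collection)) {
    scores <- .stage("score",
                     score_table(expr_cells, metadata_qc, collection,
                                 alpha = config$ssgsea_alpha))
    deltas <- delta_pathway_score(scores, reference_group = groups[1])
  }

  summary <- .run_summary(
    config = config, mode = "single_cell",
    stage_counts = list(
      n_cells_raw = n_cells_raw,
      n_cells_qc = ncol(qc$counts),
      n_genes = nrow(qc$counts),
      n_de_units = ncol(expr_de),
      n_contrast_rows = nrow(results),
      n_reversal_records = nrow(records)
    ),
    seg_counts = seg_counts, enrichment_sig = enrichment_sig, deltas = deltas)
  summary$results <- list(contrasts = results, records = records,
                          counts_by_segment = seg_counts,
                          enrichment = enrichment, deltas = deltas,
                          metadata = metadata_qc, truth = truth)
  if (!is.null(config$out_dir)) .write_artifacts(summary, config$out_dir)
  summary
}

#' Run the bulk ("mouse cortex") reversal pipeline
#'
#' Skips QC and segment annotation; runs differential expression, reversal
#' classification and enrichment directly on sample-level counts. The
#' reversal classifier is the same code path as in the single-cell mode.
#'
#' @param config A [run_config()].
#' @param counts A sample-level [count_matrix] (3 groups; cell-level input is
#'   an error).
#' @param metadata Sample metadata (`unit_id`, `sample_id`, `group`).
#' @param collection Optional [gene_set_collection()] for enrichment.
#' @return A `run_summary` list as for [run_pipeline()].
#' @export
run_mouse_mode <- function(config = run_config(), counts, metadata,
                           collection = NULL) {
  config <- validate_run_config(config)
  if (counts$unit_kind != "sample") {
    stop("run_mouse_mode expects sample-level (bulk) counts", call. = FALSE)
  }
  metadata <- validate_metadata(metadata, levels(metadata$group) %||%
                                  unique(as.character(metadata$group)))
  groups <- levels(metadata$group)
  expr <- .stage("normalize", normalize_log_cpm(counts))
  specs <- list(
    contrast_spec(paste0(groups[2], "_vs_", groups[1]), groups[2], groups[1]),
    contrast_spec(paste0(groups[3], "_vs_", groups[2]), groups[3], groups[2])
  )
  results <- .stage("de", run_contrasts(expr, metadata, specs))
  r1 <- dplyr::filter(results, .data$contrast == specs[[1]]$name)
  r2 <- dplyr::filter(results, .data$contrast == specs[[2]]$name)
  records <- .stage("reversal", classify_reversal(r1, r2, alpha = config$alpha))
  seg_counts <- count_by_segment(records)
  enrichment <- NULL
  enrichment_sig <- NULL
  if (!is.null(collection)) {
    enrichment <- .stage("enrichment",
                         enrich_by_direction(records, collection,
                                             min_overlap = config$min_overlap))
    enrichment_sig <- filter_significant(enrichment, config$alpha,
                                         config$min_overlap)
  }
  summary <- .run_summary(
    config = config, mode = "bulk",
    stage_counts = list(
      n_samples = ncol(counts$counts),
      n_genes = nrow(counts$counts),
      n_contrast_rows = nrow(results),
      n_reversal_records = nrow(records)
    ),
    seg_counts = seg_counts, enrichment_sig = enrichment_sig, deltas = NULL)
  summary$results <- list(contrasts = results, records = records,
                          counts_by_segment = seg_counts,
                          enrichment = enrichment)
  if (!is.null(config$out_dir)) .write_artifacts(summary, config$out_dir)
  summary
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

.run_summary <- function(config, mode, stage_counts, seg_counts,
                         enrichment_sig, deltas) {
  structure(list(
    mode = mode,
    config = unclass(config),
    stage_counts = stage_counts,
    reversal_by_segment = as.data.frame(seg_counts),
    significant_pathways = if (is.null(enrichment_sig)) NULL else
      as.data.frame(enrichment_sig[, c("segment", "direction", "pathway",
                                       "overlap", "p_value")]),
    delta_scores = if (is.null(deltas)) NULL else
      as.data.frame(deltas[, c("set_name", "segment", "group", "delta")]),
    seed = config$seed,
    version = as.character(packageVersion("screverse"))
  ), class = "run_summary")
}

#' Serialize a run summary to JSON
#'
#' @param summary A `run_summary` (the `results` element is not serialized).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(summary, path) {
  x <- unclass(summary)
  x$results <- NULL
  x$config$out_dir <- NULL
  if (!is.null(x$delta_scores)) {
    x$delta_scores$group <- as.character(x$delta_scores$group)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

.write_artifacts <- function(summary, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- summary$results
  readr::write_csv(res$contrasts, file.path(out_dir, "contrasts.csv"),
                   progress = FALSE)
  readr::write_csv(res$records, file.path(out_dir, "reversal_records.csv"),
                   progress = FALSE)
  readr::write_csv(res$counts_by_segment,
                   file.path(out_dir, "reversal_counts_by_segment.csv"),
                   progress = FALSE)
  if (!is.null(res$enrichment) && nrow(res$enrichment)) {
    readr::write_csv(res$enrichment, file.path(out_dir, "enrichment.csv"),
                     progress = FALSE)
  }
  if (!is.null(res$deltas)) {
    readr::write_csv(res$deltas, file.path(out_dir, "delta_scores.csv"),
                     progress = FALSE)
  }
  write_run_summary(summary, file.path(out_dir, "summary.json"))
  invisible(out_dir)
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("<run_summary> mode = %s, seed = %s\n", x$mode, x$seed))
  for (nm in names(x$stage_counts)) {
    cat(sprintf("  %s: %s\n", nm, x$stage_counts[[nm]]))
  }
  if (nrow(x$reversal_by_segment)) {
    cat("reversal by segment:\n")
    print(x$reversal_by_segment)
  }
  invisible(x)
}
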