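# Readers and writers for the standard formats the pipeline touches:
# 10x triplet (MTX + features + barcodes), dense CSV counts, metadata CSV,
# GMT gene sets, YAML run configuration.

.find_member <- function(dir, stems) {
  for (stem in stems) {
    for (ext in c("", ".gz")) {
      p <- file.path(dir, paste0(stem, ext))
      if (file.exists(p)) return(p)
    }
  }
  NULL
}

#' Read a 10x-style triplet count directory
#'
#' Expects `matrix.mtx`, a features (or genes) file and `barcodes.tsv`,
#' each optionally gzipped. Gene symbols are taken from the second column of
#' the features file when present (10x convention: id, symbol, type),
#' otherwise the first.
#'
#' @param path Directory containing the triplet files.
#' @return A [count_matrix] with `unit_kind = "cell"`; gene order matches the
#'   features file.
#' @export
read_counts_10x <- function(path) {
  if (!dir.exists(path)) stop("no such directory: ", path, call. = FALSE)
  mtx <- .find_member(path, "matrix.mtx")
  feat <- .find_member(path, c("features.tsv", "genes.tsv"))
  bc <- .find_member(path, "barcodes.tsv")
  missing <- c(if (is.null(mtx)) "matrix.mtx",
               if (is.null(feat)) "features.tsv/genes.tsv",
               if (is.null(bc)) "barcodes.tsv")
  if (length(missing)) {
    stop("missing 10x member file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m <- Matrix::readMM(mtx)
  features <- readr::read_tsv(feat, col_names = FALSE, col_types = readr::cols(),
                              progress = FALSE)
  barcodes <- readr::read_tsv(bc, col_names = FALSE, col_types = readr::cols(),
                              progress = FALSE)
  if (nrow(features) != nrow(m) || nrow(barcodes) != ncol(m)) {
    stop(sprintf(
      "dimension mismatch: matrix is %d x %d but features file lists %d genes and barcodes file %d cells",
      nrow(m), ncol(m), nrow(features), nrow(barcodes)), call. = FALSE)
  }
  symbols <- if (ncol(features) >= 2) features[[2]] else features[[1]]
  dimnames(m) <- list(symbols, barcodes[[1]])
  count_matrix(m, "cell")
}

#' Write a count matrix as a 10x-style triplet directory
#'
#' @param x A [count_matrix].
#' @param path Output directory (created if absent).
#' @param gzip Write gzipped member files.
#' @return `path`, invisibly.
#' @export
write_counts_10x <- function(x, path, gzip = FALSE) {
  stopifnot(inherits(x, "count_matrix"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".gz" else ""
  mtx <- file.path(path, "matrix.mtx")
  Matrix::writeMM(x$counts, mtx)
  if (gzip) {
    con <- gzfile(paste0(mtx, ".gz"), "wb")
    writeLines(readLines(mtx), con)
    close(con)
    unlink(mtx)
  }
  feat <- tibble::tibble(id = x$genes, symbol = x$genes,
                         type = "Gene Expression")
  readr::write_tsv(feat, file.path(path, paste0("features.tsv", ext)),
                   col_names = FALSE, progress = FALSE)
  readr::write_tsv(tibble::tibble(barcode = x$units),
                   file.path(path, paste0("barcodes.tsv", ext)),
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read / write dense CSV counts
#'
#' The CSV has genes on rows (first column `gene`) and units on columns.
#'
#' @param path CSV file.
#' @param unit_kind `"cell"` or `"sample"`.
#' @return [count_matrix] for the reader; `path` invisibly for the writer.
#' @export
read_counts_csv <- function(path, unit_kind = c("cell", "sample")) {
  unit_kind <- match.arg(unit_kind)
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  if (names(df)[1] != "gene") {
    stop("first column of a counts CSV must be 'gene'", call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  count_matrix(m, unit_kind)
}

#' @rdname read_counts_csv
#' @param x A [count_matrix].
#' @export
write_counts_csv <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- as.data.frame(as.matrix(x$counts))
  df <- tibble::as_tibble(df, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(gene = x$genes), df)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Read unit metadata
#'
#' Requires columns `unit_id`, `sample_id` and `group`; an optional `segment`
#' column is kept if present. Group labels must come from `group_levels`.
#'
#' @param path CSV file.
#' @param group_levels Allowed group labels; defaults to the human cohort
#'   labels, use [group_levels_mouse()] for murine data.
#' @return A tibble with a `group` factor ordered as `group_levels`.
#' @export
read_metadata <- function(path, group_levels = group_levels_human()) {
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  validate_metadata(df, group_levels)
}

#' Validate a metadata table
#'
#' @param df Data frame with `unit_id`, `sample_id`, `group` (and optionally
#'   `segment`).
#' @inheritParams read_metadata
#' @return The validated tibble.
#' @export
validate_metadata <- function(df, group_levels = group_levels_human()) {
  required <- c("unit_id", "sample_id", "group")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("metadata missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$unit_id)) {
    stop("duplicate unit_id in metadata: ",
         paste(head(unique(df$unit_id[duplicated(df$unit_id)]), 5),
               collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(as.character(df$group)), group_levels)
  if (length(bad)) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(group_levels, collapse = ", "), ")",
         call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  df$group <- factor(as.character(df$group), levels = group_levels)
  df
}

#' @rdname read_metadata
#' @param df Metadata tibble.
#' @export
write_metadata <- function(df, path) {
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Tab-delimited, one set per line: name, description, members. Duplicate
#' members within a line are dropped with a warning; empty sets are rejected.
#'
#' @param path GMT file.
#' @return A `gene_set_collection`: named list of character vectors with a
#'   `source` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("GMT line %d has %d field(s); need name, description, >=1 member",
                   i, length(fields)), call. = FALSE)
    }
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members)) {
      stop(sprintf("GMT line %d (%s) has no members", i, fields[1]), call. = FALSE)
    }
    if (anyDuplicated(members)) {
      warning(sprintf("set '%s': dropped %d duplicated member(s)",
                      fields[1], sum(duplicated(members))), call. = FALSE)
      members <- unique(members)
    }
    sets[[fields[1]]] <- members
  }
  gene_set_collection(sets, source = path)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (unique members, non-empty).
#' @param source Free-text provenance.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, source = "in-memory") {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("all gene sets must be named", call. = FALSE)
  }
  if (any(lengths(sets) == 0)) stop("empty gene sets are not allowed", call. = FALSE)
  sets <- lapply(sets, function(m) unique(as.character(m)))
  structure(sets, source = source, class = "gene_set_collection")
}

#' @rdname read_gmt
#' @param collection A `gene_set_collection`.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, "na", collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d set(s), sizes %s\n", length(x),
              paste(range(lengths(x)), collapse = "-")))
  invisible(x)
}

#' Run configuration
#'
#' Bundles the tunable knobs of a pipeline run with validation. Defaults
#' follow the analysis this package implements: QC keeps cells with 500-5000
#' detected genes and under 50% mitochondrial counts, differential expression
#' runs on pseudobulk, significance is FDR < 0.05, enrichment requires at
#' least 5 overlapping transcripts, and ssGSEA uses rank exponent 0.25.
#'
#' @param min_genes,max_genes,max_mito_fraction Cell QC thresholds.
#' @param de_mode `"pseudobulk"` (default) or `"cell"`.
#' @param alpha Significance level for FDR gates (in (0,1)).
#' @param min_overlap Minimum overlapping transcripts for enrichment.
#' @param ssgsea_alpha Rank-weight exponent (>= 0).
#' @param mito_prefix Gene-name prefix marking mitochondrial genes.
#' @param seed Non-negative integer seed driving all stochastic stages.
#' @param out_dir Output directory for pipeline artifacts (`NULL` = none).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(min_genes = 500, max_genes = 5000,
                       max_mito_fraction = 0.5,
                       de_mode = c("pseudobulk", "cell"),
                       alpha = 0.05, min_overlap = 5,
                       ssgsea_alpha = 0.25, mito_prefix = "MT-",
                       seed = 1L, out_dir = NULL) {
  cfg <- list(min_genes = min_genes, max_genes = max_genes,
              max_mito_fraction = max_mito_fraction,
              de_mode = match.arg(de_mode), alpha = alpha,
              min_overlap = min_overlap, ssgsea_alpha = ssgsea_alpha,
              mito_prefix = mito_prefix, seed = seed, out_dir = out_dir)
  validate_run_config(cfg)
}

#' @rdname run_config
#' @param cfg A run-config list.
#' @export
validate_run_config <- function(cfg) {
  if (!(cfg$alpha > 0 && cfg$alpha < 1)) {
    stop("alpha must be in (0,1), got ", cfg$alpha, call. = FALSE)
  }
  if (cfg$ssgsea_alpha < 0) stop("ssgsea_alpha must be >= 0", call. = FALSE)
  if (!(cfg$min_genes > 0 && cfg$min_genes <= cfg$max_genes)) {
    stop("need 0 < min_genes <= max_genes", call. = FALSE)
  }
  if (!(cfg$max_mito_fraction > 0 && cfg$max_mito_fraction <= 1)) {
    stop("max_mito_fraction must be in (0,1]", call. = FALSE)
  }
  if (cfg$seed < 0 || cfg$seed != round(cfg$seed)) {
    stop("seed must be a non-negative integer", call. = FALSE)
  }
  if (cfg$min_overlap < 0) stop("min_overlap must be >= 0", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file holding the configuration fields.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- unclass(run_config())
  for (nm in names(out)) {
    if (!is.null(cfg[[nm]])) out[[nm]] <- cfg[[nm]]
  }
  validate_run_config(out)
}

#' @rdname run_config
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
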