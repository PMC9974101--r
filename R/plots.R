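# ggplot2 views of the result tables. Each plot_* function takes the tibble
# a pipeline stage returns; autoplot() methods delegate to them.

#' Bar plot of reversed / suppressed / enhanced transcript counts per segment
#'
#' @param records A `reversal_table` (or the output of [count_by_segment()]).
#' @return A ggplot object.
#' @export
plot_reversal_counts <- function(records) {
  counts <- if (inherits(records, "reversal_table")) {
    count_by_segment(records)
  } else {
    records
  }
  long <- tidyr::pivot_longer(counts, c("reversed", "suppressed", "enhanced"),
                              names_to = "class", values_to = "n")
  long$class <- factor(long$class, levels = c("reversed", "suppressed", "enhanced"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$segment, y = .data$n,
                                     fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "tubular segment", y = "transcripts",
                  title = "Transcripts reversed by treatment") +
    ggplot2::theme_minimal()
}

#' @method autoplot reversal_table
#' @export
autoplot.reversal_table <- function(object, ...) plot_reversal_counts(object)

#' Dot plot of group-delta pathway scores per segment
#'
#' Mirrors the delta-score figure: one point per (segment, group) with the
#' group mean minus the reference mean, error bars from the dispersion of
#' sample means.
#'
#' @param deltas A `delta_score_table` from [delta_pathway_score()].
#' @param set_name Optional set to plot (default: all facetted).
#' @return A ggplot object.
#' @export
plot_delta_scores <- function(deltas, set_name = NULL) {
  df <- deltas
  if (!is.null(set_name)) df <- dplyr::filter(df, .data$set_name %in% !!set_name)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$segment, y = .data$delta,
                                   colour = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5), size = 2) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$delta - .data$sd_sample_means,
                   ymax = .data$delta + .data$sd_sample_means),
      position = ggplot2::position_dodge(width = 0.5), width = 0.2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$set_name)) +
    ggplot2::labs(x = "tubular segment", y = expression(Delta ~ "pathway score")) +
    ggplot2::theme_minimal()
}

#' @method autoplot delta_score_table
#' @export
autoplot.delta_score_table <- function(object, ...) plot_delta_scores(object, ...)

#' Dot plot of enrichment results
#'
#' @param results An `enrichment_result` tibble.
#' @param top Keep the `top` pathways by p value per (segment, direction).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(results, top = 10) {
  df <- results
  grouping <- intersect(c("segment", "direction"), names(df))
  if (length(grouping)) {
    df <- df |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
      dplyr::slice_min(.data$p_value, n = top, with_ties = FALSE) |>
      dplyr::ungroup()
  } else {
    df <- dplyr::slice_min(df, .data$p_value, n = top, with_ties = FALSE)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_value),
                                        y = stats::reorder(.data$pathway,
                                                           -.data$p_value),
                                        size = .data$overlap)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = expression(-log[10] ~ p), y = NULL, size = "overlap") +
    ggplot2::theme_minimal()
  if (all(c("segment", "direction") %in% names(df))) {
    p <- p + ggplot2::facet_grid(ggplot2::vars(.data$direction),
                                 ggplot2::vars(.data$segment))
  }
  p
}

#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, ...) plot_enrichment(object, ...)

#' Bar plot of exclusive segment intersections
#'
#' @param summary An `intersection_summary` from [shared_sets()].
#' @return A ggplot object.
#' @export
plot_intersections <- function(summary) {
  df <- summary$intersections
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$combo, -.data$n),
                                   y = .data$n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "segment combination", y = "transcripts",
                  title = sprintf("Exclusive intersections (%s)", summary$class)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @method autoplot intersection_summary
#' @export
autoplot.intersection_summary <- function(object, ...) plot_intersections(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
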