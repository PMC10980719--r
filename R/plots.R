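#' Plot an evaluation trace
#'
#' Precision, sensitivity and false positive rate against the confidence
#' threshold (one panel per stratum when present).
#'
#' @param object A `lineage_eval` tibble from [evaluate_lineages()] or
#'   [stratified_evaluate()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.lineage_eval <- function(object, ...) {
  long <- as_tibble(object) |>
    tidyr::pivot_longer(c("precision", "sensitivity", "fpr"),
                        names_to = "metric", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$value,
                                          colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "confidence threshold", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
  if ("stratum" %in% names(long)) p <- p + ggplot2::facet_wrap(~stratum)
  p
}

#' Plot a confidence matrix as a heatmap
#'
#' @param object A `confidence_matrix`.
#' @param order_by Optional `lineage_partition` used to order cells so that
#'   lineages form blocks.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.confidence_matrix <- function(object, order_by = NULL, ...) {
  ids <- object$cell_ids
  if (!is.null(order_by)) {
    ann <- as_tibble(order_by)
    ids <- c(ann$cell_id[order(ann$lineage_id)], setdiff(ids, ann$cell_id))
  }
  long <- as_tibble(as.data.frame.table(object$counts,
                                        responseName = "confidence"))
  names(long)[1:2] <- c("cell_a", "cell_b")
  long$cell_a <- factor(long$cell_a, levels = ids)
  long$cell_b <- factor(long$cell_b, levels = ids)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cell_a, y = .data$cell_b,
                                     fill = .data$confidence)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, object$n_repetitions)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "confidence") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' CV-squared versus mean plot of the gene selection
#'
#' The classic mean-variability diagnostic: each gene at its mean expression
#' and CV^2 (log-log), colored by whether it passed the selection rule.
#'
#' @param stats Output of [gene_stats()].
#' @param selected Character vector of selected gene ids (e.g. from
#'   [select_genes()]).
#' @return A ggplot.
#' @export
plot_gene_selection <- function(stats, selected) {
  df <- stats |>
    filter(.data$expressed, .data$cv2 > 0) |>
    mutate(selected = .data$gene_id %in% selected)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_expr, y = .data$cv2,
                                   colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "mean normalized expression", y = expression(CV^2)) +
    ggplot2::theme_minimal()
}

#' Plot within-lineage vs. random-group distance distributions
#'
#' @param object A `similarity_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.similarity_report <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$set, y = .data$distance,
                               fill = .data$set)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "correlation distance") +
    ggplot2::theme_minimal()
}
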