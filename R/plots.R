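#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_point geom_step
#'   geom_col scale_fill_gradient scale_fill_gradientn scale_size_area labs
#'   theme_minimal theme element_text facet_wrap coord_flip
#' @export
ggplot2::autoplot

#' Plot a consensus matrix
#'
#' Heatmap of pairwise co-clustering fractions with samples ordered by final
#' cluster label.
#'
#' @param object An `immune_consensus`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.immune_consensus <- function(object, ...) {
  ord <- names(sort(object$labels))
  df <- as_tibble(object$consensus, rownames = "sample_a") |>
    tidyr::pivot_longer(-"sample_a", names_to = "sample_b",
                        values_to = "consensus") |>
    mutate(sample_a = factor(.data$sample_a, levels = ord),
           sample_b = factor(.data$sample_b, levels = ord))
  ggplot(df, aes(.data$sample_a, .data$sample_b, fill = .data$consensus)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "#08306b", limits = c(0, 1)) +
    labs(x = NULL, y = NULL, fill = "consensus",
         title = sprintf("Consensus matrix (k = %d)", object$k)) +
    theme_minimal() +
    theme(axis.text = ggplot2::element_blank())
}

#' Plot per-cell-type scores as a heatmap
#'
#' Samples ordered by cluster label when labels are supplied.
#'
#' @param object An `immune_scores` tibble.
#' @param labels Optional cluster labels for sample ordering.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.immune_scores <- function(object, labels = NULL, ...) {
  df <- tidy(object)
  if (!is.null(labels)) {
    labels <- normalize_labels(labels, unique(df$sample_id))
    ord <- unique(df$sample_id)[order(labels)]
    df$sample_id <- factor(df$sample_id, levels = ord)
  }
  modality <- attr(object, "modality")
  ggplot(df, aes(.data$sample_id, .data$cell_type, fill = .data$score)) +
    geom_tile() +
    scale_fill_gradientn(colours = c("#2166ac", "#f7f7f7", "#b2182b")) +
    labs(x = "sample", y = NULL, fill = modality,
         title = sprintf("Per-cell-type %s scores", modality)) +
    theme_minimal() +
    theme(axis.text.x = ggplot2::element_blank())
}

#' Balloon plot of cluster contrasts
#'
#' Absolute score differences per cell type between cluster pairs; balloon
#' size encodes significance (-log10 Dunn FDR), color the absolute delta.
#'
#' @param object A `delta_beta_table` from [delta_beta_contrasts()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.delta_beta_table <- function(object, ...) {
  df <- mutate(as_tibble(object),
               neglog_fdr = -log10(pmax(.data$dunn_fdr, 1e-16)))
  ggplot(df, aes(.data$comparison, .data$cell_type,
                 size = .data$neglog_fdr, colour = .data$abs_delta_beta)) +
    geom_point() +
    scale_size_area(max_size = 8) +
    ggplot2::scale_colour_gradient(low = "#fee8c8", high = "#b30000") +
    labs(x = NULL, y = NULL, size = expression(-log[10] ~ FDR),
         colour = expression("|" * Delta * beta * "|"),
         title = "Cluster contrasts per immune cell type") +
    theme_minimal()
}

#' Kaplan-Meier curves
#'
#' Step curves per group, clipped to the display horizon (the log-rank test
#' is computed on the full follow-up).
#'
#' @param object A `km_result` from [km_logrank()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.km_result <- function(object, ...) {
  df <- tidy(object) |>
    filter(.data$time <= object$horizon)
  p <- ggplot(df, aes(.data$time, .data$estimate, colour = .data$group)) +
    geom_step() +
    ggplot2::ylim(0, 1) +
    labs(x = "time (years)", y = "survival probability",
         title = if (!is.na(object$logrank_p)) {
           sprintf("Kaplan-Meier (log-rank p = %.3g)", object$logrank_p)
         } else "Kaplan-Meier") +
    theme_minimal()
  p
}

#' Funnel plot of the CpG selection steps
#'
#' @param object An `immune_selection` from [run_selection()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.immune_selection <- function(object, ...) {
  df <- mutate(object$funnel, step = factor(.data$step, levels = rev(.data$step)))
  ggplot(df, aes(.data$step, .data$n)) +
    geom_col(fill = "#4292c6") +
    coord_flip() +
    labs(x = NULL, y = "count", title = "Selection funnel") +
    theme_minimal()
}
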