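#' Heatmap of cluster centroid marker profiles
#'
#' Mean normalized marker intensity per cluster, the standard display for
#' interpreting co-expression clusters.
#'
#' @param object A `phenograph_clust` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phenograph_clust <- function(object, ...) {
  long <- object$centroids |>
    tidyr::pivot_longer(
      -dplyr::all_of(c("cluster", "n", "pct")),
      names_to = "feature", values_to = "mean_value"
    )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$feature, y = factor(.data$cluster),
    fill = .data$mean_value
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "mean") +
    ggplot2::labs(
      x = NULL, y = "cluster",
      title = sprintf(
        "%d clusters (K = %d, Q = %.3f)",
        object$n_clusters, object$k, object$modularity
      )
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Alpha/beta diversity decomposition plot
#'
#' Per-community within-diversity (alpha_k) bars with the weighted-mean
#' alpha and pooled total marked; the gap between the two lines is beta.
#'
#' @param object A `rao_decomposition` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rao_decomposition <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$community, y = .data$alpha)) +
    ggplot2::geom_col(fill = "grey55") +
    ggplot2::geom_hline(
      yintercept = object$alpha, linetype = 2, colour = "steelblue"
    ) +
    ggplot2::geom_hline(
      yintercept = object$total, linetype = 1, colour = "firebrick"
    ) +
    ggplot2::labs(
      y = "Simpson diversity",
      title = sprintf(
        "alpha = %.3f, total = %.3f, beta = %.3f",
        object$alpha, object$total, object$beta
      )
    ) +
    ggplot2::theme_minimal()
}

#' Stacked per-core immune phenotype composition
#'
#' Fraction of patches per phenotype in each core, optionally faceted by
#' molecular subtype when metadata is supplied.
#'
#' @param fractions Output of [phenotype_fractions()].
#' @param metadata Optional per-core metadata with `core_id`, `subtype`.
#' @return A ggplot object.
#' @export
plot_phenotype_fractions <- function(fractions, metadata = NULL) {
  d <- fractions
  if (!is.null(metadata)) {
    d <- left_join(d, select(metadata, "core_id", "subtype"), by = "core_id")
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(
    x = .data$core_id, y = .data$fraction, fill = .data$phenotype
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of patches") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
  if (!is.null(metadata)) {
    p <- p + ggplot2::facet_grid(. ~ subtype, scales = "free_x", space = "free_x")
  }
  p
}

#' Per-case histoscore spread across cores
#'
#' Displays each core's H-score per case, the core-level view of
#' intra-tumoral biomarker heterogeneity.
#'
#' @param scores Output of [histoscore()] (possibly several markers bound
#'   together).
#' @param metadata Optional per-core metadata with `core_id` and `case_id`;
#'   required when `scores` lacks a `case_id` column.
#' @return A ggplot object.
#' @export
plot_histoscores <- function(scores, metadata = NULL) {
  d <- scores
  if (!"case_id" %in% names(d)) {
    if (is.null(metadata)) {
      abort("Supply metadata with case_id to group cores by case",
        class = "mxifhet_validation_error"
      )
    }
    d <- left_join(d, distinct(metadata, .data$core_id, .data$case_id),
      by = "core_id"
    )
  }
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$case_id, y = .data$H, colour = .data$marker
  )) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::ylim(0, 300) +
    ggplot2::labs(x = "case", y = "H-score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
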