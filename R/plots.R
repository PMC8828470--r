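#' Plot methods for spomics results
#'
#' `autoplot()` methods returning ggplot objects: enrichment and interaction
#' heatmaps, Ripley curves, co-occurrence ratio curves, centrality
#' lollipops, autocorrelation and Sepal rankings.
#'
#' @param object A spomics result tibble.
#' @param ... Unused.
#' @return A `ggplot`.
#' @name spomics-plots
NULL

#' @rdname spomics-plots
#' @exportS3Method ggplot2::autoplot
autoplot.nhood_enrichment <- function(object, ...) {
  lev <- spomics_meta(object)$clusters
  df <- dplyr::bind_rows(
    object,
    dplyr::rename(dplyr::filter(object, .data$cluster_1 != .data$cluster_2),
                  cluster_1 = "cluster_2", cluster_2 = "cluster_1"))
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$cluster_1, lev),
                                   factor(.data$cluster_2, lev),
                                   fill = .data$zscore)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z",
                  title = "Neighbourhood enrichment") +
    ggplot2::theme_minimal()
}

#' @rdname spomics-plots
#' @exportS3Method ggplot2::autoplot
autoplot.interaction_matrix <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$cluster_1, .data$cluster_2,
                                       fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, title = "Interaction matrix") +
    ggplot2::theme_minimal()
}

#' @rdname spomics-plots
#' @exportS3Method ggplot2::autoplot
autoplot.ripley_result <- function(object, ...) {
  mode <- spomics_meta(object)$mode
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$t, .data$value,
                                            colour = .data$cluster)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "t", y = paste0(mode, "(t)"),
                  title = paste0("Ripley ", mode)) +
    ggplot2::theme_minimal()
  if (mode == "L") {
    p <- p + ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                                  colour = "grey50")
  }
  p
}

#' @rdname spomics-plots
#' @exportS3Method ggplot2::autoplot
autoplot.co_occurrence <- function(object, ...) {
  cond <- spomics_meta(object)$conditioning
  ggplot2::ggplot(object, ggplot2::aes((.data$interval_low + .data$interval_high) / 2,
                                       .data$ratio, colour = .data$cluster)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "distance", y = "co-occurrence ratio",
                  title = paste0("Co-occurrence given '", cond, "'")) +
    ggplot2::theme_minimal()
}

#' @rdname spomics-plots
#' @exportS3Method ggplot2::autoplot
autoplot.centrality_scores <- function(object, ...) {
  long <- tidyr::pivot_longer(tidy(object),
                              c("degree_centrality", "closeness_centrality",
                                "average_clustering"),
                              names_to = "score", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$value, .data$cluster)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$value,
                                       yend = .data$cluster), colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~score, scales = "free_x") +
    ggplot2::labs(x = NULL, y = NULL, title = "Group centralities") +
    ggplot2::theme_minimal()
}

#' @rdname spomics-plots
#' @exportS3Method ggplot2::autoplot
autoplot.autocorr_result <- function(object, ...) {
  mode <- spomics_meta(object)$mode
  df <- dplyr::arrange(dplyr::filter(object, !.data$degenerate),
                       dplyr::desc(.data$statistic))
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$statistic)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$pvalue_adj < 0.05)) +
    ggplot2::geom_hline(yintercept = unique(df$expected_null), linetype = 2) +
    ggplot2::labs(x = "gene rank", y = if (mode == "moran") "Moran's I" else "Geary's C",
                  colour = "FDR < 0.05") +
    ggplot2::theme_minimal()
}

#' @rdname spomics-plots
#' @exportS3Method ggplot2::autoplot
autoplot.sepal_result <- function(object, ...) {
  df <- dplyr::arrange(object, dplyr::desc(.data$sepal_score))
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$sepal_score)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "gene rank", y = "sepal score (diffusion time)") +
    ggplot2::theme_minimal()
}

#' Plot spot coordinates coloured by a label or gene
#'
#' @param dataset A [spatial_dataset].
#' @param colour Name of a label column or gene.
#' @return A `ggplot`.
#' @export
plot_spatial <- function(dataset, colour = NULL) {
  df <- dataset$obs
  if (!is.null(colour) && !colour %in% names(df) &&
      colour %in% dataset$var_ids) {
    df[[colour]] <- as.numeric(dataset$X[, colour])
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y))
  p <- if (is.null(colour)) p + ggplot2::geom_point() else
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]))
  p + ggplot2::coord_equal() + ggplot2::scale_y_reverse() +
    ggplot2::theme_minimal()
}
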