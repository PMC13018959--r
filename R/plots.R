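#' Stacked-bar plot of reliable feature counts by family
#'
#' @param rel Output of [feature_reliability()], or a named list of such
#'   tibbles (one per mask kind) for side-by-side bars.
#' @return A ggplot object.
#' @export
plot_reliability <- function(rel) {
  if (is.data.frame(rel)) rel <- list(mask = rel)
  df <- purrr::imap_dfr(rel, function(tb, mk) {
    dplyr::mutate(reliable_by_family(tb), mask = mk)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mask, y = .data$n_reliable,
                                   fill = .data$family)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "reliable features (ICC ≥ 0.75)",
                  fill = "family") +
    ggplot2::theme_minimal()
}

#' Cluster-count sweep plot
#'
#' @param sweep Output of [cluster_count_sweep()], optionally row-bound
#'   over masks with an extra `mask` column.
#' @return A ggplot object.
#' @export
plot_cluster_sweep <- function(sweep) {
  p <- ggplot2::ggplot(sweep, ggplot2::aes(x = .data$threshold,
                                           y = .data$n_clusters))
  if ("mask" %in% names(sweep)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(color = .data$mask))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p + ggplot2::labs(x = "clustering threshold (correlation distance)",
                    y = "feature clusters") +
    ggplot2::theme_minimal()
}

#' Box plots of an experiment's validation metrics
#'
#' @param object A `fuzzrad_experiment`.
#' @param metric One of `"c_index"`, `"mean_auc"`, `"output_icc"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fuzzrad_experiment
#' @export
autoplot.fuzzrad_experiment <- function(object, metric = c("c_index", "mean_auc",
                                                           "output_icc"), ...) {
  metric <- match.arg(metric)
  df <- dplyr::filter(object$runs, .data$ok)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mask, y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
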