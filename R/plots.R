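#' Plot the edge-weight distributions of a weighted network
#'
#' Overlaid histograms of the GO weight and the fused TAP-aware weight,
#' showing how the TAP coefficient spreads the GO similarity.
#'
#' @param object A `weighted_ppi` network.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.weighted_ppi <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("w_go", "w")],
    cols = dplyr::everything(), names_to = "kind", values_to = "weight")
  df$kind <- factor(df$kind, c("w_go", "w"), c("GO weight", "fused weight"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$weight, fill = .data$kind)) +
    ggplot2::geom_histogram(bins = 30, alpha = 0.6, position = "identity") +
    ggplot2::labs(x = "edge weight", y = "edges", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a bicluster set
#'
#' Bicluster area (proteins x time points) against fitness; the dashed line
#' marks perfect density.
#'
#' @param object A bicluster tibble from [run_memetic()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bicluster_set <- function(object, ...) {
  df <- tibble::tibble(area = object$n_proteins * object$n_timepoints,
                       fitness = object$fitness)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$area, y = .data$fitness)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "bicluster area (proteins x time points)",
                  y = "fitness (active fraction)") +
    ggplot2::theme_minimal()
}

#' Plot an evaluation result
#'
#' Bar chart of precision, recall and F-1.
#'
#' @param object A `complex_eval` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.complex_eval <- function(object, ...) {
  df <- tibble::tibble(
    metric = factor(c("precision", "recall", "F-1"),
                    c("precision", "recall", "F-1")),
    value = c(object$precision, object$recall, object$f1))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$value)),
                       vjust = -0.4) +
    ggplot2::ylim(0, 1.05) +
    ggplot2::labs(x = NULL, y = "score",
                  title = sprintf("complex detection vs benchmark (th = %.2f)",
                                  object$th)) +
    ggplot2::theme_minimal()
}
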