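#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @importFrom rlang .data
NULL

#' Plot a parameter scan (accuracy vs. selection size)
#'
#' Scatter of each `(theta, lambda)` iteration: average selected genes per
#' patient against clustering accuracy, colored by theta; the optimum is
#' circled.
#'
#' @param object A `parameter_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot parameter_scan
#' @export
autoplot.parameter_scan <- function(object, ...) {
  df <- dplyr::filter(object$results, !is.na(.data$accuracy))
  best <- dplyr::filter(df, .data$theta == object$best$theta,
                        .data$lambda == object$best$lambda)
  ggplot2::ggplot(df, ggplot2::aes(.data$avg_genes, .data$accuracy)) +
    ggplot2::geom_point(ggplot2::aes(color = factor(.data$theta),
                                     size = .data$lambda), alpha = 0.8) +
    ggplot2::geom_point(data = best, shape = 1, size = 6, stroke = 1.2) +
    ggplot2::labs(
      x = "average selected genes per patient", y = "accuracy (%)",
      color = expression(theta), size = expression(lambda)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the shuffle null distribution
#'
#' Histogram of the shuffled-cohort accuracies with the null mean marked;
#' pass `observed` to overlay the accuracy of the unshuffled data.
#'
#' @param object A `shuffle_null`.
#' @param observed Optional observed (unshuffled) accuracy to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot shuffle_null
#' @export
autoplot.shuffle_null <- function(object, observed = NULL, ...) {
  df <- tidy.shuffle_null(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$accuracy)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", color = "grey30") +
    ggplot2::geom_vline(xintercept = object$mean, linetype = 2) +
    ggplot2::labs(x = "shuffled accuracy (%)", y = "replicates") +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_vline(xintercept = observed, color = "red")
  }
  p
}

#' Plot community counts along the resolution sweep
#'
#' @param object A `resolution_profile`.
#' @param ... Unused.
#' @return A ggplot of community count against resolution.
#' @method autoplot resolution_profile
#' @export
autoplot.resolution_profile <- function(object, ...) {
  df <- tibble::tibble(
    gamma = object$grid,
    communities = vapply(object$partitions,
                         function(p) length(unique(p$membership)), 1L)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$gamma, .data$communities)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = expression(gamma), y = "communities") +
    ggplot2::theme_minimal()
}
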