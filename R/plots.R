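#' Plot component stability summaries
#'
#' Bar chart of the fraction of member words whose modal bootstrap
#' co-cluster component equals the original one.
#'
#' @param object A `snowsem_stability`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot snowsem_stability
#' @export
autoplot.snowsem_stability <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = factor(.data$component), y = .data$stability)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "Component", y = "Modal co-cluster stability",
                  title = sprintf("Bootstrap cluster stability (B = %d)", object$B)) +
    ggplot2::theme_minimal()
}

#' Plot a component profile: sentiment against similarity to the focal cue
#'
#' Scatter of component mean sentiment versus mean similarity to the focal
#' concept, with bootstrap 95% CI bars, point size giving retrieval
#' proportion.
#'
#' @param object A `snowsem_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot snowsem_profile
#' @export
autoplot.snowsem_profile <- function(object, ...) {
  d <- object$components
  ggplot2::ggplot(d, ggplot2::aes(x = .data$risk_similarity, y = .data$sentiment,
                                  label = factor(.data$component))) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$sentiment_lwr,
                                        ymax = .data$sentiment_upr), width = 0) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$risk_lwr,
                                         xmax = .data$risk_upr), height = 0) +
    ggplot2::geom_point(ggplot2::aes(size = .data$retrieval), shape = 21,
                        fill = "steelblue") +
    ggplot2::geom_text(nudge_y = 0.05, size = 3) +
    ggplot2::labs(x = "Similarity to focal concept", y = "Mean sentiment",
                  size = "Retrieval\nproportion") +
    ggplot2::theme_minimal()
}

#' Plot cross-validated prediction performance
#'
#' Mean held-out R^2 per item and model variant with corrected resampled
#' standard-error bars.
#'
#' @param object A `snowsem_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot snowsem_cv
#' @export
autoplot.snowsem_cv <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$item, y = .data$mean_r2,
                                  fill = .data$variant)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_r2 - .data$se,
                                        ymax = .data$mean_r2 + .data$se),
                           position = ggplot2::position_dodge(width = 0.8),
                           width = 0.25) +
    ggplot2::labs(x = NULL, y = expression(CV~R^2), fill = "Model") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot retrieval proportions across a stratum
#'
#' Line chart of component retrieval proportions across level-1 position,
#' age bins, or genders.
#'
#' @param proportions Tibble from [retrieval_proportions()] /
#'   [component_by_group()] (must contain a stratum column).
#' @return A ggplot object.
#' @export
plot_retrieval_proportions <- function(proportions) {
  stratum <- setdiff(names(proportions), c("component", "n", "proportion"))
  if (length(stratum) != 1L) {
    stop_snowsem("Expected exactly one stratum column; found: %s.",
                 paste(stratum, collapse = ", "))
  }
  ggplot2::ggplot(proportions,
                  ggplot2::aes(x = .data[[stratum]], y = .data$proportion,
                               colour = factor(.data$component),
                               group = factor(.data$component))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = stratum, y = "Retrieval proportion", colour = "Component") +
    ggplot2::theme_minimal()
}
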