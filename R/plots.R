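# ggplot2 figures for the main result types.

#' Bar plot of conservation-class fractions
#'
#' @param classification A [classify_conservation()] result.
#' @return A ggplot object.
#' @export
plot_conservation_classes <- function(classification) {
  fr <- conservation_fractions(classification)
  ggplot2::ggplot(fr, ggplot2::aes(x = .data$class, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "fraction of binding events",
                  title = paste0("Conservation classes (anchor: ",
                                 attr(classification, "anchor"), ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Shared fraction against divergence time
#'
#' @param data Tibble with `species`, `fraction`, `divergence_my`.
#' @return A ggplot object.
#' @export
plot_divergence_trend <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$divergence_my,
                                     y = .data$fraction)) +
    ggplot2::geom_point(size = 3, colour = "steelblue") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40", linetype = "dashed") +
    ggplot2::labs(x = "divergence time (My)",
                  y = "pairwise shared fraction") +
    ggplot2::theme_minimal()
}

#' Repeat-family enrichment dot plot
#'
#' @param results A [repeat_enrichment_test()] result (possibly several
#'   species bound together).
#' @param alpha Significance level drawn as a guide (default 0.01).
#' @return A ggplot object.
#' @export
plot_repeat_enrichment <- function(results, alpha = 0.01) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = stats::reorder(.data$rep_name,
                                                  -.data$neg_log_p),
                               y = .data$neg_log_p,
                               colour = .data$significant)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = NULL, y = expression(-log[10] ~ p),
                  colour = paste0("adj. p <= ", alpha)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Summit-centred profile line plot
#'
#' @param profile A [summit_repeat_profile()] result.
#' @return A ggplot object.
#' @export
plot_summit_profile <- function(profile) {
  df <- tidy(profile)
  ylab <- if (profile$mode == "repeat_coverage") {
    "mean repeat coverage"
  } else {
    "mean read count"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset_bp, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "distance from summit (bp)", y = ylab) +
    ggplot2::theme_minimal()
}

#' Expression box plot by co-binding class
#'
#' @param comparison An [expression_comparison()] result.
#' @return A ggplot object.
#' @export
plot_expression_classes <- function(comparison) {
  ggplot2::ggplot(comparison$data,
                  ggplot2::aes(x = .data$class, y = .data$log2_estimate)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.6) +
    ggplot2::labs(x = NULL, y = expression(log[2] ~ "transcript estimate")) +
    ggplot2::theme_minimal()
}

#' @rdname plot_conservation_classes
#' @param object,... Passed through to the type-specific plotting
#'   function.
#' @method autoplot conservation_classification
#' @export
autoplot.conservation_classification <- function(object, ...) {
  plot_conservation_classes(object)
}

#' @rdname plot_summit_profile
#' @param object,... Passed through.
#' @method autoplot summit_profile
#' @export
autoplot.summit_profile <- function(object, ...) {
  plot_summit_profile(object)
}
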