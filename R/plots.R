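#' Plot benchmark results
#'
#' The default panel shows each method's mean true positives against mean
#' false positives (strict and relaxed accounting side by side); `metric =
#' "f2"` instead shows the mean F2 score per method.
#'
#' @param object A `benchmark_result`.
#' @param metric `"tradeoff"` or `"f2"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot benchmark_result
#' @export
autoplot.benchmark_result <- function(object, metric = c("tradeoff", "f2"),
                                      ...) {
  metric <- match.arg(metric)
  sm <- object$summary
  long <- tidyr::pivot_longer(
    sm, cols = c("tp_strict", "fp_strict", "f2_strict",
                 "tp_relaxed", "fp_relaxed", "f2_relaxed"),
    names_to = c("stat", "definition"), names_sep = "_")
  wide <- tidyr::pivot_wider(long, names_from = "stat",
                             values_from = "value")
  if (metric == "tradeoff") {
    ggplot2::ggplot(wide, ggplot2::aes(x = .data$fp, y = .data$tp,
                                       label = .data$method_id)) +
      ggplot2::geom_point() +
      ggplot2::geom_text(vjust = -0.6, size = 2.8) +
      ggplot2::facet_wrap(~definition, scales = "free_x") +
      ggplot2::labs(x = "mean false positives", y = "mean true positives")
  } else {
    ggplot2::ggplot(wide, ggplot2::aes(x = stats::reorder(.data$method_id,
                                                          .data$f2),
                                       y = .data$f2,
                                       fill = .data$definition)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = "mean F2 score", fill = NULL)
  }
}

#' Plot variable importance estimates with confidence bounds
#'
#' Forest-style plot of the top variables by permutation importance with the
#' simultaneous normal-approximation interval at the `1 - alpha/p` level.
#'
#' @param object A `vimp_estimate`.
#' @param alpha Family-wise rate for the displayed intervals.
#' @param top Number of variables shown.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vimp_estimate
#' @export
autoplot.vimp_estimate <- function(object, alpha = 0.05, top = 30, ...) {
  z <- qnorm(1 - alpha / (2 * nrow(object)))
  df <- object %>%
    mutate(lower = .data$importance - z * .data$std_error,
           upper = .data$importance + z * .data$std_error) %>%
    arrange(dplyr::desc(.data$importance)) %>%
    head(top)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$variable,
                                                      .data$importance),
                                   y = .data$importance)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper), size = 0.3) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "permutation importance")
}

#' Plot BART inclusion proportions against their null thresholds
#'
#' Shows the posterior-mean inclusion proportion per variable and, when a
#' permutation null is attached, the local `1 - alpha` null quantile.
#'
#' @param object An `inclusion_profile`.
#' @param alpha Threshold quantile level.
#' @param top Number of variables shown.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot inclusion_profile
#' @export
autoplot.inclusion_profile <- function(object, alpha = 0.05, top = 30, ...) {
  nm <- object$variable_names %||% sprintf("V%04d", seq_len(object$p))
  df <- tibble(variable = nm, proportion = object$proportions)
  if (!is.null(object$null_matrix)) {
    df$threshold <- apply(object$null_matrix, 2, quantile, probs = 1 - alpha)
  }
  df <- df %>% arrange(dplyr::desc(.data$proportion)) %>% head(top)
  gg <- ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$variable, .data$proportion),
    y = .data$proportion)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "inclusion proportion")
  if (!is.null(object$null_matrix)) {
    gg <- gg + ggplot2::geom_point(ggplot2::aes(y = .data$threshold),
                                   colour = "red", shape = 3)
  }
  gg
}
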