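# ggplot2 views of the main result types.

#' Plot p-values against the ratio r
#'
#' Scatter of each test's p-value against `r = wk/s` on a log p scale,
#' showing the filter's soft dependence on how much a weight exceeds its
#' node's average share. An optional significance threshold is drawn as a
#' horizontal line.
#'
#' @param object A `polya_test_table` from [link_pvalues()].
#' @param threshold Optional per-test significance threshold to mark.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot polya_test_table
#' @export
autoplot.polya_test_table <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$r, y = .data$p_value)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "r = wk / s", y = "p-value",
                  title = sprintf("Polya test p-values (a = %g)", attr(object, "a")))
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}

#' Plot a log-likelihood profile
#'
#' Profile of the Polya log-likelihood over the searched bracket, with the
#' maximizer `a_ml` marked.
#'
#' @param object A `polya_ml` object from [fit_a_ml()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot polya_ml
#' @export
autoplot.polya_ml <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$a, y = .data$log_likelihood)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$a_ml, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "reinforcement a", y = "log-likelihood",
                  title = sprintf("a_ml = %.3g", object$a_ml))
}

#' Plot the salience-based optimality criteria
#'
#' `O1` and `O2` as functions of the reinforcement parameter, with each
#' criterion's maximizer marked.
#'
#' @param object A `polya_optimality` table from [optimality_measures()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot polya_optimality
#' @export
autoplot.polya_optimality <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    dplyr::select("a", "o1", "o2") |>
    tidyr::pivot_longer(c("o1", "o2"), names_to = "criterion",
                        values_to = "value")
  stars <- tibble::tibble(
    criterion = c("o1", "o2"),
    a = c(attr(object, "a_star_o1"), attr(object, "a_star_o2")),
    value = c(max(object$o1), max(object$o2))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$a, y = .data$value,
                                     colour = .data$criterion)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = stars, shape = 4, size = 3, stroke = 1.5) +
    ggplot2::labs(x = "reinforcement a", y = "optimality",
                  title = "Salience-based optimality of the backbone family")
}
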