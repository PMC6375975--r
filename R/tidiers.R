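# broom-style tidiers for the fitted/derived objects.

#' Tidy a Polya backbone into its retained link table
#'
#' @param x A `polya_backbone`.
#' @param ... Unused.
#' @return A tibble with `source`, `target`, `weight`, `p_value_min`.
#' @method tidy polya_backbone
#' @export
tidy.polya_backbone <- function(x, ...) {
  x$links
}

#' One-row summary of a Polya backbone
#'
#' @param x A `polya_backbone`.
#' @param ... Unused.
#' @return A one-row tibble with the filter settings, the number of tests
#'   `L`, the per-test threshold and the retained fractions.
#' @method glance polya_backbone
#' @export
glance.polya_backbone <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(a = x$a, alpha_u = x$alpha_u, correction = x$correction,
                   L = x$L, threshold = x$threshold,
                   n_links = nrow(x$links),
                   n_nodes = length(unique(c(x$links$source, x$links$target)))),
    backbone_summary(x)
  )
}

#' Tidy a maximum-likelihood fit into its profile
#'
#' @param x A `polya_ml` object.
#' @param ... Unused.
#' @return The log-likelihood profile tibble (`a`, `log_likelihood`).
#' @method tidy polya_ml
#' @export
tidy.polya_ml <- function(x, ...) {
  x$profile
}

#' One-row summary of a maximum-likelihood fit
#'
#' @param x A `polya_ml` object.
#' @param ... Unused.
#' @return A one-row tibble: `a_ml`, `log_lik`, `n_obs`, `at_edge`,
#'   `pseudo`.
#' @method glance polya_ml
#' @export
glance.polya_ml <- function(x, ...) {
  tibble::tibble(a_ml = x$a_ml, log_lik = x$log_lik, n_obs = x$n_obs,
                 at_edge = x$at_edge, pseudo = x$pseudo)
}

#' One-row summary of an optimality scan
#'
#' @param x A `polya_optimality` table.
#' @param ... Unused.
#' @return A one-row tibble with the maximizers `a_star_o1`, `a_star_o2`
#'   and the maxima `o1_max`, `o2_max`.
#' @method glance polya_optimality
#' @export
glance.polya_optimality <- function(x, ...) {
  tibble::tibble(a_star_o1 = attr(x, "a_star_o1"),
                 a_star_o2 = attr(x, "a_star_o2"),
                 o1_max = max(x$o1), o2_max = max(x$o2))
}
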