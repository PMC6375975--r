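# Per-link hypothesis testing and backbone extraction.
#
# Every link is tested from the viewpoint of the two nodes it connects
# (directed: the source's out-urn and the target's in-urn), giving L = 2 x
# links tests. A link enters the backbone when at least one of its p-values
# clears the corrected threshold; degree-1 viewpoints carry p = 1, which
# realizes the convention that only the higher-degree endpoint can validate
# a link touching a leaf.

# one row per (link, viewpoint) with the viewpoint's degree and strength
viewpoint_table <- function(net) {
  ns <- node_stats(net)
  link_id <- seq_len(nrow(net))
  if (net_directed(net)) {
    out <- ns |> dplyr::select("node", k = "k_out", s = "s_out")
    inn <- ns |> dplyr::select("node", k = "k_in", s = "s_in")
    rows_out <- tibble::tibble(
      link_id = link_id, source = net$source, target = net$target,
      viewpoint = net$source, side = "out", w = net$weight
    ) |> dplyr::left_join(out, by = c(viewpoint = "node"))
    rows_in <- tibble::tibble(
      link_id = link_id, source = net$source, target = net$target,
      viewpoint = net$target, side = "in", w = net$weight
    ) |> dplyr::left_join(inn, by = c(viewpoint = "node"))
    dplyr::arrange(dplyr::bind_rows(rows_out, rows_in), .data$link_id, .data$side)
  } else {
    ks <- ns |> dplyr::select("node", "k", "s")
    dplyr::bind_rows(
      tibble::tibble(link_id = link_id, source = net$source, target = net$target,
                     viewpoint = net$source, side = "source", w = net$weight),
      tibble::tibble(link_id = link_id, source = net$source, target = net$target,
                     viewpoint = net$target, side = "target", w = net$weight)
    ) |>
      dplyr::left_join(ks, by = c(viewpoint = "node")) |>
      dplyr::arrange(.data$link_id, .data$side)
  }
}

resolve_mode <- function(mode, weight_kind, a, s) {
  if (mode == "exact") {
    if (weight_kind != "integer") {
      abort("exact mode needs integer weights; use mode = \"approx\".",
            class = "polya_mode_error")
    }
    return(rep("exact", length(s)))
  }
  if (mode %in% c("approx", "ratio")) {
    if (a == 0) {
      abort("the asymptotic tests require a > 0; use mode = \"exact\" at a = 0.",
            class = "polya_mode_error")
    }
    return(rep(mode, length(s)))
  }
  # auto: exact summation for integer weights with moderate strengths
  if (weight_kind == "integer") {
    if (a == 0) return(rep("exact", length(s)))
    ifelse(s <= 1e5, "exact", "approx")
  } else {
    if (a == 0) {
      abort("real-valued weights cannot be tested at a = 0; choose a > 0.",
            class = "polya_mode_error")
    }
    rep("approx", length(s))
  }
}

#' Two-viewpoint Polya p-values for every link
#'
#' Tests each link weight from both endpoints' urns under the Beta-Binomial
#' null with reinforcement `a`. The test mode is `"exact"` (tail summation
#' of the Beta-Binomial), `"approx"` (large-strength closed form),
#' `"ratio"` (p-value of `r = wk/s` alone) or `"auto"`, which uses the
#' exact test for integer weights with viewpoint strength at most `1e5`
#' and the approximation otherwise. Degree-1 viewpoints always get p = 1.
#'
#' @param net A [weighted_network()] or coercible data frame.
#' @param a Reinforcement parameter, non-negative.
#' @param mode One of `"auto"`, `"exact"`, `"approx"`, `"ratio"`.
#' @param directed Directedness override for bare data frames.
#' @return A `polya_test_table` tibble with one row per (link, viewpoint):
#'   `link_id`, `source`, `target`, `viewpoint`, `side`, `w`, `k`, `s`,
#'   `r`, `p_value`, `mode`; attribute `L` is the number of tests.
#' @examples
#' link_pvalues(fig1_fixture(), a = 1)
#' @export
link_pvalues <- function(net, a, mode = c("auto", "exact", "approx", "ratio"),
                         directed = NULL) {
  mode <- match.arg(mode)
  check_scalar_a(a)
  net <- as_weighted_network(net, directed)
  vt <- viewpoint_table(net)
  if (nrow(vt) == 0L) {
    res <- vt |> dplyr::mutate(r = numeric(0), p_value = numeric(0), mode = character(0))
  } else {
    vt$r <- vt$w * vt$k / vt$s
    vt$mode <- resolve_mode(mode, net_weight_kind(net), a, vt$s)
    # compute on unique (w, k, s, mode) combos, then join back
    key <- paste(vt$w, vt$k, vt$s, vt$mode, sep = "\r")
    uni <- !duplicated(key)
    p_uni <- numeric(sum(uni))
    uw <- vt$w[uni]; uk <- vt$k[uni]; us <- vt$s[uni]; um <- vt$mode[uni]
    deg1 <- uk == 1
    p_uni[deg1] <- 1
    for (m in unique(um[!deg1])) {
      idx <- !deg1 & um == m
      p_uni[idx] <- switch(
        m,
        exact  = polya_pvalue(uw[idx], uk[idx], us[idx], a),
        approx = polya_pvalue_approx(uw[idx], uk[idx], us[idx], a),
        ratio  = polya_pvalue_ratio(uw[idx] * uk[idx] / us[idx], a)
      )
    }
    vt$p_value <- p_uni[match(key, key[uni])]
    res <- vt
  }
  structure(res,
            L = nrow(res), a = a, directed = net_directed(net),
            class = c("polya_test_table", class(tibble::tibble())))
}

#' Extract the statistically validated backbone
#'
#' Keeps the links whose weight is incompatible with the Polya null at
#' reinforcement `a`, after multiple-testing correction over the family of
#' `L = 2 x links` tests. `"bonferroni"` retains a link when its smaller
#' p-value is strictly below `alpha_u / L`; `"fdr"` applies the
#' Benjamini-Hochberg step-up to all `L` p-values and keeps links with at
#' least one discovery; `"none"` compares the smaller p-value to `alpha_u`
#' directly. Links between two degree-1 nodes are never retained (both
#' p-values are 1).
#'
#' @inheritParams link_pvalues
#' @param alpha_u Univariate significance level in (0, 1).
#' @param correction `"bonferroni"`, `"fdr"` or `"none"`.
#' @return A `polya_backbone` object; see [tidy()] for the retained link
#'   table and [glance()] for a one-row summary.
#' @examples
#' extract_backbone(fig1_fixture(), a = 1, alpha_u = 0.5, correction = "none")
#' @export
extract_backbone <- function(net, a, alpha_u = 0.05,
                             correction = c("bonferroni", "fdr", "none"),
                             mode = c("auto", "exact", "approx", "ratio"),
                             directed = NULL) {
  correction <- match.arg(correction)
  mode <- match.arg(mode)
  if (!is.numeric(alpha_u) || length(alpha_u) != 1L || is.na(alpha_u) ||
      alpha_u <= 0 || alpha_u >= 1) {
    abort("`alpha_u` must be a single value in (0, 1).", class = "polya_domain_error")
  }
  net <- as_weighted_network(net, directed)
  tt <- link_pvalues(net, a = a, mode = mode)
  L <- attr(tt, "L")
  per_link <- tt |>
    dplyr::group_by(.data$link_id) |>
    dplyr::summarise(source = dplyr::first(.data$source),
                     target = dplyr::first(.data$target),
                     weight = dplyr::first(.data$w),
                     p_value_min = min(.data$p_value))
  threshold <- switch(correction,
                      bonferroni = alpha_u / max(L, 1L),
                      none = alpha_u,
                      fdr = NA_real_)
  keep_id <- if (correction == "fdr") {
    adj <- p.adjust(tt$p_value, method = "BH")
    unique(tt$link_id[adj <= alpha_u])
  } else {
    per_link$link_id[per_link$p_value_min < threshold]
  }
  links <- per_link |>
    dplyr::filter(.data$link_id %in% keep_id) |>
    dplyr::select("source", "target", "weight", "p_value_min")
  structure(
    list(links = links, a = a, alpha_u = alpha_u, correction = correction,
         L = L, threshold = threshold, directed = net_directed(net),
         weight_kind = net_weight_kind(net),
         parent_n_nodes = length(net_nodes(net)),
         parent_n_links = nrow(net),
         parent_strength = sum(net$weight)),
    class = "polya_backbone"
  )
}

#' @export
print.polya_backbone <- function(x, ...) {
  cat(sprintf(
    "Polya backbone: %d/%d links retained (a = %g, alpha_u = %g, %s, L = %d)\n",
    nrow(x$links), x$parent_n_links, x$a, x$alpha_u, x$correction, x$L))
  print(x$links, ...)
  invisible(x)
}

#' Retained fractions of links, nodes and strength
#'
#' The fraction of parent-network links, nodes and total weight that
#' survive the filter; each is monotonically non-increasing in `a` at a
#' fixed significance level.
#'
#' @param b A `polya_backbone`.
#' @return A one-row tibble: `fraction_links`, `fraction_nodes`,
#'   `fraction_strength`.
#' @export
backbone_summary <- function(b) {
  stopifnot(inherits(b, "polya_backbone"))
  tibble::tibble(
    fraction_links = nrow(b$links) / max(b$parent_n_links, 1L),
    fraction_nodes = length(unique(c(b$links$source, b$links$target))) /
      max(b$parent_n_nodes, 1L),
    fraction_strength = sum(b$links$weight) / max(b$parent_strength, 1e-300)
  )
}

link_key <- function(source, target, directed) {
  if (directed) paste(source, target, sep = "\r")
  else paste(pmin(source, target), pmax(source, target), sep = "\r")
}

#' Jaccard similarity between the backbone and the heaviest links
#'
#' With `B` links in the backbone, compares the backbone link set against
#' the `B` heaviest links of the parent network (ties broken by link name
#' for determinism). A value of 1 means the filter reduces to global
#' thresholding; low values signal that it retains locally important but
#' globally light links. An empty backbone gives 0.
#'
#' @inheritParams link_pvalues
#' @param b A `polya_backbone` extracted from `net`.
#' @return A single number in `[0, 1]`.
#' @export
top_b_jaccard <- function(net, b, directed = NULL) {
  stopifnot(inherits(b, "polya_backbone"))
  net <- as_weighted_network(net, directed)
  B <- nrow(b$links)
  if (B == 0L) return(0)
  dir <- net_directed(net)
  ord <- order(-net$weight, net$source, net$target)
  top <- link_key(net$source[ord][seq_len(B)], net$target[ord][seq_len(B)], dir)
  bb <- link_key(b$links$source, b$links$target, dir)
  length(intersect(bb, top)) / length(union(bb, top))
}

#' Compare Polya and disparity classifications link by link
#'
#' Computes, for every link, the smaller of its two Polya p-values at
#' reinforcement `a` and the smaller of its two disparity p-values, and
#' classifies the link into the four quadrants of agreement at the
#' Bonferroni threshold `alpha_u / L`. At `a = 1` and large strengths the
#' two filters agree on almost all links.
#'
#' @inheritParams extract_backbone
#' @return A tibble with per-link `p_polya`, `p_disparity`, the two
#'   significance flags and a `quadrant` label; attribute `agreement` is
#'   the fraction of links classified identically.
#' @export
compare_disparity <- function(net, a = 1, alpha_u = 0.05,
                              mode = c("auto", "exact", "approx", "ratio"),
                              directed = NULL) {
  mode <- match.arg(mode)
  net <- as_weighted_network(net, directed)
  tt <- link_pvalues(net, a = a, mode = mode)
  L <- attr(tt, "L")
  thr <- alpha_u / max(L, 1L)
  pd <- ifelse(tt$k == 1, 1, disparity_pvalue(tt$w, tt$k, tt$s))
  per_link <- tibble::tibble(link_id = tt$link_id, source = tt$source,
                             target = tt$target, weight = tt$w,
                             p_polya = tt$p_value, p_disparity = pd) |>
    dplyr::group_by(.data$link_id) |>
    dplyr::summarise(source = dplyr::first(.data$source),
                     target = dplyr::first(.data$target),
                     weight = dplyr::first(.data$weight),
                     p_polya = min(.data$p_polya),
                     p_disparity = min(.data$p_disparity)) |>
    dplyr::mutate(
      polya_significant = .data$p_polya < thr,
      disparity_significant = .data$p_disparity < thr,
      quadrant = dplyr::case_when(
        .data$polya_significant & .data$disparity_significant ~ "both_accept",
        !.data$polya_significant & !.data$disparity_significant ~ "both_reject",
        .data$polya_significant ~ "polya_only",
        TRUE ~ "disparity_only"
      )
    ) |>
    dplyr::select(-"link_id")
  structure(per_link,
            agreement = mean(per_link$polya_significant ==
                               per_link$disparity_significant),
            threshold = thr, a = a, L = L,
            class = c("polya_disparity_comparison", class(tibble::tibble())))
}
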