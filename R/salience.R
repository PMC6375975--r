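# Link salience via weighted shortest-path trees, and the salience-based
# optimality criteria for choosing the reinforcement parameter.

#' Link salience from weighted shortest-path trees
#'
#' For each node, a shortest-path tree over its reachable set is computed
#' with link distance `1/w` (heavier links are shorter). A link's salience
#' is the fraction of all nodes whose tree contains it: close to 1 for
#' links essential to transport from almost everywhere, close to 0 for
#' links bypassed by heavier routes. Salience is invariant under global
#' rescaling of the weights; on a tree every link has salience 1.
#'
#' @inheritParams link_pvalues
#' @return A tibble `source`, `target`, `weight`, `salience`, with
#'   attribute `n_reference` (the number of root nodes used).
#' @examples
#' link_salience(fig1_fixture())
#' @export
link_salience <- function(net, directed = NULL) {
  net <- as_weighted_network(net, directed)
  nodes <- net_nodes(net)
  n <- length(nodes)
  out <- tibble::tibble(source = net$source, target = net$target,
                        weight = net$weight, salience = rep(0, nrow(net)))
  if (nrow(net) == 0L || n == 0L) {
    return(structure(out, n_reference = n))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$source, to = net$target),
    directed = net_directed(net),
    vertices = data.frame(name = nodes)
  )
  dist <- 1 / net$weight
  counts <- integer(nrow(net))
  for (v in seq_len(n)) {
    # unreachable vertices are expected (trees cover the reachable set only)
    sp <- suppressWarnings(
      igraph::shortest_paths(g, from = v, to = igraph::V(g),
                             mode = "out", weights = dist,
                             output = "vpath", predecessors = TRUE)
    )
    pred <- as.integer(sp$predecessors)
    child <- which(!is.na(pred) & pred != seq_len(n))
    if (length(child) == 0L) next
    eids <- igraph::get_edge_ids(g, rbind(pred[child], child))
    eids <- eids[eids > 0L]
    counts[eids] <- counts[eids] + 1L
  }
  out$salience <- counts / n
  structure(out, n_reference = n)
}

#' Salience-based optimality of the backbone family
#'
#' Scans the reinforcement parameter over `a_grid` and reports, per
#' backbone, the mean parent-network salience of retained links `<S(a)>`,
#' the weighted Jaccard similarity `J` between the parent's and the
#' backbone's weight assignments (equal to the retained-strength fraction,
#' since backbone weights are a subset of the parent's), the retained node
#' fraction `F_n(a)`, and the two optimality products `O1 = J * <S>` and
#' `O2 = F_n * <S>`. `<S(a)>` typically increases with `a` (the filter
#' drops low-salience links first), while `J` and `F_n` shrink, so each
#' product can attain an interior maximum `a*`.
#'
#' @inheritParams extract_backbone
#' @param a_grid Increasing vector of reinforcement values to scan.
#' @return A `polya_optimality` tibble with one row per `a`: `a`,
#'   `mean_salience`, `jaccard`, `fraction_nodes`, `o1`, `o2`; attributes
#'   `a_star_o1` and `a_star_o2` give the maximizers.
#' @export
optimality_measures <- function(net, alpha_u = 0.05,
                                correction = c("bonferroni", "fdr", "none"),
                                a_grid = seq(0.2, 7, by = 0.2),
                                mode = c("auto", "exact", "approx", "ratio"),
                                directed = NULL) {
  correction <- match.arg(correction)
  mode <- match.arg(mode)
  net <- as_weighted_network(net, directed)
  sal <- link_salience(net)
  dir <- net_directed(net)
  sal_key <- link_key(sal$source, sal$target, dir)
  total_w <- sum(net$weight)
  n_nodes <- length(net_nodes(net))
  rows <- purrr::map(a_grid, function(a) {
    b <- extract_backbone(net, a = a, alpha_u = alpha_u,
                          correction = correction, mode = mode)
    if (nrow(b$links) == 0L) {
      return(tibble::tibble(a = a, mean_salience = 0, jaccard = 0,
                            fraction_nodes = 0, o1 = 0, o2 = 0))
    }
    bk <- link_key(b$links$source, b$links$target, dir)
    s_mean <- mean(sal$salience[match(bk, sal_key)])
    j <- sum(b$links$weight) / total_w
    fn <- length(unique(c(b$links$source, b$links$target))) / n_nodes
    tibble::tibble(a = a, mean_salience = s_mean, jaccard = j,
                   fraction_nodes = fn, o1 = j * s_mean, o2 = fn * s_mean)
  })
  res <- dplyr::bind_rows(rows)
  structure(res,
            a_star_o1 = res$a[which.max(res$o1)],
            a_star_o2 = res$a[which.max(res$o2)],
            class = c("polya_optimality", class(tibble::tibble())))
}
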