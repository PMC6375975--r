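# Seeded generator of networks whose per-node weight allocation follows the
# Polya null (Dirichlet-multinomial with symmetric concentration 1/a), plus
# the 4-node star used throughout the documentation.
#
# Each allocating node distributes its strength s over its k links by
# drawing p ~ Dirichlet(1/a, ..., 1/a) and w ~ Multinomial(s, p); the
# marginal weight on any single link is then exactly the Beta-Binomial null.
# A category drawn at zero is an absent link. By the neutrality of the
# Dirichlet, the weights retained after dropping zeros are again exactly
# Dirichlet-multinomial on the realized degree with the same concentration,
# so the null holds for the network the filter actually sees.

alloc_dm <- function(k, s, a) {
  p <- if (a == 0) {
    rep(1 / k, k)
  } else {
    g <- rgamma(k, shape = 1 / a)
    if (sum(g) <= 0) rep(1 / k, k) else g / sum(g)
  }
  drop(rmultinom(1, size = s, prob = p))
}

#' Generate a network with Polya-null weight allocation
#'
#' Builds a seeded synthetic network in which every allocating node
#' distributes its strength over its links through a Dirichlet-multinomial
#' draw with concentration `1/a_true` per link (`a_true = 0` gives the
#' equal-probability multinomial), so each single link weight is marginally
#' Beta-Binomial. Topologies:
#'
#' * `"out_stubs"` (directed): each of `n_nodes` sources allocates
#'   `s` over `k` private stub targets, which therefore have in-degree 1.
#' * `"star"` (undirected): a forest of stars; each hub allocates over its
#'   `k` leaves, which have degree 1.
#' * `"shared_targets"` (directed): sources allocate over `k` targets
#'   sampled without replacement from a common pool of `n_targets`.
#'
#' In the first two topologies only the allocating viewpoints carry
#' information (the other endpoints are degree-1 point masses), which keeps
#' likelihood-based recovery of `a_true` exactly specified.
#'
#' Zero draws are recorded as absent links, so all link weights are
#' positive integers and each node's retained weights still sum to `s`.
#'
#' @param n_nodes Number of allocating nodes (sources or hubs).
#' @param k Links per allocating node (recycled).
#' @param s Strength per allocating node (recycled).
#' @param a_true Reinforcement parameter of the generating process, `>= 0`.
#' @param topology `"out_stubs"`, `"star"` or `"shared_targets"`.
#' @param n_targets Pool size for `"shared_targets"`; default `2 * max(k)`.
#' @param signal Optional tibble with columns `node` (allocating-node
#'   index) and `weight`: plants the given weight on that node's first
#'   link and reallocates `s - weight` over the remaining links, creating
#'   controlled departures from the null.
#' @param seed Optional integer; sets the RNG state for bit-reproducible
#'   output.
#' @return A [weighted_network()]; attribute `signal_links` lists any
#'   planted links.
#' @examples
#' net <- generate_polya_network(20, k = 5, s = 100, a_true = 1, seed = 7)
#' @export
generate_polya_network <- function(n_nodes, k, s, a_true,
                                   topology = c("out_stubs", "star",
                                                "shared_targets"),
                                   n_targets = NULL, signal = NULL,
                                   seed = NULL) {
  topology <- match.arg(topology)
  check_scalar_a(a_true)
  if (!is.null(seed)) set.seed(seed)
  k <- rep_len(as.integer(k), n_nodes)
  s <- rep_len(as.integer(s), n_nodes)
  if (any(k < 1) || any(s < 1)) {
    abort("`k` and `s` must be positive.", class = "polya_domain_error")
  }
  directed <- topology != "star"
  src_name <- switch(topology,
                     star = sprintf("H%04d", seq_len(n_nodes)),
                     sprintf("S%04d", seq_len(n_nodes)))
  pool <- if (topology == "shared_targets") {
    sprintf("T%04d", seq_len(n_targets %||% (2L * max(k))))
  }
  if (!is.null(pool) && length(pool) < max(k)) {
    abort("`n_targets` must be at least max(k).", class = "polya_domain_error")
  }
  if (!is.null(signal)) {
    signal <- tibble::as_tibble(signal)
    stopifnot(all(c("node", "weight") %in% names(signal)))
    if (any(signal$node < 1 | signal$node > n_nodes) ||
        any(signal$weight < 1 | signal$weight > s[signal$node])) {
      abort("planted signal out of range.", class = "polya_domain_error")
    }
  }
  per_node <- vector("list", n_nodes)
  planted <- vector("list", n_nodes)
  for (i in seq_len(n_nodes)) {
    ki <- k[i]; si <- s[i]
    targets <- switch(topology,
                      out_stubs = sprintf("%s_t%03d", src_name[i], seq_len(ki)),
                      star = sprintf("%s_l%03d", src_name[i], seq_len(ki)),
                      shared_targets = sample(pool, ki))
    sig_w <- if (!is.null(signal) && i %in% signal$node) {
      signal$weight[match(i, signal$node)]
    }
    if (is.null(sig_w)) {
      w <- alloc_dm(ki, si, a_true)
    } else {
      rest <- if (ki > 1) alloc_dm(ki - 1L, si - sig_w, a_true) else integer(0)
      w <- c(sig_w, rest)
      planted[[i]] <- tibble::tibble(source = src_name[i], target = targets[1],
                                     weight = sig_w)
    }
    keep <- w > 0
    per_node[[i]] <- tibble::tibble(source = src_name[i],
                                    target = targets[keep],
                                    weight = as.numeric(w[keep]))
  }
  links <- dplyr::bind_rows(per_node)
  net <- weighted_network(links, directed = directed)
  attr(net, "signal_links") <- dplyr::bind_rows(planted)
  net
}

#' The 4-node worked-example star
#'
#' The undirected toy network used throughout the documentation: hub `A`
#' with degree 3 and strength 4, links `A-B` (weight 2), `A-C` and `A-D`
#' (weight 1). At `a = 1` the p-value of `A-B` from `A`'s viewpoint is 0.4.
#'
#' @return A [weighted_network()] with 4 nodes and 3 links.
#' @examples
#' node_stats(fig1_fixture())
#' @export
fig1_fixture <- function() {
  weighted_network(
    tibble::tibble(source = "A", target = c("B", "C", "D"), weight = c(2, 1, 1)),
    directed = FALSE
  )
}
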