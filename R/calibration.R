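# Fixing the reinforcement parameter: maximum likelihood, sparsity
# sweeping, and the (a, alpha) equivalence rescaling.

# viewpoints with k >= 2 (degree-1 urns are point masses; log-contribution 0)
likelihood_obs <- function(net) {
  vt <- viewpoint_table(net)
  vt <- vt[vt$k >= 2, c("viewpoint", "side", "w", "k", "s")]
  vt$group <- paste(vt$viewpoint, vt$side, sep = "\r")
  vt
}

# P(all k categories positive) for a Dirichlet-multinomial(s, 1/a) draw,
# by inclusion-exclusion over the categories forced to zero
lp_all_positive <- function(k, s, a) {
  j <- 0:(k - 1)
  lp0 <- lgamma(k / a) - lgamma((k - j) / a) +
    lgamma((k - j) / a + s) - lgamma(k / a + s)
  p <- sum((-1)^j * choose(k, j) * exp(lp0))
  log(max(p, 1e-300))
}

# per-viewpoint joint allocation log-likelihood, conditioned on every
# observed link having positive weight (link existence taken as given)
ll_truncated <- function(obs, a) {
  per_row <- lgamma(1 / a + obs$w) - lgamma(obs$w + 1)
  grp <- obs[!duplicated(obs$group), c("group", "k", "s")]
  row_sum <- tapply(per_row, obs$group, sum)[grp$group]
  ks_key <- paste(grp$k, grp$s, sep = "\r")
  uni <- !duplicated(ks_key)
  lpp <- vapply(which(uni), function(i) lp_all_positive(grp$k[i], grp$s[i], a),
                numeric(1))[match(ks_key, ks_key[uni])]
  sum(as.numeric(row_sum) +
        lgamma(grp$s + 1) - grp$k * lgamma(1 / a) +
        lgamma(grp$k / a) - lgamma(grp$k / a + grp$s) - lpp)
}

#' Polya log-likelihood of a network's weight allocation
#'
#' Sum over all (link, viewpoint) tests with viewpoint degree at least 2 of
#' the log Beta-Binomial mass of the observed weight; the same family of
#' observations used by [link_pvalues()], so undirected links contribute
#' from both endpoints. Degree-1 viewpoints are point masses and contribute
#' zero. For real-valued weights an asymptotic pseudo-likelihood based on
#' the large-strength kernel is used and flagged via the `pseudo`
#' attribute.
#'
#' @inheritParams link_pvalues
#' @param a Reinforcement parameter, strictly positive.
#' @param truncation `"none"` sums the marginal Beta-Binomial log-masses of
#'   the observed weights; `"positive"` instead uses each viewpoint's joint
#'   allocation likelihood conditioned on all of its observed links having
#'   positive weight. Because a weighted network by definition contains no
#'   zero-weight links, the conditioned form is the correctly specified
#'   likelihood of the data the filter actually sees, and is what
#'   [fit_a_ml()] maximizes.
#' @return A single number with attribute `pseudo` (logical).
#' @examples
#' polya_log_likelihood(fig1_fixture(), a = 1) # log(0.2) + 2 * log(4/15)
#' @export
polya_log_likelihood <- function(net, a, truncation = c("none", "positive"),
                                 directed = NULL) {
  truncation <- match.arg(truncation)
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a <= 0) {
    abort("`a` must be a single positive number.", class = "polya_domain_error")
  }
  net <- as_weighted_network(net, directed)
  obs <- likelihood_obs(net)
  if (nrow(obs) == 0L) {
    abort("degenerate likelihood: the network has no viewpoint with degree >= 2.",
          class = "polya_degenerate_error")
  }
  pseudo <- net_weight_kind(net) != "integer"
  if (truncation == "positive" && !pseudo) {
    structure(ll_truncated(obs, a), pseudo = FALSE)
  } else {
    ll_from_obs(obs, a, pseudo)
  }
}

ll_from_obs <- function(obs, a, pseudo) {
  key <- paste(obs$w, obs$k, obs$s, sep = "\r")
  cnt <- table(key)
  first <- match(names(cnt), key)
  w <- obs$w[first]; k <- obs$k[first]; s <- obs$s[first]
  lp <- if (pseudo) {
    log(polya_pvalue_approx(w, k, s, a))
  } else {
    al <- 1 / a
    lchoose(s, w) + lbeta(al + w, (k - 1) / a + s - w) - lbeta(al, (k - 1) / a)
  }
  structure(sum(as.numeric(cnt) * lp), pseudo = pseudo)
}

#' Maximum-likelihood reinforcement parameter
#'
#' Finds the reinforcement `a_ml` maximizing the Polya log-likelihood by
#' bounded 1-D optimization on the log-`a` scale (profiles are smooth in
#' log `a` and `a` spans orders of magnitude). `a_ml` identifies the
#' "nullest" member of the filter family: the Polya process most likely to
#' have generated the observed heterogeneity.
#'
#' By default the maximized function is the positive-truncated allocation
#' likelihood (see [polya_log_likelihood()]): link existence is taken as
#' given and only the weight allocation is modelled, which keeps the
#' estimator unbiased on networks whose allocations follow the null.
#'
#' @inheritParams polya_log_likelihood
#' @param bracket Search interval for `a`, within `(1e-4, 1e3)`.
#' @param n_grid Number of profile grid points (log-spaced).
#' @return A `polya_ml` object with elements `a_ml`, `log_lik`, `profile`
#'   (tibble of `a`, `log_likelihood`), `bracket`, `at_edge`, `n_obs`,
#'   `pseudo`. A maximum at the bracket edge raises a warning and sets
#'   `at_edge`.
#' @examples
#' \donttest{
#' net <- generate_polya_network(50, k = 10, s = 1000, a_true = 2, seed = 1)
#' fit_a_ml(net)$a_ml
#' }
#' @export
fit_a_ml <- function(net, bracket = c(1e-3, 1e2), n_grid = 41,
                     truncation = c("positive", "none"), directed = NULL) {
  truncation <- match.arg(truncation)
  if (length(bracket) != 2L || bracket[1] <= 1e-4 * (1 - 1e-9) ||
      bracket[2] > 1e3 || bracket[1] >= bracket[2]) {
    abort("`bracket` must be an increasing interval within (1e-4, 1e3].",
          class = "polya_domain_error")
  }
  net <- as_weighted_network(net, directed)
  obs <- likelihood_obs(net)
  if (nrow(obs) == 0L) {
    abort("degenerate likelihood: the network has no viewpoint with degree >= 2.",
          class = "polya_degenerate_error")
  }
  pseudo <- net_weight_kind(net) != "integer"
  f <- if (truncation == "positive" && !pseudo) {
    function(loga) ll_truncated(obs, exp(loga))
  } else {
    function(loga) as.numeric(ll_from_obs(obs, exp(loga), pseudo))
  }
  lb <- log(bracket)
  opt <- optimize(f, interval = lb, maximum = TRUE, tol = 1e-3)
  a_ml <- exp(opt$maximum)
  grid <- exp(seq(lb[1], lb[2], length.out = n_grid))
  profile <- tibble::tibble(
    a = grid,
    log_likelihood = vapply(log(grid), f, numeric(1))
  )
  at_edge <- a_ml <= bracket[1] * 1.05 || a_ml >= bracket[2] / 1.05
  if (at_edge) {
    warn(sprintf("likelihood maximum at the bracket edge (a_ml = %.4g); widen `bracket`.",
                 a_ml))
  }
  structure(
    list(a_ml = a_ml, log_lik = opt$objective, profile = profile,
         bracket = bracket, at_edge = at_edge, n_obs = nrow(obs),
         pseudo = pseudo),
    class = "polya_ml"
  )
}

#' @export
print.polya_ml <- function(x, ...) {
  cat(sprintf("Polya maximum likelihood: a_ml = %.4g (log L = %.4f, %d observations%s)\n",
              x$a_ml, x$log_lik, x$n_obs,
              if (x$pseudo) ", pseudo-likelihood" else ""))
  if (x$at_edge) cat("warning: maximum at bracket edge\n")
  invisible(x)
}

#' Smallest reinforcement reaching a target sparsity
#'
#' Exploits the monotone shrinkage of backbones in `a` to find, by
#' bisection on a log-spaced grid with resolution 0.01 in log10(a), the
#' smallest grid value whose backbone retains at most `target_fraction` of
#' the chosen metric (links, nodes or strength). `a = 0` is the first grid
#' point.
#'
#' @inheritParams extract_backbone
#' @param metric `"links"`, `"nodes"` or `"strength"`.
#' @param target_fraction Desired retained fraction in (0, 1].
#' @param a_max Upper end of the searched grid.
#' @return A one-row tibble: `a`, `metric`, `target_fraction`,
#'   `achieved_fraction`. Fails with an explicit error, reporting the
#'   end-of-grid fractions, when the target is unreachable.
#' @export
sweep_a <- function(net, metric = c("links", "nodes", "strength"),
                    target_fraction, alpha_u = 0.05,
                    correction = c("bonferroni", "fdr", "none"),
                    mode = c("auto", "exact", "approx", "ratio"),
                    a_max = 1e3, directed = NULL) {
  metric <- match.arg(metric)
  correction <- match.arg(correction)
  mode <- match.arg(mode)
  if (!is.numeric(target_fraction) || length(target_fraction) != 1L ||
      target_fraction <= 0 || target_fraction > 1) {
    abort("`target_fraction` must be in (0, 1].", class = "polya_domain_error")
  }
  net <- as_weighted_network(net, directed)
  grid <- c(0, 10^seq(-2, log10(a_max), by = 0.01))
  col <- paste0("fraction_", metric)
  frac_at <- function(a) {
    backbone_summary(extract_backbone(net, a = a, alpha_u = alpha_u,
                                      correction = correction, mode = mode))[[col]]
  }
  f_lo <- frac_at(grid[1])
  if (f_lo <= target_fraction) {
    return(tibble::tibble(a = 0, metric = metric,
                          target_fraction = target_fraction,
                          achieved_fraction = f_lo))
  }
  f_hi <- frac_at(grid[length(grid)])
  if (f_hi > target_fraction) {
    abort(sprintf(
      "target fraction %.4g unreachable: metric is %.4g at a = 0 and %.4g at a = %g.",
      target_fraction, f_lo, f_hi, a_max), class = "polya_sweep_error")
  }
  lo <- 1L                      # metric > target here
  hi <- length(grid)            # metric <= target here
  f_hi_val <- f_hi
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    fm <- frac_at(grid[mid])
    if (fm <= target_fraction) {
      hi <- mid; f_hi_val <- fm
    } else {
      lo <- mid
    }
  }
  tibble::tibble(a = grid[hi], metric = metric,
                 target_fraction = target_fraction,
                 achieved_fraction = f_hi_val)
}

#' Significance rescaling that makes two reinforcement values equivalent
#'
#' Backbones at reinforcement `a1` can be approximately reproduced at
#' `a2 = d * a1` (`d >= 1`) by shrinking the compatibility region around
#' the null mean of `r` by the factor
#' \deqn{c = \sqrt{\frac{a_1 + k/d}{a_1 + k} \cdot \frac{a_1 s + k}{a_1 s + k/d}},}
#' a monotonically decreasing function of `d`: larger reinforcement trades
#' off against stricter significance.
#'
#' @param a1 Baseline reinforcement, `> 0`.
#' @param d Scale factor, `>= 1` (vectorized).
#' @param k Node degree.
#' @param s Node strength.
#' @return Numeric vector of factors `c` in `(0, 1]`.
#' @examples
#' equivalence_scale(1, d = 2, k = 10, s = 100) # ~ 0.7559
#' @export
equivalence_scale <- function(a1, d, k, s) {
  if (!is.numeric(a1) || any(a1 <= 0)) {
    abort("`a1` must be positive.", class = "polya_domain_error")
  }
  if (any(d < 1)) abort("`d` must be >= 1.", class = "polya_domain_error")
  sqrt((a1 + k / d) / (a1 + k) * (a1 * s + k) / (a1 * s + k / d))
}
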