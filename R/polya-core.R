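# Beta-Binomial (Polya urn) null model: pmf, survival p-values, asymptotic
# approximations, the ratio r = wk/s, its null moments, and the disparity
# filter reference p-value.
#
# All beta/binomial terms are computed as sums of log-gamma values so that
# strengths up to 1e6 and beyond stay finite; survival probabilities are
# obtained by summing whichever tail has fewer terms and complementing only
# when the complement is the larger tail.

check_scalar_a <- function(a) {
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a < 0) {
    abort("`a` must be a single non-negative number.", class = "polya_domain_error")
  }
}

is_wholenumber <- function(x, tol = 1e-9) {
  is.finite(x) & abs(x - round(x)) < tol
}

#' Beta-Binomial probability mass under the Polya urn null
#'
#' Probability that a node of degree `k` and strength `s`, distributing its
#' strength through a Polya urn process with reinforcement parameter `a`,
#' places exactly weight `x` on a focal link. The urn starts with 1 red and
#' `k - 1` black balls and returns `a` extra balls of the drawn colour after
#' each of the `s` draws.
#'
#' At `a = 0` the distribution reduces to Binomial(`s`, 1/`k`); a degree-1
#' node has no black balls, so its mass is a point mass at `x = s`.
#'
#' @param x Number of red draws (candidate link weight), integer in `[0, s]`.
#' @param k Node degree, `>= 1`.
#' @param s Node strength (number of draws), non-negative integer.
#' @param a Reinforcement parameter, a single non-negative real.
#' @return Numeric vector of probabilities; `x`, `k`, `s` are recycled.
#' @examples
#' polya_pmf(2, k = 3, s = 4, a = 1) # 0.2
#' sum(polya_pmf(0:10, k = 4, s = 10, a = 0.5)) # 1
#' @export
polya_pmf <- function(x, k, s, a) {
  check_scalar_a(a)
  n <- max(length(x), length(k), length(s))
  x <- rep_len(as.numeric(x), n)
  k <- rep_len(as.numeric(k), n)
  s <- rep_len(as.numeric(s), n)
  if (any(k < 1)) abort("`k` must be >= 1.", class = "polya_domain_error")
  if (any(x < 0 | x > s)) {
    abort("`x` must lie in [0, s].", class = "polya_domain_error")
  }
  if (any(!is_wholenumber(x) | !is_wholenumber(s))) {
    abort("exact Beta-Binomial mass requires whole-number `x` and `s`.",
          class = "polya_mode_error")
  }
  out <- numeric(n)
  deg1 <- k == 1
  out[deg1] <- as.numeric(x[deg1] == s[deg1])
  if (a == 0) {
    i <- !deg1
    out[i] <- dbinom(x[i], size = s[i], prob = 1 / k[i])
    return(out)
  }
  i <- !deg1
  if (any(i)) {
    al <- 1 / a
    be <- (k[i] - 1) / a
    out[i] <- exp(lchoose(s[i], x[i]) +
                    lbeta(al + x[i], be + s[i] - x[i]) -
                    lbeta(al, be))
  }
  out
}

# log-sum-exp over a numeric vector of log terms
logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

# survival P(X >= w) for a single observation, exact summation
polya_survival_one <- function(w, k, s, a) {
  if (w <= 0) return(1)
  if (k == 1) return(1)          # point mass at s: any w <= s is certain
  if (a == 0) return(pbinom(w - 1, size = s, prob = 1 / k, lower.tail = FALSE))
  al <- 1 / a
  be <- (k - 1) / a
  lnorm <- lbeta(al, be)
  lterm <- function(x) lchoose(s, x) + lbeta(al + x, be + s - x) - lnorm
  n_upper <- s - w + 1
  n_lower <- w
  if (n_upper <= n_lower) {
    p <- exp(logsumexp(lterm(w:s)))
  } else {
    p <- 1 - exp(logsumexp(lterm(0:(w - 1))))
  }
  min(max(p, 0), 1)
}

#' Exact Polya urn p-value of a link weight
#'
#' Survival probability `P(X >= w)` of the Beta-Binomial null: the chance
#' that a node of degree `k` and strength `s` would place at least weight
#' `w` on the focal link through a reinforcement-`a` Polya process. The tail
#' with fewer terms is summed directly; the complement is used only for the
#' larger tail, so small p-values never suffer catastrophic cancellation.
#'
#' @inheritParams polya_pmf
#' @param w Observed link weight, whole number with `0 <= w <= s` (`w = 0`
#'   returns 1).
#' @return Numeric vector of p-values in `[0, 1]`.
#' @examples
#' polya_pvalue(2, k = 3, s = 4, a = 1) # 0.4
#' @export
polya_pvalue <- function(w, k, s, a) {
  check_scalar_a(a)
  n <- max(length(w), length(k), length(s))
  w <- rep_len(as.numeric(w), n)
  k <- rep_len(as.numeric(k), n)
  s <- rep_len(as.numeric(s), n)
  if (any(k < 1)) abort("`k` must be >= 1.", class = "polya_domain_error")
  if (any(w > s | w < 0)) {
    abort("`w` must lie in [0, s].", class = "polya_domain_error")
  }
  if (any(!is_wholenumber(w) | !is_wholenumber(s))) {
    abort(paste("the exact test requires whole-number weights and strengths;",
                "use `polya_pvalue_approx()` for real-valued weights."),
          class = "polya_mode_error")
  }
  vapply(seq_len(n), function(i) {
    polya_survival_one(round(w[i]), k[i], round(s[i]), a)
  }, numeric(1))
}

#' Asymptotic Polya p-value for large strengths and real-valued weights
#'
#' Closed-form approximation of the Polya urn survival probability, valid
#' when `s >> k/a` and `w >> 1`:
#' \deqn{\pi \approx \Gamma(1/a)^{-1} (1 - w/s)^{(k-1)/a} (wk/(sa))^{1/a - 1},}
#' clipped to `[0, 1]`. Unlike the exact test it depends on `w` and `s` only
#' through the rate `w/s`, which is what makes it applicable to networks
#' with non-integer weights. At `a = 1` it reduces exactly to the disparity
#' filter formula `(1 - w/s)^(k-1)`.
#'
#' @inheritParams polya_pmf
#' @param w Observed link weight, real, `0 < w <= s`.
#' @return Numeric vector of clipped p-values.
#' @examples
#' polya_pvalue_approx(10, k = 3, s = 100, a = 1) # 0.81
#' @export
polya_pvalue_approx <- function(w, k, s, a) {
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a <= 0) {
    abort("the asymptotic p-value requires `a` > 0; at a = 0 use the exact binomial test.",
          class = "polya_domain_error")
  }
  n <- max(length(w), length(k), length(s))
  w <- rep_len(as.numeric(w), n)
  k <- rep_len(as.numeric(k), n)
  s <- rep_len(as.numeric(s), n)
  if (any(k < 1)) abort("`k` must be >= 1.", class = "polya_domain_error")
  if (any(w > s | w <= 0)) {
    abort("`w` must lie in (0, s].", class = "polya_domain_error")
  }
  if (a == 1) {
    # closed form; identical to disparity_pvalue() by construction
    return((1 - w / s)^(k - 1))
  }
  lp <- -lgamma(1 / a) + (1 / a - 1) * log(w * k / (s * a))
  kk <- k > 1
  lp[kk] <- lp[kk] + ((k[kk] - 1) / a) * log1p(-w[kk] / s[kk])
  pmin(exp(lp), 1)
}

#' Polya p-value as a function of the ratio r alone
#'
#' Small-rate expansion of the asymptotic p-value: for `r = wk/s`,
#' \deqn{\pi \approx e^{-r/a} (r/a)^{1/a - 1} / \Gamma(1/a),}
#' clipped to `[0, 1]`. This form captures the filter's soft dependence on
#' how much a weight exceeds its node's average link weight.
#'
#' @param r Ratio `wk/s`, strictly positive.
#' @param a Reinforcement parameter, strictly positive.
#' @return Numeric vector of clipped p-values.
#' @examples
#' polya_pvalue_ratio(1, a = 1) # exp(-1)
#' @export
polya_pvalue_ratio <- function(r, a) {
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a <= 0) {
    abort("`a` must be a single positive number.", class = "polya_domain_error")
  }
  if (any(!is.numeric(r)) || any(r <= 0)) {
    abort("`r` must be strictly positive.", class = "polya_domain_error")
  }
  pmin(exp(-r / a + (1 / a - 1) * log(r / a) - lgamma(1 / a)), 1)
}

#' Disparity filter p-value
#'
#' The classical disparity filter test `(1 - w/s)^(k - 1)`, i.e. the
#' probability under uniform random strength allocation that a link carries
#' a rate at least `w/s`. It coincides with the large-strength limit of the
#' Polya filter at `a = 1`.
#'
#' @inheritParams polya_pvalue_approx
#' @param w Observed link weight, `0 <= w <= s`.
#' @return Numeric vector of p-values in `[0, 1]`.
#' @examples
#' disparity_pvalue(2, k = 3, s = 4) # 0.25
#' @export
disparity_pvalue <- function(w, k, s) {
  n <- max(length(w), length(k), length(s))
  w <- rep_len(as.numeric(w), n)
  k <- rep_len(as.numeric(k), n)
  s <- rep_len(as.numeric(s), n)
  if (any(w > s | w < 0)) abort("`w` must lie in [0, s].", class = "polya_domain_error")
  if (any(k < 1)) abort("`k` must be >= 1.", class = "polya_domain_error")
  (1 - w / s)^(k - 1)
}

#' Weight-to-average ratio r = wk/s
#'
#' The observed weight relative to the node's average link weight `s/k`;
#' `r = 1` means the link carries exactly its node's average share.
#'
#' @inheritParams disparity_pvalue
#' @return Numeric vector of ratios in `(0, k]`.
#' @examples
#' ratio_r(2, k = 3, s = 4) # 1.5
#' @export
ratio_r <- function(w, k, s) {
  n <- max(length(w), length(k), length(s))
  w <- rep_len(as.numeric(w), n)
  k <- rep_len(as.numeric(k), n)
  s <- rep_len(as.numeric(s), n)
  if (any(s <= 0)) abort("`s` must be strictly positive.", class = "polya_domain_error")
  w * k / s
}

#' Null mean and variance of the ratio r
#'
#' Under the Polya null the ratio `r = wk/s` has mean exactly 1 for every
#' `a`, and variance `(k-1)/s * (k + a s)/(a + k)`; at `a = 0` the variance
#' reduces to the binomial value `(k-1)/s`.
#'
#' @param k Node degree, `>= 1`.
#' @param s Node strength, `> 0`.
#' @param a Reinforcement parameter, non-negative.
#' @return A tibble with columns `k`, `s`, `a`, `mu_r`, `var_r`.
#' @examples
#' null_ratio_moments(k = 3, s = 4, a = 1) # var_r = 0.875
#' @export
null_ratio_moments <- function(k, s, a) {
  check_scalar_a(a)
  n <- max(length(k), length(s))
  k <- rep_len(as.numeric(k), n)
  s <- rep_len(as.numeric(s), n)
  if (any(k < 1) || any(s <= 0)) {
    abort("`k` must be >= 1 and `s` > 0.", class = "polya_domain_error")
  }
  tibble::tibble(
    k = k, s = s, a = a,
    mu_r = 1,
    var_r = (k - 1) / s * (k + a * s) / (a + k)
  )
}

#' Sample link weights from the Polya urn null
#'
#' Draws `n` weights from the Beta-Binomial null for a node of degree `k`
#' and strength `s` with reinforcement `a`, via its Beta-mixture
#' representation (`p ~ Beta(1/a, (k-1)/a)`, `w ~ Binomial(s, p)`).
#'
#' @param n Number of draws.
#' @inheritParams null_ratio_moments
#' @return Integer vector of length `n` with values in `[0, s]`.
#' @examples
#' set.seed(1)
#' mean(rpolya(1e4, k = 5, s = 200, a = 2) * 5 / 200) # ~ 1
#' @export
rpolya <- function(n, k, s, a) {
  check_scalar_a(a)
  if (k < 1) abort("`k` must be >= 1.", class = "polya_domain_error")
  if (k == 1) return(rep.int(as.integer(s), n))
  if (a == 0) return(rbinom(n, size = s, prob = 1 / k))
  p <- rbeta(n, shape1 = 1 / a, shape2 = (k - 1) / a)
  rbinom(n, size = s, prob = p)
}
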