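# Beta-Binomial null: agreement with the urn enumeration oracle, limits,
# approximations, ratio moments.

test_that("pmf matches the worked 4-draw urn example and the binomial limit", {
  expect_equal(polya_pmf(2, k = 3, s = 4, a = 1), 0.2, tolerance = 1e-12)
  expect_equal(polya_pmf(1, k = 2, s = 2, a = 0), 0.5, tolerance = 1e-12)
  # degree-1 urn is a point mass at s
  expect_equal(polya_pmf(0:3, k = 1, s = 3, a = 2), c(0, 0, 0, 1))
})

test_that("pmf equals brute-force urn enumeration on a small grid", {
  for (a in c(0.5, 1, 2)) {
    for (k in c(2, 3, 5)) {
      for (s in c(1, 4, 7)) {
        expect_equal(polya_pmf(0:s, k, s, a),
                     vapply(0:s, oracle_urn_pmf, numeric(1), k = k, s = s,
                            reinforcement = a),
                     tolerance = 1e-12,
                     label = sprintf("pmf(k=%d,s=%d,a=%g)", k, s, a))
      }
    }
  }
})

test_that("pmf normalizes to 1 across (k, s, a)", {
  grid <- expand.grid(k = c(2, 5, 17), s = c(10, 137, 1000), a = c(0, 0.3, 1, 4.5))
  for (i in seq_len(nrow(grid))) {
    with(grid[i, ], expect_equal(sum(polya_pmf(0:s, k, s, a)), 1,
                                 tolerance = 1e-12))
  }
})

test_that("survival p-value matches enumeration, is monotone, and handles w = 0", {
  expect_equal(polya_pvalue(2, k = 3, s = 4, a = 1), 0.4, tolerance = 1e-12)
  expect_equal(polya_pvalue(2, k = 3, s = 4, a = 1),
               oracle_urn_survival(2, 3, 4, 1), tolerance = 1e-12)
  for (a in c(0.5, 2)) {
    p <- polya_pvalue(0:7, k = 4, s = 7, a = a)
    expect_equal(p, vapply(0:7, oracle_urn_survival, numeric(1), k = 4, s = 7,
                           reinforcement = a), tolerance = 1e-12)
    expect_true(all(diff(p) <= 0))
  }
  expect_equal(polya_pvalue(0, k = 7, s = 50, a = 2.3), 1)
})

test_that("a = 0 equals the binomial survival closed form", {
  w <- c(1, 5, 20, 90)
  expect_equal(polya_pvalue(w, k = 7, s = 100, a = 0),
               pbinom(w - 1, 100, 1 / 7, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("a -> infinity limit gives p = 1/k", {
  expect_equal(polya_pvalue(5, k = 4, s = 10, a = 1e8), 0.25, tolerance = 1e-6)
  expect_equal(polya_pvalue(900, k = 10, s = 1000, a = 1e8), 0.1,
               tolerance = 1e-6)
})

test_that("large strengths do not overflow the exact tail sum", {
  p <- polya_pvalue(5e4, k = 20, s = 1e5, a = 0.5)
  expect_true(is.finite(p) && p >= 0 && p <= 1 && p < 1e-10)
})

test_that("survival sum rejects real-valued inputs with a pointer to approx", {
  expect_error(polya_pvalue(1.5, k = 3, s = 4, a = 1), class = "polya_mode_error")
  expect_error(polya_pvalue(5, k = 3, s = 4, a = 1), class = "polya_domain_error")
  expect_error(polya_pmf(2, k = 3, s = 4, a = -1), class = "polya_domain_error")
})

test_that("asymptotic p-value: closed form at a = 1, agreement, clipping", {
  expect_equal(polya_pvalue_approx(10, k = 3, s = 100, a = 1), 0.81)
  # bit-identical to the disparity formula at a = 1
  w <- c(1, 7, 50, 99); k <- c(2, 5, 9, 30)
  expect_identical(polya_pvalue_approx(w, k, s = 100, a = 1),
                   disparity_pvalue(w, k, s = 100))
  # approaches the exact tail where significance is decided (s >> k/a, w >> 1)
  expect_lt(abs(polya_pvalue_approx(5000, 10, 1e4, a = 2) -
                  polya_pvalue(5000, 10, 1e4, a = 2)), 1e-3)
  d <- abs(polya_pvalue_approx(3000, 10, 1e4, a = 2) -
             polya_pvalue(3000, 10, 1e4, a = 2))
  expect_lt(d / polya_pvalue(3000, 10, 1e4, a = 2), 0.15)
  # raw expression can exceed 1 -> clipped
  expect_equal(polya_pvalue_approx(1e-4, k = 2, s = 1, a = 2), 1)
  expect_error(polya_pvalue_approx(1, 2, 10, a = 0), class = "polya_domain_error")
})

test_that("ratio-form p-value evaluates, is monotone in r, and clips", {
  expect_equal(polya_pvalue_ratio(1, a = 1), exp(-1), tolerance = 1e-12)
  expect_lt(polya_pvalue_ratio(4, a = 1), polya_pvalue_ratio(2, a = 1))
  expect_equal(polya_pvalue_ratio(1e-8, a = 2), 1)
  expect_error(polya_pvalue_ratio(-1, a = 1), class = "polya_domain_error")
})

test_that("disparity p-value closed form and edge cases", {
  expect_equal(disparity_pvalue(2, k = 3, s = 4), 0.25)
  expect_equal(disparity_pvalue(0, k = 5, s = 10), 1)
  expect_equal(disparity_pvalue(7, k = 1, s = 7), 1)
})

test_that("ratio r = wk/s", {
  expect_equal(ratio_r(2, 3, 4), 1.5)
  expect_equal(ratio_r(5, 4, 20), 1)
  expect_equal(ratio_r(20, 4, 20), 4)
  expect_error(ratio_r(1, 2, 0), class = "polya_domain_error")
})

test_that("null ratio moments: unit mean, stated variance, binomial limit", {
  m <- null_ratio_moments(k = 3, s = 4, a = 1)
  expect_equal(m$mu_r, 1)
  expect_equal(m$var_r, 0.875)
  m0 <- null_ratio_moments(k = 6, s = 120, a = 0)
  expect_equal(m0$var_r, 5 / 120)
})

test_that("Monte-Carlo moments of r match the null formulas within 3 SE", {
  set.seed(401)
  n <- 1e5
  for (a in c(0.5, 2)) {
    k <- 5; s <- 200
    r <- rpolya(n, k, s, a) * k / s
    mom <- null_ratio_moments(k, s, a)
    se_mean <- sd(r) / sqrt(n)
    expect_lt(abs(mean(r) - 1), 3 * se_mean)
    v <- var(r)
    se_var <- sqrt((mean((r - mean(r))^4) - v^2) / n)
    expect_lt(abs(v - mom$var_r), 3 * se_var)
  }
})
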