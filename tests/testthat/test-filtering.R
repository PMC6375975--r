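# Two-viewpoint testing, multiple-testing correction, backbone extraction
# and its summary metrics.

test_that("toy star p-values match the enumeration oracle from both viewpoints", {
  tt <- link_pvalues(fig1_fixture(), a = 1)
  expect_equal(attr(tt, "L"), 6)
  hub <- tt[tt$viewpoint == "A", ]
  expect_equal(hub$p_value[hub$target == "B"], 0.4, tolerance = 1e-12)
  expect_equal(hub$p_value[hub$target %in% c("C", "D")], rep(2 / 3, 2),
               tolerance = 1e-12)
  leaves <- tt[tt$viewpoint != "A", ]
  expect_equal(leaves$p_value, rep(1, 3))
})

test_that("a = 0 test table equals binomial survival values", {
  net <- generate_polya_network(10, k = 5, s = 100, a_true = 0, seed = 3)
  tt <- link_pvalues(net, a = 0, mode = "exact")
  src <- tt[tt$side == "out", ]
  expect_equal(src$p_value,
               pbinom(src$w - 1, src$s, 1 / src$k, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("directed links are tested from the source out-urn and target in-urn", {
  net <- weighted_network(
    data.frame(source = c("A", "A", "B"), target = c("B", "C", "C"),
               weight = c(6, 2, 4)),
    directed = TRUE
  )
  tt <- link_pvalues(net, a = 1)
  ab_out <- tt[tt$source == "A" & tt$target == "B" & tt$side == "out", ]
  expect_equal(c(ab_out$k, ab_out$s), c(2, 8))   # A's out-urn
  ab_in <- tt[tt$source == "A" & tt$target == "B" & tt$side == "in", ]
  expect_equal(c(ab_in$k, ab_in$s), c(1, 6))     # B's in-urn (degree 1 -> p = 1)
  expect_equal(ab_in$p_value, 1)
  cc_in <- tt[tt$target == "C" & tt$source == "B" & tt$side == "in", ]
  expect_equal(c(cc_in$k, cc_in$s), c(2, 6))
})

test_that("mode handling: exact rejects real weights, approx rejects a = 0", {
  real_net <- weighted_network(
    data.frame(source = c("A", "A"), target = c("B", "C"), weight = c(1.5, 2.5))
  )
  expect_error(link_pvalues(real_net, a = 1, mode = "exact"),
               class = "polya_mode_error")
  expect_error(link_pvalues(real_net, a = 0), class = "polya_mode_error")
  tt <- link_pvalues(real_net, a = 1)   # auto routes real weights to approx
  expect_true(all(tt$mode[tt$k > 1] == "approx"))
})

test_that("backbone extraction: uncorrected and Bonferroni on the toy star", {
  b1 <- extract_backbone(fig1_fixture(), a = 1, alpha_u = 0.5, correction = "none")
  expect_equal(nrow(b1$links), 1)
  expect_equal(b1$links$source, "A")
  expect_equal(b1$links$target, "B")
  b2 <- extract_backbone(fig1_fixture(), a = 1, alpha_u = 0.05,
                         correction = "bonferroni")
  expect_equal(nrow(b2$links), 0)
  expect_error(extract_backbone(fig1_fixture(), a = 1, alpha_u = 1.5),
               class = "polya_domain_error")
})

test_that("backbones are nested in a and corrections are ordered", {
  net <- generate_polya_network(40, k = 8, s = 400, a_true = 1, seed = 21)
  keys <- function(b) paste(b$links$source, b$links$target)
  prev <- NULL
  for (a in c(0, 0.5, 1, 2, 4)) {
    cur <- keys(extract_backbone(net, a = a, alpha_u = 0.05,
                                 correction = "bonferroni"))
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
  bon <- keys(extract_backbone(net, a = 1, alpha_u = 0.05, "bonferroni"))
  fdr <- keys(extract_backbone(net, a = 1, alpha_u = 0.05, "fdr"))
  unc <- keys(extract_backbone(net, a = 1, alpha_u = 0.05, "none"))
  expect_true(all(bon %in% fdr))
  expect_true(all(fdr %in% unc))
})

test_that("a link's tests depend only on its endpoints' degree and strength", {
  net <- generate_polya_network(20, k = 6, s = 300, a_true = 1, seed = 31)
  b <- extract_backbone(net, a = 1, alpha_u = 0.05, correction = "bonferroni")
  kept <- paste(b$links$source, b$links$target)
  all_keys <- paste(net$source, net$target)
  drop_key <- setdiff(all_keys, kept)[1]
  # removing a rejected link from an unrelated node leaves other nodes' tests
  # untouched; only L (and so the threshold) changes
  sub <- net[all_keys != drop_key, ]
  tt_full <- link_pvalues(net, a = 1, directed = TRUE)
  tt_sub <- link_pvalues(weighted_network(sub, directed = TRUE), a = 1)
  dropped_src <- strsplit(drop_key, " ")[[1]][1]
  same <- tt_full$viewpoint != dropped_src & tt_full$side == "out"
  m <- merge(tt_full[same, c("source", "target", "p_value")],
             tt_sub[tt_sub$side == "out", c("source", "target", "p_value")],
             by = c("source", "target"))
  expect_equal(m$p_value.x, m$p_value.y)
})

test_that("summary fractions are bounded, exhaustive at the extremes, monotone", {
  net <- generate_polya_network(30, k = 6, s = 300, a_true = 1, seed = 41)
  full <- extract_backbone(net, a = 0, alpha_u = 0.999, correction = "none")
  if (nrow(full$links) == full$parent_n_links) {
    expect_equal(unlist(backbone_summary(full)), c(fraction_links = 1,
                                                   fraction_nodes = 1,
                                                   fraction_strength = 1))
  }
  empty <- extract_backbone(net, a = 50, alpha_u = 0.05, correction = "bonferroni")
  if (nrow(empty$links) == 0) {
    expect_equal(unlist(backbone_summary(empty)), c(fraction_links = 0,
                                                    fraction_nodes = 0,
                                                    fraction_strength = 0))
  }
  fr <- sapply(c(0, 0.5, 1, 2, 4), function(a) {
    unlist(backbone_summary(extract_backbone(net, a = a, alpha_u = 0.05,
                                             correction = "bonferroni")))
  })
  expect_true(all(apply(fr, 1, function(x) all(diff(x) <= 1e-12))))
})

test_that("top-B Jaccard: identity, disjointness, and the 2/4 worked case", {
  net <- weighted_network(
    data.frame(source = "Z", target = paste0("L", 1:5), weight = c(5, 4, 3, 2, 1))
  )
  mk <- function(targets) {
    structure(list(
      links = tibble::tibble(source = "Z", target = targets,
                             weight = net$weight[match(targets, net$target)],
                             p_value_min = 0),
      a = 1, alpha_u = 0.05, correction = "none", L = 10, threshold = 0.05,
      directed = FALSE, weight_kind = "integer",
      parent_n_nodes = 6, parent_n_links = 5, parent_strength = 15
    ), class = "polya_backbone")
  }
  expect_equal(top_b_jaccard(net, mk(paste0("L", 1:3))), 1)
  expect_equal(top_b_jaccard(net, mk(c("L1", "L2", "L4"))), 0.5)
  expect_equal(top_b_jaccard(net, mk(character(0))), 0)
})

test_that("tidiers summarize backbones consistently", {
  b <- extract_backbone(fig1_fixture(), a = 1, alpha_u = 0.5, correction = "none")
  td <- tidy(b)
  expect_named(td, c("source", "target", "weight", "p_value_min"))
  g <- glance(b)
  expect_equal(g$n_links, 1)
  expect_equal(g$fraction_strength, 0.5)
  expect_equal(g$L, 6)
})

test_that("disparity comparison agrees almost everywhere at a = 1, large s", {
  net <- generate_polya_network(40, k = 10, s = 5000, a_true = 1, seed = 51)
  cmp <- compare_disparity(net, a = 1, alpha_u = 0.05)
  expect_gte(attr(cmp, "agreement"), 0.99)
  expect_setequal(unique(cmp$quadrant) %in%
                    c("both_accept", "both_reject", "polya_only",
                      "disparity_only"), TRUE)
})
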