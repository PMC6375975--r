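---
title: "The Pólya urn filter: model, calibration, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Pólya urn filter: model, calibration, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyafilter)
```

## The null model

A weighted network assigns each node a degree $k$ (number of links) and a
strength $s$ (summed weight). The filter asks, link by link: is this
weight surprising, given how its endpoint spreads strength across its
links? The null model is a Pólya urn: the focal link is 1 red ball among
$k-1$ black ones, the node makes $s$ draws, and each draw returns $a$
extra balls of the drawn colour. The number of red draws — the weight
that lands on the focal link — is Beta-Binomial,

$$\mathbb{P}(w \mid k, s, a) = \binom{s}{w}
  \frac{B(1/a + w,\; (k-1)/a + s - w)}{B(1/a,\; (k-1)/a)},$$

and the p-value is the survival probability $\pi = \mathbb{P}(X \ge w)$.
The reinforcement parameter $a \ge 0$ is the only tunable of the null:

* $a = 0$: no reinforcement, Binomial$(s, 1/k)$ — the classical
  random-allocation null;
* $a = 1$ with $s \gg k$: the disparity filter $(1 - w/s)^{k-1}$;
* $a \to \infty$: the first draw decides everything and
  $\pi \to 1/k$, so no link can clear a corrected threshold.

$a$ is a non-negative *real*; the urn story extends through the
Beta-Binomial formula, and profiles are scanned continuously.

Every link is tested twice — once from each endpoint's urn; a directed
link uses the source's out-urn $(k_\text{out}, s_\text{out})$ and the
target's in-urn $(k_\text{in}, s_\text{in})$. This symmetric directed
convention mirrors the undirected two-viewpoint rule. The family of tests
has size $L = 2 \times \text{links}$, and the default protocol keeps a
link when its smaller p-value is strictly below the Bonferroni threshold
$\alpha_u / L$. A degree-1 viewpoint is an urn with no black balls: its
weight is a point mass at $s$ and its p-value is 1, so only the
higher-degree endpoint of a leaf link can validate it, and leaf–leaf
links are never retained. Benjamini–Hochberg FDR (step-up over all $L$
p-values, a link kept on any discovery) and uncorrected thresholds are
offered as alternatives.

Backbones are nested: raising $a$ at fixed $\alpha_u$ only removes links.
This monotonicity is what `sweep_a()` exploits to reach a target sparsity
by bisection on a grid of resolution $10^{-2}$ in $\log_{10} a$ (backbone
size is a step function of $a$, so a grid value is returned rather than a
root of a continuous function).

## Numerical evaluation

All Beta and binomial factors are computed as sums of log-gamma terms;
direct Beta functions overflow once strengths reach the $10^5$–$10^6$
range common in trade or traffic data. Survival probabilities sum
whichever tail has fewer terms and complement only the larger tail, so
small p-values (the ones that decide significance) are never formed as
$1 - \Sigma$ with catastrophic cancellation.

Mode selection (`mode = "auto"`): exact tail summation for integer
weights with viewpoint strength up to $10^5$; beyond that, and for
real-valued weights, the large-strength closed form

$$\pi \approx \frac{1}{\Gamma(1/a)} \left(1 - \frac{w}{s}\right)^{(k-1)/a}
  \left(\frac{wk}{sa}\right)^{1/a - 1}$$

is used, clipped to $[0, 1]$ since the asymptotic expression is not a
normalized probability. The crossover threshold is this package's choice;
the two forms agree closely wherever p-values are small — which is where
retention decisions are made — but the closed form saturates at 1 for
weights far below a node's average, so it should not be read as an
approximation of large p-values (the shipped tests measure a difference
of 0.16 at $w = 50$, $k = 10$, $s = 10^4$, $a = 2$, against $8 \times
10^{-4}$ at $w = 5000$). At $a = 1$ the closed form is evaluated directly
as $(1 - w/s)^{k-1}$, making it bit-identical to the disparity filter.
The still-simpler kernel in the ratio $r = wk/s$ alone,
$\pi \approx e^{-r/a} (r/a)^{1/a-1} / \Gamma(1/a)$, is available as
`mode = "ratio"` on explicit request; it captures the filter's soft
preference for links carrying more than their node's average weight
($r > 1$), with null mean $\mu_r = 1$ and variance
$\frac{k-1}{s}\frac{k + as}{a + k}$.

Real-valued weights cannot enter the exact urn test; they are routed
through the closed form, which depends on the data only through the rate
$w/s$. At $a = 0$ there is no asymptotic form, so real weights cannot be
tested there at all and the package says so rather than rescaling
silently.

## Choosing the reinforcement parameter

Three criteria are implemented.

**Sweeping.** Fix the sparsity you want (e.g. 5% of nodes) and let
monotonicity find the smallest $a$ that achieves it.

**Maximum likelihood.** `fit_a_ml()` maximizes the allocation likelihood
on the $\log a$ scale with bounded 1-D optimization (tolerance $10^{-3}$;
default bracket $10^{-3}$–$10^{2}$ inside the hard limits
$10^{-4}$–$10^{3}$; a maximum at the bracket edge raises a warning rather
than failing silently — homogeneous networks legitimately push toward
$a = 0$). The fitted $a_\text{ML}$ is the "nullest" family member: links
significant at that $a$ are remarkable *beyond* the network's own
self-reinforcement.

Two likelihood forms are available, and the distinction matters.
`polya_log_likelihood(truncation = "none")` is the plain sum of marginal
Beta-Binomial log-masses over all viewpoints with $k \ge 2$ (degree-1
viewpoints are point masses and contribute zero; for the 4-node toy star
at $a = 1$ the value is $\log 0.2 + 2 \log(4/15)$). But a weighted
network, by definition, contains no zero-weight links: observing the
network at all conditions every weight to be positive. Fitting the
unconditioned marginals to such data is biased toward small $a$ —
strongly so when reinforcement is high and zero allocations would have
been common. `truncation = "positive"` therefore models each viewpoint's
*joint* allocation (Dirichlet-multinomial with concentration $1/a$ per
link) conditioned on all of its observed links being positive; the
conditioning constant $\mathbb{P}(\text{all } k \text{ categories} > 0)$
is computed by inclusion–exclusion over forced-zero category sets. This
conditioned form is the correctly specified likelihood of the data the
filter actually sees, and it is what `fit_a_ml()` maximizes by default.
On networks generated from the null it recovers the generating $a$
without bias across the whole range the package is tested on
($a_\text{true}$ from 0.5 to 5); the unconditioned composite remains
available for profiling and matches the documented closed-form values.
For real-valued weights a pseudo-likelihood built from the asymptotic
kernel is used and flagged.

An undirected link contributes from both endpoints — the same family as
the test table. This double-counting makes the likelihood a composite
rather than a joint density over the whole network; it is consistent for
a common $a$ because every per-viewpoint term is correctly specified.

**Salience.** `link_salience()` computes, for every node, a
shortest-path tree over its reachable set with link distance $1/w$
(heavier links are shorter — the standard proximity-to-distance
conversion), and scores each link by the fraction of nodes whose tree
contains it. Tree computation uses Dijkstra predecessors from `igraph`,
whose deterministic predecessor choice fixes tie-breaking; ties are
measure-zero for generic weights. `optimality_measures()` scans $a$ and
reports $O_1 = J \cdot \langle S(a) \rangle$ and
$O_2 = F_n(a) \cdot \langle S(a) \rangle$, where $\langle S(a) \rangle$
is the mean parent-network salience of retained links, $F_n$ the retained
node fraction, and $J$ the Jaccard similarity between the weight
assignments of parent and backbone. Because backbone weights are a subset
of the parent's, the weighted Jaccard reduces to the retained-strength
fraction, which is how $J$ is computed; a set-based Jaccard would ignore
the weights it is meant to compare. Empty backbones are scored
$\langle S \rangle = 0$, $O_1 = O_2 = 0$ by convention.

The equivalence scaling
$c = \sqrt{\frac{a_1 + k/d}{a_1 + k}\,\frac{a_1 s + k}{a_1 s + k/d}}$
(`equivalence_scale()`) quantifies the trade-off the family allows: a
backbone extracted at $a_1$ can be approximately reproduced at
$a_2 = d a_1 \ge a_1$ by shrinking the null-compatibility region around
$\mu_r = 1$ by the factor $c \le 1$ — reinforcement tolerance and
statistical significance are two ends of the same dial.

## The synthetic generator

`generate_polya_network()` is the package's test bed. Each allocating
node draws $p \sim \text{Dirichlet}(1/a, \ldots, 1/a)$ over its $k$ links
and $w \sim \text{Multinomial}(s, p)$, so the marginal weight on any
single link is exactly the Beta-Binomial null ($a = 0$ degenerates to the
equal-probability multinomial). Topologies are deliberately restricted to
allocations with a single informative side: directed out-stubs (each
source allocates over private targets of in-degree 1), undirected star
forests (hubs allocate over leaves), and a shared-target variant for
topology-mixing tests. A joint undirected generative model in which
*both* endpoints' urns hold simultaneously is not defined by the null,
and inventing one would contaminate the recovery tests.

A multinomial category can be drawn at zero; zero means "no link", so the
generated network omits it. By the neutrality of the Dirichlet, the
retained weights are again exactly Dirichlet-multinomial on the realized
degree with the same concentration — the null holds exactly for the
network the filter sees, which is what makes the truncation-aware
likelihood above recover $a_\text{true}$ and the goodness-of-fit tests
legitimate (absent links are counted as zero draws when frequencies are
compared to the p.m.f.).

Planted departures (`signal =`) overwrite a designated link's weight and
reallocate the remainder over the node's other links by the same
Dirichlet-multinomial mechanism, keeping the unplanted links exactly
null-distributed. Given a `seed`, output is bit-reproducible.

Study conditions used by the shipped tests, chosen once as typical
counting-scale data: recovery runs use 300 sources with $k = 10$,
$s = 1000$ (6000 tests per network, 20 networks per generating $a$);
nestedness runs use 50 networks of 40 sources ($k = 6$, $s = 300$) over a
geometric grid of $a$; the disparity correspondence uses $s = 10^4$ so
that the large-strength regime applies; planted-signal fixtures plant
weight 850 of 1000 at $a_\text{true} = 1$, far past the Bonferroni
quantile. The Monte-Carlo check of the null moments of $r$ uses $10^5$
draws at $k = 5$, $s = 200$.

What the generator does *not* emulate: realistic degree distributions,
weight correlations between neighbouring nodes, or reciprocity in
directed networks. Passing tests demonstrate the statistical machinery —
exactness of the null, error control, parameter recovery — not that any
particular empirical network is well described by a single global $a$.

## Known limitations

* Exact p-values cost $O(\min(w, s - w))$ log-gamma evaluations per test;
  strengths beyond $10^5$ are automatically routed to the closed form.
* The inclusion–exclusion constant in the truncated likelihood alternates
  in sign; for very small strengths combined with large $a$ and large $k$
  it can lose precision (it is floored at $10^{-300}$). In that regime
  zeros dominate anyway and degrees collapse.
* The directed convention (out-urn of the source, in-urn of the target)
  and the both-endpoint likelihood composition are declared package
  choices among defensible alternatives; estimates on directed data
  should be compared under the same convention.
* `sweep_a` returns grid values; two targets inside the same step of the
  backbone-size staircase return the same $a$.
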