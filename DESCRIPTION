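Package: polyafilter
Title: Polya Urn Filtering of Weighted Network Backbones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical validation of link weights in heterogeneous weighted
    networks against a self-reinforcing Beta-Binomial (Polya urn) null model
    tunable by a single reinforcement parameter. Provides numerically stable
    exact and asymptotic p-values, Bonferroni/FDR-corrected backbone
    extraction, maximum-likelihood and salience-based criteria for fixing the
    reinforcement parameter, the disparity filter as a limiting case, and a
    seeded Dirichlet-multinomial network generator for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
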