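Package: micinet
Title: Bayesian Network Structure Learning by Mutual Information and
    Conditional Independence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns the structure of discrete Bayesian networks with a
    single-pass algorithm that ranks candidate edges by mutual information,
    resolves triangles with G-squared conditional-independence tests, and
    orients edges through MDL-score immorality (v-structure) tests, reporting
    the subset of orientations fixed by those tests as a trustworthy network.
    Includes forward sampling from known networks, benchmark metrics
    (missed/wrong edges, trustworthy-network accuracy), a hill-climbing MDL
    baseline, minimum-entropy (MDLP) discretization for continuous expression
    data, and readers/writers for a JSON network format, a BIF subset, and DOT.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
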