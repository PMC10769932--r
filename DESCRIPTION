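Package: indriflex
Title: Vocal Sequence Flexibility Analysis for Indri Songs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies flexibility in the phrase-concatenation syntax of
    indri (Indri indri) songs. Individual song contributions are encoded as
    sequences of phrase-type tokens (SU, DP2-DP6); the package computes
    token-level Jaro similarities and the full pairwise matrix, the dyadic
    within/between distance dataset and its mixed-model analysis, a
    normalized-diversity statistic with per-group duet covariation tests,
    and first-order Markov transition matrices with analytic and
    simulation-based entropy rates. A synthetic-corpus generator with
    controllable Markov structure, category effects, and duet coupling
    makes every stage testable without field data. Readers for Praat
    TextGrid annotations and delimited corpus tables are included, along
    with an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    lme4,
    emmeans,
    kernlab,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    lmerTest,
    pbkrtest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
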