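Package: adspread
Title: Simulated Alzheimer-Type Degradation and Staging of Structural
    Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Couples a weighted susceptible-infected spreading process to
    streamline-count decay on structural connectomes, with a fitted
    normal-aging drift per connection. Provides a synthetic-connectome
    generator with known ground truth, link-wise best-subset aging
    regressions, forward simulation of yearly disease stages, inverse
    fitting of the disease parameters (seed region, infection rate,
    degradation rate) by exhaustive grid search, centrality-based feature
    extraction, random-forest ranked radial-kernel classification with
    cross-validation, and per-stage significance testing with false
    discovery rate control to locate the earliest detectable stage of
    network degradation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    dplyr,
    e1071,
    igraph,
    jsonlite,
    ranger,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
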