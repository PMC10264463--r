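Package: qrgwas
Title: Quantile-Regression Genome-Wide Association Scans in Simulated Composite Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of composite plant-breeding populations with
    known quantitative trait loci (QTLs), and per-marker genome-wide
    association scans by quantile regression (check-loss fit via an
    interior-point linear program, rank-score hypothesis tests) and by
    ordinary least squares with principal-component correction for
    population structure. Includes linkage-disequilibrium decay analysis to
    calibrate QTL detection windows at the r2 = 0.20 threshold, false
    discovery rate control by q-values, and a scenario engine that estimates
    QTL detection power and false-positive rates across population sizes,
    heritabilities and genetic architectures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    ggplot2,
    generics,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
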