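Package: adaptarch
Title: Inferring Adaptive Architecture from the Evolution of Phenotypic Variance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward Wright-Fisher simulation of quantitative traits under
    stabilizing selection with an optimum shift, and inference of the adaptive
    architecture (oligogenic versus polygenic) from the temporal dynamics of
    phenotypic variance. Provides founder-haplotype and genetic-map generators,
    gamma-distributed effect sizes with a negative frequency-effect correlation,
    single- and multi-trait (modular) Gaussian fitness regimes, variance-change
    statistics (F = sigma_x^2 / sigma_1^2), simulation-based power analyses for
    evolve-and-resequence designs, and an RNA-seq expression-variance stage
    (TMM-normalized log-CPM, per-gene variance ratios, jackknife confidence
    intervals, and a partition of the squared coefficient of variation into
    technical and biological components) exercisable end to end on synthetic
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    edgeR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
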