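Package: qmricart
Title: Quantitative MRI Analysis of Femoral Cartilage T2 and Thickness
Version: 0.1.0
Authors@R:
    person("Quantitative Cartilage", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pipeline for longitudinal quantitative MRI analysis of femoral
    condylar cartilage: per-voxel T2 relaxometry by monoexponential fitting of
    multi-echo spin-echo signals, mesh-based cartilage thickness mapping as the
    minimum distance from the subchondral bone surface to the cartilage
    surface, partition of the condyles into anatomical volumes of interest with
    anterior sub-regions and superficial/deep layers, robust per-region
    aggregation with outlier exclusion, medial-lateral ratios, annualized
    change rates, and a repeated-measures statistical ladder (Shapiro-Wilk
    gate, Friedman or repeated-measures ANOVA omnibus, Wilcoxon signed-rank or
    paired t post-hoc tests with Bonferroni correction and effect sizes). A
    synthetic bi-condylar knee phantom generator with Rician noise and
    configurable longitudinal progression makes every stage testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
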