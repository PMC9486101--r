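Package: wheatmqtl
Title: Meta-QTL Analysis for Yield Traits Under Contrasting Water Regimes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for meta-analysis of published quantitative trait loci
    (QTL) in biparental crop populations, built around the durum wheat
    yield-component literature. Confidence intervals of collected QTL are
    standardized from population design, size and phenotypic variance
    explained; QTL are projected from their source linkage maps onto a
    consensus map by homothetic (shared flanking marker) interpolation;
    per-chromosome meta-QTL are estimated either by best contiguous
    partitioning (ten or fewer QTL) or by an EM-fitted Gaussian mixture
    with fixed per-observation variances, with the number of components
    chosen by a majority vote over five information criteria (AIC, AICc,
    AIC3, BIC, AWE). Additional stages detect genomic regions where
    irrigated- and rainfed-regime meta-QTL overlap, map meta-QTL intervals
    to candidate genes with an expression filter, and simulate multi-study
    QTL catalogs with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    S4Vectors,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
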