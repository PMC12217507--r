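Package: paralogGI
Title: Genetic-Interaction Scoring for Multiplex CRISPR Paralog Knockout Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores genetic interactions between paralog gene pairs from
    multiplex CRISPR knockout screen read counts. Implements delta log fold
    change (dLFC) scoring against an additive single-knockout expectation,
    Z-transformed dLFC (ZdLFC) against a single-Gaussian null fitted after
    Tukey-fence outlier removal, and a supervised rescaled dLFC (RdLFC)
    anchored to a positive-control synthetic-lethal reference set. Includes
    screen preprocessing (pseudocount, depth normalization, log2 fold change,
    Cohen's D quality control), a two-component Gaussian mixture null for
    Z-transformed LFC, cross-screen hit-consistency evaluation (Jaccard
    coefficients, overlap strata, sequence-identity and expression checks),
    and a negative-binomial simulator of multi-screen count data with planted
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
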