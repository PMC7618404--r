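Package: alleleaugment
Title: Multi-Omic Characterization of Gain-of-Function Kinase Alleles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the "augmented wild-type" signature of a
    gain-of-function kinase allele from multi-omic evidence. Implements
    negative-binomial Wald differential expression with median-of-ratios
    normalization and trend-shrunk dispersions, cross-condition
    significance-pattern clustering with direction-concordance and
    amplitude-ratio statistics, preranked gene-set enrichment and
    hypergeometric over-representation analysis, AP-MS label-free
    interactome filtering with exclusive and preferential binder calling,
    and PS-in/PS-out conformer classification of predicted-structure
    ensembles from predicted-aligned-error matrices. A synthetic-data
    generator with known ground truth makes every stage testable by
    parameter recovery, and a pipeline driver runs the whole analysis
    from a single YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    DESeq2,
    fgsea
Config/testthat/edition: 3
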