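Package: crdscan
Title: Cis-Regulatory Domain Calling, QTL Mapping and Causal Inference for
    Population-Scale Chromatin Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls cis-regulatory domains (CRDs) from interindividual
    correlation of chromatin peak activity (e.g. H3K27ac ChIP-seq), quantifies
    per-individual domain activity, tests domains and genes for differential
    activity between conditions with a negative-binomial Wald test, maps
    cis-QTLs with a permutation pass and beta approximation (including
    forward-backward conditional signals, genotype-by-condition interaction
    QTLs and regulatory trait concordance), associates domains with genes, and
    classifies variant-domain-gene triplets as causal, reactive or independent
    with Gaussian Bayesian networks and bootstrap confidence. Includes a
    synthetic cohort generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
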