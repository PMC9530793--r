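Package: hologreml
Title: Host Genetics x Gut Microbiome Variance Decomposition via Multi-Kernel REML
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates heritability, microbiability and host-genetics x
    gut-microbiome interaction effects on quantitative traits from SNP
    genotypes and 16S OTU abundance profiles. Builds genomic (VanRaden and
    GCTA dialects), microbial, and Hadamard interaction relationship
    kernels; fits multi-kernel linear mixed models by average-information
    REML with EM fallback; selects fixed-covariate sets by BIC; screens
    candidate genera by microbiome-wide association (F-tests under an
    optional polygenic random effect) and by divergent-group Wilcoxon
    rank-sum tests. Includes PLINK 1 binary and GCTA GRM readers/writers,
    OTU-table handling with genus aggregation and alpha diversity, and a
    synthetic hologenome generator with known ground-truth variance
    fractions for estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan
Suggests:
    biomformat,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
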