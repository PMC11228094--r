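Package: orchardGS
Title: Genomic Selection Toolkit for Pedigreed Clonal Crop Breeding
    Populations with Multi-Platform Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing pedigreed breeding populations of clonally
    propagated crops genotyped on more than one marker platform. Merges
    genotype panels that share a physical reference coordinate system,
    phases and imputes full-sib family genotypes against phased parents
    with a dynamic-programming parental-origin model and a window-voting
    parental-origin classifier, computes pedigree- and runs-of-homozygosity
    based inbreeding coefficients and ROH islands, runs linear mixed model
    genome-wide association scans (single-SNP and sliding SNP-set kernel
    tests) with kinship and principal-component correction, and fits
    GBLUP genomic prediction models with additive and dominance kernels
    and a directional inbreeding (inbreeding depression) fixed effect.
    A fully instrumented breeding-population simulator with retained
    ground truth supports accuracy evaluation and parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
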