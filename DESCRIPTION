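Package: cohortval
Title: Technical Validation of Cohort Genotyping Archives
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the technical validation of cohort-scale genotyping
    resources: call-rate and sex-concordance quality control, technical
    replicate reproducibility (Bland-Altman and kinship), robust pairwise
    kinship estimation with relationship-degree classification, supervised
    model-based ancestry projection, HLA imputation accuracy and
    concordance scoring, a configurable polygenic risk score engine with
    HLA diplotype interaction terms, cross-platform per-SNP concordance,
    and rare deleterious variant prioritization in gene panels. A seeded
    synthetic cohort generator produces every input with known ground
    truth for parameter-recovery testing, so the whole pipeline can be
    exercised end-to-end without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    GenomeInfoDb,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
biocViews: QualityControl, SNP, Genetics, VariantAnnotation
RoxygenNote: 7.3.3
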