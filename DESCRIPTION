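Package: wecmap
Title: Regional Heritability Mapping and Genomic Prediction with Preselected
    Sequence Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mixed-model toolkit for quantitative-trait analysis in
    multi-breed livestock populations: REML variance-component estimation
    (average-information algorithm with eigendecomposition and low-rank fast
    paths), single-variant GWAS with a Wald test against a pedigree
    relationship matrix, regional heritability mapping (RHM) with sliding
    marker windows and a boundary-corrected likelihood-ratio test, scenario
    based selection of sequence variants (GWAS, RHM, or GWAS-within-RHM) with
    LD pruning, and two-component GBLUP in which a genomic relationship
    matrix from the selected variants is fitted alongside the standard array
    GRM. Prediction accuracy and dispersion bias are evaluated by replicated
    sire-family cross-validation. Includes a gene-dropping simulator of
    multi-breed half-sib populations with nested marker panels (50k subset of
    HD subset of sequence) and realistic linkage disequilibrium, plus PLINK
    BED/BIM/FAM input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
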