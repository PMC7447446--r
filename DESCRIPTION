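Package: proteoQTL
Title: Kinship-Aware Mapping of Protein and RNA Quantitative Trait Loci
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A population-scale proteogenomic QTL pipeline for cohorts of
    cell lines with matched genotypes, RNA-seq and isobaric-label (TMT)
    proteomics. Provides quality control and normalisation of peptide and
    protein-group intensity matrices (line filtering, polymorphic-peptide
    removal, recurrence filtering, batch median scaling, quantile
    normalisation to a reference line), latent-factor estimation for hidden
    confounders, linear mixed-model cis and trans association scans with a
    genotype-derived kinship random effect, permutation-based
    Beta-approximated empirical p-values with hierarchical
    Bonferroni/Benjamini-Hochberg adjustment, cross-layer replication and
    mechanistic classification of protein QTLs, variance-component
    decomposition of molecular traits, X-chromosome-inactivation scoring
    from allele-specific counts, and a fully synthetic cohort generator
    with ground truth for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    lme4,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Proteomics, Genetics, SNP, GeneExpression, Normalization,
    StatisticalMethod
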