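Package: corecurator
Title: Germplasm Core-Collection Curation and Diversity Analysis from SNP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing genebank germplasm collections from
    biallelic SNP genotypes of inbred accessions: quality control and
    duplicate-accession detection via simple-matching similarity,
    population-structure summaries (genotype PCA, Evanno delta-k from
    STRUCTURE log-probability series, membership-threshold assignment),
    per-SNP AMOVA-based Phi-PT divergence scans with permutation tests,
    linkage-disequilibrium analysis (r-squared, Fisher exact tests, a
    power-transform significance threshold from unlinked marker pairs, and
    structure-corrected logistic-regression LD with principal-component
    covariates), Q+K mixed-linear-model association scans with
    Benjamini-Hochberg FDR control, and stepwise PIC-maximization selection
    of mini-core accession sets. Includes a generator of structured synthetic
    genotype data (Balding-Nichols subpopulation model with admixture,
    genetic-map-aware LD, planted duplicates and QTL) used throughout the
    test suite, and a configurable end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    MASS,
    knitr,
    rmarkdown
Config/testthat/edition: 3
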