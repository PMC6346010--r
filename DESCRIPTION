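Package: genocurate
Title: Genotype-Based Curation of Genebank Germplasm Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identify duplicated germplasm accessions within and across
    genebank collections from biallelic SNP genotype matrices. Implements
    pairwise percent identity-by-state (pIBS) over homozygous complete
    sites, threshold grouping of identical accessions, replicate-based
    genotyping error-rate estimation, seed-lot heterogeneity detection,
    hierarchical clustering and outlier screening, supervised
    geographic-origin assignment by allele-frequency posteriors, a
    forward curation protocol for newly genotyped accessions against a
    genotype database, and a synthetic panel generator with truth tables
    for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
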