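# genocurate

Genotype-based curation of genebank germplasm collections.

Genebanks conserve millions of seed accessions, and a large share of
them are unintentional duplicates: the same genotype shared between
collections, re-numbered, or re-collected and stored under a new
identifier. genocurate finds those duplicates from biallelic SNP
genotypes (GBS, DArTseq or any platform that yields a genotype matrix),
calibrates the decision threshold with biological replicates, detects
mixed seed lots, imputes missing geographic passport data, and screens
newly genotyped accessions against a genotype database so redundancy
stops accumulating.

## The statistics at the core

**Identity by state.** For accessions *i*, *j*, over the *n* sites with
no missing data and a homozygous call in both,

    pIBS_ij = (1/n) * Σ_x  1[ g_ix == g_jx ]

Pairs with pIBS ≥ 0.99 are declared identical and grouped by single
linkage (connected components); the 1% allowance covers the combined
error of two independent genotyping runs.

**Error rate from biological replicates.** For the *n* accessions with
replicates, with *m_i* replicates each,

    error = (1/n) * Σ_i [ (1/m_i) * Σ_j (1 - pIBS_ij) ]

Replicate pairs far below the threshold are mixups or heterogeneous
seed lots, not genotyping error; the report separates the raw and
screened estimates and lists the anomalous pairs.

**Origin assignment.** Accessions with known origin act as learning
samples; a query's homozygous calls are scored under per-region
pseudocounted allele frequencies (product-Bernoulli, uniform prior) and
assigned only when the top posterior reaches 0.6.

See `vignettes/genebank-curation.Rmd` for the full model description,
defaults and their rationale, and known limitations.

## Worked example

Simulate a three-genebank panel of a two-lineage selfing species
(300 accessions, 5,000 markers, replicates, planted duplicates and two
mixed seed lots), then run the curation pipeline:

```r
library(genocurate)

panel <- simulate_panel(sim_config(seed = 42))
orig  <- subset(panel$records, sample_type == "original")$accession_id

pm     <- pibs_matrix(panel$geno[orig, ])
groups <- group_duplicates(pm, threshold = 0.99)
genebank_summary(groups, panel$records)
#> # A tibble: 3 × 5
#>   genebank_id total unique_count percent_unique percent_duplicated
#>   <chr>       <int>        <int>          <dbl>              <dbl>
#> 1 GB1           150          101           67.3               32.7
#> 2 GB2           100           76           76                 24
#> 3 GB3            50           42           84                 16
```

A third to a sixth of each collection is redundant — each genebank's
accessions collapse into fewer distinct genotypes (`unique_count`).
Replicates put a number on the genotyping noise behind the 99% rule:

```r
error_rate(panel$geno, panel$records)
#> <error_rate_report> 30 accessions, 30 replicate pairs
#>   error rate (all pairs):    2.2659%
#>   error rate (screened):     0.5288%  [2 anomalous pair(s) at pIBS < 0.99 removed]
```

The two screened pairs are the panel's planted sample mixups; after
removing them the error rate (~0.5%) sits well under the 1% the
threshold allows. Cross-genebank sharing comes from the same grouping:

```r
sharing_summary(groups, panel$records)
#> <sharing_summary> 300 accessions -> 149 globally unique groups
#> # A tibble: 7 × 4
#>   genebanks   n_genebanks n_groups percent
#>   <chr>             <int>    <int>   <dbl>
#> 1 GB1                   1       46   30.9
#> 2 GB2                   1       27   18.1
#> 3 GB3                   1       15   10.1
#> 4 GB1+GB2               2       34   22.8
#> 5 GB1+GB3               2       12    8.05
#> 6 GB2+GB3               2        6    4.03
#> 7 GB1+GB2+GB3           3        9    6.04
```

Only 149 of 300 accessions are globally unique; the remaining cells
show which combinations of genebanks hold the shared genotypes. From
here, `detect_heterogeneity()` inspects suspicious accessions,
`assign_origin()` fills missing passport data, and
`geno_db()`/`batch_curate()` screen newly collected material before it
is accessioned. Every result is a tibble (or has `tidy()`/`glance()`
methods) and the main ones have `autoplot()` methods.

A command-line wrapper over the same functions ships in
`inst/cli/genocurate.R` (subcommands `simulate`, `ibs`, `dedupe`,
`share`, `hetero`, `cluster`, `assign`, `error-rate`, `curate`, ...).

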