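---
title: "Genotype-based curation of genebank collections: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-based curation of genebank collections: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genocurate)
```

Germplasm collections accumulate duplicates: the same wild-collected
genotype gets shared between genebanks, re-numbered, re-collected at the
same site, and stored again under a fresh identifier. genocurate
implements a genotype-level curation pipeline for such collections built
on reduced-representation SNP data (GBS, DArTseq): it finds accessions
that are the same genotype, calibrates the identity threshold with
biological replicates, detects mixed seed lots, imputes missing
geographic passport data, and screens newly genotyped material against a
database before it is accessioned. This vignette documents the models,
the defaults and why they are what they are, and what the validation on
synthetic panels does and does not demonstrate.

## The identity model

All analyses run on an accession × marker matrix of biallelic SNP calls
in four states: homozygous reference, heterozygous, homozygous
alternate, missing. For accessions $i$ and $j$, percent identity by
state is

$$\mathrm{pIBS}_{ij} = \frac{1}{n}\sum_{x=1}^{n}
  \mathbb{1}\left[g_{ix} = g_{jx}\right],$$

where the sum runs over the $n$ *comparable* sites of the pair: sites
with no missing call and a homozygous call in **both** accessions. The
restriction to homozygous complete sites is the right statistic for a
highly selfing species genotyped at low coverage: residual or miscalled
heterozygotes and missing calls carry almost no identity information but
plenty of noise, so they are excluded pair by pair (`pibs_pair()`,
`pibs_matrix()`). Two consequences worth knowing:

* pIBS is invariant to allele polarity. Swapping which allele is called
  reference at any marker leaves every coefficient unchanged, so the
  arbitrary REF/ALT polarity of reference-free GBS pipelines is
  harmless.
* $n$ varies per pair. With sparse data a pair can have too few
  comparable sites to mean anything; below `min_sites` the coefficient
  is reported as undefined (`NA`) and never treated as identity.

**`min_sites` default 500.** A floor is required — two accessions
overlapping at 20 sites will occasionally agree at all 20 — and 500
homozygous complete sites bounds the standard error of pIBS near 1 at
about $\sqrt{0.01 \cdot 0.99 / 500} \approx 0.004$, comfortably below
the decision margin at the 0.99 threshold. Panels of the scale the
package targets typically yield thousands of comparable sites per pair.

## Declaring duplicates

Accessions with $\mathrm{pIBS} \ge 0.99$ are declared identical
(`group_duplicates()`, threshold inclusive, applied to full-precision
values). The 1% allowance absorbs the combined sequencing, alignment and
sampling error of two independent measurements, and is checked — not
assumed — via biological replicates (below).

Grouping uses single linkage: groups are connected components of the
graph whose edges are pairs at or above the threshold. When A~B and B~C
pass but A–C sits at 98.5%, components are the only closure under which
"belongs to the group" is well defined; the alternative of complete
linkage (every pair above threshold) is offered as an option for
stricter reporting. Raising the threshold can only split groups, never
merge them, which makes threshold sensitivity analyses monotone and easy
to read. Group numbering and the choice of representative
(lexicographically smallest id, or earliest collection date when dates
are available) are deterministic so that reports are stable across runs.

Per-genebank uniqueness (`genebank_summary()`) counts, for each
genebank, the distinct groups its own accessions fall into; the
cross-genebank Venn cells (`sharing_summary()`) assign each globally
unique group the set of genebanks its members span. Venn-cell
percentages are reported on an explicit denominator — the number of
globally unique groups — because percentages on shifting denominators
are a classic source of irreproducible summary tables.

## Error calibration from biological replicates

For accession $i$ with $m_i$ replicated samples, the error rate is the
nested mean

$$\widehat{e} = \frac{1}{n}\sum_{i=1}^{n}
  \frac{1}{m_i}\sum_{j=1}^{m_i}\left(1 - \mathrm{pIBS}_{ij}\right),$$

the outer mean running over the $n$ accessions with replicates
(`error_rate()`). The inner mean first protects against a single
heavily replicated accession dominating the estimate.

Replicate pairs far below the identity threshold are not genotyping
error: they are sample mixups, contamination, or a heterogeneous seed
lot, and leaving them in inflates the estimate by an order of magnitude.
The report therefore carries both numbers — `error_rate_all` and
`error_rate_clean` after screening pairs with pIBS < 0.99 — plus the
list of anomalous pairs for follow-up (re-sequencing, seed-lot
inspection). An accession whose every replicate pair is anomalous drops
out of the screened outer mean entirely.

## Seed-lot heterogeneity

`detect_heterogeneity()` reruns identity grouping restricted to the
samples of one accession (original, seed splits, replicates). One
component means a homogeneous lot; two or more mean distinct genotypes
are stored under one identifier, and the sub-group membership tells the
curator which seeds belong together. Bulked or mixed tissue also
inflates heterozygous calls, so the report raises an
elevated-heterozygosity flag when the samples' mean heterozygosity
exceeds `het_cutoff` (default 0.10; normal inbred samples run well
below this, and the same cutoff drives the hold decision in forward
curation).

## Origin assignment

Missing geographic passport data is imputed with a supervised
classifier: accessions with known origin are learning samples, and each
query is scored under per-region allele frequencies
(`assign_origin()`). Markers are screened first (missing fraction ≤
0.30, MAF ≥ 0.05 — rare and sparse markers carry unstable frequency
estimates). Per region, alt-allele frequencies use a Laplace
pseudocount of 1 on each allele count so that a query carrying an
allele unseen in a small learning set is penalised, not annihilated.
The likelihood of a query is a product of Bernoulli terms over its
homozygous non-missing screened calls — for inbred material the
homozygous state is a single draw, so a Hardy–Weinberg $p^2$ model
would double-count every observation. Posteriors follow from a uniform
prior over regions; a query is assigned only when its top posterior
reaches 0.6, reflecting that geographic groups are not fully isolated
and a coin-flip posterior should not mint passport data. Below the
cutoff, or below `min_informative` usable sites, the query stays
unassigned with an explicit reason.

A full admixture model (MCMC over ancestry proportions) is deliberately
out of scope: used as a supervised classifier with labeled learning
samples, it reduces to exactly this decision rule, and the closed-form
model is testable to machine precision.

## Clustering and outliers

`build_tree()` clusters accessions agglomeratively on the distance
$1 - \mathrm{pIBS}$ and returns an `ape` tree. Average linkage (UPGMA)
is the default — a reasonable general-purpose choice for ultrametric-ish
population data — with single and complete available; the choice is
cosmetic for the pipeline since no curation decision is taken from the
tree. Clustering is the quick first look: it shows lineage structure
and exposes material that belongs to no cluster. `flag_outliers()`
formalises that with two nearest-neighbour rules: a distributional rule
(nearest-neighbour distance above the 0.75 quantile plus 3 IQR of the
panel's nearest-neighbour distances) and an absolute rule (distance
above 0.45, roughly the mismatch level of an unrelated genome —
misidentified species, inter-lineage hybrids). Undefined pairs count as
distance 1, so an accession comparable with nothing is always flagged.

## Forward curation

`curate_new()` implements the intake protocol for newly genotyped
material: (1) heterozygosity above `het_cutoff` → hold for purification
by single seed descent, database untouched; (2) otherwise match in two
stages — against every group representative, then against all members
of groups whose representative came within `candidate_margin` (0.02) of
the threshold — and a best match at or above threshold makes the query
a duplicate of that group; (3) otherwise register it under a fresh
global id. The member-level confirmation matters because under single
linkage a group's representative need not itself be within 1% of every
member. Database writes are atomic (staged directory renamed into
place) and the store is plain text: genotype CSV, metadata CSV, JSON
registry. `batch_curate()` processes a new collection in sorted-id
order against the evolving database, so duplicates *within* the new
collection are caught, not only matches to stored material.

## The synthetic panel generator

`simulate_panel()` emulates the statistical structure the pipeline
assumes, with truth tables for every claim a test makes:

* **Two deeply diverged lineages.** A configurable fraction of markers
  (default 0.3) is fixed-different between lineages; the rest segregate
  within lineages with MAF drawn uniformly from 0.05–0.5. This
  reproduces the bimodal pIBS distribution of a structured selfing
  species: a between-lineage mode far below the within-lineage mode.
* **Founders and duplicates.** Fully homozygous founder genotypes
  (default 90 per lineage) are resampled with replacement by the
  genebank collections (default 150 + 100 + 50 = 300 accessions), so
  true duplicates arise within and across genebanks with naturally
  varying group sizes and roughly half the panel redundant — the
  curation burden the tool exists for. The truth partition is the
  founder assignment.
* **Noise.** Each sample is an independent measurement of its founder:
  symmetric homozygote flips, heterozygote miscalls (default 2%,
  keeping sample heterozygosity in the low single digits), and
  per-marker missingness drawn from Beta(1.5, 8.5) — mean 15% with a
  long right tail, so the ≤50% missing-data filter has something to do.
* **Error parameterisation.** The generator's `error_rate` (default
  0.005) is defined on the scale the pipeline measures: the expected
  discordance between two independent measurements of the same
  genotype, i.e. the replicate $1-\mathrm{pIBS}$ that the error
  estimator reports and that the 99% threshold is set against ("1%
  error ↔ 99% identity"). Internally each copy flips with the per-call
  probability $q$ solving $2q(1-q) = \varepsilon$. Parameterising by
  the per-copy flip rate instead would make the same numeric value mean
  double the observable discordance and would put default duplicates
  exactly on the decision boundary — a knife-edge that belongs in a
  stress test, not in the default conditions.
* **Planted pathologies.** A configurable number of accessions are
  two-founder seed mixtures emitting per-seed samples (heterogeneity
  ground truth), and a configurable number of biological replicates are
  silently drawn from the wrong founder (mixup ground truth for the
  anomaly screen).

What the generator does **not** emulate: linkage disequilibrium between
markers (sites are independent), coalescent within-lineage relatedness
(founders are exchangeable draws, so there are no "near-duplicate"
sibling genotypes), locus-specific error profiles, and allele-frequency
clines within regions. Passing tests therefore demonstrate correctness
of the statistics and decision rules under the assumed noise model, not
robustness to cryptic relatedness — on real data, accessions related at
just below the threshold (e.g. sibling lines) remain the user's
judgement call, which is why every report carries the underlying
coefficients.

## Numerical choices and degenerate inputs

* Threshold comparisons (`pibs >= threshold`, posterior `>= 0.6`,
  missingness `<= 0.5`) are inclusive and applied to full-precision
  doubles; nothing is rounded before a decision.
* Undefined pIBS (below `min_sites`) never links a pair, never enters a
  tree (tree building stops with guidance instead), and counts as
  maximal distance in outlier screening.
* An accession with zero observed calls has undefined heterozygosity,
  reported as such — not as zero.
* Fisher's exact test for allelic-tag disassociation
  (`allelic_tag_test()`) is two-sided with the direction checked on the
  odds ratio: only significant *disassociation* (OR < 1; the two tags
  mutually exclusive across inbred individuals, as expected for the two
  alleles of one locus) qualifies a tag pair as a biallelic SNP.
  Degenerate tables (a tag absent everywhere) are rejected with a
  reason rather than tested. Whether to treat the test as one- or
  two-sided is genuinely open; two-sided is the conservative default
  and the decision direction is enforced separately.
* Grouping ties (which group gets number 1, who represents it) are
  broken lexicographically; with `representative = "date"`, missing
  dates sort last and ties fall back to the id.

## Validation scale

The test suite validates the oracle equivalences exhaustively at small
scale (all 2×2 Fisher tables up to 12 individuals; identity matrices
against a naive double loop on 10 × 50 panels over 100 seeds) and the
full pipeline on the generator's default conditions — 300 accessions ×
5,000 markers, pairwise error 0.005, ten independent seeds — chosen as
a realistic desk-scale stand-in for a multi-genebank collection:
duplicate-pair sensitivity, absence of cross-lineage merges,
heterogeneity detection, origin-assignment accuracy at 1,000 markers,
and agreement of the error estimator with realized replicate
discordance. `scripts/acceptance.R` recomputes the same quantities from
scratch at any seed.

## Known limitations

* Identity is genotype identity at the assayed markers; epigenetic or
  structural variation between "duplicates" is invisible by design.
* The origin classifier assumes the labeled regions are exhaustive: a
  query from an unrepresented region will be assigned to the nearest
  represented one whenever its posterior clears the cutoff.
* The genotype database is single-writer; concurrent curation needs
  external locking.
* Group membership under single linkage can chain through intermediate
  genotypes on dense near-threshold data; the complete-linkage option
  and the per-pair tables are the audit trail.
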