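pibs_tbl_of <- function(...) {
  # build a pair table from "A-B" = value entries
  entries <- list(...)
  ij <- strsplit(names(entries), "-", fixed = TRUE)
  tibble::tibble(
    accession_i = vapply(ij, `[`, "", 1),
    accession_j = vapply(ij, `[`, "", 2),
    n_sites = 1000L,
    pibs = unlist(entries)
  )
}

test_that("single-linkage grouping is transitive closure; complete linkage is stricter", {
  tb <- pibs_tbl_of(`A-B` = 0.995, `B-C` = 0.992, `A-C` = 0.985)
  g <- group_duplicates(tb, threshold = 0.99)
  expect_equal(dplyr::n_distinct(g$group_id), 1)
  expect_setequal(g$accession_id, c("A", "B", "C"))

  gc <- group_duplicates(tb, threshold = 0.99, linkage = "complete")
  expect_equal(dplyr::n_distinct(gc$group_id), 2)

  none <- group_duplicates(pibs_tbl_of(`A-B` = 0.9, `B-C` = 0.5, `A-C` = 0.2))
  expect_equal(dplyr::n_distinct(none$group_id), 3)
  expect_true(all(none$representative))
})

test_that("undefined pairs never link and grouping is deterministic", {
  tb <- pibs_tbl_of(`A-B` = NA, `A-C` = 0.995, `B-C` = NA)
  g <- group_duplicates(tb)
  expect_equal(g$group_id[g$accession_id == "A"], g$group_id[g$accession_id == "C"])
  expect_false(g$group_id[g$accession_id == "B"] %in%
                 g$group_id[g$accession_id == "A"])
  # group numbering follows the smallest member id; representative is that id
  expect_equal(g$group_id[g$accession_id == "A"], 1)
  expect_true(g$representative[g$accession_id == "A"])
  expect_false(g$representative[g$accession_id == "C"])
})

test_that("earliest collection date can take over representative choice", {
  tb <- pibs_tbl_of(`A-B` = 0.999)
  rec <- simple_records(c("A", "B"))
  rec$collection_date <- c("2012-06-01", "1955-01-01")
  g <- group_duplicates(tb, records = rec, representative = "date")
  expect_true(g$representative[g$accession_id == "B"])
})

test_that("raising the threshold only refines the partition", {
  set.seed(31)
  ids <- sprintf("A%02d", 1:12)
  pairs <- t(combn(ids, 2))
  tb <- tibble::tibble(accession_i = pairs[, 1], accession_j = pairs[, 2],
                       n_sites = 1000L,
                       pibs = stats::runif(nrow(pairs), 0.9, 1.0))
  thresholds <- c(0.92, 0.95, 0.98, 0.995)
  parts <- lapply(thresholds, function(th) {
    g <- group_duplicates(tb, threshold = th)
    stats::setNames(g$group_id, g$accession_id)[ids]
  })
  for (k in seq_along(parts)[-1]) {
    lo <- parts[[k - 1]]; hi <- parts[[k]]
    # same group at the higher threshold implies same group at the lower one
    same_hi <- outer(hi, hi, "==")
    same_lo <- outer(lo, lo, "==")
    expect_true(all(same_lo[same_hi]))
  }
})

test_that("grouping at 1.0 on error-free simulated data recovers the planted partition", {
  p <- simulate_panel(small_config(seed = 5, error_rate = 0, het_rate = 0,
                                   missing_beta = c(0, 1)))
  orig <- p$truth$samples[p$truth$samples$sample_type == "original", ]
  pm <- pibs_matrix(p$geno[orig$sample_id, ], min_sites = 100)
  g <- group_duplicates(pm, threshold = 1.0)
  got <- stats::setNames(g$group_id, g$accession_id)[orig$sample_id]
  truth <- stats::setNames(orig$founder_id, orig$sample_id)[orig$sample_id]
  expect_equal(outer(got, got, "=="), outer(truth, truth, "=="),
               ignore_attr = TRUE)
})

test_that("per-genebank summaries reproduce printed-count arithmetic", {
  # 568 accessions collapsing to 421 within-genebank groups -> 74.12% unique
  mk <- function(gb, total, unique) {
    sizes <- c(rep(1L, unique - 1L), total - unique + 1L)
    tibble::tibble(
      group_id = paste0(gb, rep(seq_along(sizes), sizes)),
      accession_id = paste0(gb, "_", seq_len(total)),
      genebank = gb)
  }
  g1 <- mk("WGRC", 568, 421); g2 <- mk("PAU", 187, 86)
  groups <- dplyr::bind_rows(g1, g2) |>
    dplyr::mutate(group_id = match(group_id, unique(group_id)))
  rec <- tibble::tibble(accession_id = groups$accession_id,
                        genebank_id = groups$genebank)
  s <- genebank_summary(groups[c("group_id", "accession_id")],
                        validate_records(rec))
  expect_equal(s$percent_unique[s$genebank_id == "WGRC"], 100 * 421 / 568,
               tolerance = 1e-12)
  expect_equal(round(s$percent_unique[s$genebank_id == "WGRC"], 2), 74.12)
  expect_equal(round(s$percent_duplicated[s$genebank_id == "WGRC"], 2), 25.88)
  expect_equal(round(s$percent_unique[s$genebank_id == "PAU"], 2), 45.99)
  expect_equal(round(s$percent_duplicated[s$genebank_id == "PAU"], 2), 54.01)
  expect_equal(s$percent_unique + s$percent_duplicated, c(100, 100))

  # no duplicates -> 100% unique
  solo <- tibble::tibble(group_id = 1:4, accession_id = letters[1:4])
  s0 <- genebank_summary(solo, validate_records(
    tibble::tibble(accession_id = letters[1:4], genebank_id = "X")))
  expect_equal(s0$percent_unique, 100)

  expect_error(genebank_summary(solo, validate_records(
    tibble::tibble(accession_id = letters[1:3], genebank_id = "X"))),
    "without metadata")
})

test_that("sharing summary partitions global groups into Venn cells that sum up", {
  groups <- tibble::tibble(
    group_id = c(1, 1, 2, 2, 2, 3, 4, 5),
    accession_id = c("w1", "p1", "w2", "c1", "p2", "w3", "c2", "p3"))
  rec <- validate_records(tibble::tibble(
    accession_id = groups$accession_id,
    genebank_id = c("WGRC", "PAU", "WGRC", "CIMMYT", "PAU", "WGRC", "CIMMYT", "PAU")))
  sh <- sharing_summary(groups, rec)
  expect_equal(sh$total_unique_groups, 5)
  expect_equal(sum(sh$cells$n_groups), sh$total_unique_groups)
  expect_equal(sh$cells$n_groups[sh$cells$genebanks == "PAU+WGRC"], 1)
  expect_equal(sh$cells$n_groups[sh$cells$genebanks == "CIMMYT+PAU+WGRC"], 1)
  expect_equal(sum(sh$cells$percent), 100)

  # disjoint single-genebank groups populate only exclusive cells
  solo <- tibble::tibble(group_id = 1:3, accession_id = c("a", "b", "c"))
  rec3 <- validate_records(tibble::tibble(accession_id = c("a", "b", "c"),
                                          genebank_id = c("X", "Y", "Z")))
  sh3 <- sharing_summary(solo, rec3)
  expect_true(all(sh3$cells$n_genebanks == 1))
  expect_equal(sum(sh3$cells$n_groups), 3)
})

test_that("group members always sum to the accession count", {
  p <- simulate_panel(small_config(seed = 8))
  orig <- p$truth$samples$sample_id[p$truth$samples$sample_type == "original"]
  g <- group_duplicates(pibs_matrix(p$geno[orig, ], min_sites = 100))
  expect_equal(nrow(g), length(orig))
  expect_equal(sum(table(g$group_id)), length(orig))
  expect_equal(anyDuplicated(g$accession_id), 0)
})

test_that("seed-lot heterogeneity splits mixed accessions into the planted sub-groups", {
  p <- simulate_panel(small_config(seed = 13))
  het <- p$truth$heterogeneous
  rep <- detect_heterogeneity(p$geno, p$records, het$accession_id[1],
                              min_sites = 100)
  expect_identical(rep$verdict, "heterogeneous")
  expect_equal(rep$n_subgroups, 2)
  # seed splits divide by their true founder (6 + 6); accession row joins its own founder
  seeds <- p$truth$samples[p$truth$samples$parent_accession_id %in%
                             het$accession_id[1] &
                             !is.na(p$truth$samples$parent_accession_id), ]
  sub <- tidy(rep)
  seed_groups <- sub$sub_group[match(seeds$sample_id, sub$sample_id)]
  expect_equal(as.vector(table(seed_groups)), c(6, 6), ignore_attr = TRUE)
  split <- split(seeds$founder_id, seed_groups)
  expect_true(all(vapply(split, function(f) length(unique(f)) == 1, logical(1))))

  # a homogeneous accession stays in one group
  homo <- setdiff(p$records$accession_id[p$records$sample_type == "original"],
                  het$accession_id)
  reps <- setdiff(
    p$records$accession_id[p$records$sample_type == "biological_replicate"],
    p$truth$anomalous_replicates$sample_id)
  parent <- p$records$parent_accession_id[match(reps[1], p$records$accession_id)]
  rep2 <- detect_heterogeneity(p$geno, p$records, parent, min_sites = 100)
  expect_identical(rep2$verdict, "homogeneous")

  expect_error(detect_heterogeneity(p$geno, p$records, homo[1], min_sites = 100),
               "at least 2")
})

test_that("bulk mixtures raise the elevated-heterozygosity flag", {
  set.seed(21)
  f1 <- sample(c(0L, 2L), 600, replace = TRUE)
  f2 <- sample(c(0L, 2L), 600, replace = TRUE)
  bulk <- mix_bulk(f1, f2)
  g <- gm_from_rows(list(f1, bulk), ids = c("ACC", "ACC_s1"))
  rec <- tibble::tibble(accession_id = c("ACC", "ACC_s1"), genebank_id = "GB",
                        sample_type = c("original", "seed_split"),
                        parent_accession_id = c(NA, "ACC"))
  rep <- detect_heterogeneity(g, rec, "ACC", min_sites = 50)
  expect_true(rep$elevated_het)
})
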