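tb3 <- tibble::tibble(
  accession_i = c("A", "A", "B"), accession_j = c("B", "C", "C"),
  n_sites = 1000L, pibs = c(0.99, 0.5, 0.5)
)

test_that("closest accessions join first and duplicates sit as sibling leaves", {
  tr <- build_tree(tb3)
  expect_s3_class(tr, "phylo")
  # the cherry is {A, B}
  cherry <- ape::prop.part(tr)
  parts <- lapply(cherry, function(idx) sort(tr$tip.label[idx]))
  expect_true(list(c("A", "B")) %in% parts)
})

test_that("the deepest bipartition separates the planted lineages", {
  p <- simulate_panel(small_config(seed = 17))
  orig <- p$truth$samples[p$truth$samples$sample_type == "original", ]
  pm <- pibs_matrix(p$geno[orig$sample_id, ], min_sites = 100)
  tr <- build_tree(pm)
  # cut the dendrogram into two clusters; they must match lineage labels
  d <- stats::as.dist(pibs_wide(pm, "distance"))
  k2 <- stats::cutree(stats::hclust(d, "average"), k = 2)
  tab <- table(k2, orig$lineage[match(names(k2), orig$sample_id)])
  expect_equal(min(rowSums(tab > 0)), 1)  # each cluster is one lineage
  expect_equal(dim(tab), c(2L, 2L))
})

test_that("undefined distances stop tree building with guidance", {
  tb <- tb3
  tb$pibs[2] <- NA
  expect_error(build_tree(tb), "undefined")
})

test_that("tree topology is invariant to leaf input order", {
  g <- rand_gm(8, 120, p_missing = 0, p_het = 0, seed = 23)
  pm1 <- pibs_matrix(g, min_sites = 10)
  perm <- c(4, 1, 7, 2, 8, 3, 6, 5)
  pm2 <- pibs_matrix(g[perm, ], min_sites = 10)
  t1 <- build_tree(pm1); t2 <- build_tree(pm2)
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[1], 0)
})

test_that("outlier screening flags alien and hybrid genotypes but not clean panels", {
  set.seed(41)
  m <- 800
  l1 <- sample(c(0L, 2L), m, replace = TRUE)
  l2 <- sample(c(0L, 2L), m, replace = TRUE)
  jitter <- function(v, k) { i <- sample(m, k); v[i] <- 2L - v[i]; v }
  rows <- c(lapply(1:5, function(i) jitter(l1, 10)),
            lapply(1:5, function(i) jitter(l2, 10)))
  clean <- gm_from_rows(rows)
  expect_equal(nrow(flag_outliers(pibs_matrix(clean, min_sites = 10))), 0)

  # a random (misidentified-species) genotype matches nothing
  alien <- sample(c(0L, 2L), m, replace = TRUE)
  g2 <- gm_from_rows(c(rows, list(alien)))
  fo <- flag_outliers(pibs_matrix(g2, min_sites = 10))
  expect_true("A11" %in% fo$accession_id)

  # a synthetic hybrid-like intermediate is nearest-neighbour isolated
  hybrid <- ifelse(stats::runif(m) < 0.5, l1, l2)
  g3 <- gm_from_rows(c(rows, list(hybrid)))
  fo3 <- flag_outliers(pibs_matrix(g3, min_sites = 10), max_nn_dist = 0.2)
  expect_true("A11" %in% fo3$accession_id)
})

test_that("origin posteriors are normalised, order-invariant and match closed-form Bayes", {
  # two regions with engineered pseudocounted frequencies:
  # G1 all hom-alt, G2 all hom-ref at 10 complete markers, 5 learners each
  n_mark <- 10
  g1 <- lapply(1:5, function(i) rep(2L, n_mark))
  g2 <- lapply(1:5, function(i) rep(0L, n_mark))
  query <- rep(0L, n_mark)
  g <- gm_from_rows(c(g1, g2, list(query)),
                    ids = c(sprintf("E%d", 1:5), sprintf("W%d", 1:5), "Q"))
  rec <- simple_records(accessions(g))
  rec$origin_region <- c(rep("east", 5), rep("west", 5), NA)
  oa <- assign_origin(g, rec, threshold = 0.6, min_maf = 0.05,
                      max_missing = 0.5, min_informative = 5)
  # pseudocounted alt frequency: east (10+1)/12, west 1/12; query all hom-ref
  p_e <- (1 / 12)^n_mark
  p_w <- (11 / 12)^n_mark
  expect_equal(oa$post_west, p_w / (p_e + p_w), tolerance = 1e-12)
  expect_equal(oa$post_east + oa$post_west, 1, tolerance = 1e-12)
  expect_identical(oa$assigned_group, "west")

  # marker order must not matter
  perm <- sample(n_mark)
  g_perm <- geno_matrix(g$calls[, perm])
  oa2 <- assign_origin(g_perm, rec, threshold = 0.6, min_maf = 0.05,
                       max_missing = 0.5, min_informative = 5)
  expect_equal(oa2$post_west, oa$post_west)
})

test_that("weak posteriors leave accessions unassigned with a reason", {
  # nearly identical groups: posterior hovers near 0.5, below the 0.6 rule
  set.seed(3)
  base <- lapply(1:8, function(i) sample(c(0L, 2L), 40, replace = TRUE))
  g <- gm_from_rows(c(base, list(sample(c(0L, 2L), 40, replace = TRUE))),
                    ids = c(sprintf("L%d", 1:8), "Q"))
  rec <- simple_records(accessions(g))
  rec$origin_region <- c(rep(c("north", "south"), 4), NA)
  oa <- assign_origin(g, rec, threshold = 0.6, min_maf = 0.01,
                      max_missing = 1, min_informative = 5)
  if (is.na(oa$assigned_group)) {
    expect_identical(oa$reason, "max_posterior_below_threshold")
    expect_lt(max(oa$post_north, oa$post_south), 0.6)
  } else {
    expect_gte(max(oa$post_north, oa$post_south), 0.6)
  }

  # too few informative sites -> unassigned with the sites reason
  sparse <- g
  sparse$calls["Q", ] <- NA_integer_
  sparse$calls["Q", 1] <- 0L
  sparse <- geno_matrix(sparse$calls)
  oa2 <- assign_origin(sparse, rec, min_informative = 5, min_maf = 0.01,
                       max_missing = 1)
  expect_identical(oa2$reason, "insufficient_sites")
  expect_true(is.na(oa2$assigned_group))
})

test_that("assignment accuracy climbs to certainty as informative sites grow", {
  accs <- c(`50` = 0, `200` = 0, `1000` = 0)
  for (m in c(50, 200, 1000)) {
    p <- simulate_panel(sim_config(
      seed = 100 + m, n_markers = as.integer(m), n_founders = 20L,
      collections = tibble::tibble(genebank_id = "GB1", n_accessions = 60L,
                                   p_lineage1 = 0.5),
      n_replicated = 0L, n_heterogeneous = 0L, n_anomalous_replicates = 0L))
    rec <- p$records
    set.seed(m)
    mask <- sample(rec$accession_id, 15)
    truth <- rec$origin_region[match(mask, rec$accession_id)]
    rec$origin_region[rec$accession_id %in% mask] <- NA
    oa <- assign_origin(p$geno, rec, unlabeled_ids = mask, min_informative = 3)
    accs[as.character(m)] <- mean(oa$assigned_group == truth, na.rm = TRUE)
  }
  expect_true(all(diff(accs) >= 0) || accs[["1000"]] == 1)
  expect_equal(accs[["1000"]], 1)
})

test_that("assign_origin validates its learning-set preconditions", {
  g <- rand_gm(6, 30, seed = 2)
  rec <- simple_records(accessions(g))
  rec$origin_region <- c("east", NA, NA, NA, NA, NA)
  expect_error(assign_origin(g, rec), ">= 2 labeled origin groups")
  rec$origin_region <- c("east", "west", NA, NA, NA, NA)
  expect_error(assign_origin(g, rec), ">= 2 labeled accessions")
})
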