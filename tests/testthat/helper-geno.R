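# fixture builders and independent oracles, all generated in code

`%||%` <- function(a, b) if (is.null(a)) b else a

# genotype matrix from a list of integer call vectors (rows = accessions)
gm_from_rows <- function(rows, ids = NULL, markers = NULL) {
  m <- do.call(rbind, rows)
  if (is.null(ids)) ids <- sprintf("A%02d", seq_len(nrow(m)))
  if (is.null(markers)) markers <- sprintf("M%03d", seq_len(ncol(m)))
  dimnames(m) <- list(ids, markers)
  geno_matrix(m)
}

# random four-state matrix
rand_gm <- function(n, m, p_missing = 0.1, p_het = 0.1, seed = 1) {
  set.seed(seed)
  calls <- matrix(sample(c(0L, 2L), n * m, replace = TRUE), n, m)
  calls[matrix(runif(n * m) < p_het, n, m)] <- 1L
  calls[matrix(runif(n * m) < p_missing, n, m)] <- NA_integer_
  dimnames(calls) <- list(sprintf("A%02d", 1:n), sprintf("M%03d", 1:m))
  geno_matrix(calls)
}

# brute-force double-loop pIBS oracle, independent of the package's
# cross-product implementation
pibs_oracle <- function(gm, min_sites = 1) {
  g <- gm$calls
  ids <- rownames(g)
  out <- list()
  for (i in seq_len(nrow(g) - 1)) {
    for (j in (i + 1):nrow(g)) {
      n <- 0L; match <- 0L
      for (x in seq_len(ncol(g))) {
        a <- g[i, x]; b <- g[j, x]
        if (!is.na(a) && !is.na(b) && a != 1L && b != 1L) {
          n <- n + 1L
          if (a == b) match <- match + 1L
        }
      }
      out[[length(out) + 1]] <- data.frame(
        accession_i = ids[i], accession_j = ids[j], n_sites = n,
        pibs = if (n >= min_sites) match / n else NA_real_)
    }
  }
  do.call(rbind, out)
}

# exact two-sided Fisher P by hypergeometric enumeration over the
# conditional distribution with fixed margins
fisher_oracle_p <- function(both, a_only, b_only, neither) {
  m <- both + a_only        # individuals carrying tag A
  n <- b_only + neither     # individuals not carrying tag A
  k <- both + b_only        # individuals carrying tag B
  support <- max(0, k - n):min(m, k)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(both, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# minimal metadata table for a set of accession ids
simple_records <- function(ids, genebank = "GB1") {
  tibble::tibble(accession_id = ids, genebank_id = genebank,
                 sample_type = "original",
                 parent_accession_id = NA_character_,
                 origin_region = NA_character_,
                 collection_date = NA_character_)
}

# small, fast simulation configuration used across tests
small_config <- function(seed = 1, n_replicated = 6L, n_heterogeneous = 1L,
                         n_anomalous_replicates = 1L, ...) {
  sim_config(
    seed = seed, n_markers = 1200L, n_founders = 25L,
    collections = tibble::tibble(genebank_id = c("GB1", "GB2"),
                                 n_accessions = c(40L, 30L),
                                 p_lineage1 = c(0.5, 0.5)),
    n_replicated = n_replicated, n_heterogeneous = n_heterogeneous,
    n_anomalous_replicates = n_anomalous_replicates,
    ...
  )
}
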