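#' Filter markers on missing-data fraction
#'
#' Population-level SNP filtering: retain exactly the markers whose
#' missing-call fraction is less than or equal to `max_missing` (the cutoff
#' is inclusive). The accession set is unchanged. The default 0.5 is the
#' usual screen applied before clustering a GBS panel.
#'
#' @param x A [geno_matrix()].
#' @param max_missing Maximum tolerated per-marker missing fraction, in
#'   `[0, 1]`. Default `0.5`.
#' @param min_maf Optional minimum minor-allele frequency; `NULL` (default)
#'   disables the MAF screen. Markers with undefined MAF (no observed
#'   calls) are removed when a MAF screen is requested.
#' @return A filtered `geno_matrix`; the numbers retained/removed are
#'   reported via `message()`.
#' @export
filter_markers <- function(x, max_missing = 0.5, min_maf = NULL) {
  stopifnot(inherits(x, "geno_matrix"),
            is.numeric(max_missing), max_missing >= 0, max_missing <= 1)
  keep <- x$marker_info$missing_frac <= max_missing
  if (!is.null(min_maf)) {
    stopifnot(min_maf >= 0, min_maf <= 1)
    keep <- keep & !is.na(x$marker_info$maf) & x$marker_info$maf >= min_maf
  }
  message(sprintf("filter_markers: retained %d of %d markers (removed %d)",
                  sum(keep), length(keep), sum(!keep)))
  if (!any(keep)) warning("no markers retained", call. = FALSE)
  x[, keep]
}

#' Per-accession and per-marker summary statistics
#'
#' Heterozygosity is the fraction of het calls among an accession's
#' non-missing calls; an accession with no observed calls gets `NA` with
#' `het_defined = FALSE` (undefined, not zero). Marker missingness is the
#' fraction of accessions with a missing call at that marker.
#'
#' @param x A [geno_matrix()].
#' @return A list with tibbles `accessions` (`accession_id`, `n_calls`,
#'   `n_missing`, `het_frac`, `het_defined`) and `markers` (the
#'   `marker_info` table, including `missing_frac` and `maf`).
#' @export
sample_stats <- function(x) {
  stopifnot(inherits(x, "geno_matrix"), nrow(x$calls) > 0, ncol(x$calls) > 0)
  obs <- rowSums(!is.na(x$calls))
  het <- rowSums(x$calls == 1L, na.rm = TRUE)
  acc <- tibble::tibble(
    accession_id = rownames(x$calls),
    n_calls = as.integer(unname(obs)),
    n_missing = as.integer(ncol(x$calls) - unname(obs)),
    het_frac = unname(ifelse(obs > 0, het / obs, NA_real_)),
    het_defined = unname(obs > 0)
  )
  list(accessions = acc, markers = x$marker_info)
}

#' Test a tag pair for allelic disassociation
#'
#' In a reduced-representation pipeline on inbred material, the two
#' alternate sequence tags of a true biallelic SNP are mutually exclusive
#' within an individual: each (homozygous) individual carries one tag or
#' the other, rarely both. A Fisher exact test on the 2x2 co-occurrence
#' table of tag presence detects this disassociation; pairs significant at
#' `P <= alpha` in the disassociation direction (odds ratio < 1) qualify
#' as biallelic SNPs, all others are rejected.
#'
#' @param tag_a,tag_b Logical vectors of per-individual tag presence, same
#'   length (>= 2).
#' @param alpha Significance cutoff; default `0.001`.
#' @return A one-row tibble: `n`, the 2x2 cell counts (`both`, `a_only`,
#'   `b_only`, `neither`), `p_value`, `odds_ratio`, `verdict`
#'   (`"biallelic_snp"` or `"rejected"`) and `reason`.
#' @export
allelic_tag_test <- function(tag_a, tag_b, alpha = 0.001) {
  stopifnot(is.logical(tag_a), is.logical(tag_b),
            length(tag_a) == length(tag_b), length(tag_a) >= 2)
  both <- sum(tag_a & tag_b); a_only <- sum(tag_a & !tag_b)
  b_only <- sum(!tag_a & tag_b); neither <- sum(!tag_a & !tag_b)
  res <- tibble::tibble(
    n = length(tag_a), both = both, a_only = a_only,
    b_only = b_only, neither = neither,
    p_value = NA_real_, odds_ratio = NA_real_,
    verdict = "rejected", reason = NA_character_
  )
  if (!any(tag_a) || !any(tag_b)) {
    res$reason <- "degenerate: a tag is absent from every individual"
    return(res)
  }
  tab <- matrix(c(both, a_only, b_only, neither), 2, 2)
  ft <- stats::fisher.test(tab)
  res$p_value <- ft$p.value
  res$odds_ratio <- unname(ft$estimate)
  disassociated <- ft$p.value <= alpha && res$odds_ratio < 1
  if (disassociated) {
    res$verdict <- "biallelic_snp"
  } else {
    res$reason <- if (ft$p.value > alpha) "not significant" else
      "significant association, not disassociation"
  }
  res
}

#' Run the allelic-tag test over a table of tag pairs
#'
#' @param pairs A data frame with list-columns or matrix-style columns is
#'   not required; instead supply a tibble with columns `pair_id`,
#'   `tag_a` and `tag_b` where the tag columns are list-columns of logical
#'   vectors, or a long tibble with columns `pair_id`, `individual`,
#'   `tag_a`, `tag_b`.
#' @param alpha Significance cutoff, default 0.001.
#' @return A tibble with one row per pair, the [allelic_tag_test()] output
#'   plus `pair_id`.
#' @export
allelic_tag_test_all <- function(pairs, alpha = 0.001) {
  pairs <- tibble::as_tibble(pairs)
  if (is.list(pairs$tag_a) && !is.data.frame(pairs$tag_a)) {
    out <- purrr::map2(pairs$tag_a, pairs$tag_b, allelic_tag_test, alpha = alpha)
    return(dplyr::bind_cols(pairs["pair_id"], dplyr::bind_rows(out)))
  }
  pairs |>
    dplyr::group_by(.data$pair_id) |>
    dplyr::group_modify(~ allelic_tag_test(as.logical(.x$tag_a),
                                           as.logical(.x$tag_b), alpha = alpha)) |>
    dplyr::ungroup()
}
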