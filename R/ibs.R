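#' Pairwise percent identity-by-state
#'
#' pIBS between accessions i and j is the fraction of comparable SNP sites
#' at which the two carry the same homozygous genotype. Comparable sites
#' are those with no missing data and a homozygous call in *both*
#' accessions; sites that are missing or heterozygous in either accession
#' are excluded pair by pair, not globally. With fewer than `min_sites`
#' comparable sites the coefficient is undefined (`NA`) — sparse overlaps
#' must not produce spurious 100% identity.
#'
#' @param x A [geno_matrix()].
#' @param i,j Accession ids (or row indices). `i == j` is allowed and gives
#'   pIBS 1 over the accession's homozygous sites.
#' @param min_sites Minimum comparable sites for a defined coefficient;
#'   default 500.
#' @return One-row tibble: `accession_i`, `accession_j`, `n_sites`, `pibs`.
#' @export
pibs_pair <- function(x, i, j, min_sites = 500) {
  stopifnot(inherits(x, "geno_matrix"))
  gi <- resolve_accession(x, i)
  gj <- resolve_accession(x, j)
  a <- x$calls[gi, ]
  b <- x$calls[gj, ]
  comp <- !is.na(a) & !is.na(b) & a != 1L & b != 1L
  n <- sum(comp)
  pibs <- if (n >= min_sites) sum(a[comp] == b[comp]) / n else NA_real_
  tibble::tibble(accession_i = rownames(x$calls)[gi],
                 accession_j = rownames(x$calls)[gj],
                 n_sites = n, pibs = pibs)
}

resolve_accession <- function(x, id) {
  if (is.numeric(id)) {
    if (id < 1 || id > nrow(x$calls)) stop("accession index out of range", call. = FALSE)
    return(as.integer(id))
  }
  k <- match(id, rownames(x$calls))
  if (is.na(k)) stop("unknown accession id: ", id, call. = FALSE)
  k
}

#' Full pairwise identity matrix
#'
#' Computes pIBS for every unordered pair of accessions. The heavy lifting
#' is three matrix cross-products on homozygote indicator matrices, so
#' panels of a few hundred accessions by tens of thousands of markers are
#' handled in seconds.
#'
#' @param x A [geno_matrix()] with at least 2 accessions.
#' @param min_sites Minimum comparable sites per pair (default 500); pairs
#'   below it get `pibs = NA`.
#' @return A tibble of class `pibs_tbl` with columns `accession_i`,
#'   `accession_j` (i before j in matrix row order), `n_sites`, `pibs`.
#'   Attributes: `accession_ids` (row order) and `mean_n_sites`, the mean
#'   number of comparable sites across pairs.
#' @export
pibs_matrix <- function(x, min_sites = 500) {
  stopifnot(inherits(x, "geno_matrix"), nrow(x$calls) >= 2)
  g <- x$calls
  A <- (!is.na(g) & g == 0L) + 0   # hom-ref indicator
  B <- (!is.na(g) & g == 2L) + 0   # hom-alt indicator
  matches <- tcrossprod(A) + tcrossprod(B)
  nsites <- tcrossprod(A + B)
  ids <- rownames(g)
  ut <- upper.tri(nsites)
  idx <- which(ut, arr.ind = TRUE)
  n <- nsites[ut]
  pibs <- ifelse(n >= min_sites, matches[ut] / n, NA_real_)
  out <- tibble::tibble(
    accession_i = ids[idx[, 1]],
    accession_j = ids[idx[, 2]],
    n_sites = as.integer(n),
    pibs = pibs
  )
  out <- out[order(idx[, 1], idx[, 2]), ]
  structure(out,
            class = c("pibs_tbl", class(out)),
            accession_ids = ids,
            mean_n_sites = mean(n),
            min_sites = min_sites)
}

#' Square pIBS (or distance) matrix from a pair table
#'
#' @param pairs A `pibs_tbl` from [pibs_matrix()].
#' @param what `"pibs"` (default) or `"distance"` (1 - pIBS).
#' @return A symmetric numeric matrix; diagonal 1 for pIBS, 0 for distance.
#' @export
pibs_wide <- function(pairs, what = c("pibs", "distance")) {
  what <- match.arg(what)
  ids <- attr(pairs, "accession_ids")
  if (is.null(ids)) ids <- sort(unique(c(pairs$accession_i, pairs$accession_j)))
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  i <- match(pairs$accession_i, ids)
  j <- match(pairs$accession_j, ids)
  m[cbind(i, j)] <- pairs$pibs
  m[cbind(j, i)] <- pairs$pibs
  diag(m) <- 1
  if (what == "distance") m <- 1 - m
  m
}

#' Genotyping error rate from biological replicates
#'
#' For each accession i with m_i replicated samples, the inner mean of
#' (1 - pIBS) between the accession and each of its replicates is taken;
#' the error rate is the outer mean of those per-accession means over the
#' n replicated accessions. Replicate pairs whose pIBS falls below
#' `identity_threshold` are anomalies — sample mixups, contamination or a
#' heterogeneous seed source rather than genotyping error — and are
#' excluded from the screened estimate `error_rate_clean` (an accession
#' whose every pair is anomalous drops out of the outer mean entirely).
#'
#' @param x A [geno_matrix()] containing originals and replicate samples
#'   as rows.
#' @param records Accession metadata ([validate_records()]); rows with
#'   `sample_type == "biological_replicate"` are paired with their
#'   `parent_accession_id`.
#' @param identity_threshold Anomaly screen on replicate pIBS; default 0.99.
#' @param min_sites Passed to the pairwise comparison; default 500.
#' @return An object of class `error_rate_report`: list with `pairs`
#'   (tibble: `accession_id`, `replicate_id`, `n_sites`, `pibs`,
#'   `anomalous`), `error_rate_all`, `error_rate_clean`, `n_accessions`,
#'   `n_pairs`, `n_anomalous`, `threshold`.
#' @export
error_rate <- function(x, records, identity_threshold = 0.99, min_sites = 500) {
  stopifnot(inherits(x, "geno_matrix"))
  records <- validate_records(records)
  reps <- dplyr::filter(records, .data$sample_type == "biological_replicate")
  if (nrow(reps) == 0) stop("no biological replicates in records", call. = FALSE)
  missing_rows <- setdiff(c(reps$accession_id, reps$parent_accession_id),
                          rownames(x$calls))
  if (length(missing_rows)) {
    stop("replicate samples absent from genotype matrix: ",
         paste(missing_rows, collapse = ", "), call. = FALSE)
  }
  pairs <- purrr::map2_dfr(reps$parent_accession_id, reps$accession_id,
                           function(p, r) pibs_pair(x, p, r, min_sites = min_sites))
  pairs <- tibble::tibble(
    accession_id = pairs$accession_i,
    replicate_id = pairs$accession_j,
    n_sites = pairs$n_sites,
    pibs = pairs$pibs
  )
  if (anyNA(pairs$pibs)) {
    warning(sum(is.na(pairs$pibs)),
            " replicate pair(s) undefined (too few comparable sites); dropped",
            call. = FALSE)
    pairs <- dplyr::filter(pairs, !is.na(.data$pibs))
    if (nrow(pairs) == 0) stop("no usable replicate pairs", call. = FALSE)
  }
  pairs$anomalous <- pairs$pibs < identity_threshold
  eq2 <- function(p) {
    if (nrow(p) == 0) return(NA_real_)
    p |>
      dplyr::group_by(.data$accession_id) |>
      dplyr::summarise(inner = mean(1 - .data$pibs), .groups = "drop") |>
      dplyr::pull(.data$inner) |>
      mean()
  }
  structure(list(
    pairs = pairs,
    error_rate_all = eq2(pairs),
    error_rate_clean = eq2(dplyr::filter(pairs, !.data$anomalous)),
    n_accessions = dplyr::n_distinct(pairs$accession_id),
    n_pairs = nrow(pairs),
    n_anomalous = sum(pairs$anomalous),
    threshold = identity_threshold
  ), class = "error_rate_report")
}

#' @export
print.error_rate_report <- function(x, ...) {
  cat(sprintf("<error_rate_report> %d accessions, %d replicate pairs\n",
              x$n_accessions, x$n_pairs))
  cat(sprintf("  error rate (all pairs):    %.4f%%\n", 100 * x$error_rate_all))
  cat(sprintf("  error rate (screened):     %.4f%%  [%d anomalous pair(s) at pIBS < %g removed]\n",
              100 * x$error_rate_clean, x$n_anomalous, x$threshold))
  invisible(x)
}

#' Tidy the per-pair replicate comparisons of an error-rate report
#' @param x An `error_rate_report`.
#' @param ... Unused.
#' @return The `pairs` tibble.
#' @export
tidy.error_rate_report <- function(x, ...) x$pairs

#' One-row summary of an error-rate report
#' @param x An `error_rate_report`.
#' @param ... Unused.
#' @return One-row tibble with the two Eq.-style estimates and counts.
#' @export
glance.error_rate_report <- function(x, ...) {
  tibble::tibble(
    n_accessions = x$n_accessions,
    n_pairs = x$n_pairs,
    n_anomalous = x$n_anomalous,
    error_rate_all = x$error_rate_all,
    error_rate_clean = x$error_rate_clean,
    threshold = x$threshold
  )
}
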