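#' Hierarchical clustering tree over genetic distances
#'
#' Agglomerative clustering of accessions on the distance 1 - pIBS.
#' Clustering gives a quick view of lineage structure and flags obvious
#' outliers and misclassified material, but it cannot by itself declare
#' accessions identical — that is what threshold grouping is for.
#'
#' @param pairs A `pibs_tbl` from [pibs_matrix()], or a [geno_matrix()]
#'   (in which case the pair table is computed first with `min_sites`).
#' @param linkage Agglomeration method: `"average"` (default),
#'   `"single"` or `"complete"`.
#' @param min_sites Used only when `pairs` is a `geno_matrix`.
#' @return An [ape::as.phylo()] tree (class `phylo`); write it with
#'   [ape::write.tree()] for Newick output.
#' @export
build_tree <- function(pairs, linkage = c("average", "single", "complete"),
                       min_sites = 500) {
  linkage <- match.arg(linkage)
  if (inherits(pairs, "geno_matrix")) pairs <- pibs_matrix(pairs, min_sites)
  if (anyNA(pairs$pibs)) {
    bad <- dplyr::filter(pairs, is.na(.data$pibs))
    stop("undefined pairwise distances for ", nrow(bad), " pair(s) ",
         "(too few comparable sites); filter markers less aggressively, ",
         "lower min_sites, or drop the sparse accessions",
         call. = FALSE)
  }
  d <- stats::as.dist(pibs_wide(pairs, what = "distance"))
  hc <- stats::hclust(d, method = linkage)
  ape::as.phylo(hc)
}

#' Flag outlier accessions from the identity structure
#'
#' Outliers are accessions that do not resemble anything else in the
#' panel: misidentified species, inter-lineage hybrids, or contaminated
#' samples. Two rules are applied to each accession's nearest-neighbour
#' distance d = min over partners of (1 - pIBS): a distributional rule,
#' d above `quantile(d, q) + iqr_mult * IQR(d)`, and an absolute rule,
#' d above `max_nn_dist` (no other accession matches it even loosely).
#' Undefined pairs count as distance 1.
#'
#' @param pairs A `pibs_tbl` from [pibs_matrix()].
#' @param q Quantile anchoring the distributional cutoff; default 0.75.
#' @param iqr_mult IQR multiplier; default 3.
#' @param max_nn_dist Absolute nearest-neighbour distance cutoff; default
#'   0.45 (about the mismatch level of an unrelated genome).
#' @return A tibble: `accession_id`, `nn_dist`, `nn_id`, `rule`
#'   (`"distribution"`, `"no_match"`, or `"distribution+no_match"`).
#'   Zero rows when the panel is clean.
#' @export
flag_outliers <- function(pairs, q = 0.75, iqr_mult = 3, max_nn_dist = 0.45) {
  long <- dplyr::bind_rows(
    tibble::tibble(id = pairs$accession_i, other = pairs$accession_j, pibs = pairs$pibs),
    tibble::tibble(id = pairs$accession_j, other = pairs$accession_i, pibs = pairs$pibs)
  ) |>
    dplyr::mutate(dist = ifelse(is.na(.data$pibs), 1, 1 - .data$pibs))
  nn <- long |>
    dplyr::group_by(.data$id) |>
    dplyr::slice_min(.data$dist, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  cutoff <- stats::quantile(nn$dist, q, names = FALSE) +
    iqr_mult * stats::IQR(nn$dist)
  nn |>
    dplyr::mutate(
      by_dist = .data$dist > cutoff,
      by_abs = .data$dist > max_nn_dist
    ) |>
    dplyr::filter(.data$by_dist | .data$by_abs) |>
    dplyr::transmute(
      accession_id = .data$id,
      nn_dist = .data$dist,
      nn_id = .data$other,
      rule = dplyr::case_when(
        .data$by_dist & .data$by_abs ~ "distribution+no_match",
        .data$by_abs ~ "no_match",
        TRUE ~ "distribution"
      )
    ) |>
    dplyr::arrange(dplyr::desc(.data$nn_dist))
}

#' Supervised geographic-origin assignment
#'
#' Imputes missing passport origin by treating accessions with a known
#' `origin_region` as learning samples. Markers are first screened
#' (missing fraction <= `max_missing`, MAF >= `min_maf`, computed on the
#' supplied panel). Per region, alt-allele frequencies are estimated from
#' the learning samples' calls with a Laplace pseudocount (+1 on each
#' allele count). A query accession's homozygous, non-missing calls are
#' scored under a product-Bernoulli model per region (hom alt with
#' probability p, hom ref with 1 - p, sites independent — the material is
#' inbred, so the homozygous state is a single draw). Posteriors follow
#' from a uniform prior over regions; an accession is assigned to the top
#' region only when its posterior reaches `threshold`, otherwise it is
#' left `UNASSIGNED`.
#'
#' @param x A [geno_matrix()] containing learning and query accessions.
#' @param records Accession metadata; `origin_region` non-`NA` marks a
#'   learning sample.
#' @param unlabeled_ids Accessions to assign. Default: every accession in
#'   `x` whose record has no `origin_region`.
#' @param threshold Posterior needed to assign; default 0.6.
#' @param min_maf,max_missing Marker screen; defaults 0.05 and 0.30.
#' @param pseudocount Laplace pseudocount on allele counts; default 1.
#' @param min_informative Minimum usable (homozygous, non-missing,
#'   screened) sites per query; below it the accession is `UNASSIGNED`
#'   with reason `"insufficient_sites"`. Default 10.
#' @return A tibble of class `origin_tbl`: `accession_id`, one posterior
#'   column `post_<region>` per region, `n_informative`, `assigned_group`
#'   (`NA` when unassigned), `reason`.
#' @export
assign_origin <- function(x, records, unlabeled_ids = NULL, threshold = 0.6,
                          min_maf = 0.05, max_missing = 0.30,
                          pseudocount = 1, min_informative = 10) {
  stopifnot(inherits(x, "geno_matrix"))
  records <- validate_records(records)
  lab <- dplyr::filter(records, !is.na(.data$origin_region),
                       .data$accession_id %in% rownames(x$calls))
  groups <- sort(unique(lab$origin_region))
  if (length(groups) < 2) stop("need >= 2 labeled origin groups", call. = FALSE)
  sizes <- table(lab$origin_region)
  if (any(sizes < 2)) stop("each origin group needs >= 2 labeled accessions",
                           call. = FALSE)
  if (is.null(unlabeled_ids)) {
    known <- records$accession_id[!is.na(records$origin_region)]
    unlabeled_ids <- setdiff(rownames(x$calls), known)
  }
  unknown <- setdiff(unlabeled_ids, rownames(x$calls))
  if (length(unknown)) stop("unlabeled ids absent from matrix: ",
                            paste(unknown, collapse = ", "), call. = FALSE)

  keep <- x$marker_info$missing_frac <= max_missing &
    !is.na(x$marker_info$maf) & x$marker_info$maf >= min_maf
  g <- x$calls[, keep, drop = FALSE]
  if (ncol(g) == 0) stop("no markers survive the assignment screen", call. = FALSE)

  # per-region pseudocounted alt-allele frequencies (HET adds one of each)
  freqs <- vapply(groups, function(grp) {
    rows <- lab$accession_id[lab$origin_region == grp]
    sub <- g[rows, , drop = FALSE]
    n_obs <- colSums(!is.na(sub))
    alt <- colSums(sub, na.rm = TRUE)
    (alt + pseudocount) / (2 * n_obs + 2 * pseudocount)
  }, numeric(ncol(g)))
  if (is.null(dim(freqs))) freqs <- matrix(freqs, nrow = 1L, dimnames = list(NULL, groups))

  out <- purrr::map_dfr(unlabeled_ids, function(id) {
    calls <- g[id, ]
    use <- !is.na(calls) & calls != 1L
    row <- tibble::tibble(accession_id = id, n_informative = sum(use))
    if (sum(use) < min_informative) {
      post <- rep(NA_real_, length(groups))
      row$assigned_group <- NA_character_
      row$reason <- "insufficient_sites"
    } else {
      alt <- calls[use] == 2L
      loglik <- vapply(seq_along(groups), function(k) {
        p <- freqs[use, k]
        sum(log(ifelse(alt, p, 1 - p)))
      }, numeric(1))
      post <- exp(loglik - max(loglik))
      post <- post / sum(post)
      top <- which.max(post)
      if (post[top] >= threshold) {
        row$assigned_group <- groups[top]
        row$reason <- NA_character_
      } else {
        row$assigned_group <- NA_character_
        row$reason <- "max_posterior_below_threshold"
      }
    }
    for (k in seq_along(groups)) row[[paste0("post_", groups[k])]] <- post[k]
    row
  })
  out <- out[c("accession_id", paste0("post_", groups), "n_informative",
               "assigned_group", "reason")]
  structure(out, class = c("origin_tbl", class(out)),
            groups = groups, threshold = threshold)
}

#' One-row summary of origin assignments
#' @param x An `origin_tbl` from [assign_origin()].
#' @param ... Unused.
#' @return One-row tibble with counts of assigned/unassigned accessions.
#' @export
glance.origin_tbl <- function(x, ...) {
  tibble::tibble(
    n_queries = nrow(x),
    n_assigned = sum(!is.na(x$assigned_group)),
    n_unassigned = sum(is.na(x$assigned_group)),
    threshold = attr(x, "threshold")
  )
}
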