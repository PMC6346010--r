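#' Group accessions that are identical at the pIBS threshold
#'
#' Accessions with pIBS at or above the threshold are declared identical
#' and placed in the same group. Under the default single linkage, groups
#' are the connected components of the graph whose edges are pairs with
#' `pibs >= threshold`: with A~B and B~C at 99% but A-C at 98.5%,
#' components are the only closure that keeps group membership
#' well-defined. Complete linkage (every within-group pair above
#' threshold) is available as a stricter option. Undefined pairs (pIBS
#' `NA`, too few comparable sites) never create a link.
#'
#' @param pairs A `pibs_tbl` from [pibs_matrix()], or any tibble with
#'   columns `accession_i`, `accession_j`, `pibs` covering all pairs.
#' @param threshold Identity threshold, inclusive; default 0.99. Applied
#'   to full-precision pIBS, no rounding.
#' @param linkage `"single"` (connected components, default) or
#'   `"complete"`.
#' @param records Optional accession metadata; with
#'   `representative = "date"` the member with the earliest
#'   `collection_date` becomes the group representative.
#' @param representative `"id"` (lexicographically smallest accession id,
#'   default) or `"date"`.
#' @return A tibble of class `dup_groups`: one row per accession with
#'   `group_id` (integer, numbered by smallest member id), `accession_id`,
#'   `representative` (logical), `group_size`. Singletons are their own
#'   group, so the rows partition the accession set.
#' @export
group_duplicates <- function(pairs, threshold = 0.99,
                             linkage = c("single", "complete"),
                             records = NULL,
                             representative = c("id", "date")) {
  linkage <- match.arg(linkage)
  representative <- match.arg(representative)
  ids <- attr(pairs, "accession_ids")
  if (is.null(ids)) ids <- sort(unique(c(pairs$accession_i, pairs$accession_j)))
  member <- if (linkage == "single") {
    edges <- dplyr::filter(pairs, !is.na(.data$pibs), .data$pibs >= threshold)
    g <- igraph::graph_from_data_frame(
      edges[c("accession_i", "accession_j")], directed = FALSE,
      vertices = data.frame(name = ids))
    comp <- igraph::components(g)$membership
    comp[ids]
  } else {
    d <- 1 - pibs_wide(pairs)
    d[is.na(d)] <- 1
    hc <- stats::hclust(stats::as.dist(d), method = "complete")
    stats::cutree(hc, h = 1 - threshold)[ids]
  }
  out <- tibble::tibble(accession_id = ids, raw = unname(member))
  # deterministic numbering: groups ordered by their smallest member id
  key <- out |>
    dplyr::group_by(.data$raw) |>
    dplyr::summarise(first_id = min(.data$accession_id), .groups = "drop") |>
    dplyr::arrange(.data$first_id) |>
    dplyr::mutate(group_id = dplyr::row_number())
  out <- out |>
    dplyr::left_join(key[c("raw", "group_id")], by = "raw") |>
    dplyr::select("group_id", "accession_id") |>
    dplyr::arrange(.data$group_id, .data$accession_id)
  out <- out |>
    dplyr::group_by(.data$group_id) |>
    dplyr::mutate(group_size = dplyr::n(),
                  representative = pick_representative(
                    .data$accession_id, records, representative)) |>
    dplyr::ungroup()
  structure(out, class = c("dup_groups", class(tibble::tibble())),
            threshold = threshold, linkage = linkage)
}

pick_representative <- function(ids, records, mode) {
  rep_id <- if (mode == "date" && !is.null(records) &&
                "collection_date" %in% names(records)) {
    dates <- records$collection_date[match(ids, records$accession_id)]
    ord <- order(is.na(dates), dates, ids)
    ids[ord[1]]
  } else {
    min(ids)
  }
  ids == rep_id
}

#' Per-genebank duplication summary
#'
#' For each genebank: how many of its accessions are there, how many
#' distinct identity groups they fall into (its unique accessions), and
#' the percent unique / percent duplicated split.
#'
#' @param groups A `dup_groups` tibble from [group_duplicates()].
#' @param records Accession metadata carrying `genebank_id` for every
#'   grouped accession.
#' @return A tibble: `genebank_id`, `total`, `unique_count`,
#'   `percent_unique`, `percent_duplicated`.
#' @export
genebank_summary <- function(groups, records) {
  records <- tibble::as_tibble(records)
  miss <- setdiff(groups$accession_id, records$accession_id)
  if (length(miss)) stop("accessions without metadata: ",
                         paste(utils::head(miss, 10), collapse = ", "), call. = FALSE)
  groups |>
    dplyr::left_join(records[c("accession_id", "genebank_id")], by = "accession_id") |>
    dplyr::group_by(.data$genebank_id) |>
    dplyr::summarise(
      total = dplyr::n(),
      unique_count = dplyr::n_distinct(.data$group_id),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      percent_unique = 100 * .data$unique_count / .data$total,
      percent_duplicated = 100 - .data$percent_unique
    )
}

#' Cross-genebank sharing summary (Venn cells)
#'
#' Each globally unique identity group is assigned the set of genebanks
#' its members span; the counts over those sets are the cells of the
#' genebank Venn diagram. Percentages are on an explicit denominator: the
#' total number of globally unique groups.
#'
#' @inheritParams genebank_summary
#' @return A list of class `sharing_summary`: `cells` (tibble:
#'   `genebanks` label such as `"WGRC+PAU"`, `n_genebanks`, `n_groups`,
#'   `percent` of globally unique groups), `total_unique_groups`,
#'   `n_accessions`.
#' @export
sharing_summary <- function(groups, records) {
  records <- tibble::as_tibble(records)
  miss <- setdiff(groups$accession_id, records$accession_id)
  if (length(miss)) stop("accessions without metadata: ",
                         paste(utils::head(miss, 10), collapse = ", "), call. = FALSE)
  spans <- groups |>
    dplyr::left_join(records[c("accession_id", "genebank_id")], by = "accession_id") |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(
      genebanks = paste(sort(unique(.data$genebank_id)), collapse = "+"),
      n_genebanks = dplyr::n_distinct(.data$genebank_id),
      .groups = "drop"
    )
  cells <- spans |>
    dplyr::count(.data$genebanks, .data$n_genebanks, name = "n_groups") |>
    dplyr::arrange(.data$n_genebanks, .data$genebanks) |>
    dplyr::mutate(percent = 100 * .data$n_groups / nrow(spans))
  structure(list(cells = cells,
                 total_unique_groups = nrow(spans),
                 n_accessions = nrow(groups)),
            class = "sharing_summary")
}

#' @export
print.sharing_summary <- function(x, ...) {
  cat(sprintf("<sharing_summary> %d accessions -> %d globally unique groups\n",
              x$n_accessions, x$total_unique_groups))
  print(x$cells)
  invisible(x)
}

#' Detect seed-lot heterogeneity within an accession
#'
#' Runs identity grouping restricted to the samples of one accession (the
#' original plus its seed splits and biological replicates). A homogeneous
#' seed lot yields a single group with all samples mutually at or above
#' the identity threshold; two or more sub-groups indicate a heterogeneous
#' seed source. Elevated heterozygosity across the samples is reported as
#' an additional warning flag, since bulked or mixed tissue inflates het
#' calls.
#'
#' @param x A [geno_matrix()] whose rows include the accession's samples.
#' @param records Accession metadata; samples of the accession are the
#'   accession's own row (if present) plus records whose
#'   `parent_accession_id` equals `accession_id`.
#' @param accession_id The accession to examine (needs >= 2 samples).
#' @param threshold Identity threshold, default 0.99.
#' @param min_sites Minimum comparable sites per pair; default 500.
#' @param het_cutoff Heterozygosity fraction above which the
#'   elevated-heterozygosity flag is raised; default 0.10.
#' @return A list of class `heterogeneity_report`: `accession_id`,
#'   `samples` (tibble: `sample_id`, `sub_group`, `het_frac`),
#'   `n_subgroups`, `verdict` (`"homogeneous"`/`"heterogeneous"`),
#'   `elevated_het` (logical).
#' @export
detect_heterogeneity <- function(x, records, accession_id, threshold = 0.99,
                                 min_sites = 500, het_cutoff = 0.10) {
  records <- validate_records(records)
  fam <- records$accession_id[
    records$accession_id == accession_id |
      (!is.na(records$parent_accession_id) &
         records$parent_accession_id == accession_id)]
  fam <- intersect(unique(fam), rownames(x$calls))
  if (length(fam) < 2) {
    stop("need at least 2 genotyped samples for accession ", accession_id,
         call. = FALSE)
  }
  sub <- x[fam, ]
  pairs <- pibs_matrix(sub, min_sites = min_sites)
  grp <- group_duplicates(pairs, threshold = threshold)
  het <- sample_stats(sub)$accessions
  samples <- tibble::tibble(sample_id = grp$accession_id,
                            sub_group = grp$group_id) |>
    dplyr::left_join(het[c("accession_id", "het_frac")],
                     by = c(sample_id = "accession_id"))
  n_sub <- dplyr::n_distinct(samples$sub_group)
  structure(list(
    accession_id = accession_id,
    samples = samples,
    n_subgroups = n_sub,
    verdict = if (n_sub >= 2) "heterogeneous" else "homogeneous",
    elevated_het = isTRUE(mean(samples$het_frac, na.rm = TRUE) > het_cutoff)
  ), class = "heterogeneity_report")
}

#' @export
print.heterogeneity_report <- function(x, ...) {
  cat(sprintf("<heterogeneity_report> %s: %s (%d sub-group%s, %d samples)%s\n",
              x$accession_id, x$verdict, x$n_subgroups,
              if (x$n_subgroups == 1) "" else "s", nrow(x$samples),
              if (x$elevated_het) " [elevated heterozygosity]" else ""))
  invisible(x)
}

#' Tidy a heterogeneity report
#' @param x A `heterogeneity_report`.
#' @param ... Unused.
#' @return The per-sample tibble with sub-group assignments.
#' @export
tidy.heterogeneity_report <- function(x, ...) x$samples

#' One-row summary of a heterogeneity report
#' @param x A `heterogeneity_report`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.heterogeneity_report <- function(x, ...) {
  tibble::tibble(accession_id = x$accession_id,
                 n_samples = nrow(x$samples),
                 n_subgroups = x$n_subgroups,
                 verdict = x$verdict,
                 elevated_het = x$elevated_het)
}
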