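#' Create a genotype database for forward curation
#'
#' A genotype database holds the genotyped accessions of one or more
#' collections together with their identity-group registry, so that newly
#' genotyped material can be screened for redundancy before it is
#' accessioned. Groups are registered with stable global identifiers
#' (`G0001`, ...): one global id per unique genotype.
#'
#' @param x A [geno_matrix()] of the existing accessions.
#' @param records Accession metadata ([validate_records()]).
#' @param threshold Identity threshold used for grouping and later
#'   curation; default 0.99.
#' @param min_sites Minimum comparable sites for a defined pIBS; default
#'   500.
#' @return An object of class `geno_db`.
#' @export
geno_db <- function(x, records, threshold = 0.99, min_sites = 500) {
  stopifnot(inherits(x, "geno_matrix"))
  records <- validate_records(records)
  missing_meta <- setdiff(rownames(x$calls), records$accession_id)
  if (length(missing_meta)) {
    stop("accessions without metadata: ",
         paste(utils::head(missing_meta, 10), collapse = ", "), call. = FALSE)
  }
  if (nrow(x$calls) >= 2) {
    grp <- group_duplicates(pibs_matrix(x, min_sites = min_sites),
                            threshold = threshold)
  } else {
    grp <- tibble::tibble(group_id = 1L, accession_id = rownames(x$calls),
                          group_size = 1L, representative = TRUE)
  }
  groups <- tibble::tibble(
    global_id = sprintf("G%04d", grp$group_id),
    accession_id = grp$accession_id,
    representative = grp$representative
  )
  db <- structure(list(
    geno = x,
    records = records[match(rownames(x$calls), records$accession_id), ],
    groups = groups,
    log = tibble::tibble(sequence = integer(), action = character(),
                         id = character(), details = character()),
    threshold = threshold,
    min_sites = min_sites,
    next_group = max(grp$group_id) + 1L
  ), class = "geno_db")
  db_log(db, "create", NA_character_,
         sprintf("%d accessions in %d groups", nrow(groups),
                 dplyr::n_distinct(groups$global_id)))
}

db_log <- function(db, action, id, details) {
  db$log <- dplyr::add_row(db$log, sequence = nrow(db$log) + 1L,
                           action = action, id = id, details = details)
  db
}

#' @export
print.geno_db <- function(x, ...) {
  cat(sprintf("<geno_db> %d accessions, %d groups, %d markers (threshold %g)\n",
              nrow(x$geno$calls), dplyr::n_distinct(x$groups$global_id),
              ncol(x$geno$calls), x$threshold))
  invisible(x)
}

#' Write a genotype database to a directory
#'
#' Serialises the database as plain text: `genotypes.csv`, `metadata.csv`
#' and `registry.json` (groups, provenance log, parameters). The write is
#' atomic — files are staged in a temporary sibling directory that is
#' renamed into place, so a crash never leaves a half-written database.
#'
#' @param db A [geno_db()].
#' @param dir Target directory (replaced if it exists).
#' @return `dir`, invisibly.
#' @export
db_write <- function(db, dir) {
  stopifnot(inherits(db, "geno_db"))
  stage <- paste0(dir, ".staging")
  if (dir.exists(stage)) unlink(stage, recursive = TRUE)
  dir.create(stage, recursive = TRUE)
  write_geno_csv(db$geno, file.path(stage, "genotypes.csv"))
  write_metadata(db$records, file.path(stage, "metadata.csv"))
  registry <- list(
    format_version = 1L,
    threshold = db$threshold,
    min_sites = db$min_sites,
    next_group = db$next_group,
    groups = db$groups,
    log = db$log
  )
  jsonlite::write_json(registry, file.path(stage, "registry.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  if (dir.exists(dir)) unlink(dir, recursive = TRUE)
  ok <- file.rename(stage, dir)
  if (!ok) stop("could not move staged database into place", call. = FALSE)
  invisible(dir)
}

#' Read a genotype database from a directory
#' @param dir Directory written by [db_write()].
#' @return A [geno_db()].
#' @export
db_read <- function(dir) {
  geno <- read_geno_csv(file.path(dir, "genotypes.csv"))
  records <- read_metadata(file.path(dir, "metadata.csv"))
  reg <- jsonlite::read_json(file.path(dir, "registry.json"), simplifyVector = TRUE)
  structure(list(
    geno = geno,
    records = records,
    groups = tibble::as_tibble(reg$groups),
    log = tibble::as_tibble(reg$log),
    threshold = reg$threshold,
    min_sites = reg$min_sites,
    next_group = as.integer(reg$next_group)
  ), class = "geno_db")
}

# pIBS of one query call vector against every row of a call matrix
pibs_query <- function(calls, query, min_sites) {
  q0 <- !is.na(query) & query == 0L
  q2 <- !is.na(query) & query == 2L
  A <- (!is.na(calls) & calls == 0L)
  B <- (!is.na(calls) & calls == 2L)
  matches <- as.vector(A %*% q0 + B %*% q2)
  n <- as.vector((A | B) %*% (q0 | q2))
  tibble::tibble(accession_id = rownames(calls), n_sites = as.integer(n),
                 pibs = ifelse(n >= min_sites, matches / n, NA_real_))
}

#' Curate one newly genotyped accession against the database
#'
#' The forward-curation decision for new material: (1) a query with
#' heterozygosity above `het_cutoff` is held back as a suspected
#' heterogeneous (mixed) seed source — purify by single seed descent and
#' re-genotype — and the database is not touched; (2) otherwise the query
#' is matched in two stages, first against every group representative,
#' then against all members of the candidate groups, and a best match at
#' or above the identity threshold makes it a duplicate of that group;
#' (3) with no match it is registered as a new unique accession under a
#' freshly minted global id. The database is updated atomically in both
#' registering cases.
#'
#' @param db A [geno_db()].
#' @param query Named integer vector of calls in `{0, 1, 2, NA}` (names =
#'   marker ids), or a one-row [geno_matrix()].
#' @param query_id Identifier for the new accession; must not collide with
#'   a stored id unless it *is* that accession (re-curating a stored
#'   accession is a no-op returning its own group).
#' @param genebank_id Genebank attribution recorded for the query;
#'   default `"NEW"`.
#' @param threshold,min_sites Defaults taken from the database.
#' @param het_cutoff Heterozygosity hold cutoff; default 0.10.
#' @param candidate_margin Representatives within this margin below the
#'   threshold promote their group to full-member comparison; default
#'   0.02.
#' @return A list: `decision` (one-row tibble: `query_id`,
#'   `best_match_id`, `best_match_pibs`, `best_match_n_sites`, `decision`,
#'   `assigned_global_id`) and `db` (the updated database).
#' @export
curate_new <- function(db, query, query_id, genebank_id = "NEW",
                       threshold = db$threshold, min_sites = db$min_sites,
                       het_cutoff = 0.10, candidate_margin = 0.02) {
  stopifnot(inherits(db, "geno_db"))
  if (inherits(query, "geno_matrix")) {
    stopifnot(nrow(query$calls) == 1)
    if (missing(query_id)) query_id <- rownames(query$calls)
    query <- query$calls[1, ]
  }
  if (is.null(names(query))) stop("`query` must be named by marker id", call. = FALSE)

  stored <- query_id %in% rownames(db$geno$calls)
  shared <- intersect(names(query), colnames(db$geno$calls))
  if (length(shared) < min_sites) {
    stop("query overlaps the database at only ", length(shared),
         " marker(s); need >= ", min_sites, call. = FALSE)
  }
  q <- query[shared]

  obs <- sum(!is.na(q))
  het <- if (obs > 0) sum(q == 1L, na.rm = TRUE) / obs else NA_real_
  decision <- tibble::tibble(
    query_id = query_id, best_match_id = NA_character_,
    best_match_pibs = NA_real_, best_match_n_sites = NA_integer_,
    decision = NA_character_, assigned_global_id = NA_character_
  )
  if (!is.na(het) && het > het_cutoff) {
    decision$decision <- "HETEROGENEOUS_HOLD"
    return(list(decision = decision, db = db))
  }

  calls <- db$geno$calls[, shared, drop = FALSE]
  reps <- db$groups$accession_id[db$groups$representative]
  rep_hits <- pibs_query(calls[reps, , drop = FALSE], q, min_sites)
  cand_reps <- rep_hits$accession_id[!is.na(rep_hits$pibs) &
                                       rep_hits$pibs >= threshold - candidate_margin]
  best <- NULL
  if (length(cand_reps)) {
    cand_groups <- unique(db$groups$global_id[db$groups$accession_id %in% cand_reps])
    members <- db$groups$accession_id[db$groups$global_id %in% cand_groups]
    hits <- pibs_query(calls[members, , drop = FALSE], q, min_sites)
    hits <- hits[!is.na(hits$pibs), , drop = FALSE]
    if (nrow(hits)) best <- hits[which.max(hits$pibs), ]
  }

  if (!is.null(best) && best$pibs >= threshold) {
    gid <- db$groups$global_id[db$groups$accession_id == best$accession_id]
    decision$best_match_id <- best$accession_id
    decision$best_match_pibs <- best$pibs
    decision$best_match_n_sites <- best$n_sites
    decision$decision <- "DUPLICATE_OF"
    decision$assigned_global_id <- gid
    if (stored) {
      # re-curating stored material: no mutation
      return(list(decision = decision, db = db))
    }
    db <- db_add_accession(db, query, query_id, genebank_id, gid,
                           representative = FALSE)
    db <- db_log(db, "duplicate", query_id,
                 sprintf("grouped into %s (pIBS %.5f vs %s over %d sites)",
                         gid, best$pibs, best$accession_id, best$n_sites))
  } else {
    if (stored) {
      stop("stored accession ", query_id,
           " no longer matches its own group; database inconsistent", call. = FALSE)
    }
    gid <- sprintf("G%04d", db$next_group)
    db$next_group <- db$next_group + 1L
    decision$decision <- "NEW_UNIQUE"
    decision$assigned_global_id <- gid
    if (!is.null(best)) {
      decision$best_match_id <- best$accession_id
      decision$best_match_pibs <- best$pibs
      decision$best_match_n_sites <- best$n_sites
    }
    db <- db_add_accession(db, query, query_id, genebank_id, gid,
                           representative = TRUE)
    db <- db_log(db, "new_unique", query_id, sprintf("registered as %s", gid))
  }
  list(decision = decision, db = db)
}

db_add_accession <- function(db, query, query_id, genebank_id, global_id,
                             representative) {
  if (query_id %in% rownames(db$geno$calls)) {
    stop("accession id already stored: ", query_id, call. = FALSE)
  }
  row <- rep(NA_integer_, ncol(db$geno$calls))
  names(row) <- colnames(db$geno$calls)
  shared <- intersect(names(query), names(row))
  row[shared] <- query[shared]
  calls <- rbind(db$geno$calls, matrix(row, nrow = 1,
                                       dimnames = list(query_id, names(row))))
  db$geno <- geno_matrix(calls, db$geno$marker_info)
  db$records <- dplyr::add_row(db$records, accession_id = query_id,
                               genebank_id = genebank_id,
                               sample_type = "original",
                               parent_accession_id = NA_character_,
                               origin_region = NA_character_,
                               collection_date = NA_character_)
  db$groups <- dplyr::add_row(db$groups, global_id = global_id,
                              accession_id = query_id,
                              representative = representative)
  db
}

#' Curate a batch of newly genotyped accessions
#'
#' Applies [curate_new()] to each row of a new panel in deterministic
#' order (sorted accession id), updating the database as it goes — so new
#' accessions can and do match each other, not just the stored
#' collection. Per-row errors are caught, reported in the decision table
#' and the batch continues.
#'
#' @param db A [geno_db()].
#' @param panel A [geno_matrix()] of the newly genotyped accessions.
#' @param genebank_id Attribution recorded for the batch; default `"NEW"`.
#' @param ... Passed to [curate_new()].
#' @return A list of class `curation_batch`: `decisions` (tibble, one row
#'   per query in processing order), `db` (final database),
#'   `n_unique`, `percent_unique` (share of the batch registered
#'   `NEW_UNIQUE`).
#' @export
batch_curate <- function(db, panel, genebank_id = "NEW", ...) {
  stopifnot(inherits(db, "geno_db"), inherits(panel, "geno_matrix"))
  ids <- sort(rownames(panel$calls))
  decisions <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    res <- tryCatch(
      curate_new(db, panel$calls[id, ], id, genebank_id = genebank_id, ...),
      error = function(e) {
        list(decision = tibble::tibble(
          query_id = id, best_match_id = NA_character_,
          best_match_pibs = NA_real_, best_match_n_sites = NA_integer_,
          decision = "ERROR", assigned_global_id = NA_character_,
          error = conditionMessage(e)), db = db)
      })
    if (!"error" %in% names(res$decision)) res$decision$error <- NA_character_
    decisions[[k]] <- res$decision
    db <- res$db
  }
  decisions <- dplyr::bind_rows(decisions)
  n_unique <- sum(decisions$decision == "NEW_UNIQUE", na.rm = TRUE)
  structure(list(decisions = decisions, db = db, n_unique = n_unique,
                 percent_unique = 100 * n_unique / max(nrow(decisions), 1)),
            class = "curation_batch")
}

#' @export
print.curation_batch <- function(x, ...) {
  cat(sprintf("<curation_batch> %d queries: %d new unique (%.1f%%), %d duplicates, %d held, %d errors\n",
              nrow(x$decisions), x$n_unique, x$percent_unique,
              sum(x$decisions$decision == "DUPLICATE_OF"),
              sum(x$decisions$decision == "HETEROGENEOUS_HOLD"),
              sum(x$decisions$decision == "ERROR")))
  invisible(x)
}

#' Tidy the per-query decisions of a curation batch
#' @param x A `curation_batch`.
#' @param ... Unused.
#' @return The decisions tibble.
#' @export
tidy.curation_batch <- function(x, ...) x$decisions

#' One-row summary of a curation batch
#' @param x A `curation_batch`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.curation_batch <- function(x, ...) {
  tibble::tibble(
    n_queries = nrow(x$decisions),
    n_unique = x$n_unique,
    n_duplicates = sum(x$decisions$decision == "DUPLICATE_OF"),
    n_held = sum(x$decisions$decision == "HETEROGENEOUS_HOLD"),
    n_errors = sum(x$decisions$decision == "ERROR"),
    percent_unique = x$percent_unique
  )
}
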