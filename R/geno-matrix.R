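#' Construct a genotype matrix
#'
#' The central container of the package: an accession-by-marker grid of
#' biallelic SNP calls in a four-state coding. Calls are stored as an
#' integer matrix with `0` = homozygous reference (major) allele, `1` =
#' heterozygous, `2` = homozygous alternate (minor) allele and `NA` =
#' missing. Row names are accession (sample) identifiers, column names are
#' marker identifiers.
#'
#' @param calls Integer (or numeric) matrix with values in `{0, 1, 2, NA}`.
#'   Must carry unique, non-empty row and column names.
#' @param marker_info Optional tibble of per-marker annotation with at least
#'   a `marker_id` column matching `colnames(calls)`. Columns `chrom`,
#'   `pos`, `ref` and `alt` are carried through opaquely; summary columns
#'   `missing_frac` and `maf` are (re)computed from the calls so they can
#'   never drift out of sync with the data.
#'
#' @return An object of class `geno_matrix`.
#' @export
#' @examples
#' g <- geno_matrix(matrix(c(0L, 2L, 1L, NA), 2, 2,
#'   dimnames = list(c("A1", "A2"), c("M1", "M2"))))
#' g
geno_matrix <- function(calls, marker_info = NULL) {
  if (!is.matrix(calls)) stop("`calls` must be a matrix", call. = FALSE)
  mode(calls) <- "integer"
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2)) {
    stop("genotype calls must be 0 (hom ref), 1 (het), 2 (hom alt) or NA",
         call. = FALSE)
  }
  if (is.null(rownames(calls)) || is.null(colnames(calls))) {
    stop("`calls` must have accession row names and marker column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(calls))) stop("duplicate accession ids", call. = FALSE)
  if (anyDuplicated(colnames(calls))) stop("duplicate marker ids", call. = FALSE)
  info <- build_marker_info(calls, marker_info)
  structure(list(calls = calls, marker_info = info), class = "geno_matrix")
}

build_marker_info <- function(calls, marker_info = NULL) {
  base <- tibble::tibble(
    marker_id = colnames(calls),
    missing_frac = colMeans(is.na(calls)),
    maf = marker_maf(calls)
  )
  if (is.null(marker_info)) return(base)
  marker_info <- tibble::as_tibble(marker_info)
  if (!"marker_id" %in% names(marker_info)) {
    stop("`marker_info` needs a marker_id column", call. = FALSE)
  }
  if (!setequal(marker_info$marker_id, colnames(calls))) {
    stop("`marker_info$marker_id` must match the call matrix columns",
         call. = FALSE)
  }
  extra <- marker_info[match(base$marker_id, marker_info$marker_id),
                       setdiff(names(marker_info),
                               c("marker_id", "missing_frac", "maf")),
                       drop = FALSE]
  dplyr::bind_cols(base["marker_id"], extra, base[c("missing_frac", "maf")])
}

# Minor-allele frequency per marker on non-missing calls; a HET call
# contributes one copy of each allele.
marker_maf <- function(calls) {
  n_obs <- colSums(!is.na(calls))
  alt <- colSums(calls, na.rm = TRUE)        # alt-allele dosage 0/1/2
  p <- ifelse(n_obs > 0, alt / (2 * n_obs), NA_real_)
  pmin(p, 1 - p)
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d accessions x %d markers\n",
              nrow(x$calls), ncol(x$calls)))
  cat(sprintf("  missing: %.1f%% of calls; het: %.1f%% of non-missing calls\n",
              100 * mean(is.na(x$calls)),
              100 * mean(x$calls == 1L, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Accession and marker identifiers of a genotype matrix
#' @param x A [geno_matrix()].
#' @return Character vector of ids.
#' @export
accessions <- function(x) rownames(x$calls)

#' @rdname accessions
#' @export
markers <- function(x) colnames(x$calls)

#' Subset a genotype matrix
#'
#' Row (accession) and column (marker) subsetting by name, index or logical
#' mask; marker summary statistics are recomputed on the subset.
#'
#' @param x A [geno_matrix()].
#' @param i,j Accession and marker selectors.
#' @param ... Unused.
#' @return A `geno_matrix`.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  calls <- x$calls[i, j, drop = FALSE]
  keep <- x$marker_info[match(colnames(calls), x$marker_info$marker_id), ]
  geno_matrix(calls, keep)
}

#' Coerce a tabular genotype object to `geno_matrix`
#'
#' Accepts a data frame whose first column holds accession ids and whose
#' remaining columns are markers with cells in `{0, 1, 2, NA}`, or a named
#' matrix.
#'
#' @param x Data frame or matrix.
#' @param ... Passed to [geno_matrix()].
#' @return A `geno_matrix`.
#' @export
as_geno_matrix <- function(x, ...) {
  if (inherits(x, "geno_matrix")) return(x)
  if (is.data.frame(x)) {
    ids <- as.character(x[[1]])
    m <- as.matrix(x[, -1, drop = FALSE])
    mode(m) <- "integer"
    rownames(m) <- ids
    return(geno_matrix(m, ...))
  }
  geno_matrix(x, ...)
}

#' Turn a genotype matrix into a long tibble of calls
#'
#' @param x A [geno_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `accession_id`, `marker_id`, `call`
#'   (integer dosage) and `state` (factor: hom_ref/het/hom_alt/missing).
#' @export
tidy.geno_matrix <- function(x, ...) {
  out <- tibble::as_tibble(as.table(x$calls), .name_repair = "minimal")
  names(out) <- c("accession_id", "marker_id", "call")
  out$call <- as.integer(out$call)
  out$state <- factor(
    dplyr::case_when(
      is.na(out$call) ~ "missing",
      out$call == 0L ~ "hom_ref",
      out$call == 1L ~ "het",
      TRUE ~ "hom_alt"
    ),
    levels = c("hom_ref", "het", "hom_alt", "missing")
  )
  out
}

#' One-row summary of a genotype matrix
#' @param x A [geno_matrix()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.geno_matrix <- function(x, ...) {
  tibble::tibble(
    n_accessions = nrow(x$calls),
    n_markers = ncol(x$calls),
    missing_frac = mean(is.na(x$calls)),
    het_frac = mean(x$calls == 1L, na.rm = TRUE),
    median_maf = stats::median(x$marker_info$maf, na.rm = TRUE)
  )
}
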