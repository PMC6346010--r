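#' Read a VCF file into a genotype matrix
#'
#' Diploid genotypes are mapped onto the four-state coding: `0/0` -> hom
#' ref, `0/1`/`1/0` -> het, `1/1` -> hom alt, `./.` -> missing. Phased and
#' unphased genotypes are treated identically. Only biallelic SNP records
#' are kept; multiallelic or indel records are skipped with a message (or
#' rejected, per `multiallelic`). Positions and alleles are carried through
#' opaquely into `marker_info`.
#'
#' @param path Path to a VCF (v4.x) file, plain or gzipped.
#' @param multiallelic `"skip"` (default, logs the count) or `"error"`.
#' @return A [geno_matrix()] with accessions as rows.
#' @export
read_vcf <- function(path, multiallelic = c("skip", "error")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE))
  ok <- !is.na(fix$REF) & !is.na(fix$ALT) &
    !grepl(",", fix$ALT, fixed = TRUE) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L
  if (any(!ok)) {
    if (multiallelic == "error") {
      stop(sum(!ok), " multiallelic or non-SNP record(s) in ", path, call. = FALSE)
    }
    message("read_vcf: skipped ", sum(!ok), " multiallelic/non-SNP record(s)")
  }
  if (!any(ok)) stop("no biallelic SNP records in ", path, call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")[ok, , drop = FALSE]
  fix <- fix[ok, ]
  marker_id <- ifelse(is.na(fix$ID) | fix$ID == ".",
                      paste0(fix$CHROM, "_", fix$POS), fix$ID)
  m <- t(gt)                               # samples x markers
  calls <- matrix(decode_gt(m), nrow = nrow(m),
                  dimnames = list(rownames(m), marker_id))
  info <- tibble::tibble(
    marker_id = marker_id, chrom = fix$CHROM,
    pos = suppressWarnings(as.integer(fix$POS)),
    ref = fix$REF, alt = fix$ALT
  )
  geno_matrix(calls, info)
}

decode_gt <- function(gt) {
  gt <- sub("|", "/", gt, fixed = TRUE)
  out <- rep(NA_integer_, length(gt))
  out[gt %in% c("0/0", "0")] <- 0L
  out[gt %in% c("0/1", "1/0")] <- 1L
  out[gt %in% c("1/1", "1")] <- 2L
  out
}

#' Read a HapMap-format genotype table
#'
#' Tab-delimited HapMap text as produced by GBS pipelines: 11 annotation
#' columns (`rs#`, `alleles`, `chrom`, `pos`, ...) followed by one column
#' per sample, cells as IUPAC single-letter codes or two-letter diploid
#' genotypes. Heterozygote IUPAC codes (R, Y, S, W, K, M) map to het and
#' `N`/`NN` to missing.
#'
#' The four-state coding needs an allele polarity. With
#' `polarity = "alleles"` (default) the first allele of the `alleles`
#' column is the reference — GBS HapMap writers order that field
#' major/minor, and the package's own writer emits ref/alt, making
#' read/write lossless. With `polarity = "major"` the reference is recoded
#' to the observed major allele, ties broken alphabetically.
#'
#' @param path Path to the HapMap text file.
#' @param polarity `"alleles"` or `"major"`.
#' @param nonbiallelic `"skip"` (default) or `"error"` for rows whose
#'   alleles field is not two single bases.
#' @return A [geno_matrix()].
#' @export
read_hapmap <- function(path, polarity = c("alleles", "major"),
                        nonbiallelic = c("skip", "error")) {
  polarity <- match.arg(polarity)
  nonbiallelic <- match.arg(nonbiallelic)
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(tab) < 12L) stop("not a HapMap table (needs 11 meta columns + samples)",
                            call. = FALSE)
  alleles <- strsplit(tab[[2]], "/", fixed = TRUE)
  ok <- vapply(alleles, function(a) {
    length(a) == 2L && all(nchar(a) == 1L) && all(a %in% c("A", "C", "G", "T"))
  }, logical(1))
  if (any(!ok)) {
    if (nonbiallelic == "error") stop(sum(!ok), " non-biallelic HapMap row(s)", call. = FALSE)
    message("read_hapmap: skipped ", sum(!ok), " non-biallelic row(s)")
  }
  if (!any(ok)) stop("no biallelic rows in ", path, call. = FALSE)
  tab <- tab[ok, ]
  alleles <- alleles[ok]
  samples <- names(tab)[-(1:11)]
  raw <- as.matrix(tab[, -(1:11), drop = FALSE])
  calls <- matrix(NA_integer_, nrow = nrow(tab), ncol = length(samples))
  for (r in seq_len(nrow(tab))) {
    calls[r, ] <- decode_hapmap_cell(raw[r, ], alleles[[r]][1], alleles[[r]][2])
  }
  if (polarity == "major") {
    # reference := observed major allele; ties -> alphabetically first
    for (r in seq_len(nrow(tab))) {
      a <- alleles[[r]]
      dose <- calls[r, ]
      alt_copies <- sum(dose, na.rm = TRUE)
      ref_copies <- 2 * sum(!is.na(dose)) - alt_copies
      flip <- alt_copies > ref_copies ||
        (alt_copies == ref_copies && a[2] < a[1])
      if (flip) {
        calls[r, ] <- 2L - calls[r, ]
        alleles[[r]] <- rev(a)
      }
    }
  }
  calls <- t(calls)
  rownames(calls) <- samples
  colnames(calls) <- tab[[1]]
  info <- tibble::tibble(
    marker_id = tab[[1]], chrom = tab[[3]],
    pos = suppressWarnings(as.integer(tab[[4]])),
    ref = vapply(alleles, `[`, "", 1), alt = vapply(alleles, `[`, "", 2)
  )
  geno_matrix(calls, info)
}

iupac_het <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

decode_hapmap_cell <- function(cells, ref, alt) {
  cells <- toupper(cells)
  out <- rep(NA_integer_, length(cells))
  hom_ref <- c(ref, paste0(ref, ref))
  hom_alt <- c(alt, paste0(alt, alt))
  het_pair <- paste(sort(c(ref, alt)), collapse = "")
  het_codes <- c(names(iupac_het)[iupac_het == het_pair],
                 paste0(ref, alt), paste0(alt, ref))
  out[cells %in% hom_ref] <- 0L
  out[cells %in% hom_alt] <- 2L
  out[cells %in% het_codes] <- 1L
  out
}

#' Read a CSV genotype table
#'
#' Accessions as rows (first column `accession_id`), markers as columns,
#' cells in `{0, 1, 2, NA}` (alt-allele dosage).
#'
#' @param path Path to the CSV file.
#' @return A [geno_matrix()].
#' @export
read_geno_csv <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_integer()), progress = FALSE)
  as_geno_matrix(as.data.frame(tab))
}

#' Write a genotype matrix to disk
#'
#' Lossless for the four-state coding in all three formats: reading the
#' written file reproduces `calls` exactly. VCF and HapMap need per-marker
#' `chrom`/`pos`/`ref`/`alt`; when `marker_info` lacks them, deterministic
#' placeholders are used (chrom `"1"`, positions in marker order, alleles
#' A/C).
#'
#' @param x A [geno_matrix()].
#' @param path Output file path.
#' @param format One of `"csv"`, `"vcf"`, `"hapmap"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, format = c("csv", "vcf", "hapmap")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "geno_matrix"))
  switch(format,
    csv = write_geno_csv(x, path),
    vcf = write_geno_vcf(x, path),
    hapmap = write_geno_hapmap(x, path)
  )
  invisible(path)
}

write_geno_csv <- function(x, path) {
  tab <- tibble::as_tibble(x$calls, rownames = "accession_id")
  readr::write_csv(tab, path, na = "NA", progress = FALSE)
}

marker_anno <- function(x) {
  info <- x$marker_info
  n <- nrow(info)
  tibble::tibble(
    marker_id = info$marker_id,
    chrom = if ("chrom" %in% names(info)) info$chrom else rep("1", n),
    pos = if ("pos" %in% names(info)) info$pos else seq_len(n),
    ref = if ("ref" %in% names(info)) info$ref else rep("A", n),
    alt = if ("alt" %in% names(info)) info$alt else rep("C", n)
  )
}

write_geno_vcf <- function(x, path) {
  an <- marker_anno(x)
  gt_code <- c("0/0", "0/1", "1/1")
  body <- matrix("./.", nrow(x$calls), ncol(x$calls))   # accessions x markers
  idx <- !is.na(x$calls)
  body[idx] <- gt_code[x$calls[idx] + 1L]
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=genocurate",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(x$calls)), collapse = "\t"),
    paste(an$chrom, an$pos, an$marker_id, an$ref, an$alt, ".", "PASS", ".",
          "GT",
          vapply(seq_len(ncol(body)), function(j) {
            paste(body[, j], collapse = "\t")
          }, ""),
          sep = "\t")
  )
  writeLines(lines, path)
}

write_geno_hapmap <- function(x, path) {
  an <- marker_anno(x)
  cell <- function(col, ref, alt) {
    out <- rep("NN", length(col))
    out[!is.na(col)] <- c(paste0(ref, ref), paste0(ref, alt),
                          paste0(alt, alt))[col[!is.na(col)] + 1L]
    out
  }
  body <- vapply(seq_len(ncol(x$calls)), function(j) {
    paste(cell(x$calls[, j], an$ref[j], an$alt[j]), collapse = "\t")
  }, "")
  header <- paste(c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                    "center", "protLSID", "assayLSID", "panelLSID", "QCcode",
                    rownames(x$calls)), collapse = "\t")
  lines <- c(header,
             paste(an$marker_id, paste0(an$ref, "/", an$alt), an$chrom, an$pos,
                   "+", "NA", "NA", "NA", "NA", "NA", "NA", body, sep = "\t"))
  writeLines(lines, path)
}

#' Read an accession metadata table
#'
#' A delimited table with required columns `accession_id` and
#' `genebank_id`; optional `sample_type` (`original`,
#' `biological_replicate`, `seed_split`; anything else falls back to
#' `original` with a warning), `parent_accession_id`, `origin_region` and
#' `collection_date`. Replicates and seed splits must reference an existing
#' parent accession.
#'
#' @param path Path to a CSV file.
#' @return A tibble of accession records.
#' @export
read_metadata <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  validate_records(tab)
}

#' Validate (and normalise) accession records
#'
#' @param records Data frame with at least `accession_id` and `genebank_id`.
#' @return A validated tibble with the full set of record columns.
#' @export
validate_records <- function(records) {
  tab <- tibble::as_tibble(records)
  need <- c("accession_id", "genebank_id")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  for (col in c("sample_type", "parent_accession_id", "origin_region",
                "collection_date")) {
    if (!col %in% names(tab)) tab[[col]] <- NA_character_
  }
  tab$sample_type[is.na(tab$sample_type) | tab$sample_type == ""] <- "original"
  known <- c("original", "biological_replicate", "seed_split")
  bad <- !tab$sample_type %in% known
  if (any(bad)) {
    warning("unknown sample_type for ", sum(bad),
            " record(s); treated as 'original'", call. = FALSE)
    tab$sample_type[bad] <- "original"
  }
  tab$parent_accession_id[tab$parent_accession_id %in% ""] <- NA_character_
  if (anyDuplicated(tab$accession_id)) {
    stop("duplicate accession_id in metadata", call. = FALSE)
  }
  child <- tab$sample_type != "original"
  orphan <- child & (is.na(tab$parent_accession_id) |
                       !tab$parent_accession_id %in% tab$accession_id)
  if (any(orphan)) {
    stop("replicate/seed_split record(s) with missing parent: ",
         paste(tab$accession_id[orphan], collapse = ", "), call. = FALSE)
  }
  tab[c("accession_id", "genebank_id", "sample_type", "parent_accession_id",
        "origin_region", "collection_date")]
}

#' Write accession records to CSV
#' @param records Tibble from [read_metadata()] or [validate_records()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(records, path) {
  readr::write_csv(records, path, na = "", progress = FALSE)
  invisible(path)
}
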