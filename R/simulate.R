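#' Configuration for the synthetic panel generator
#'
#' Describes a two-lineage, highly selfing species panel of the kind a
#' genebank-curation pipeline faces: deeply diverged lineages (bimodal
#' pIBS), genebank collections that resample a shared founder pool (hence
#' within- and cross-genebank duplicates with varying group sizes),
#' per-call genotyping error, per-marker missingness, residual
#' heterozygote miscalls, a few mixed-seed (heterogeneous) accessions, and
#' biological replicates for error calibration — some of them deliberate
#' sample mixups.
#'
#' `error_rate` is calibrated on the scale the pipeline measures it: the
#' expected genotype discordance between two independent measurements of
#' the same material (the replicate 1 - pIBS of the error-rate
#' estimator). Internally each copy's homozygous calls flip symmetrically
#' with per-call probability q solving 2q(1-q) = `error_rate`.
#'
#' @param seed Integer RNG seed; runs are bit-reproducible.
#' @param n_markers Number of biallelic SNP markers (default 5000).
#' @param lineage_divergence Fraction of markers fixed-different between
#'   the two lineages (default 0.3).
#' @param maf_range Within-lineage minor-allele-frequency range for the
#'   polymorphic markers (default `c(0.05, 0.5)`).
#' @param n_founders Distinct founder genotypes per lineage (default 90;
#'   with 300 accessions this yields roughly half the panel duplicated,
#'   like a poorly curated collection).
#' @param collections Tibble with `genebank_id`, `n_accessions`,
#'   `p_lineage1` (probability an accession comes from lineage 1).
#' @param error_rate Expected replicate discordance (default 0.005).
#' @param het_rate Probability a homozygous call is miscalled het
#'   (default 0.02).
#' @param missing_beta Shape parameters of the Beta distribution from
#'   which each marker's missing-call rate is drawn (default
#'   `c(1.5, 8.5)`, mean 15% with a long right tail). A first shape of 0
#'   disables missingness entirely.
#' @param n_heterogeneous Accessions planted as two-founder seed mixtures
#'   (default 2).
#' @param n_seed_samples Seed-split samples genotyped per heterogeneous
#'   accession, half from each founder (default 12).
#' @param n_replicated Accessions given biological replicates (default 30).
#' @param replicates_per Replicates per replicated accession (default 1).
#' @param n_anomalous_replicates Replicate samples silently drawn from the
#'   wrong founder, emulating sample mixups (default 2).
#' @param origin_regions Region labels attached to lineages 1 and 2
#'   (default `c("caspian_west", "caspian_east")`).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_markers = 5000L,
                       lineage_divergence = 0.3,
                       maf_range = c(0.05, 0.5),
                       n_founders = 90L,
                       collections = tibble::tibble(
                         genebank_id = c("GB1", "GB2", "GB3"),
                         n_accessions = c(150L, 100L, 50L),
                         p_lineage1 = c(0.6, 0.5, 0.4)
                       ),
                       error_rate = 0.005,
                       het_rate = 0.02,
                       missing_beta = c(1.5, 8.5),
                       n_heterogeneous = 2L,
                       n_seed_samples = 12L,
                       n_replicated = 30L,
                       replicates_per = 1L,
                       n_anomalous_replicates = 2L,
                       origin_regions = c("caspian_west", "caspian_east")) {
  cfg <- list(seed = as.integer(seed), n_markers = as.integer(n_markers),
              lineage_divergence = lineage_divergence, maf_range = maf_range,
              n_founders = as.integer(n_founders),
              collections = tibble::as_tibble(collections),
              error_rate = error_rate, het_rate = het_rate,
              missing_beta = missing_beta,
              n_heterogeneous = as.integer(n_heterogeneous),
              n_seed_samples = as.integer(n_seed_samples),
              n_replicated = as.integer(n_replicated),
              replicates_per = as.integer(replicates_per),
              n_anomalous_replicates = as.integer(n_anomalous_replicates),
              origin_regions = origin_regions)
  rates <- c(cfg$lineage_divergence, cfg$error_rate, cfg$het_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]", call. = FALSE)
  if (cfg$error_rate > 0.5) stop("error_rate is a pairwise discordance; must be <= 0.5",
                                 call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Simulate a genotype panel with truth tables
#'
#' Founder genotypes (fully homozygous, as expected for a selfing species)
#' are drawn per lineage; each genebank's accessions copy founders sampled
#' with replacement, so two accessions sharing a founder are true
#' duplicates — within or across genebanks. Every genotyped sample
#' (accession, replicate, seed split) is an independent noisy measurement
#' of its founder genotype: symmetric homozygote flips, het miscalls, and
#' per-marker missingness.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_panel`: `geno` ([geno_matrix()] of all
#'   samples), `records` (metadata tibble usable by every pipeline
#'   function), and `truth` — a list with `samples` (per-sample founder,
#'   lineage and region), `heterogeneous` (planted seed mixtures),
#'   `anomalous_replicates` (planted mixups) and the `config`.
#' @export
simulate_panel <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  m <- cfg$n_markers
  n_div <- round(cfg$lineage_divergence * m)
  div_idx <- seq_len(n_div)
  # which lineage carries the alt allele at each divergent marker
  alt_in_l2 <- sample(c(TRUE, FALSE), n_div, replace = TRUE)

  founder_lineage <- rep(c("L1", "L2"), each = cfg$n_founders)
  founder_id <- paste0(founder_lineage, "_F",
                       sprintf("%03d", rep(seq_len(cfg$n_founders), 2)))
  founders <- matrix(0L, length(founder_id), m,
                     dimnames = list(founder_id, NULL))
  founders[founder_lineage == "L1", div_idx] <-
    rep(ifelse(alt_in_l2, 0L, 2L), each = cfg$n_founders)
  founders[founder_lineage == "L2", div_idx] <-
    rep(ifelse(alt_in_l2, 2L, 0L), each = cfg$n_founders)
  if (n_div < m) {
    poly <- (n_div + 1):m
    for (lin in c("L1", "L2")) {
      p <- stats::runif(length(poly), cfg$maf_range[1], cfg$maf_range[2])
      rows <- which(founder_lineage == lin)
      draw <- matrix(stats::rbinom(length(rows) * length(poly), 1,
                                   rep(p, each = length(rows))) * 2L,
                     nrow = length(rows))
      founders[rows, poly] <- draw
    }
  }

  # accessions resample the founder pool
  acc <- purrr::pmap_dfr(cfg$collections, function(genebank_id, n_accessions,
                                                   p_lineage1) {
    lin <- ifelse(stats::runif(n_accessions) < p_lineage1, "L1", "L2")
    fidx <- vapply(lin, function(l) {
      sample(which(founder_lineage == l), 1)
    }, integer(1))
    tibble::tibble(genebank_id = genebank_id, lineage = lin,
                   founder = founder_id[fidx])
  })
  acc$accession_id <- sprintf("%s_A%03d", acc$genebank_id,
                              stats::ave(seq_len(nrow(acc)), acc$genebank_id,
                                         FUN = seq_along))

  samples <- tibble::tibble(
    sample_id = acc$accession_id, genebank_id = acc$genebank_id,
    sample_type = "original", parent_accession_id = NA_character_,
    founder_id = acc$founder, lineage = acc$lineage
  )

  # planted heterogeneous accessions: seed splits from two founders
  het_truth <- tibble::tibble(accession_id = character(),
                              founder_a = character(), founder_b = character())
  if (cfg$n_heterogeneous > 0) {
    het_acc <- sample(acc$accession_id, cfg$n_heterogeneous)
    for (a in het_acc) {
      row <- samples[samples$sample_id == a, ]
      pool <- setdiff(founder_id[founder_lineage == row$lineage], row$founder_id)
      fb <- sample(pool, 1)
      het_truth <- dplyr::add_row(het_truth, accession_id = a,
                                  founder_a = row$founder_id, founder_b = fb)
      n_a <- ceiling(cfg$n_seed_samples / 2)
      n_b <- cfg$n_seed_samples - n_a
      seeds <- tibble::tibble(
        sample_id = sprintf("%s_seed%02d", a, seq_len(cfg$n_seed_samples)),
        genebank_id = row$genebank_id, sample_type = "seed_split",
        parent_accession_id = a,
        founder_id = c(rep(row$founder_id, n_a), rep(fb, n_b)),
        lineage = row$lineage
      )
      samples <- dplyr::bind_rows(samples, seeds)
    }
  }

  # biological replicates; a few are planted mixups from the wrong founder
  anomalous <- tibble::tibble(sample_id = character(),
                              parent_accession_id = character(),
                              true_founder = character())
  if (cfg$n_replicated > 0) {
    pool <- setdiff(acc$accession_id, het_truth$accession_id)
    rep_acc <- sample(pool, min(cfg$n_replicated, length(pool)))
    reps <- purrr::map_dfr(rep_acc, function(a) {
      row <- samples[samples$sample_id == a, ]
      tibble::tibble(
        sample_id = sprintf("%s_rep%d", a, seq_len(cfg$replicates_per)),
        genebank_id = row$genebank_id, sample_type = "biological_replicate",
        parent_accession_id = a, founder_id = row$founder_id,
        lineage = row$lineage
      )
    })
    if (cfg$n_anomalous_replicates > 0 && nrow(reps) > 0) {
      bad <- sample(seq_len(nrow(reps)),
                    min(cfg$n_anomalous_replicates, nrow(reps)))
      for (b in bad) {
        lin <- reps$lineage[b]
        wrong <- sample(setdiff(founder_id[founder_lineage == lin],
                                reps$founder_id[b]), 1)
        anomalous <- dplyr::add_row(anomalous, sample_id = reps$sample_id[b],
                                    parent_accession_id = reps$parent_accession_id[b],
                                    true_founder = reps$founder_id[b])
        reps$founder_id[b] <- wrong
      }
    }
    samples <- dplyr::bind_rows(samples, reps)
  }

  # independent noisy measurement of every sample's founder genotype
  truth_calls <- founders[samples$founder_id, , drop = FALSE]
  g <- add_call_noise(truth_calls, cfg)
  rownames(g) <- samples$sample_id
  colnames(g) <- sprintf("S%05d", seq_len(m))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  info <- tibble::tibble(marker_id = colnames(g), chrom = "1",
                         pos = seq_len(m) * 100L, ref = ref, alt = unname(alt),
                         divergent = seq_len(m) %in% div_idx)
  geno <- geno_matrix(g, info)

  region <- stats::setNames(cfg$origin_regions, c("L1", "L2"))
  records <- tibble::tibble(
    accession_id = samples$sample_id,
    genebank_id = samples$genebank_id,
    sample_type = samples$sample_type,
    parent_accession_id = samples$parent_accession_id,
    origin_region = unname(region[samples$lineage]),
    collection_date = NA_character_
  )
  samples$origin_region <- unname(region[samples$lineage])

  structure(list(geno = geno, records = records,
                 truth = list(samples = samples, heterogeneous = het_truth,
                              anomalous_replicates = anomalous,
                              config = cfg)),
            class = "sim_panel")
}

# Noise channels, in order: symmetric homozygote flip (per-copy rate q with
# 2q(1-q) = error_rate), het miscall, per-marker missingness.
add_call_noise <- function(truth, cfg) {
  n <- nrow(truth); m <- ncol(truth)
  g <- truth
  q <- (1 - sqrt(1 - 2 * cfg$error_rate)) / 2
  if (q > 0) {
    flip <- matrix(stats::runif(n * m) < q, n, m)
    flip <- flip & !is.na(g) & g != 1L
    g[flip] <- 2L - g[flip]
  }
  if (cfg$het_rate > 0) {
    hets <- matrix(stats::runif(n * m) < cfg$het_rate, n, m)
    hets <- hets & !is.na(g) & g != 1L
    g[hets] <- 1L
  }
  miss_rate <- if (cfg$missing_beta[1] <= 0) rep(0, m) else
    stats::rbeta(m, cfg$missing_beta[1], cfg$missing_beta[2])
  miss <- matrix(stats::runif(n * m) < rep(miss_rate, each = n), n, m)
  g[miss] <- NA_integer_
  g
}

#' Bulk-tissue genotype of a two-genotype mixture
#'
#' The call observed when tissue from two homozygous genotypes is pooled
#' before genotyping: concordant sites keep the shared call, discordant
#' homozygous sites read heterozygous, and a missing call in either
#' component is missing.
#'
#' @param a,b Integer call vectors in `{0, 1, 2, NA}`.
#' @return Integer call vector.
#' @export
mix_bulk <- function(a, b) {
  out <- ifelse(is.na(a) | is.na(b), NA_integer_,
                ifelse(a == b, a, 1L))
  as.integer(out)
}

#' @export
print.sim_panel <- function(x, ...) {
  cat(sprintf("<sim_panel> %d samples x %d markers (%d original accessions)\n",
              nrow(x$geno$calls), ncol(x$geno$calls),
              sum(x$truth$samples$sample_type == "original")))
  cat(sprintf("  %d founders used, %d heterogeneous, %d replicated, %d mixup replicate(s)\n",
              dplyr::n_distinct(x$truth$samples$founder_id),
              nrow(x$truth$heterogeneous),
              sum(x$truth$samples$sample_type == "biological_replicate"),
              nrow(x$truth$anomalous_replicates)))
  invisible(x)
}

#' Distribution summaries of a genotype panel
#'
#' Summarises the pairwise identity structure: with lineage labels (from a
#' `sim_panel` truth table or supplied directly) it contrasts within- and
#' between-lineage pIBS and checks the expected bimodality — the
#' between-lineage mode must sit strictly below the within-lineage mode.
#'
#' @param x A `sim_panel` or a [geno_matrix()].
#' @param lineage Optional named character vector (accession -> lineage
#'   label); taken from truth tables when `x` is a `sim_panel`.
#' @param min_sites Minimum comparable sites per pair; default 100.
#' @return A list of class `panel_summary`: `pibs_pairs` (tibble with
#'   `within_lineage` flag where labels are known), `modes` (within /
#'   between density modes), `bimodal` (logical or `NA`), `het_range`,
#'   `marker_missing_range`.
#' @export
summarize_panel <- function(x, lineage = NULL, min_sites = 100) {
  if (inherits(x, "sim_panel")) {
    orig <- x$truth$samples[x$truth$samples$sample_type == "original", ]
    lineage <- stats::setNames(orig$lineage, orig$sample_id)
    geno <- x$geno[orig$sample_id, ]
  } else {
    geno <- x
  }
  pairs <- pibs_matrix(geno, min_sites = min_sites)
  stats <- sample_stats(geno)
  out <- list(
    pibs_pairs = pairs,
    modes = c(within = NA_real_, between = NA_real_),
    bimodal = NA,
    het_range = range(stats$accessions$het_frac, na.rm = TRUE),
    marker_missing_range = range(stats$markers$missing_frac)
  )
  if (!is.null(lineage)) {
    pairs$within_lineage <- lineage[pairs$accession_i] == lineage[pairs$accession_j]
    out$pibs_pairs <- pairs
    ok <- !is.na(pairs$pibs)
    dmode <- function(v) {
      if (length(v) < 2) return(stats::median(v))
      d <- stats::density(v)
      d$x[which.max(d$y)]
    }
    w <- pairs$pibs[ok & pairs$within_lineage]
    b <- pairs$pibs[ok & !pairs$within_lineage]
    if (length(w) && length(b)) {
      out$modes <- c(within = dmode(w), between = dmode(b))
      out$bimodal <- out$modes[["between"]] < out$modes[["within"]]
    }
  }
  structure(out, class = "panel_summary")
}

#' @export
print.panel_summary <- function(x, ...) {
  cat("<panel_summary>\n")
  if (!is.na(x$bimodal)) {
    cat(sprintf("  pIBS modes: within-lineage %.3f, between-lineage %.3f (%s)\n",
                x$modes[["within"]], x$modes[["between"]],
                if (x$bimodal) "bimodal" else "not bimodal"))
  }
  cat(sprintf("  sample heterozygosity: %.1f%% - %.1f%%\n",
              100 * x$het_range[1], 100 * x$het_range[2]))
  cat(sprintf("  marker missingness: %.1f%% - %.1f%%\n",
              100 * x$marker_missing_range[1], 100 * x$marker_missing_range[2]))
  invisible(x)
}
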