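#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Histogram of pairwise identity coefficients
#'
#' A structured panel shows the characteristic bimodal pIBS distribution:
#' a between-lineage peak well below a within-lineage peak, with
#' duplicates piling up against 1. The identity threshold is drawn as a
#' dashed line.
#'
#' @param object A `pibs_tbl` from [pibs_matrix()].
#' @param threshold Identity threshold to mark; default 0.99.
#' @param bins Histogram bins; default 60.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pibs_tbl <- function(object, threshold = 0.99, bins = 60, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$pibs))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pibs))
  if ("within_lineage" %in% names(df)) {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pibs,
                                          fill = .data$within_lineage))
  }
  p +
    ggplot2::geom_histogram(bins = bins, alpha = 0.8, position = "identity") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "pairwise identity by state (pIBS)", y = "pairs",
                  fill = "within lineage") +
    ggplot2::theme_minimal()
}

#' Replicate concordance plot for an error-rate report
#'
#' Each point is one accession-replicate comparison; anomalous pairs
#' (below the identity threshold, flagged for mixup or heterogeneity
#' follow-up) are highlighted.
#'
#' @param object An `error_rate_report` from [error_rate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.error_rate_report <- function(object, ...) {
  df <- object$pairs |>
    dplyr::arrange(.data$pibs) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$pibs,
                                   colour = .data$anomalous)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "replicate pair (ranked by pIBS)",
                  y = "pIBS with biological replicate", colour = "anomalous") +
    ggplot2::theme_minimal()
}

#' Bar chart of per-genebank uniqueness
#'
#' @param summary A tibble from [genebank_summary()].
#' @return A ggplot object.
#' @export
plot_genebank_summary <- function(summary) {
  df <- tidyr::pivot_longer(summary,
                            c("percent_unique", "percent_duplicated"),
                            names_to = "status", values_to = "percent") |>
    dplyr::mutate(status = sub("percent_", "", .data$status))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$genebank_id, y = .data$percent,
                                   fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of genebank accessions", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of cross-genebank sharing (Venn cells)
#'
#' @param x A `sharing_summary` from [sharing_summary()].
#' @return A ggplot object.
#' @export
plot_sharing <- function(x) {
  stopifnot(inherits(x, "sharing_summary"))
  ggplot2::ggplot(x$cells,
                  ggplot2::aes(x = stats::reorder(.data$genebanks, .data$n_genebanks),
                               y = .data$n_groups)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_groups), vjust = -0.3) +
    ggplot2::labs(x = "genebank combination",
                  y = "globally unique groups") +
    ggplot2::theme_minimal()
}
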