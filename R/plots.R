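#' Plot the per-variant F1 distribution
#'
#' Histograms of REF- and ALT-perspective F1 scores; well-genotyped SVs
#' cluster near 1, poorly genotyped ones near 0 (bimodal when short-read
#' genotyping fails for a subset of variants).
#'
#' @param scores Concordance tibble from [score_concordance()].
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_f1_distribution <- function(scores, bins = 40) {
  df <- tidyr::pivot_longer(
    scores[, c("variant_id", "f1_ref", "f1_alt")],
    cols = c("f1_ref", "f1_alt"),
    names_to = "perspective", values_to = "f1")
  df$perspective <- toupper(sub("^f1_", "", df$perspective))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$f1)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~perspective) +
    ggplot2::geom_vline(xintercept = c(0.2, 0.8), linetype = "dashed") +
    ggplot2::labs(x = "per-variant F1", y = "SV count",
                  title = "Genotype concordance against the truth set") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.eqtl_scan <- function(object, fdr = 0.05, ...) {
  df <- object$results
  df$significant <- df$fdr < fdr
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta, y = -log10(.data$p),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "effect size (beta, INT scale)",
                  y = expression(-log[10](p)),
                  colour = sprintf("FDR < %.2g", fdr)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.sveqtl_enrichment <- function(object, ...) {
  df <- tibble::tibble(stat = object$perm_stats)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stat)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "darkgreen",
                        linewidth = 1) +
    ggplot2::labs(x = "permutation statistic", y = "count",
                  title = sprintf("observed = %.3g, p = %.4g",
                                  object$observed, object$p)) +
    ggplot2::theme_minimal()
}

#' Plot absolute effect size against minor allele frequency
#'
#' @param leads Association tibble with `beta` and `allele_frequency`.
#' @return A ggplot object.
#' @export
plot_effect_frequency <- function(leads) {
  df <- dplyr::mutate(leads,
                      maf = pmin(.data$allele_frequency,
                                 1 - .data$allele_frequency),
                      abs_beta = abs(.data$beta))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$maf, y = .data$abs_beta)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = "minor allele frequency", y = "|beta| (INT scale)") +
    ggplot2::theme_minimal()
}

#' Plot TE family composition per SV group
#'
#' @param composition Tibble from [te_composition()].
#' @param level_type `"family"` or `"class"`.
#' @return A ggplot object.
#' @export
plot_te_composition <- function(composition, level_type = "family") {
  df <- composition[composition$level_type == level_type, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$fraction,
                                   fill = .data$level)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of SVs", fill = level_type) +
    ggplot2::theme_minimal()
}
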