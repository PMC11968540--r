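#' Effect size vs allele frequency trend
#'
#' Rare alleles are expected to carry larger expression effects. Computes
#' the Spearman rank correlation between minor allele frequency (allele
#' frequency folded at 0.5) and absolute effect size over lead
#' associations, plus equal-width frequency-bin means.
#'
#' @param leads Association tibble with `beta` and `allele_frequency`
#'   (typically lead rows of a scan).
#' @param n_bins Number of equal-width MAF bins on \[0, 0.5\].
#' @return List: `trend` (tibble `rho`, `p`, `n`) and `bins` (tibble `bin`,
#'   `maf_mid`, `mean_abs_beta`, `n`).
#' @export
effect_frequency_trend <- function(leads, n_bins = 5) {
  if (nrow(leads) < 10) rlang::abort("Need at least 10 lead associations.")
  maf <- pmin(leads$allele_frequency, 1 - leads$allele_frequency)
  ab <- abs(leads$beta)
  if (max(maf) == min(maf)) {
    rlang::warn("All allele frequencies equal; trend undefined.")
    trend <- tibble::tibble(rho = NA_real_, p = NA_real_, n = length(maf))
  } else {
    ct <- suppressWarnings(stats::cor.test(maf, ab, method = "spearman"))
    trend <- tibble::tibble(rho = unname(ct$estimate), p = ct$p.value,
                            n = length(maf))
  }
  breaks <- seq(0, 0.5, length.out = n_bins + 1)
  bin <- cut(maf, breaks, include.lowest = TRUE)
  bins <- tibble::tibble(maf = maf, abs_beta = ab, bin = bin) %>%
    dplyr::group_by(.data$bin, .drop = FALSE) %>%
    dplyr::summarise(mean_abs_beta = mean(.data$abs_beta),
                     n = dplyr::n(), .groups = "drop") %>%
    dplyr::mutate(maf_mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
                  .after = "bin")
  list(trend = trend, bins = bins)
}

#' Insertion vs deletion effect direction, stratified by TE status
#'
#' Summarises the signed effect of the ALT allele (for a deletion the ALT
#' allele is the deleted state) per SV type, separately for TE-similar and
#' non-TE SVs, with a Mann-Whitney rank-sum comparison of insertion vs
#' deletion betas within each TE stratum. Strata with no observations are
#' omitted with a warning.
#'
#' @param leads Association tibble with `variant_id`, `beta`.
#' @param variants Variant tibble (for `svtype`).
#' @param te_assignments Optional tibble from [assign_te_family()]; SVs
#'   without a family are the non-TE stratum. When omitted, all SVs are
#'   treated as non-TE.
#' @return List: `strata` (per svtype x TE-status beta summaries) and
#'   `tests` (rank-sum p per TE stratum).
#' @export
insertion_deletion_effect <- function(leads, variants, te_assignments = NULL) {
  df <- dplyr::inner_join(leads, variants[, c("id", "svtype")],
                          by = c(variant_id = "id")) %>%
    dplyr::filter(.data$svtype %in% c("INS", "DEL"))
  if (dplyr::n_distinct(df$svtype) < 2) {
    rlang::abort("Both INS and DEL must be present among leads.")
  }
  if (is.null(te_assignments)) {
    df$te_status <- "non-TE"
  } else {
    df <- dplyr::left_join(df, te_assignments[, c("sv_id", "family")],
                           by = c(variant_id = "sv_id"))
    df$te_status <- ifelse(!is.na(df$family), "TE", "non-TE")
  }
  strata <- df %>%
    dplyr::group_by(.data$svtype, .data$te_status) %>%
    dplyr::summarise(n = dplyr::n(), mean_beta = mean(.data$beta),
                     median_beta = stats::median(.data$beta),
                     .groups = "drop")
  full <- tidyr::expand_grid(svtype = c("INS", "DEL"),
                             te_status = unique(df$te_status))
  missing <- dplyr::anti_join(full, strata, by = c("svtype", "te_status"))
  if (nrow(missing)) {
    rlang::warn(sprintf("Empty stratum(a) omitted: %s",
                        paste(missing$svtype, missing$te_status,
                              sep = "/", collapse = ", ")))
  }
  tests <- df %>%
    dplyr::group_by(.data$te_status) %>%
    dplyr::group_modify(function(d, key) {
      if (dplyr::n_distinct(d$svtype) < 2) {
        return(tibble::tibble(p_value = NA_real_))
      }
      tibble::tibble(p_value = stats::wilcox.test(
        beta ~ svtype, data = d, exact = FALSE)$p.value)
    }) %>%
    dplyr::ungroup()
  list(strata = strata, tests = tests)
}

#' Partial variance in expression explained by a variant
#'
#' Fits the full model (dosage + covariates + intercept) and the reduced
#' model (covariates + intercept) by least squares and returns the partial
#' r-squared of the dosage term,
#' `(RSS_reduced - RSS_full) / RSS_reduced`, which equals
#' `t^2 / (t^2 + df)` for the dosage t statistic. A reduced model with zero
#' residual variance returns the boundary value 1.
#'
#' @param expr_row Numeric expression vector (one transcript, INT scale).
#' @param dosage_row Numeric dosage vector (0/1/2, mean-imputed).
#' @param covariates Optional numeric matrix (samples x covariates).
#' @return Partial r-squared in \[0, 1\].
#' @export
variance_explained <- function(expr_row, dosage_row, covariates = NULL) {
  n <- length(expr_row)
  stopifnot(length(dosage_row) == n)
  X0 <- cbind(rep(1, n), covariates)
  X1 <- cbind(X0, dosage_row)
  rss <- function(X) {
    fit <- stats::lm.fit(X, expr_row)
    sum(fit$residuals^2)
  }
  rss0 <- rss(X0)
  if (rss0 < 1e-300) return(1)
  r2 <- (rss0 - rss(X1)) / rss0
  min(max(r2, 0), 1)
}

#' Fraction of SV-lead transcripts without any significant SNP
#'
#' Among transcripts whose lead association is an SV, the fraction for
#' which no SNP association passes the FDR threshold — the signal captured
#' only when SVs are included in the scan.
#'
#' @param results Full association tibble (joint SNP + SV scan) with
#'   `transcript_id`, `variant_id`, `fdr`, `is_lead` (see
#'   [lead_variants()]).
#' @param variant_classes Named character vector mapping variant id to
#'   `"SNP"` or `"SV"`.
#' @param fdr FDR threshold (default 0.05).
#' @return List: `fraction`, `n_sv_lead`, `transcripts` (tibble with
#'   per-transcript `has_significant_snp`).
#' @export
sv_only_transcripts <- function(results, variant_classes, fdr = 0.05) {
  results$class <- unname(variant_classes[results$variant_id])
  if (anyNA(results$class)) {
    rlang::abort("Every variant id must have a class in `variant_classes`.")
  }
  sig_leads <- results[results$is_lead & results$fdr < fdr, ]
  sv_lead_tx <- unique(sig_leads$transcript_id[sig_leads$class == "SV"])
  if (length(sv_lead_tx) == 0) {
    rlang::warn("No SV-lead transcripts; fraction undefined.")
    return(list(fraction = NA_real_, n_sv_lead = 0L,
                transcripts = tibble::tibble()))
  }
  if (!any(results$class == "SNP")) {
    rlang::warn("No SNP associations supplied; fraction is 1 by definition.")
    return(list(fraction = 1, n_sv_lead = length(sv_lead_tx),
                transcripts = tibble::tibble(
                  transcript_id = sv_lead_tx, has_significant_snp = FALSE)))
  }
  snp_sig_tx <- unique(results$transcript_id[
    results$class == "SNP" & results$fdr < fdr])
  tx <- tibble::tibble(
    transcript_id = sv_lead_tx,
    has_significant_snp = sv_lead_tx %in% snp_sig_tx
  )
  list(fraction = mean(!tx$has_significant_snp),
       n_sv_lead = length(sv_lead_tx), transcripts = tx)
}
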