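#' Post-calling variant quality-control thresholds
#'
#' Defaults follow the filtering applied after long-read SV calling and
#' short-read SNP calling: genotype missing call rate < 5%, heterozygous call
#' rate < 5% (heterozygous SVs are unexpected in highly inbred lines and
#' indicate calling errors), SVs longer than 20 kb removed, SNP minor allele
#' frequency > 5%. `min_minor_count` is used by the association-stage MAF
#' filter (minor allele carried by at least five samples).
#'
#' @param max_missing_rate Maximum fraction of missing calls (exclusive).
#' @param max_het_rate Maximum fraction of heterozygous calls (exclusive).
#' @param max_sv_length Maximum SV length in bp (inclusive; longer removed).
#' @param min_maf Minor-allele-frequency threshold.
#' @param min_minor_count Minimum number of samples carrying the minor allele.
#' @param maf_strict If `TRUE` the MAF comparison is strict (`> min_maf`, the
#'   SNP-calling filter); if `FALSE` it is inclusive (`>= min_maf`, the
#'   association-stage filter).
#' @return A list of thresholds with class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_missing_rate = 0.05, max_het_rate = 0.05,
                          max_sv_length = 20000, min_maf = 0.05,
                          min_minor_count = 5, maf_strict = FALSE) {
  stopifnot(max_missing_rate >= 0, max_missing_rate <= 1,
            max_het_rate >= 0, max_het_rate <= 1,
            max_sv_length > 0, min_maf >= 0, min_maf <= 1,
            min_minor_count >= 0)
  structure(
    list(max_missing_rate = max_missing_rate, max_het_rate = max_het_rate,
         max_sv_length = max_sv_length, min_maf = min_maf,
         min_minor_count = min_minor_count, maf_strict = maf_strict),
    class = "qc_thresholds"
  )
}

#' Filter structural variants on type, call rates and length
#'
#' A variant is retained iff it is an insertion or deletion, its missing-call
#' rate and heterozygous-call rate are both below their thresholds, and its
#' length does not exceed `max_sv_length`. Retained and rejected rows
#' partition the input; rejected rows carry every failed condition
#' (`svtype`, `missing`, `het`, `length`) joined by `";"`.
#'
#' @param variants Variant tibble (see [read_sv_vcf()]).
#' @param gm Genotype call matrix with rows matching `variants$id`.
#' @param thresholds A [qc_thresholds()] object.
#' @return The variant tibble plus `missing_rate`, `het_rate`, `retained`
#'   and `reason` (NA when retained) columns.
#' @export
filter_sv <- function(variants, gm, thresholds = qc_thresholds()) {
  if (!identical(variants$id, rownames(gm))) {
    rlang::abort("`variants$id` and `rownames(gm)` must match in order.")
  }
  st <- allele_stats(gm)
  fail <- cbind(
    svtype = !(variants$svtype %in% c("INS", "DEL")),
    missing = st$missing_rate >= thresholds$max_missing_rate,
    het = st$het_rate >= thresholds$max_het_rate,
    length = variants$length > thresholds$max_sv_length
  )
  reason <- unname(apply(fail, 1, function(f) {
    if (any(f)) paste(colnames(fail)[f], collapse = ";") else NA_character_
  }))
  dplyr::mutate(variants,
                missing_rate = st$missing_rate,
                het_rate = st$het_rate,
                retained = is.na(reason),
                reason = reason)
}

#' Filter SNPs on call rates and minor allele frequency
#'
#' Retains SNPs with missing rate and heterozygous rate below threshold and
#' MAF above `min_maf` (strict comparison, the SNP-calling convention,
#' unless `thresholds$maf_strict` is `FALSE`). MAF is computed over
#' non-missing calls.
#'
#' @inheritParams filter_sv
#' @param gm Genotype call matrix of SNPs.
#' @return Tibble with `variant_id`, call-rate and MAF columns, `retained`
#'   and `reason`.
#' @export
filter_snp <- function(gm, thresholds = qc_thresholds(maf_strict = TRUE)) {
  if (nrow(gm) == 0 || ncol(gm) == 0) rlang::abort("Empty genotype matrix.")
  st <- allele_stats(gm)
  maf_pass <- if (thresholds$maf_strict) st$maf > thresholds$min_maf
              else st$maf >= thresholds$min_maf
  maf_pass[is.na(maf_pass)] <- FALSE
  fail <- cbind(
    missing = st$missing_rate >= thresholds$max_missing_rate,
    het = st$het_rate >= thresholds$max_het_rate,
    maf = !maf_pass
  )
  reason <- unname(apply(fail, 1, function(f) {
    if (any(f)) paste(colnames(fail)[f], collapse = ";") else NA_character_
  }))
  dplyr::mutate(st, retained = is.na(reason), reason = reason)
}

#' Association-stage minor-allele-frequency filter
#'
#' Retains variants with MAF at or above `min_maf` *and* the minor allele
#' carried by at least `min_minor_count` samples (both computed over
#' non-missing calls with additive dosage). The final association scan uses
#' (0.05, 5); the comparison between cohorts of different sizes uses
#' (0.10, 5). A variant with all calls missing is rejected with reason
#' `"all-missing"`.
#'
#' @param gm Genotype call matrix.
#' @param min_maf MAF threshold (inclusive).
#' @param min_minor_count Minimum minor-allele carrier count (inclusive).
#' @return Tibble with `variant_id`, `maf`, `minor_count`, `retained`,
#'   `reason`.
#' @export
maf_filter <- function(gm, min_maf = 0.05, min_minor_count = 5) {
  st <- allele_stats(gm)
  all_missing <- is.na(st$maf)
  fail_maf <- !all_missing & st$maf < min_maf
  fail_count <- !all_missing & st$minor_count < min_minor_count
  reason <- dplyr::case_when(
    all_missing ~ "all-missing",
    fail_maf & fail_count ~ "maf;minor-count",
    fail_maf ~ "maf",
    fail_count ~ "minor-count",
    TRUE ~ NA_character_
  )
  tibble::tibble(variant_id = st$variant_id, maf = st$maf,
                 minor_count = st$minor_count,
                 retained = is.na(reason), reason = reason)
}
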