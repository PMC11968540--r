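#' Construct a genotype call matrix
#'
#' A genotype matrix is a plain character matrix with one row per variant and
#' one column per sample; every cell is one of `"REF_HOM"`, `"ALT_HOM"`,
#' `"HET"` or `"MISSING"`. Row names are variant ids, column names sample ids.
#'
#' @param calls Character matrix of call states with dimnames.
#' @return The validated matrix (invisibly classed as `genotype_matrix`).
#' @export
genotype_matrix <- function(calls) {
  if (!is.matrix(calls) || !is.character(calls)) {
    rlang::abort("`calls` must be a character matrix.")
  }
  if (is.null(rownames(calls)) || is.null(colnames(calls))) {
    rlang::abort("`calls` must have variant row names and sample column names.")
  }
  bad <- !(calls %in% GT_STATES)
  if (any(bad)) {
    rlang::abort(sprintf(
      "Invalid genotype state(s): %s",
      paste(unique(calls[bad]), collapse = ", ")
    ))
  }
  structure(calls, class = c("genotype_matrix", class(calls)))
}

#' Additive dosage coding of a genotype matrix
#'
#' REF_HOM = 0, HET = 1, ALT_HOM = 2, MISSING = NA. Optionally mean-imputes
#' missing dosages per variant (row), the convention used by matrix-style
#' eQTL scans.
#'
#' @param gm Genotype call matrix (variants x samples).
#' @param impute `"none"` (default) keeps NA; `"mean"` replaces missing calls
#'   by the variant's mean dosage over non-missing samples.
#' @return Numeric matrix of dosages with the same dimnames.
#' @export
dosage_matrix <- function(gm, impute = c("none", "mean")) {
  impute <- match.arg(impute)
  d <- matrix(NA_real_, nrow(gm), ncol(gm), dimnames = dimnames(gm))
  d[gm == "REF_HOM"] <- 0
  d[gm == "HET"] <- 1
  d[gm == "ALT_HOM"] <- 2
  if (impute == "mean") {
    mu <- rowMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    if (nrow(idx)) d[idx] <- mu[idx[, 1]]
  }
  d
}

#' Per-variant allele and call-rate statistics
#'
#' Computes, for every row of a genotype matrix: the missing-call fraction,
#' the heterozygous-call fraction, the ALT allele frequency over non-missing
#' calls (additive dosage), the minor allele frequency, and the number of
#' samples carrying the minor allele. MISSING cells are excluded from the
#' allele-frequency denominator; HET cells count toward the het rate and
#' carry one ALT allele.
#'
#' @param gm Genotype call matrix.
#' @return A tibble with one row per variant:
#'   `variant_id`, `n`, `missing_rate`, `het_rate`, `alt_freq`, `maf`,
#'   `minor_count` (NA frequency columns when all calls are missing).
#' @export
allele_stats <- function(gm) {
  n <- ncol(gm)
  n_missing <- rowSums(gm == "MISSING")
  n_het <- rowSums(gm == "HET")
  n_alt <- rowSums(gm == "ALT_HOM")
  n_ref <- rowSums(gm == "REF_HOM")
  n_called <- n - n_missing
  alt_freq <- ifelse(n_called > 0, (2 * n_alt + n_het) / (2 * n_called), NA_real_)
  maf <- pmin(alt_freq, 1 - alt_freq)
  # carriers of the minor allele (ALT minor when alt_freq <= 0.5)
  alt_minor <- !is.na(alt_freq) & alt_freq <= 0.5
  minor_count <- ifelse(alt_minor, n_alt + n_het, n_ref + n_het)
  minor_count[is.na(alt_freq)] <- NA_integer_
  tibble::tibble(
    variant_id = rownames(gm),
    n = n,
    missing_rate = unname(n_missing / n),
    het_rate = unname(n_het / n),
    alt_freq = unname(alt_freq),
    maf = unname(maf),
    minor_count = as.integer(unname(minor_count))
  )
}

#' Restrict a genotype or expression matrix to a subset of samples
#'
#' Columns are restricted to `keep` in the order given; used e.g. to
#' downsample a 100-sample short-read cohort to the 57 samples that also have
#' long-read data.
#'
#' @param x Matrix with sample column names (genotype or expression).
#' @param keep Character vector of sample ids to retain (non-empty, all
#'   present in `colnames(x)`).
#' @return The column-subset matrix, same type as the input.
#' @export
downsample_samples <- function(x, keep) {
  if (!is.matrix(x) || is.null(colnames(x))) {
    rlang::abort("`x` must be a matrix with sample column names.")
  }
  if (length(keep) == 0) rlang::abort("`keep` must name at least one sample.")
  unknown <- setdiff(keep, colnames(x))
  if (length(unknown)) {
    rlang::abort(sprintf("Unknown sample id(s): %s", paste(unknown, collapse = ", ")))
  }
  x[, keep, drop = FALSE]
}

# Variant genomic interval: insertions occupy the single reference point
# `pos`; deletions occupy [pos + 1, pos + length] (VCF padding-base
# convention); SNPs occupy [pos, pos].
variant_interval <- function(variants) {
  start <- ifelse(variants$svtype == "DEL", variants$pos + 1L, variants$pos)
  end <- ifelse(variants$svtype == "DEL", variants$pos + variants$length, variants$pos)
  tibble::tibble(variant_id = variants$id, chrom = variants$chrom,
                 start = as.integer(start), end = as.integer(end))
}

variant_granges <- function(variants) {
  iv <- variant_interval(variants)
  GenomicRanges::GRanges(iv$chrom, IRanges::IRanges(iv$start, iv$end),
                         variant_id = iv$variant_id)
}

gene_body_granges <- function(genes, flank = 0L) {
  start <- pmin(genes$tss, genes$tts) - flank
  end <- pmax(genes$tss, genes$tts) + flank
  GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(pmax(start, 1L), end),
                         transcript_id = genes$transcript_id)
}
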