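#' Confusion counts for one variant from one allele perspective
#'
#' Compares a test call vector against a truth call vector across samples.
#' A sample contributes only when it is non-missing in *both* vectors
#' (heterozygous calls are expected to have been mapped to `MISSING`
#' beforehand; see [score_variant()]). For the ALT perspective a positive is
#' an `ALT_HOM` call; for the REF perspective a positive is `REF_HOM`.
#' TP = positive in both, FP = positive in test only, FN = positive in truth
#' only.
#'
#' @param truth,test Character call vectors of equal length.
#' @param perspective `"ALT"` or `"REF"`.
#' @return Named integer vector `c(tp, fp, fn)`.
#' @export
confusion_counts <- function(truth, test, perspective = c("ALT", "REF")) {
  perspective <- match.arg(perspective)
  if (length(truth) != length(test)) {
    rlang::abort("`truth` and `test` must have the same length.")
  }
  ok <- truth != "MISSING" & test != "MISSING"
  pos <- if (perspective == "ALT") "ALT_HOM" else "REF_HOM"
  pt <- truth[ok] == pos
  ps <- test[ok] == pos
  c(tp = sum(pt & ps), fp = sum(!pt & ps), fn = sum(pt & !ps))
}

#' F1 score from confusion counts
#'
#' `F1 = 2 TP / (2 TP + FP + FN)`, the harmonic mean of precision and recall.
#' The vacuous case `TP = FP = FN = 0` (no positives anywhere, e.g. a variant
#' monomorphic for the non-focal allele) is defined as 1: agreement is
#' perfect, and returning 0 would spuriously classify such variants as poorly
#' genotyped.
#'
#' @param tp,fp,fn Non-negative integer counts (vectorised).
#' @return F1 in \[0, 1\].
#' @export
f1_from_counts <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) rlang::abort("Counts must be non-negative.")
  denom <- 2 * tp + fp + fn
  ifelse(denom == 0, 1, 2 * tp / denom)
}

#' Dual-perspective F1 concordance score for a single variant
#'
#' Heterozygous calls are mapped to `MISSING` in both vectors before
#' counting. The missing rate is the fraction of samples missing (after that
#' mapping) in *either* vector; a variant whose missing rate exceeds
#' `max_missing` (default 20%) is designated F1 = 0 on both perspectives and
#' classified LOW regardless of the agreement among the remaining samples.
#'
#' @param truth,test Character call vectors of equal length (>= 1).
#' @param max_missing Maximum tolerated joint missing rate (exclusive).
#' @return One-row tibble: confusion counts for both perspectives, `f1_alt`,
#'   `f1_ref`, `missing_rate`, `quality_class`.
#' @export
score_variant <- function(truth, test, max_missing = 0.20) {
  if (length(truth) == 0 || length(test) == 0) {
    rlang::abort("Call vectors must be non-empty.")
  }
  tm <- matrix(truth, nrow = 1, dimnames = list("v", names(truth)))
  sm <- matrix(test, nrow = 1, dimnames = list("v", names(test)))
  if (is.null(colnames(tm))) {
    colnames(tm) <- colnames(sm) <- paste0("s", seq_along(truth))
  }
  res <- score_concordance(tm, sm, max_missing = max_missing)
  res$variant_id <- NULL
  res
}

#' Per-variant dual-perspective F1 scores for a genotype matrix pair
#'
#' Vectorised form of [score_variant()] over all shared variants of a truth
#' and a test genotype matrix (e.g. long-read truth genotypes vs short-read
#' graph-based genotyping of the same samples). Variants are classified
#' HIGH (correctly genotyped) when both F1 >= `high`, LOW (poorly genotyped)
#' when either F1 <= `low`, INTERMEDIATE otherwise.
#'
#' @param truth_gm,test_gm Genotype call matrices sharing variant row names
#'   and sample column names (matched by name; order-insensitive).
#' @param max_missing Maximum tolerated joint missing rate (exclusive).
#' @param high,low Classification bands (see [classify_f1()]).
#' @return Tibble with one row per variant: `variant_id`, `tp_alt`, `fp_alt`,
#'   `fn_alt`, `tp_ref`, `fp_ref`, `fn_ref`, `f1_alt`, `f1_ref`,
#'   `missing_rate`, `quality_class`.
#' @export
score_concordance <- function(truth_gm, test_gm, max_missing = 0.20,
                              high = 0.8, low = 0.2) {
  shared_v <- intersect(rownames(truth_gm), rownames(test_gm))
  shared_s <- intersect(colnames(truth_gm), colnames(test_gm))
  if (length(shared_v) == 0) rlang::abort("No shared variants.")
  if (length(shared_s) == 0) rlang::abort("No shared samples.")
  tr <- truth_gm[shared_v, shared_s, drop = FALSE]
  te <- test_gm[shared_v, shared_s, drop = FALSE]
  # heterozygous calls carry no information in inbred material: treat missing
  tr[tr == "HET"] <- "MISSING"
  te[te == "HET"] <- "MISSING"
  ok <- tr != "MISSING" & te != "MISSING"
  missing_rate <- 1 - rowMeans(ok)

  counts <- function(pos) {
    pt <- tr == pos & ok
    ps <- te == pos & ok
    list(tp = rowSums(pt & ps), fp = rowSums(!pt & ps & ok),
         fn = rowSums(pt & !ps))
  }
  a <- counts("ALT_HOM")
  r <- counts("REF_HOM")
  f1_alt <- f1_from_counts(a$tp, a$fp, a$fn)
  f1_ref <- f1_from_counts(r$tp, r$fp, r$fn)
  over <- missing_rate > max_missing
  f1_alt[over] <- 0
  f1_ref[over] <- 0
  tibble::tibble(
    variant_id = shared_v,
    tp_alt = as.integer(unname(a$tp)), fp_alt = as.integer(unname(a$fp)),
    fn_alt = as.integer(unname(a$fn)),
    tp_ref = as.integer(unname(r$tp)), fp_ref = as.integer(unname(r$fp)),
    fn_ref = as.integer(unname(r$fn)),
    f1_alt = unname(f1_alt), f1_ref = unname(f1_ref),
    missing_rate = unname(missing_rate),
    quality_class = unname(classify_f1(f1_ref, f1_alt, high = high, low = low))
  )
}

#' Classify genotyping quality from dual-perspective F1 scores
#'
#' HIGH iff both REF and ALT F1 >= `high` (correctly genotyped); LOW iff
#' either F1 <= `low` (poorly genotyped); INTERMEDIATE otherwise. With the
#' default bands (0.8 / 0.2) the two conditions are mutually exclusive; this
#' is asserted for non-default bands where both could hold, in which case LOW
#' takes precedence.
#'
#' @param f1_ref,f1_alt Numeric F1 vectors in \[0, 1\].
#' @param high,low Band thresholds.
#' @return Character vector in `{"HIGH", "LOW", "INTERMEDIATE"}`.
#' @export
classify_f1 <- function(f1_ref, f1_alt, high = 0.8, low = 0.2) {
  is_low <- f1_ref <= low | f1_alt <= low
  is_high <- f1_ref >= high & f1_alt >= high
  dplyr::case_when(is_low ~ "LOW", is_high ~ "HIGH", TRUE ~ "INTERMEDIATE")
}

#' Gene proximity of variants
#'
#' Classifies each variant as `inside` (its interval intersects a gene
#' body), `within_window` (nearest gene body at most `window` bp away,
#' default 1 kb) or `outside`. Variants on chromosomes absent from the gene
#' models are `outside`, with a warning.
#'
#' @param variants Variant tibble.
#' @param genes Gene-model tibble (see [read_gene_models()]).
#' @param window Proximity window in bp.
#' @return Tibble `variant_id`, `proximity`, `distance` (0 when inside, NA
#'   when the chromosome is unknown).
#' @export
gene_proximity <- function(variants, genes, window = 1000) {
  vg <- variant_granges(variants)
  gg <- gene_body_granges(genes)
  unknown <- !(as.character(GenomicRanges::seqnames(vg)) %in% genes$chrom)
  if (any(unknown)) {
    rlang::warn(sprintf("%d variant(s) on chromosomes without gene models; set to 'outside'.",
                        sum(unknown)))
  }
  inside <- GenomicRanges::countOverlaps(vg, gg) > 0
  hits <- GenomicRanges::distanceToNearest(vg, gg)
  dist <- rep(NA_real_, length(vg))
  # GRanges distance counts bases strictly between ranges; +1 gives the
  # conventional "bp away" so that a variant 1,000 bp from a gene end is
  # within the 1 kb window and 1,001 bp is not.
  dist[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance + 1
  dist[inside] <- 0
  prox <- dplyr::case_when(
    inside ~ "inside",
    !is.na(dist) & dist <= window ~ "within_window",
    TRUE ~ "outside"
  )
  tibble::tibble(variant_id = variants$id, proximity = prox, distance = dist)
}

#' Genome-wide copy number of SV sequences by local alignment
#'
#' Each query sequence is searched against a genome with a local aligner
#' (NCBI blastn, E-value cutoff `max_evalue`); hits whose genome intervals
#' overlap by more than `merge_overlap` of the shorter hit are merged, and
#' the copy number is the number of merged hit clusters.
#'
#' @param sequences Named [Biostrings::DNAStringSet] (or named character
#'   vector) of SV sequences, each at least 30 bp.
#' @param genome Path to a genome FASTA file or a `DNAStringSet`.
#' @param max_evalue E-value cutoff.
#' @param merge_overlap Fraction of the shorter hit above which two genome
#'   hits are merged.
#' @return Named integer vector of copy numbers (0 = not found).
#' @export
copy_number <- function(sequences, genome, max_evalue = 1e-5,
                        merge_overlap = 0.5) {
  sequences <- as_dna_set(sequences)
  if (any(Biostrings::width(sequences) < 30)) {
    rlang::abort("All query sequences must be at least 30 bp.")
  }
  hits <- run_blastn(sequences, genome, max_evalue = max_evalue)
  out <- stats::setNames(integer(length(sequences)), names(sequences))
  if (nrow(hits) == 0) return(out)
  counted <- hits %>%
    dplyr::mutate(gstart = pmin(.data$sstart, .data$send),
                  gend = pmax(.data$sstart, .data$send)) %>%
    dplyr::group_by(.data$qseqid) %>%
    dplyr::summarise(n = count_merged(.data$sseqid, .data$gstart, .data$gend,
                                      merge_overlap), .groups = "drop")
  out[counted$qseqid] <- counted$n
  out
}

# greedy single-linkage merge of genome intervals that reciprocally overlap
# more than `frac` of the shorter interval; returns cluster count
count_merged <- function(chrom, start, end, frac) {
  n_total <- 0L
  for (ch in unique(chrom)) {
    s <- start[chrom == ch]; e <- end[chrom == ch]
    o <- order(s)
    s <- s[o]; e <- e[o]
    clusters <- 0L
    cur_end <- -Inf
    cur_start <- -Inf
    for (i in seq_along(s)) {
      ov <- min(cur_end, e[i]) - max(cur_start, s[i]) + 1
      shorter <- min(e[i] - s[i] + 1, cur_end - cur_start + 1)
      if (is.finite(cur_end) && ov > frac * shorter) {
        cur_end <- max(cur_end, e[i])
      } else {
        clusters <- clusters + 1L
        cur_start <- s[i]; cur_end <- e[i]
      }
    }
    n_total <- n_total + clusters
  }
  n_total
}

#' Compare features of correctly vs poorly genotyped variants
#'
#' Summarises length, breakpoint confidence-interval widths and (when
#' supplied) copy number for the HIGH and LOW quality classes, with
#' Mann-Whitney rank-sum p-values per feature, and the gene-proximal fraction
#' (inside or within the window) per class with a chi-square p-value.
#'
#' @param scores Concordance tibble from [score_concordance()].
#' @param variants Variant tibble aligned by id.
#' @param copy_numbers Optional named copy-number vector (see
#'   [copy_number()]).
#' @param proximity Optional proximity tibble from [gene_proximity()].
#' @return Tibble: `feature`, `mean_high`, `median_high`, `mean_low`,
#'   `median_low`, `p_value`, `test`.
#' @export
compare_groups <- function(scores, variants, copy_numbers = NULL,
                           proximity = NULL) {
  df <- dplyr::inner_join(scores, variants, by = c(variant_id = "id"))
  if (!is.null(copy_numbers)) {
    df$copy_number <- unname(copy_numbers[df$variant_id])
  }
  if (!is.null(proximity)) {
    df <- dplyr::left_join(df, proximity, by = "variant_id")
  }
  hi <- df[df$quality_class == "HIGH", ]
  lo <- df[df$quality_class == "LOW", ]
  if (nrow(hi) == 0) rlang::abort("Empty group: HIGH")
  if (nrow(lo) == 0) rlang::abort("Empty group: LOW")
  features <- intersect(c("length", "copy_number", "ci_pos_width", "ci_len_width"),
                        colnames(df))
  rows <- purrr::map_dfr(features, function(f) {
    x <- hi[[f]]; y <- lo[[f]]
    p <- tryCatch(stats::wilcox.test(x, y, exact = FALSE)$p.value,
                  error = function(e) NA_real_)
    tibble::tibble(feature = f,
                   mean_high = mean(x), median_high = stats::median(x),
                   mean_low = mean(y), median_low = stats::median(y),
                   p_value = p, test = "wilcoxon")
  })
  if (!is.null(proximity)) {
    ph <- mean(hi$proximity %in% c("inside", "within_window"))
    pl <- mean(lo$proximity %in% c("inside", "within_window"))
    tab <- rbind(
      c(sum(hi$proximity %in% c("inside", "within_window")),
        sum(!hi$proximity %in% c("inside", "within_window"))),
      c(sum(lo$proximity %in% c("inside", "within_window")),
        sum(!lo$proximity %in% c("inside", "within_window")))
    )
    p <- tryCatch(stats::chisq.test(tab)$p.value, error = function(e) NA_real_)
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      feature = "gene_proximal_fraction",
      mean_high = ph, median_high = ph, mean_low = pl, median_low = pl,
      p_value = p, test = "chi-square"))
  }
  rows
}
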