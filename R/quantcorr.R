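#' Per-transcript correlation between two expression quantifications
#'
#' Compares two expression matrices (e.g. a linear-reference quantification
#' vs a pangenome-graph quantification of the same RNA-seq samples)
#' transcript by transcript across their shared samples. Transcripts absent
#' from either matrix are dropped; transcripts constant in either matrix
#' have no defined correlation and are flagged.
#'
#' @param a,b Expression matrices (transcripts x samples) sharing ids.
#' @return Tibble: `transcript_id`, `pearson`, `spearman`, `n_samples`,
#'   `defined`.
#' @export
per_transcript_correlation <- function(a, b) {
  tx <- intersect(rownames(a), rownames(b))
  ss <- intersect(colnames(a), colnames(b))
  if (length(ss) < 3) rlang::abort("Fewer than 3 shared samples.")
  if (length(tx) == 0) rlang::abort("No shared transcripts.")
  am <- a[tx, ss, drop = FALSE]
  bm <- b[tx, ss, drop = FALSE]
  const <- matrixStats_row_sd(am) == 0 | matrixStats_row_sd(bm) == 0
  pearson <- row_cor(am, bm)
  ra <- t(apply(am, 1, rank))
  rb <- t(apply(bm, 1, rank))
  spearman <- row_cor(ra, rb)
  pearson[const] <- NA_real_
  spearman[const] <- NA_real_
  tibble::tibble(transcript_id = tx, pearson = unname(pearson),
                 spearman = unname(spearman),
                 n_samples = length(ss), defined = unname(!const))
}

matrixStats_row_sd <- function(m) {
  mu <- rowMeans(m)
  sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
}

row_cor <- function(x, y) {
  xc <- x - rowMeans(x)
  yc <- y - rowMeans(y)
  num <- rowSums(xc * yc)
  den <- sqrt(rowSums(xc^2) * rowSums(yc^2))
  ifelse(den == 0, NA_real_, num / den)
}

#' Select discordant transcripts and a matched concordant set
#'
#' Discordant transcripts have Pearson correlation below `cutoff` (default
#' 0.75); the matched set is the same number of transcripts with the highest
#' Pearson correlations. Undefined correlations are excluded from both sets.
#' A warning is raised when more than half the universe is discordant (the
#' matched set is still returned).
#'
#' @param records Correlation tibble from [per_transcript_correlation()].
#' @param cutoff Pearson cutoff.
#' @return List with character vectors `discordant` and `concordant`
#'   (disjoint).
#' @export
select_discordant <- function(records, cutoff = 0.75) {
  if (nrow(records) == 0) rlang::abort("Empty correlation table.")
  rec <- records[records$defined & !is.na(records$pearson), ]
  disc <- rec$transcript_id[rec$pearson < cutoff]
  if (length(disc) > nrow(rec) / 2) {
    rlang::warn("More than half of the transcripts are discordant.")
  }
  rest <- rec[!(rec$transcript_id %in% disc), ]
  rest <- rest[order(-rest$pearson, rest$transcript_id), ]
  conc <- utils::head(rest$transcript_id, length(disc))
  list(discordant = disc, concordant = conc)
}

#' Count variants overlapping each transcript
#'
#' The overlap interval is the gene body extended by `window` bp on both
#' sides (default 1 kb). Used as the statistic carrier for the permutation
#' enrichment test.
#'
#' @param variants Variant tibble.
#' @param genes Gene-model tibble.
#' @param window Flank in bp added to the gene body.
#' @return Named integer vector (transcript id -> overlapping variant count).
#' @export
variant_hits <- function(variants, genes, window = 1000) {
  vg <- variant_granges(variants)
  gg <- gene_body_granges(genes, flank = as.integer(window))
  stats::setNames(GenomicRanges::countOverlaps(gg, vg), genes$transcript_id)
}

#' Permutation test for variant enrichment in a transcript set
#'
#' The observed statistic is the total variant count over the target set.
#' Each of `n_perm` permutations draws `|target|` transcripts from the
#' universe without replacement and records the same statistic. The p-value
#' uses the small-sample correction `p = (1 + #{perm >= obs}) / (n_perm + 1)`
#' for over-representation (`<=` for depletion), so it is bounded below by
#' `1 / (n_perm + 1)`.
#'
#' @param target Character vector of transcript ids (subset of `universe`).
#' @param universe Character vector of resampling universe ids.
#' @param hits Named integer vector of per-transcript variant counts (ids
#'   missing from `hits` count 0).
#' @param n_perm Number of permutations (default 100).
#' @param seed Optional integer seed for reproducible resampling.
#' @param alternative `"over"` (enrichment, default) or `"under"`
#'   (depletion).
#' @return An object of class `sveqtl_enrichment` with fields `observed`,
#'   `perm_mean`, `perm_sd`, `z`, `p`, `n_perm`, `seed`, `alternative`,
#'   `perm_stats`. Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
permutation_enrichment <- function(target, universe, hits, n_perm = 100,
                                   seed = NULL,
                                   alternative = c("over", "under")) {
  alternative <- match.arg(alternative)
  if (n_perm < 1) rlang::abort("`n_perm` must be at least 1.")
  if (length(target) > length(universe)) {
    rlang::abort("Target set larger than universe.")
  }
  extra <- setdiff(target, universe)
  if (length(extra)) {
    rlang::abort(sprintf("Target id(s) not in universe: %s",
                         paste(utils::head(extra, 5), collapse = ", ")))
  }
  h <- function(ids) sum(hits[ids], na.rm = TRUE)
  observed <- h(target)
  runner <- function() {
    vapply(seq_len(n_perm),
           function(i) h(sample(universe, length(target))), numeric(1))
  }
  perm <- if (is.null(seed)) runner() else withr::with_seed(seed, runner())
  m <- mean(perm)
  s <- stats::sd(perm)
  z <- if (is.na(s) || s == 0) {
    if (observed == m) 0 else sign(observed - m) * Inf
  } else (observed - m) / s
  p <- if (alternative == "over") (1 + sum(perm >= observed)) / (n_perm + 1)
       else (1 + sum(perm <= observed)) / (n_perm + 1)
  structure(
    list(observed = observed, perm_mean = m, perm_sd = s, z = z, p = p,
         n_perm = n_perm, seed = seed, alternative = alternative,
         n_target = length(target), perm_stats = perm),
    class = "sveqtl_enrichment"
  )
}

#' @exportS3Method generics::tidy
tidy.sveqtl_enrichment <- function(x, ...) {
  tibble::tibble(observed = x$observed, perm_mean = x$perm_mean,
                 perm_sd = x$perm_sd, z = x$z, p = x$p,
                 n_perm = x$n_perm, alternative = x$alternative)
}

#' @exportS3Method generics::glance
glance.sveqtl_enrichment <- function(x, ...) tidy.sveqtl_enrichment(x)

#' @export
print.sveqtl_enrichment <- function(x, ...) {
  cat(sprintf(
    "Permutation %s-representation test: observed %.3g vs %.3g +/- %.3g over %d permutations (z = %.2f, p = %.4g)\n",
    x$alternative, x$observed, x$perm_mean, x$perm_sd, x$n_perm, x$z, x$p))
  invisible(x)
}
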