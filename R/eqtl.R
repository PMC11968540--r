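#' Expression filter for eQTL analysis
#'
#' Retains transcripts with mean TPM >= 0.1 and TPM >= 1 in at least two
#' samples.
#'
#' @param expr Expression matrix (transcripts x samples) in TPM.
#' @param min_mean Mean-TPM threshold (inclusive).
#' @param min_tpm,min_samples A transcript must reach `min_tpm` in at least
#'   `min_samples` samples.
#' @return Character vector of retained transcript ids.
#' @export
filter_expression <- function(expr, min_mean = 0.1, min_tpm = 1,
                              min_samples = 2) {
  if (nrow(expr) == 0 || ncol(expr) == 0) rlang::abort("Empty expression matrix.")
  unit <- attr(expr, "unit")
  if (!is.null(unit) && unit != "TPM") {
    rlang::abort("Expression filter expects TPM values.")
  }
  keep <- rowMeans(expr) >= min_mean & rowSums(expr >= min_tpm) >= min_samples
  rownames(expr)[keep]
}

#' Rank-based inverse normal transformation
#'
#' Maps values to standard-normal quantiles through their ranks (ties get
#' the average rank) at the Blom plotting positions
#' `(rank - 3/8) / (n + 1/4)`. For a matrix the transformation is applied
#' per row (per transcript). Output is monotone in the input; a constant
#' vector carries no order information and is an error.
#'
#' @param x Numeric vector (length >= 3) or matrix (transcripts x samples).
#' @return Transformed vector or matrix of the same shape.
#' @export
inverse_normal_transform <- function(x) {
  if (is.matrix(x)) {
    out <- t(apply(x, 1, inverse_normal_transform))
    dimnames(out) <- dimnames(x)
    return(out)
  }
  if (length(x) < 3) rlang::abort("Need at least 3 values.")
  if (max(x) == min(x)) rlang::abort("Constant vector: no order information.")
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
}

#' Select the elbow of a scree curve
#'
#' The elbow is the scree point with maximum perpendicular distance to the
#' chord joining the first and last points. With a sharp factor structure
#' the farthest point is the first component of the noise floor (it lies
#' below the chord); the retained count then stops one short of it, so that
#' `k` planted factors yield `k`. A scree without an elbow (all points on
#' the chord) yields the minimal model, 1 component.
#'
#' @param variances Decreasing numeric vector of component variances.
#' @return Integer number of components to retain.
#' @export
select_elbow <- function(variances) {
  m <- length(variances)
  if (m < 3) return(1L)
  x <- (seq_len(m) - 1) / (m - 1)
  rng <- variances[1] - variances[m]
  if (rng <= 0) return(1L)
  y <- (variances - variances[m]) / rng
  # distance to chord from (0, 1) to (1, 0); signed: negative = below chord
  signed <- (y - (1 - x)) / sqrt(2)
  dist <- abs(signed)
  if (max(dist) < 1e-12) return(1L)
  i <- which.max(dist)
  k <- if (signed[i] < 0) i - 1L else i
  max(k, 1L)
}

#' Build the covariate set for the association scan
#'
#' Covariates are the top `n_geno_pcs` principal components of the centred
#' SNP dosage matrix (population-structure correction) plus expression
#' principal components (hidden technical/biological factors), their number
#' chosen by the scree elbow rule of [select_elbow()] applied to the
#' per-component variances of the inverse-normal-transformed expression
#' matrix.
#'
#' @param snp_gm SNP genotype call matrix.
#' @param expr Expression matrix (transcripts x samples), raw TPM; the INT
#'   is applied internally before the PCA.
#' @param n_geno_pcs Number of genotype PCs (default 5).
#' @param max_expr_pcs Cap on the expression scree length considered.
#' @return Object of class `covariate_set`: `sample_ids`, `matrix`
#'   (samples x covariates), `n_genotype_pcs`, `n_expression_pcs`, `scree`.
#' @export
build_covariates <- function(snp_gm, expr, n_geno_pcs = 5,
                             max_expr_pcs = 30) {
  samples <- intersect(colnames(snp_gm), colnames(expr))
  if (length(samples) < n_geno_pcs + 2) {
    rlang::abort("Too few shared samples for the requested genotype PCs.")
  }
  d <- dosage_matrix(snp_gm[, samples, drop = FALSE], impute = "mean")
  d <- d[matrixStats_row_sd(d) > 0, , drop = FALSE]
  if (nrow(d) < n_geno_pcs) rlang::abort("Rank-deficient genotype matrix.")
  gp <- stats::prcomp(t(d), center = TRUE, scale. = FALSE)
  if (ncol(gp$x) < n_geno_pcs) rlang::abort("Rank-deficient genotype matrix.")
  gmat <- gp$x[, seq_len(n_geno_pcs), drop = FALSE]
  colnames(gmat) <- paste0("geno_PC", seq_len(n_geno_pcs))

  e <- expr[, samples, drop = FALSE]
  e <- e[matrixStats_row_sd(e) > 0, , drop = FALSE]
  eint <- inverse_normal_transform(e)
  ep <- stats::prcomp(t(eint), center = TRUE, scale. = FALSE)
  vars <- ep$sdev^2
  vars <- vars[vars > 1e-12]
  vars <- utils::head(vars, max_expr_pcs)
  k <- select_elbow(vars)
  emat <- ep$x[, seq_len(k), drop = FALSE]
  colnames(emat) <- paste0("expr_PC", seq_len(k))

  structure(
    list(sample_ids = samples,
         matrix = cbind(gmat, emat),
         n_genotype_pcs = as.integer(n_geno_pcs),
         n_expression_pcs = as.integer(k),
         scree = vars),
    class = "covariate_set"
  )
}

#' Candidate transcript-variant pairs within a testing window
#'
#' Pairs every variant with every transcript whose gene body, extended by
#' `window` bp on both sides (default 100 kb), it overlaps. Final cis labels
#' use the narrower 3 kb definition of [classify_cis()].
#'
#' @param variants Variant tibble.
#' @param genes Gene-model tibble.
#' @param window Testing window in bp.
#' @return Tibble `transcript_id`, `variant_id`.
#' @export
make_cis_pairs <- function(variants, genes, window = 1e5) {
  vg <- variant_granges(variants)
  gg <- gene_body_granges(genes, flank = as.integer(window))
  ov <- GenomicRanges::findOverlaps(gg, vg)
  tibble::tibble(
    transcript_id = genes$transcript_id[S4Vectors::queryHits(ov)],
    variant_id = variants$id[S4Vectors::subjectHits(ov)]
  )
}

#' Additive linear-model association scan
#'
#' For each candidate pair, ordinary least squares of inverse-normal
#' transformed expression on additive dosage (0/1/2; missing calls
#' mean-imputed per variant) plus the covariates and an intercept. The
#' covariates are projected out of both sides once (Frisch-Waugh), which
#' reproduces the full per-pair regression exactly: beta, its t statistic
#' with `n - k - 2` degrees of freedom (k covariates) and a two-sided
#' p-value, with Benjamini-Hochberg FDR across all tested pairs. Variants
#' with zero dosage variance after imputation are skipped.
#'
#' @param expr_int INT-transformed expression matrix (transcripts x
#'   samples).
#' @param genotypes Genotype call matrix of the variants to test.
#' @param covariates Optional [build_covariates()] object or numeric matrix
#'   (samples x covariates) with sample row names.
#' @param pairs Tibble of candidate `transcript_id`, `variant_id` pairs,
#'   e.g. from [make_cis_pairs()].
#' @return Object of class `eqtl_scan`; [tidy()] returns the per-pair
#'   association tibble (`transcript_id`, `variant_id`, `beta`, `t_stat`,
#'   `p`, `fdr`, `allele_frequency`), [glance()] a one-row scan summary.
#' @export
association_scan <- function(expr_int, genotypes, covariates = NULL, pairs) {
  cov_mat <- NULL
  if (inherits(covariates, "covariate_set")) {
    cov_mat <- covariates$matrix
    rownames(cov_mat) <- covariates$sample_ids
  } else if (!is.null(covariates)) {
    cov_mat <- as.matrix(covariates)
  }
  samples <- intersect(colnames(expr_int), colnames(genotypes))
  if (!is.null(cov_mat)) samples <- intersect(samples, rownames(cov_mat))
  n <- length(samples)
  if (n < 4) rlang::abort("Too few shared samples.")
  pairs <- dplyr::filter(pairs,
                         .data$transcript_id %in% rownames(expr_int),
                         .data$variant_id %in% rownames(genotypes))
  if (nrow(pairs) == 0) rlang::abort("No testable pairs.")

  Y <- t(expr_int[unique(pairs$transcript_id), samples, drop = FALSE])
  G <- t(dosage_matrix(genotypes[unique(pairs$variant_id), samples,
                                 drop = FALSE], impute = "mean"))
  X <- cbind(`(Intercept)` = rep(1, n),
             if (!is.null(cov_mat)) cov_mat[samples, , drop = FALSE])
  k <- ncol(X) - 1L
  df <- n - k - 2L
  if (df < 1) rlang::abort("Not enough residual degrees of freedom.")
  Q <- qr.Q(qr(X))
  Yr <- Y - Q %*% crossprod(Q, Y)
  Gr <- G - Q %*% crossprod(Q, G)
  yss <- colSums(Yr^2)
  gss <- colSums(Gr^2)

  zero_var <- gss < 1e-12
  skipped <- colnames(G)[zero_var]
  if (length(skipped)) {
    rlang::inform(sprintf("Skipping %d variant(s) with zero dosage variance.",
                          length(skipped)))
    pairs <- dplyr::filter(pairs, !(.data$variant_id %in% skipped))
    if (nrow(pairs) == 0) rlang::abort("No testable pairs after skipping.")
  }

  ti <- match(pairs$transcript_id, colnames(Yr))
  vi <- match(pairs$variant_id, colnames(Gr))
  xy <- colSums(Yr[, ti, drop = FALSE] * Gr[, vi, drop = FALSE])
  beta <- xy / gss[vi]
  rss <- pmax(yss[ti] - beta^2 * gss[vi], 0)
  sigma2 <- rss / df
  se <- sqrt(sigma2 / gss[vi])
  t_stat <- beta / se
  p <- 2 * stats::pt(-abs(t_stat), df)
  af <- allele_stats(genotypes[, samples, drop = FALSE])
  results <- tibble::tibble(
    transcript_id = pairs$transcript_id,
    variant_id = pairs$variant_id,
    beta = unname(beta),
    t_stat = unname(t_stat),
    p = unname(p),
    fdr = stats::p.adjust(p, method = "BH"),
    allele_frequency = af$alt_freq[match(pairs$variant_id, af$variant_id)]
  )
  structure(
    list(results = results, n_samples = n, n_covariates = k, df = df,
         skipped_variants = skipped),
    class = "eqtl_scan"
  )
}

#' @exportS3Method generics::tidy
tidy.eqtl_scan <- function(x, ...) x$results

#' @exportS3Method generics::glance
glance.eqtl_scan <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$results),
    n_transcripts = dplyr::n_distinct(x$results$transcript_id),
    n_variants = dplyr::n_distinct(x$results$variant_id),
    n_samples = x$n_samples,
    n_covariates = x$n_covariates,
    df = x$df,
    n_significant = sum(x$results$fdr < 0.05),
    n_skipped_variants = length(x$skipped_variants)
  )
}

#' @export
print.eqtl_scan <- function(x, ...) {
  g <- glance.eqtl_scan(x)
  cat(sprintf(
    "cis-eQTL scan: %d pairs (%d transcripts x %d variants), n = %d, %d covariates, %d pairs at FDR < 0.05\n",
    g$n_pairs, g$n_transcripts, g$n_variants, g$n_samples, g$n_covariates,
    g$n_significant))
  invisible(x)
}

#' Strand-aware cis-feature classification
#'
#' Classifies each transcript-variant pair by the gene feature the variant
#' interval overlaps: `promoter` (`window` bp upstream of the TSS in
#' transcription direction), `exon` or `intron` within the gene body,
#' `downstream` (`window` bp past the TTS), `none` outside all of these.
#' Variants spanning several features follow the precedence
#' exon > intron > promoter > downstream (coding impact ranked above
#' regulatory). With this precedence every position of the +/- window
#' neighbourhood maps to exactly one category.
#'
#' @param pairs Tibble of `transcript_id`, `variant_id` pairs.
#' @param variants Variant tibble.
#' @param genes Gene-model tibble.
#' @param window Promoter/downstream window in bp (default 3000).
#' @return `pairs` with a `cis_category` column.
#' @export
classify_cis <- function(pairs, variants, genes, window = 3000) {
  iv <- variant_interval(variants)
  vi <- match(pairs$variant_id, iv$variant_id)
  gi <- match(pairs$transcript_id, genes$transcript_id)
  if (anyNA(vi) || anyNA(gi)) rlang::abort("Unknown variant or transcript id in `pairs`.")
  cat_one <- function(vs, ve, vchrom, g) {
    if (vchrom != g$chrom) return("none")
    minus <- g$strand == "-"
    body_s <- min(g$tss, g$tts); body_e <- max(g$tss, g$tts)
    prom <- if (minus) c(g$tss + 1, g$tss + window) else c(g$tss - window, g$tss - 1)
    down <- if (minus) c(g$tts - window, g$tts - 1) else c(g$tts + 1, g$tts + window)
    ovl <- function(s, e) vs <= e && ve >= s
    ex <- g$exons[[1]]
    if (any(vs <= ex$end & ve >= ex$start)) return("exon")
    if (ovl(body_s, body_e)) return("intron")
    if (ovl(prom[1], prom[2])) return("promoter")
    if (ovl(down[1], down[2])) return("downstream")
    "none"
  }
  cis_category <- vapply(seq_len(nrow(pairs)), function(i) {
    v <- iv[vi[i], ]
    cat_one(v$start, v$end, v$chrom, genes[gi[i], ])
  }, character(1))
  dplyr::mutate(pairs, cis_category = cis_category)
}

#' Flag lead variants per transcript
#'
#' The lead association(s) of a transcript are those with the lowest
#' p-value; exact ties (e.g. a SNP and an SV with bitwise-equal p) are all
#' retained.
#'
#' @param results Association tibble (from `tidy()` on an [association_scan()]
#'   result) with `transcript_id` and `p`.
#' @return `results` with an `is_lead` logical column.
#' @export
lead_variants <- function(results) {
  results %>%
    dplyr::group_by(.data$transcript_id) %>%
    dplyr::mutate(is_lead = .data$p == min(.data$p)) %>%
    dplyr::ungroup()
}

#' SNP-vs-SV composition test over categories
#'
#' Pearson chi-square test of the contingency table of variant class
#' (SNP/SV) against a categorical label (cis feature, chromosome group,
#' ...). When any expected cell count falls below 1 the chi-square
#' approximation is unreliable; a warning is raised and Fisher's exact test
#' is reported instead.
#'
#' @param class_labels Character vector (e.g. `"SNP"`/`"SV"`).
#' @param categories Character vector of the same length.
#' @return One-row tibble: `statistic`, `df`, `p`, `method`.
#' @export
composition_test <- function(class_labels, categories) {
  tab <- table(class_labels, categories)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ct$expected < 1)) {
    rlang::warn("Expected cell count < 1; reporting Fisher's exact test.")
    ft <- stats::fisher.test(tab, simulate.p.value = prod(dim(tab)) > 10,
                             B = 1e4)
    return(tibble::tibble(statistic = NA_real_, df = NA_integer_,
                          p = ft$p.value, method = "fisher"))
  }
  tibble::tibble(statistic = unname(ct$statistic),
                 df = as.integer(ct$parameter),
                 p = unname(ct$p.value), method = "chi-square")
}

#' Compare two eQTL variant sets
#'
#' Partitions the union of two lead-variant sets (e.g. scans based on
#' short-read vs long-read derived genotypes) into exclusive and shared
#' membership.
#'
#' @param ids_a,ids_b Character vectors of variant ids.
#' @return List: `a_only`, `b_only`, `shared` (character vectors) and
#'   `counts` (tibble).
#' @export
compare_eqtl_sets <- function(ids_a, ids_b) {
  ids_a <- unique(ids_a); ids_b <- unique(ids_b)
  shared <- intersect(ids_a, ids_b)
  a_only <- setdiff(ids_a, ids_b)
  b_only <- setdiff(ids_b, ids_a)
  list(a_only = a_only, b_only = b_only, shared = shared,
       counts = tibble::tibble(set = c("a_only", "b_only", "shared"),
                               n = c(length(a_only), length(b_only),
                                     length(shared))))
}
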