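#' Configuration for the synthetic SV-eQTL cohort generator
#'
#' Defaults emulate the study design the package targets: ~100 highly
#' inbred (near-homozygous) lines with matched long-read truth and
#' short-read observed SV genotypes, a SNP panel with population structure,
#' and leaf expression with implanted cis effects. Cohort scale defaults
#' (2,000 SVs, 20,000 SNPs, 2,000 transcripts) keep desk-scale runtime;
#' distributional defaults follow the reported cohort where a value is
#' reported (SV length medians ~776/432 bp and copy-number medians ~4/5
#' for well/poorly genotyped variants, ~36% poorly genotypable, 70% of SVs
#' TE-similar with Helitrons half of the TE fraction).
#'
#' @param n_samples,n_sv,n_snp,n_transcripts Cohort dimensions.
#' @param het_rate Residual heterozygous-call rate in the inbred lines.
#' @param missing_rate Baseline missing-call rate.
#' @param frac_poorly_genotypable Fraction of SVs whose short-read
#'   genotyping fails (the poor class).
#' @param allele_flip_rate_poor Per-call REF/ALT flip rate for poor-class
#'   variants in the observed set.
#' @param missing_rate_poor Missing-call rate for poor-class variants in
#'   the observed set; genotyping *failure* (not just wrong calls) is the
#'   dominant error mode, and the default 0.30 routinely trips the >20%
#'   missing-rate rule that designates F1 = 0.
#' @param sv_length_meanlog_good,sv_length_sdlog_good,sv_length_meanlog_poor,sv_length_sdlog_poor
#'   Log-normal SV length parameters per genotypability class (bp,
#'   truncated to \[50, 20000\]).
#' @param copy_number_meanlog_good,copy_number_sdlog_good,copy_number_meanlog_poor,copy_number_sdlog_poor
#'   Log-normal genome copy-number parameters per class.
#' @param ci_pos_mean_good,ci_pos_mean_poor,ci_len_mean_good,ci_len_mean_poor
#'   Mean breakpoint/length confidence-interval widths (bp, exponential).
#' @param te_fraction Fraction of SV sequences copied from TE-library
#'   entries.
#' @param helitron_fraction_of_te Fraction of TE-derived SVs drawn from
#'   Helitron entries.
#' @param te_mutation_rate Per-base substitution rate applied to TE-derived
#'   SV sequences (fragment divergence).
#' @param af_shape1,af_shape2 Beta parameters of the ALT allele-frequency
#'   spectrum (clipped to \[0.02, 0.98\]); the default is low-frequency
#'   skewed.
#' @param n_subpops,fst Population structure: number of subpopulations and
#'   the Balding-Nichols divergence of subpopulation allele frequencies.
#' @param causal_fraction Fraction of transcripts given a causal cis SV.
#' @param cis_effect_sd Scale of causal effect magnitudes (on the latent
#'   log-expression scale whose residual sd is `noise_sd`).
#' @param beta_frequency_exponent Effect magnitudes are drawn proportional
#'   to `(maf / 0.5) ^ -beta_frequency_exponent`: rarer alleles get larger
#'   effects.
#' @param te_insertion_effect_shift Additive shift (negative) applied to
#'   the effect of causal TE insertions: TE insertions depress expression.
#' @param noise_sd Residual sd of latent log expression.
#' @param n_expression_factors,factor_sd Hidden expression factors (count
#'   and loading sd) generating correlated expression the covariate PCs
#'   should absorb.
#' @param tag_snp_fraction Fraction of causal SVs with a nearby tag SNP in
#'   high linkage disequilibrium; the remainder are LD-free from all SNPs.
#' @param tag_snp_mismatch_rate Per-sample genotype mismatch rate between a
#'   causal SV and its tag SNP.
#' @param quant_bias_sd Per-cell sd of the multiplicative log-normal
#'   quantification bias applied, in the second expression matrix, to
#'   transcripts overlapping SVs (reference-sequence bias).
#' @param expr_base_meanlog,expr_base_sdlog Baseline TPM log-normal
#'   parameters.
#' @param chrom_names,chrom_length Synthetic genome layout.
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   outputs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 100, n_sv = 2000, n_snp = 20000,
                       n_transcripts = 2000,
                       het_rate = 0.005, missing_rate = 0.01,
                       frac_poorly_genotypable = 0.36,
                       allele_flip_rate_poor = 0.5,
                       missing_rate_poor = 0.30,
                       sv_length_meanlog_good = 6.654,
                       sv_length_sdlog_good = 1.31,
                       sv_length_meanlog_poor = 6.068,
                       sv_length_sdlog_poor = 1.59,
                       copy_number_meanlog_good = 1.386,
                       copy_number_sdlog_good = 2.19,
                       copy_number_meanlog_poor = 1.609,
                       copy_number_sdlog_poor = 2.18,
                       ci_pos_mean_good = 30, ci_pos_mean_poor = 120,
                       ci_len_mean_good = 40, ci_len_mean_poor = 150,
                       te_fraction = 0.70, helitron_fraction_of_te = 0.5,
                       te_mutation_rate = 0.01,
                       af_shape1 = 0.6, af_shape2 = 2.0,
                       n_subpops = 3, fst = 0.1,
                       causal_fraction = 0.15, cis_effect_sd = 1,
                       beta_frequency_exponent = 0.5,
                       te_insertion_effect_shift = -0.5,
                       noise_sd = 1,
                       n_expression_factors = 3, factor_sd = 0.55,
                       tag_snp_fraction = 0.5,
                       tag_snp_mismatch_rate = 0.05,
                       quant_bias_sd = 1.0,
                       expr_base_meanlog = 1.5, expr_base_sdlog = 1,
                       chrom_names = c("A01", "C01"),
                       chrom_length = 2.5e7,
                       seed = 1L) {
  cfg <- as.list(environment())
  probs <- c("het_rate", "missing_rate", "frac_poorly_genotypable",
             "allele_flip_rate_poor", "missing_rate_poor", "te_fraction",
             "helitron_fraction_of_te", "te_mutation_rate",
             "causal_fraction", "tag_snp_fraction", "tag_snp_mismatch_rate")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      rlang::abort(sprintf("`%s` must be a probability in [0, 1].", p))
    }
  }
  if (n_samples < 4) rlang::abort("`n_samples` must be at least 4.")
  for (s in c("cis_effect_sd", "noise_sd", "quant_bias_sd")) {
    if (cfg[[s]] <= 0) rlang::abort(sprintf("`%s` must be positive.", s))
  }
  if (te_insertion_effect_shift > 0) {
    rlang::abort("`te_insertion_effect_shift` must be non-positive.")
  }
  structure(cfg, class = "sim_config")
}

# library families: 3 entries each, lengths 1-4 kb
te_family_tags <- c(
  Helitron = "DNA/Helitron", CACTA = "DNA/CACTA", Mutator = "DNA/Mutator",
  hAT = "DNA/hAT", `Tc1-Mariner` = "DNA/Tc1-Mariner",
  Copia = "LTR/Copia", Gypsy = "LTR/Gypsy", LINE = "LINE"
)

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

make_te_library <- function(entries_per_family = 3) {
  fams <- rep(names(te_family_tags), each = entries_per_family)
  lens <- sample(1000:4000, length(fams), replace = TRUE)
  seqs <- vapply(lens, random_dna, character(1))
  names(seqs) <- sprintf("TE%03d#%s", seq_along(fams),
                         te_family_tags[fams])
  Biostrings::DNAStringSet(seqs)
}

# fragment of a library entry with the requested length (tiled when the
# entry is shorter) plus point substitutions
te_fragment <- function(entry, len, mutation_rate) {
  s <- as.character(entry)
  while (nchar(s) < len + 1) s <- paste0(s, s)
  start <- sample.int(nchar(s) - len + 1, 1)
  frag <- strsplit(substr(s, start, start + len - 1), "")[[1]]
  nmut <- stats::rbinom(1, len, mutation_rate)
  if (nmut > 0) {
    pos <- sample.int(len, nmut)
    frag[pos] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
  }
  paste(frag, collapse = "")
}

# Balding-Nichols subpopulation frequencies, then near-homozygous calls
sim_genotypes <- function(af, subpop, het_rate, missing_rate, fst,
                          n_subpops, ids, samples) {
  n_var <- length(af)
  n_samp <- length(subpop)
  a <- af * (1 - fst) / fst
  b <- (1 - af) * (1 - fst) / fst
  p_sub <- matrix(stats::rbeta(n_var * n_subpops, rep(a, n_subpops),
                               rep(b, n_subpops)), n_var, n_subpops)
  p <- p_sub[, subpop, drop = FALSE]
  calls <- matrix(ifelse(matrix(stats::runif(n_var * n_samp), n_var) < p,
                         "ALT_HOM", "REF_HOM"), n_var, n_samp)
  calls[matrix(stats::runif(n_var * n_samp), n_var) < het_rate] <- "HET"
  calls[matrix(stats::runif(n_var * n_samp), n_var) < missing_rate] <- "MISSING"
  dimnames(calls) <- list(ids, samples)
  calls
}

#' Simulate a matched truth/observed SV-eQTL cohort
#'
#' Generates, under one seed: near-homozygous truth SV genotypes; observed
#' genotypes derived from the truth by a class-dependent error process
#' (poor-class variants receive REF/ALT flips and elevated missingness,
#' good-class variants only baseline missingness), yielding a bimodal
#' per-variant F1 distribution; class-dependent SV lengths, copy numbers
#' and confidence-interval widths (poor-class variants are shorter, higher
#' copy number, wider intervals); SV sequences, a fraction of which are
#' mutated fragments of TE-library entries; a structured SNP panel
#' including tag SNPs in high LD with a fraction of the causal SVs; gene
#' models; and two TPM expression matrices, the second differing only by
#' multiplicative per-cell quantification bias on SV-overlapping
#' transcripts. Ground truth (variant classes, causal effects on both the
#' generative and the INT scale, TE provenance) is returned for recovery
#' tests.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `sveqtl_cohort`: `samples`, `genes`, `variants`
#'   (SV tibble), `snp_variants`, `truth_gt`, `observed_gt`, `snp_gt`,
#'   `sv_sequences`, `te_library`, `expr_a`, `expr_b`, `variant_truth`,
#'   `transcript_truth`, `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n_causal <- round(cfg$causal_fraction * cfg$n_transcripts)
  if (n_causal > cfg$n_transcripts) {
    rlang::abort("More causal assignments than transcripts.")
  }
  if (n_causal > cfg$n_sv) {
    rlang::abort("More causal assignments than SVs.")
  }
  samples <- sprintf("S%03d", seq_len(cfg$n_samples))
  subpop <- sort(rep_len(seq_len(cfg$n_subpops), cfg$n_samples))

  ## gene models: evenly spaced, random strand, 1-4 exons
  n_chrom <- length(cfg$chrom_names)
  gene_chrom_idx <- rep_len(seq_len(n_chrom), cfg$n_transcripts)
  per_chrom <- tabulate(gene_chrom_idx, n_chrom)
  genes <- purrr::map_dfr(seq_len(n_chrom), function(ci) {
    ng <- per_chrom[ci]
    if (ng == 0) return(NULL)
    spacing <- floor(cfg$chrom_length / (ng + 1))
    start <- spacing * seq_len(ng)
    purrr::map_dfr(seq_len(ng), function(i) {
      n_ex <- sample(1:4, 1)
      ex_len <- sample(200:1500, n_ex, replace = TRUE)
      in_len <- if (n_ex > 1) sample(100:800, n_ex - 1, replace = TRUE) else integer(0)
      s <- start[i]
      ex_start <- s + cumsum(c(0, ex_len[-n_ex] + in_len))
      ex_end <- ex_start + ex_len - 1
      strand <- sample(c("+", "-"), 1)
      gstart <- ex_start[1]; gend <- ex_end[n_ex]
      ex <- data.frame(start = ex_start, end = ex_end)
      if (strand == "-") ex <- ex[rev(seq_len(n_ex)), , drop = FALSE]
      rownames(ex) <- NULL
      tibble::tibble(chrom = cfg$chrom_names[ci], strand = strand,
                     start = gstart, end = gend,
                     tss = if (strand == "+") gstart else gend,
                     tts = if (strand == "+") gend else gstart,
                     exons = list(ex))
    })
  })
  ord <- order(match(genes$chrom, cfg$chrom_names), genes$start)
  genes <- genes[ord, ]
  genes$gene_id <- sprintf("G%05d", seq_len(nrow(genes)))
  genes$transcript_id <- sprintf("G%05d.1", seq_len(nrow(genes)))
  genes <- genes[, c("gene_id", "transcript_id", "chrom", "strand", "tss",
                     "tts", "start", "end", "exons")]

  ## SV records
  sv_ids <- sprintf("SV%05d", seq_len(cfg$n_sv))
  poor <- stats::runif(cfg$n_sv) < cfg$frac_poorly_genotypable
  svtype <- sample(c("INS", "DEL"), cfg$n_sv, replace = TRUE)
  draw_trunc_lnorm <- function(n, meanlog, sdlog, lo, hi) {
    x <- stats::rlnorm(n, meanlog, sdlog)
    while (any(bad <- x < lo | x > hi)) {
      x[bad] <- stats::rlnorm(sum(bad), meanlog, sdlog)
    }
    round(x)
  }
  len <- integer(cfg$n_sv)
  len[!poor] <- draw_trunc_lnorm(sum(!poor), cfg$sv_length_meanlog_good,
                                 cfg$sv_length_sdlog_good, 50, 20000)
  len[poor] <- draw_trunc_lnorm(sum(poor), cfg$sv_length_meanlog_poor,
                                cfg$sv_length_sdlog_poor, 50, 20000)
  copy_n <- integer(cfg$n_sv)
  copy_n[!poor] <- pmax(1, round(stats::rlnorm(sum(!poor),
    cfg$copy_number_meanlog_good, cfg$copy_number_sdlog_good)))
  copy_n[poor] <- pmax(1, round(stats::rlnorm(sum(poor),
    cfg$copy_number_meanlog_poor, cfg$copy_number_sdlog_poor)))
  ci_pos <- round(stats::rexp(cfg$n_sv,
    1 / ifelse(poor, cfg$ci_pos_mean_poor, cfg$ci_pos_mean_good)))
  ci_len <- round(stats::rexp(cfg$n_sv,
    1 / ifelse(poor, cfg$ci_len_mean_poor, cfg$ci_len_mean_good)))

  ## positions: causal SVs are placed in the cis window of their target
  ## transcript, the rest uniformly
  causal_tx <- sort(sample(genes$transcript_id, n_causal))
  causal_sv <- sv_ids[seq_len(n_causal)]
  chrom <- sample(cfg$chrom_names, cfg$n_sv, replace = TRUE)
  pos <- floor(stats::runif(cfg$n_sv, 1, cfg$chrom_length - 30000))
  gi <- match(causal_tx, genes$transcript_id)
  for (j in seq_len(n_causal)) {
    g <- genes[gi[j], ]
    chrom[j] <- g$chrom
    lo <- max(min(g$tss, g$tts) - 2500, 1)
    hi <- max(g$tss, g$tts) + 2500
    pos[j] <- sample(lo:hi, 1)
  }

  ## TE provenance and sequences
  te_library <- make_te_library()
  lib_fams <- parse_te_family(names(te_library))
  is_te <- stats::runif(cfg$n_sv) < cfg$te_fraction
  te_family <- rep(NA_character_, cfg$n_sv)
  n_te <- sum(is_te)
  is_heli <- stats::runif(n_te) < cfg$helitron_fraction_of_te
  other <- setdiff(unique(lib_fams), "Helitron")
  te_family[is_te] <- ifelse(is_heli, "Helitron",
                             sample(other, n_te, replace = TRUE))
  seqs <- character(cfg$n_sv)
  for (i in seq_len(cfg$n_sv)) {
    if (is_te[i]) {
      entry <- sample(which(lib_fams == te_family[i]), 1)
      seqs[i] <- te_fragment(te_library[[entry]], len[i],
                             cfg$te_mutation_rate)
    } else {
      seqs[i] <- random_dna(len[i])
    }
  }
  sv_sequences <- Biostrings::DNAStringSet(stats::setNames(seqs, sv_ids))

  variants <- tibble::tibble(
    id = sv_ids, chrom = chrom, pos = as.integer(pos), svtype = svtype,
    length = as.integer(len), sequence = seqs,
    ci_pos_width = as.integer(ci_pos), ci_len_width = as.integer(ci_len)
  )

  ## truth genotypes (long-read-style) and observed genotypes
  ## (short-read-style with class-dependent errors)
  af <- pmin(pmax(stats::rbeta(cfg$n_sv, cfg$af_shape1, cfg$af_shape2),
                  0.02), 0.98)
  truth_gt <- sim_genotypes(af, subpop, cfg$het_rate, cfg$missing_rate,
                            cfg$fst, cfg$n_subpops, sv_ids, samples)
  observed_gt <- truth_gt
  good_rows <- which(!poor)
  if (length(good_rows)) {
    extra_miss <- matrix(stats::runif(length(good_rows) * cfg$n_samples),
                         length(good_rows)) < cfg$missing_rate
    observed_gt[good_rows, ][extra_miss] <- "MISSING"
  }
  poor_rows <- which(poor)
  if (length(poor_rows)) {
    blk <- observed_gt[poor_rows, , drop = FALSE]
    flip <- matrix(stats::runif(length(blk)), nrow(blk)) <
      cfg$allele_flip_rate_poor
    swap <- flip & blk %in% c("REF_HOM", "ALT_HOM")
    blk[swap] <- ifelse(blk[swap] == "REF_HOM", "ALT_HOM", "REF_HOM")
    blk[matrix(stats::runif(length(blk)), nrow(blk)) <
          cfg$missing_rate_poor] <- "MISSING"
    observed_gt[poor_rows, ] <- blk
  }

  ## SNP panel; the first SNPs are LD tags of a fraction of the causal SVs
  snp_ids <- sprintf("SNP%06d", seq_len(cfg$n_snp))
  snp_af <- pmin(pmax(stats::rbeta(cfg$n_snp, cfg$af_shape1, cfg$af_shape2),
                      0.02), 0.98)
  snp_chrom <- sample(cfg$chrom_names, cfg$n_snp, replace = TRUE)
  snp_pos <- floor(stats::runif(cfg$n_snp, 1, cfg$chrom_length))
  snp_gt <- sim_genotypes(snp_af, subpop, cfg$het_rate, cfg$missing_rate,
                          cfg$fst, cfg$n_subpops, snp_ids, samples)
  has_tag <- stats::runif(n_causal) < cfg$tag_snp_fraction
  tag_snp_id <- rep(NA_character_, n_causal)
  tag_idx <- which(has_tag)
  if (length(tag_idx) > cfg$n_snp) {
    rlang::abort("Not enough SNPs to host the requested tag SNPs.")
  }
  for (j in seq_along(tag_idx)) {
    ci <- tag_idx[j]
    tag_snp_id[ci] <- snp_ids[j]
    g <- genes[gi[ci], ]
    snp_chrom[j] <- g$chrom
    snp_pos[j] <- min(max(g$tss + sample(-5e4:5e4, 1), 1), cfg$chrom_length)
    tag <- truth_gt[causal_sv[ci], ]
    mism <- stats::runif(cfg$n_samples) < cfg$tag_snp_mismatch_rate &
      tag %in% c("REF_HOM", "ALT_HOM")
    tag[mism] <- ifelse(tag[mism] == "REF_HOM", "ALT_HOM", "REF_HOM")
    snp_gt[j, ] <- tag
  }
  snp_variants <- tibble::tibble(
    id = snp_ids, chrom = snp_chrom, pos = as.integer(snp_pos),
    svtype = "SNP", length = 1L, sequence = NA_character_,
    ci_pos_width = 0L, ci_len_width = 0L
  )

  ## expression: hidden factors + causal cis effects + noise, exponentiated
  ## onto a baseline-TPM scale (the latent scale is what INT recovers)
  n_tx <- nrow(genes)
  fac <- matrix(stats::rnorm(cfg$n_expression_factors * cfg$n_samples),
                cfg$n_expression_factors, cfg$n_samples)
  lam <- matrix(stats::rnorm(n_tx * cfg$n_expression_factors,
                             sd = cfg$factor_sd),
                n_tx, cfg$n_expression_factors)
  y <- lam %*% fac + matrix(stats::rnorm(n_tx * cfg$n_samples,
                                         sd = cfg$noise_sd),
                            n_tx, cfg$n_samples)
  rownames(y) <- genes$transcript_id
  colnames(y) <- samples

  dos <- dosage_matrix(truth_gt[causal_sv, , drop = FALSE], impute = "mean")
  dos_c <- dos - rowMeans(dos)
  v_maf <- pmin(af[seq_len(n_causal)], 1 - af[seq_len(n_causal)])
  magnitude <- cfg$cis_effect_sd * (v_maf / 0.5)^(-cfg$beta_frequency_exponent)
  sgn <- sample(c(-1, 1), n_causal, replace = TRUE)
  beta_raw <- sgn * magnitude
  te_ins <- is_te[seq_len(n_causal)] & svtype[seq_len(n_causal)] == "INS"
  beta_raw[te_ins] <- beta_raw[te_ins] + cfg$te_insertion_effect_shift
  ti <- match(causal_tx, genes$transcript_id)
  y[ti, ] <- y[ti, ] + beta_raw * dos_c
  var_g <- apply(dos_c, 1, stats::var)
  sd_y <- sqrt(beta_raw^2 * var_g +
                 rowSums(lam[ti, , drop = FALSE]^2) + cfg$noise_sd^2)
  beta_int <- beta_raw / sd_y

  base_tpm <- stats::rlnorm(n_tx, cfg$expr_base_meanlog, cfg$expr_base_sdlog)
  expr_a <- base_tpm * exp(y)
  dimnames(expr_a) <- dimnames(y)
  attr(expr_a, "unit") <- "TPM"

  hits <- variant_hits(variants, genes, window = 1000)
  biased <- names(hits)[hits > 0]
  expr_b <- expr_a
  if (length(biased)) {
    bi <- match(biased, rownames(expr_b))
    expr_b[bi, ] <- expr_b[bi, ] *
      exp(matrix(stats::rnorm(length(bi) * cfg$n_samples,
                              sd = cfg$quant_bias_sd), length(bi)))
  }
  attr(expr_b, "unit") <- "TPM"

  variant_truth <- tibble::tibble(
    variant_id = sv_ids,
    genotypability = ifelse(poor, "poor", "good"),
    te_family = te_family,
    copy_number = copy_n,
    ci_pos_width = as.integer(ci_pos),
    ci_len_width = as.integer(ci_len),
    target_af = af
  )
  transcript_truth <- tibble::tibble(
    transcript_id = genes$transcript_id,
    causal_variant = NA_character_,
    beta_raw = NA_real_,
    beta_int = NA_real_,
    tag_snp = NA_character_
  )
  transcript_truth$causal_variant[ti] <- causal_sv
  transcript_truth$beta_raw[ti] <- beta_raw
  transcript_truth$beta_int[ti] <- beta_int
  transcript_truth$tag_snp[ti] <- tag_snp_id

  structure(
    list(samples = tibble::tibble(sample_id = samples, subpop = subpop),
         genes = genes, variants = variants, snp_variants = snp_variants,
         truth_gt = genotype_matrix(truth_gt),
         observed_gt = genotype_matrix(observed_gt),
         snp_gt = genotype_matrix(snp_gt),
         sv_sequences = sv_sequences, te_library = te_library,
         expr_a = expr_a, expr_b = expr_b,
         variant_truth = variant_truth,
         transcript_truth = transcript_truth,
         config = cfg),
    class = "sveqtl_cohort"
  )
}

#' Write a simulated cohort to standard file formats
#'
#' Emits truth/observed/SNP VCFs, SV and TE-library FASTA files, a GFF3 of
#' the gene models, two expression TSVs and the ground-truth tables.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  sv_noseq <- dplyr::mutate(cohort$variants, sequence = NA_character_)
  write_sv_vcf(sv_noseq, cohort$truth_gt, p("truth.vcf"))
  write_sv_vcf(sv_noseq, cohort$observed_gt, p("observed.vcf"))
  write_sv_vcf(cohort$snp_variants, cohort$snp_gt, p("snp.vcf"))
  Biostrings::writeXStringSet(cohort$sv_sequences, p("sv_sequences.fasta"))
  Biostrings::writeXStringSet(cohort$te_library, p("te_library.fasta"))
  write_gene_models(cohort$genes, p("genes.gff3"))
  write_expression_matrix(cohort$expr_a, p("expression_graph.tsv"))
  write_expression_matrix(cohort$expr_b, p("expression_linear.tsv"))
  utils::write.table(cohort$variant_truth, p("sim_truth_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$transcript_truth, p("sim_truth_transcripts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(stats::setNames(
    file.path(dir, c("truth.vcf", "observed.vcf", "snp.vcf",
                     "sv_sequences.fasta", "te_library.fasta", "genes.gff3",
                     "expression_graph.tsv", "expression_linear.tsv",
                     "sim_truth_variants.tsv", "sim_truth_transcripts.tsv")),
    c("truth_vcf", "observed_vcf", "snp_vcf", "sv_fasta", "te_library",
      "gff3", "expr_a", "expr_b", "truth_variants", "truth_transcripts")))
}

#' Worked genotype-concordance example
#'
#' One variant over 57 inbred lines: the truth set calls the alternative
#' allele in two lines; the observed (short-read) genotypes call it in
#' three lines, including both truth ALT lines. Scoring this example gives
#' ALT-perspective F1 = 0.8 and REF-perspective F1 = 108/109 (0.99 at two
#' decimals).
#'
#' @return List with 1 x 57 `truth` and `observed` genotype matrices.
#' @export
worked_example_genotypes <- function() {
  samples <- sprintf("L%02d", 1:57)
  truth <- matrix("REF_HOM", 1, 57, dimnames = list("SV_example", samples))
  observed <- truth
  truth[, c("L01", "L02")] <- "ALT_HOM"
  observed[, c("L01", "L02", "L03")] <- "ALT_HOM"
  list(truth = genotype_matrix(truth), observed = genotype_matrix(observed))
}
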