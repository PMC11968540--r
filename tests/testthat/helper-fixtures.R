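# Small in-code fixture builders shared across test files.

# genotype matrix from per-variant state vectors
make_gm <- function(..., samples = NULL) {
  rows <- list(...)
  n <- length(rows[[1]])
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(n))
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows) %||% paste0("v", seq_along(rows))
  if (is.null(names(rows))) rownames(m) <- paste0("v", seq_along(rows))
  colnames(m) <- samples
  genotype_matrix(m)
}

# a call vector with given counts (REF_HOM fill)
calls_with <- function(n, alt = 0, het = 0, missing = 0) {
  v <- rep("REF_HOM", n)
  idx <- seq_len(alt + het + missing)
  v[seq_len(alt)] <- "ALT_HOM"
  if (het > 0) v[alt + seq_len(het)] <- "HET"
  if (missing > 0) v[alt + het + seq_len(missing)] <- "MISSING"
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-written VCF fixture exercising GT states, CIPOS and symbolic alleles
write_fixture_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"l\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
    "##INFO=<ID=CIPOS,Number=2,Type=Integer,Description=\"c\">",
    "##INFO=<ID=CILEN,Number=2,Type=Integer,Description=\"c\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsampA\tsampB\tsampC",
    "A01\t100\tsv1\tN\tNACGTACGT\t.\tPASS\tSVTYPE=INS;SVLEN=8;CIPOS=-50,50\tGT\t0/0\t1/1\t./.",
    "A01\t500\tsv2\t<pad>\t<DEL>\t.\tPASS\tSVTYPE=DEL;SVLEN=-561\tGT\t0|0\t0/1\t1/1",
    "C01\t900\tsv3\tNAAAATTTTC\tN\t.\tPASS\tSVTYPE=DEL;SVLEN=-9;CILEN=-3,4\tGT\t1/0\t1|1\t0/0"
  )
  lines <- sub("<pad>", "N", lines, fixed = TRUE)
  writeLines(lines, path)
  path
}

# minimal gene set: one plus-strand and one minus-strand two-exon gene
fixture_genes <- function() {
  tibble::tibble(
    gene_id = c("gP", "gM"),
    transcript_id = c("gP.1", "gM.1"),
    chrom = c("A01", "A01"),
    strand = c("+", "-"),
    tss = c(10000L, 52000L),
    tts = c(14000L, 50000L),
    start = c(10000L, 50000L),
    end = c(14000L, 52000L),
    exons = list(
      data.frame(start = c(10000L, 12000L), end = c(10800L, 14000L)),
      data.frame(start = c(51500L, 50000L), end = c(52000L, 50900L))
    )
  )
}

make_variant <- function(id, chrom, pos, svtype = "INS", length = 1L) {
  tibble::tibble(id = id, chrom = chrom, pos = as.integer(pos),
                 svtype = svtype, length = as.integer(length),
                 sequence = NA_character_, ci_pos_width = 0L,
                 ci_len_width = 0L)
}

# small cohort configuration used where a full-scale one is unnecessary
tiny_config <- function(seed = 42L, ...) {
  sim_config(n_samples = 60, n_sv = 150, n_snp = 600, n_transcripts = 80,
             seed = seed, ...)
}
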