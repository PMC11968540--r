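#' Read a biallelic VCF into variant records and a genotype matrix
#'
#' Accepts VCF 4.x with biallelic records and a GT FORMAT field. Genotypes are
#' encoded as `0/0 -> REF_HOM`, `1/1 -> ALT_HOM`, `0/1` or `1/0 -> HET`,
#' `./.` (or a missing cell) `-> MISSING`; phased separators (`|`) are treated
#' identically to unphased. The INFO keys `SVTYPE`, `SVLEN`, `END`, `CIPOS`
#' and `CILEN` are parsed when present; confidence-interval widths are
#' `end - start` of the interval (0 when the key is absent).
#'
#' @param path Path to a VCF file (plain text or gzipped).
#' @return A list with `variants` (tibble: `id`, `chrom`, `pos`, `svtype`,
#'   `length`, `sequence`, `ci_pos_width`, `ci_len_width`) and `genotypes`
#'   (call matrix, variants x samples).
#' @export
read_sv_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    rlang::abort(sprintf(
      "Multi-allelic record(s) not supported: %s",
      paste(fix[multi, "ID"], collapse = ", ")
    ))
  }
  gt_raw <- v@gt
  if (is.null(gt_raw) || !any(grepl("GT", gt_raw[, "FORMAT"]))) {
    rlang::abort("VCF has no GT field.")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  calls <- matrix("MISSING", nrow(gt), ncol(gt),
                  dimnames = list(NULL, colnames(gt)))
  gt_clean <- gsub("|", "/", gt, fixed = TRUE)
  calls[gt_clean %in% "0/0"] <- "REF_HOM"
  calls[gt_clean %in% "1/1"] <- "ALT_HOM"
  calls[gt_clean %in% c("0/1", "1/0")] <- "HET"

  info <- fix[, "INFO"]
  ref <- fix[, "REF"]
  id <- fix[, "ID"]
  if (anyNA(id) || any(id == ".")) {
    id <- ifelse(is.na(id) | id == ".",
                 paste0(fix[, "CHROM"], "_", fix[, "POS"]), id)
  }
  svtype <- info_field(info, "SVTYPE")
  svlen <- suppressWarnings(as.numeric(info_field(info, "SVLEN")))
  symbolic <- grepl("^<", alt)
  # infer type from allele lengths where SVTYPE is absent
  inferred <- dplyr::case_when(
    nchar(ref) == 1 & nchar(alt) == 1 & !symbolic ~ "SNP",
    nchar(alt) > nchar(ref) ~ "INS",
    TRUE ~ "DEL"
  )
  svtype <- ifelse(is.na(svtype), inferred, svtype)
  len <- dplyr::case_when(
    svtype == "SNP" ~ 1,
    !is.na(svlen) ~ abs(svlen),
    !symbolic ~ abs(nchar(alt) - nchar(ref)) * 1.0,
    TRUE ~ NA_real_
  )
  end_info <- suppressWarnings(as.numeric(info_field(info, "END")))
  pos <- as.integer(fix[, "POS"])
  len <- ifelse(is.na(len) & !is.na(end_info), end_info - pos, len)
  if (anyNA(len)) {
    rlang::abort(sprintf("Cannot determine length for record(s): %s",
                         paste(id[is.na(len)], collapse = ", ")))
  }
  sequence <- rep(NA_character_, length(id))
  take_alt <- svtype == "INS" & !symbolic & nchar(alt) > 1
  sequence[take_alt] <- substr(alt[take_alt], 2, nchar(alt[take_alt]))
  take_ref <- svtype == "DEL" & !symbolic & nchar(ref) > 1
  sequence[take_ref] <- substr(ref[take_ref], 2, nchar(ref[take_ref]))

  variants <- tibble::tibble(
    id = id,
    chrom = fix[, "CHROM"],
    pos = pos,
    svtype = svtype,
    length = as.integer(round(len)),
    sequence = sequence,
    ci_pos_width = ci_width(info, "CIPOS"),
    ci_len_width = ci_width(info, "CILEN")
  )
  rownames(calls) <- variants$id
  list(variants = variants, genotypes = genotype_matrix(calls))
}

info_field <- function(info, key) {
  vapply(info, function(x) {
    mm <- regmatches(x, regexec(paste0("(?:^|;)", key, "=([^;]+)"), x))[[1]]
    if (length(mm) == 2) mm[2] else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

ci_width <- function(info, key) {
  raw <- info_field(info, key)
  vapply(raw, function(x) {
    if (is.na(x)) return(0L)
    parts <- suppressWarnings(as.numeric(strsplit(x, ",", fixed = TRUE)[[1]]))
    if (length(parts) != 2 || anyNA(parts)) return(0L)
    as.integer(parts[2] - parts[1])
  }, integer(1), USE.NAMES = FALSE)
}

#' Write variant records and genotypes as a VCF file
#'
#' Emits a minimal VCF 4.2 with `SVTYPE`, `SVLEN`, `END`, `CIPOS`, `CILEN`
#' INFO keys and per-sample GT. Records carrying a sequence are written with
#' explicit padded REF/ALT alleles; records without one are written as
#' symbolic `<INS>`/`<DEL>`. `write_sv_vcf()` followed by [read_sv_vcf()]
#' reproduces the in-memory objects.
#'
#' @param variants Variant tibble as returned by [read_sv_vcf()].
#' @param genotypes Genotype call matrix aligned with `variants$id`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(variants, genotypes, path) {
  stopifnot(identical(variants$id, rownames(genotypes)))
  gt_code <- c(REF_HOM = "0/0", ALT_HOM = "1/1", HET = "0/1", MISSING = "./.")
  seqs <- variants$sequence
  has_seq <- !is.na(seqs)
  ref <- alt <- rep(NA_character_, nrow(variants))
  ref[variants$svtype == "SNP"] <- "A"
  alt[variants$svtype == "SNP"] <- "C"
  ins <- variants$svtype == "INS"
  del <- variants$svtype == "DEL"
  ref[ins & has_seq] <- "N"
  alt[ins & has_seq] <- paste0("N", seqs[ins & has_seq])
  ref[del & has_seq] <- paste0("N", seqs[del & has_seq])
  alt[del & has_seq] <- "N"
  ref[ins & !has_seq] <- "N"; alt[ins & !has_seq] <- "<INS>"
  ref[del & !has_seq] <- "N"; alt[del & !has_seq] <- "<DEL>"
  svlen <- ifelse(del, -variants$length, variants$length)
  info <- paste0(
    "SVTYPE=", variants$svtype,
    ifelse(variants$svtype == "SNP", "", paste0(";SVLEN=", svlen)),
    ifelse(del, paste0(";END=", variants$pos + variants$length), ""),
    ifelse(variants$ci_pos_width > 0,
           paste0(";CIPOS=0,", variants$ci_pos_width), ""),
    ifelse(variants$ci_len_width > 0,
           paste0(";CILEN=0,", variants$ci_len_width), "")
  )
  gt_txt <- matrix(gt_code[genotypes], nrow(genotypes), ncol(genotypes))
  body <- cbind(variants$chrom, variants$pos, variants$id, ref, alt,
                ".", "PASS", info, "GT", gt_txt)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Variant type\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Variant length\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=CIPOS,Number=2,Type=Integer,Description=\"Breakpoint position confidence interval\">",
    "##INFO=<ID=CILEN,Number=2,Type=Integer,Description=\"Length confidence interval\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(genotypes)), collapse = "\t")
  )
  writeLines(c(header, apply(body, 1, paste, collapse = "\t")), path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Builds one gene model per mRNA feature with strand-aware TSS/TTS (the TSS
#' is the 5' transcript end: the numerically larger coordinate on the minus
#' strand) and 5'-to-3' sorted exons. An exon whose parent is not a known
#' mRNA is an error.
#'
#' @param path Path to a GFF3 file.
#' @return Tibble with `gene_id`, `transcript_id`, `chrom`, `strand`, `tss`,
#'   `tts`, `start`, `end` and an `exons` list-column of data frames
#'   (`start`, `end`, sorted 5' to 3').
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$type <- as.character(df$type)
  mrna <- df[df$type %in% c("mRNA", "transcript"), ]
  exons <- df[df$type == "exon", ]
  if (nrow(mrna) == 0) rlang::abort("GFF3 contains no mRNA features.")
  mrna_parent <- vapply(mrna$Parent, function(p) {
    if (length(p)) as.character(p)[1] else NA_character_
  }, character(1))
  exon_parent <- vapply(exons$Parent, function(p) {
    if (length(p)) as.character(p)[1] else NA_character_
  }, character(1))
  unknown <- setdiff(exon_parent, mrna$ID)
  if (length(unknown) || anyNA(exon_parent)) {
    rlang::abort(sprintf("Exon(s) with no parent mRNA: %s",
                         paste(stats::na.omit(unknown), collapse = ", ")))
  }
  purrr::map_dfr(seq_len(nrow(mrna)), function(i) {
    m <- mrna[i, ]
    ex <- exons[exon_parent == m$ID, c("start", "end")]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) == 0) ex <- data.frame(start = m$start, end = m$end)
    minus <- as.character(m$strand) == "-"
    if (minus) ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
    rownames(ex) <- NULL
    tibble::tibble(
      gene_id = mrna_parent[i] %||% m$ID,
      transcript_id = m$ID,
      chrom = as.character(m$seqnames),
      strand = as.character(m$strand),
      tss = if (minus) m$end else m$start,
      tts = if (minus) m$start else m$end,
      start = m$start,
      end = m$end,
      exons = list(as.data.frame(ex))
    )
  })
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gene_models()]: emits gene, mRNA and exon features.
#'
#' @param models Gene-model tibble (see [read_gene_models()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    ex <- m$exons[[1]]
    g <- sprintf("%s\tsveqtl\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                 m$chrom, m$start, m$end, m$strand, m$gene_id)
    t <- sprintf("%s\tsveqtl\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                 m$chrom, m$start, m$end, m$strand, m$transcript_id, m$gene_id)
    e <- sprintf("%s\tsveqtl\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
                 m$chrom, ex$start, ex$end, m$strand, m$transcript_id,
                 seq_len(nrow(ex)), m$transcript_id)
    lines <- c(lines, g, t, e)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read / write an expression matrix as tab-separated text
#'
#' The format is a header row of sample ids preceded by a `transcript_id`
#' column; values are non-negative reals (TPM or counts).
#'
#' @param path File path.
#' @param unit `"TPM"` or `"count"`; stored as an attribute of the matrix.
#' @return `read_expression_matrix()`: numeric matrix (transcripts x samples)
#'   with a `unit` attribute. `write_expression_matrix()`: `path`, invisibly.
#' @export
read_expression_matrix <- function(path, unit = c("TPM", "count")) {
  unit <- match.arg(unit)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (any(m < 0)) rlang::abort("Expression values must be non-negative.")
  attr(m, "unit") <- unit
  m
}

#' @rdname read_expression_matrix
#' @param expr Numeric expression matrix (transcripts x samples).
#' @export
write_expression_matrix <- function(expr, path) {
  df <- data.frame(transcript_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
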