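# Thin wrapper around NCBI blastn for local-alignment searches with E-value
# semantics (copy-number counting, TE family assignment). Uses the pairwise
# `-subject` mode, which needs no pre-built database.

as_dna_set <- function(x) {
  if (inherits(x, "DNAStringSet")) return(x)
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(Biostrings::DNAStringSet(x))
  }
  rlang::abort("Sequences must be a DNAStringSet or a named character vector.")
}

run_blastn <- function(query, subject, max_evalue = 1e-5) {
  blastn <- Sys.which("blastn")
  if (blastn == "") {
    rlang::abort("blastn not found on PATH; required for local-alignment search.")
  }
  query <- as_dna_set(query)
  qfile <- tempfile(fileext = ".fa")
  on.exit(unlink(qfile), add = TRUE)
  Biostrings::writeXStringSet(query, qfile)
  if (inherits(subject, "DNAStringSet")) {
    sfile <- tempfile(fileext = ".fa")
    on.exit(unlink(sfile), add = TRUE)
    Biostrings::writeXStringSet(subject, sfile)
  } else {
    sfile <- subject
    if (!file.exists(sfile)) rlang::abort(sprintf("No such FASTA file: %s", sfile))
  }
  out <- tempfile(fileext = ".tsv")
  on.exit(unlink(out), add = TRUE)
  # synthetic sequences can be low-complexity-free random DNA; disable
  # dust masking so planted copies are never filtered
  status <- system2(blastn, c(
    "-query", qfile, "-subject", sfile,
    "-evalue", format(max_evalue, scientific = TRUE),
    "-dust", "no", "-soft_masking", "false",
    "-outfmt", shQuote("6 qseqid sseqid pident length mismatch gapopen qstart qend sstart send evalue bitscore"),
    "-out", out
  ))
  if (status != 0) rlang::abort("blastn failed.")
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (!file.exists(out) || file.size(out) == 0) {
    df <- as.data.frame(matrix(nrow = 0, ncol = length(cols)))
    names(df) <- cols
    df$qseqid <- character(); df$sseqid <- character()
    return(tibble::as_tibble(df))
  }
  df <- utils::read.delim(out, header = FALSE, col.names = cols,
                          stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}
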