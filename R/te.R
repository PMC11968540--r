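#' Parse the family tag of a TE-library FASTA header
#'
#' Library headers follow the RepeatMasker-style taxonomy
#' `NAME#CLASS/FAMILY` (e.g. `TE0001#DNA/Helitron`, `TE0042#LTR/Copia`) or
#' `NAME#FAMILY` (e.g. `TE0077#LINE`). The family is the part after the
#' `/` when present, otherwise the whole label after `#`.
#'
#' @param headers Character vector of FASTA header names.
#' @return Character vector of family names.
#' @export
parse_te_family <- function(headers) {
  vapply(headers, function(h) {
    if (!grepl("#", h, fixed = TRUE)) {
      rlang::abort(sprintf("Unparseable family tag in library entry: %s", h))
    }
    label <- sub("^[^#]*#", "", h)
    if (label == "") {
      rlang::abort(sprintf("Unparseable family tag in library entry: %s", h))
    }
    sub("^.*/", "", label)
  }, character(1), USE.NAMES = FALSE)
}

#' Map a TE family to its class
#'
#' Class I (RNA/retro-) elements: LTR, LINE, SINE, Copia, Gypsy. Class II
#' (DNA) elements: TIR, CACTA, Mutator, PIF-Harbinger, hAT, Tc1-Mariner,
#' Helitron (rolling-circle). Unknown labels map to `"none"` with a
#' warning.
#'
#' @param family Character vector of family names (or NA).
#' @return Character vector in `{"I", "II", "none"}`.
#' @export
te_class_of <- function(family) {
  class_i <- c("ltr", "line", "sine", "copia", "gypsy")
  class_ii <- c("tir", "cacta", "mutator", "pif-harbinger", "hat",
                "tc1-mariner", "helitron", "dna")
  f <- tolower(family)
  out <- dplyr::case_when(
    is.na(f) ~ "none",
    f %in% class_i ~ "I",
    f %in% class_ii ~ "II",
    TRUE ~ "none"
  )
  unknown <- !is.na(f) & !(f %in% c(class_i, class_ii))
  if (any(unknown)) {
    rlang::warn(sprintf("Unknown TE family label(s): %s",
                        paste(unique(family[unknown]), collapse = ", ")))
  }
  out
}

#' Assign SV sequences to TE families by best local-alignment hit
#'
#' Each SV sequence is searched against the TE library with blastn
#' (E-value cutoff `max_evalue`); the top-scoring qualifying hit determines
#' the family. Ties are broken by higher bitscore, then lower E-value, then
#' library order. A sequence with no qualifying hit gets family `NA` and
#' class `"none"`.
#'
#' @param sequences Named `DNAStringSet` (or named character vector) of SV
#'   sequences, each at least 30 bp.
#' @param library `DNAStringSet` with family-tagged names (see
#'   [parse_te_family()]) or a path to such a FASTA file.
#' @param max_evalue E-value cutoff.
#' @return Tibble: `sv_id`, `family`, `te_class`, `hit_evalue`,
#'   `hit_bitscore`, `hit_coverage` (alignment length / SV length).
#' @export
assign_te_family <- function(sequences, library, max_evalue = 1e-5) {
  sequences <- as_dna_set(sequences)
  if (any(Biostrings::width(sequences) < 30)) {
    rlang::abort("All SV sequences must be at least 30 bp.")
  }
  if (is.character(library) && length(library) == 1) {
    library <- Biostrings::readDNAStringSet(library)
  }
  if (length(library) == 0) rlang::abort("Empty TE library.")
  lib_names <- sub("\\s.*$", "", names(library))
  fam_by_entry <- stats::setNames(parse_te_family(lib_names), lib_names)
  names(library) <- lib_names
  hits <- run_blastn(sequences, library, max_evalue = max_evalue)
  qlen <- stats::setNames(Biostrings::width(sequences), names(sequences))
  empty <- tibble::tibble(
    sv_id = names(sequences), family = NA_character_, te_class = "none",
    hit_evalue = NA_real_, hit_bitscore = NA_real_, hit_coverage = NA_real_)
  if (nrow(hits) == 0) return(empty)
  best <- hits %>%
    dplyr::mutate(lib_order = match(.data$sseqid, lib_names)) %>%
    dplyr::arrange(.data$qseqid, dplyr::desc(.data$bitscore), .data$evalue,
                   .data$lib_order) %>%
    dplyr::distinct(.data$qseqid, .keep_all = TRUE)
  out <- empty
  i <- match(best$qseqid, out$sv_id)
  out$family[i] <- unname(fam_by_entry[best$sseqid])
  out$te_class[i] <- suppressWarnings(te_class_of(out$family[i]))
  out$hit_evalue[i] <- best$evalue
  out$hit_bitscore[i] <- best$bitscore
  out$hit_coverage[i] <- best$length / qlen[best$qseqid]
  out
}

#' Positional confirmation of annotation intervals
#'
#' An interval of set A is confirmed when at least `min_fraction` of its
#' length is covered by the (merged) intervals of set B — the semantics of
#' `bedtools intersect -f`. Returns the confirmed fraction of A.
#'
#' @param a,b Tibbles/data frames with `chrom`, `start`, `end` (1-based,
#'   inclusive).
#' @param min_fraction Minimum covered fraction of the A interval
#'   (inclusive).
#' @return List: `fraction` (confirmed / total A), `confirmed` (logical
#'   per A interval), `coverage` (covered fraction per A interval).
#' @export
positional_confirmation <- function(a, b, min_fraction = 0.5) {
  check_iv <- function(x, nm) {
    if (any(x$end < x$start)) {
      rlang::abort(sprintf("Negative-length interval in %s.", nm))
    }
  }
  check_iv(a, "a"); check_iv(b, "b")
  ga <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start, a$end))
  gb <- GenomicRanges::reduce(
    GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$start, b$end)))
  ov <- GenomicRanges::findOverlaps(ga, gb)
  inter <- GenomicRanges::pintersect(
    ga[S4Vectors::queryHits(ov)], gb[S4Vectors::subjectHits(ov)])
  covered <- numeric(length(ga))
  if (length(ov)) {
    w <- tapply(GenomicRanges::width(inter), S4Vectors::queryHits(ov), sum)
    covered[as.integer(names(w))] <- as.numeric(w)
  }
  frac <- covered / GenomicRanges::width(ga)
  # a zero threshold means "any overlap" (the aligner-style -f floor)
  confirmed <- frac >= max(min_fraction, 1e-9)
  list(fraction = mean(confirmed), confirmed = confirmed, coverage = frac)
}

#' TE family and class composition per variant group
#'
#' Tabulates family and class proportions of TE assignments within groups
#' of SVs (e.g. eQTL-SVs vs genome-wide). Variants without an assignment
#' row are counted as `none` with a warning.
#'
#' @param assignments Tibble from [assign_te_family()].
#' @param groups Named character vector mapping `sv_id` to a group label.
#' @return Tibble: `group`, `level_type` (`"family"` or `"class"`),
#'   `level`, `n`, `fraction` (within group and level type).
#' @export
te_composition <- function(assignments, groups) {
  if (length(groups) == 0) rlang::abort("`groups` must be non-empty.")
  df <- tibble::tibble(sv_id = names(groups), group = unname(groups)) %>%
    dplyr::left_join(assignments, by = "sv_id")
  miss <- is.na(df$te_class) & !(df$sv_id %in% assignments$sv_id)
  if (any(miss)) {
    rlang::warn(sprintf("%d SV(s) without a TE assignment; counted as none.",
                        sum(miss)))
    df$te_class[miss] <- "none"
  }
  df$family[is.na(df$family)] <- "none"
  fam <- df %>%
    dplyr::count(.data$group, level = .data$family) %>%
    dplyr::mutate(level_type = "family")
  cls <- df %>%
    dplyr::count(.data$group, level = .data$te_class) %>%
    dplyr::mutate(level_type = "class")
  dplyr::bind_rows(fam, cls) %>%
    dplyr::group_by(.data$group, .data$level_type) %>%
    dplyr::mutate(fraction = .data$n / sum(.data$n)) %>%
    dplyr::ungroup() %>%
    dplyr::select("group", "level_type", "level", "n", "fraction")
}
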