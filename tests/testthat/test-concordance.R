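# brute-force confusion-matrix oracle: explicit per-sample loop
oracle_counts <- function(truth, test, pos) {
  tp <- fp <- fn <- 0L
  for (i in seq_along(truth)) {
    if (truth[i] %in% c("MISSING", "HET") || test[i] %in% c("MISSING", "HET")) next
    t_pos <- truth[i] == pos
    s_pos <- test[i] == pos
    if (t_pos && s_pos) tp <- tp + 1L
    else if (!t_pos && s_pos) fp <- fp + 1L
    else if (t_pos && !s_pos) fn <- fn + 1L
  }
  c(tp = tp, fp = fp, fn = fn)
}

worked_truth <- function() calls_with(57, alt = 2)
worked_test <- function() c(rep("ALT_HOM", 3), rep("REF_HOM", 54))

test_that("confusion counts reproduce the dual-perspective worked example", {
  expect_equal(confusion_counts(worked_truth(), worked_test(), "ALT"),
               c(tp = 2, fp = 1, fn = 0))
  expect_equal(confusion_counts(worked_truth(), worked_test(), "REF"),
               c(tp = 54, fp = 0, fn = 1))
  same <- calls_with(30, alt = 8, missing = 2)
  expect_equal(confusion_counts(same, same, "ALT")[c("fp", "fn")],
               c(fp = 0, fn = 0))
  expect_equal(confusion_counts(same, same, "REF")[c("fp", "fn")],
               c(fp = 0, fn = 0))
  expect_error(confusion_counts(same, same[-1], "ALT"), "length")
})

test_that("F1 from counts matches the closed form and conventions", {
  expect_equal(f1_from_counts(2, 1, 0), 0.8)
  expect_equal(f1_from_counts(54, 0, 1), 108 / 109)
  # vacuous perfect agreement
  expect_equal(f1_from_counts(0, 0, 0), 1)
  expect_error(f1_from_counts(-1, 0, 0))
})

test_that("score_variant applies HET-as-missing and the 20% missing rule", {
  s <- score_variant(worked_truth(), worked_test())
  expect_equal(s$f1_alt, 0.8)
  expect_equal(s$f1_ref, 108 / 109)
  expect_equal(round(s$f1_ref, 2), 0.99)

  # 12/57 missing = 21.05% > 20% -> both zero; 11/57 = 19.3% does not trip
  tr <- calls_with(57, alt = 10)
  te12 <- calls_with(57, alt = 10, missing = 12)
  te11 <- calls_with(57, alt = 10, missing = 11)
  s12 <- score_variant(tr, te12)
  expect_equal(c(s12$f1_alt, s12$f1_ref), c(0, 0))
  expect_equal(s12$quality_class, "LOW")
  s11 <- score_variant(tr, te11)
  expect_true(s11$f1_alt > 0 && s11$f1_ref > 0)

  # HET counts as missing on either side
  tr_het <- tr; tr_het[30:41] <- "HET"
  s_het <- score_variant(tr_het, calls_with(57, alt = 10))
  expect_equal(s_het$missing_rate, 12 / 57)
  expect_equal(c(s_het$f1_alt, s_het$f1_ref), c(0, 0))

  perfect <- score_variant(tr, tr)
  expect_equal(c(perfect$f1_alt, perfect$f1_ref), c(1, 1))
  expect_equal(perfect$quality_class, "HIGH")
  expect_error(score_variant(character(0), character(0)))
})

test_that("quality classification follows the HIGH/LOW bands", {
  expect_equal(classify_f1(0.99, 0.8), "HIGH")
  expect_equal(classify_f1(0.95, 0.1), "LOW")
  expect_equal(classify_f1(0.5, 0.5), "INTERMEDIATE")
  expect_equal(classify_f1(0.2, 0.99), "LOW")
  expect_equal(classify_f1(c(1, 0, 0.5), c(1, 1, 0.6)),
               c("HIGH", "LOW", "INTERMEDIATE"))
})

test_that("scored counts and F1 match the brute-force oracle on random pairs", {
  withr::local_seed(7)
  for (rep in 1:4) {
    n <- sample(20:80, 1)
    truth <- matrix(sample(GT_STATES, 250 * n, replace = TRUE,
                           prob = c(0.6, 0.25, 0.05, 0.1)), 250, n)
    test <- matrix(sample(GT_STATES, 250 * n, replace = TRUE,
                          prob = c(0.5, 0.3, 0.1, 0.1)), 250, n)
    dimnames(truth) <- dimnames(test) <-
      list(paste0("v", 1:250), paste0("s", 1:n))
    scores <- score_concordance(genotype_matrix(truth),
                                genotype_matrix(test), max_missing = 1.01)
    for (i in seq(1, 250, by = 10)) {
      tr <- truth[i, ]; te <- test[i, ]
      oa <- oracle_counts(tr, te, "ALT_HOM")
      or <- oracle_counts(tr, te, "REF_HOM")
      expect_equal(unlist(scores[i, c("tp_alt", "fp_alt", "fn_alt")],
                          use.names = FALSE), unname(oa))
      expect_equal(unlist(scores[i, c("tp_ref", "fp_ref", "fn_ref")],
                          use.names = FALSE), unname(or))
      expect_equal(scores$f1_alt[i],
                   unname(f1_from_counts(oa[1], oa[2], oa[3])))
      # swapping truth and test swaps FP and FN
      swapped <- oracle_counts(te, tr, "ALT_HOM")
      expect_equal(unname(swapped[c("fp", "fn")]), unname(oa[c("fn", "fp")]))
    }
    # perfect F1 iff full agreement on mutually called samples
    agree <- vapply(1:250, function(i) {
      ok <- !(truth[i, ] %in% c("MISSING", "HET")) &
        !(test[i, ] %in% c("MISSING", "HET"))
      all(truth[i, ok] == test[i, ok])
    }, logical(1))
    expect_equal(scores$f1_alt == 1 & scores$f1_ref == 1, unname(agree))
  }
})

test_that("gene proximity distinguishes inside/within-window/outside", {
  genes <- fixture_genes()
  variants <- dplyr::bind_rows(
    make_variant("in_exon", "A01", 10500, "INS", 200),
    make_variant("near", "A01", 14500, "INS", 100),      # 500 bp past gene end
    make_variant("edge", "A01", 15000, "INS", 50),       # exactly 1000 bp
    make_variant("far", "A01", 15001, "INS", 50),        # 1001 bp
    make_variant("del_span", "A01", 9500, "DEL", 600),   # del reaches into gene
    make_variant("nochrom", "Z99", 100, "INS", 50)
  )
  expect_warning(prox <- gene_proximity(variants, genes, window = 1000),
                 "without gene models")
  got <- setNames(prox$proximity, prox$variant_id)
  expect_equal(got[["in_exon"]], "inside")
  expect_equal(got[["near"]], "within_window")
  expect_equal(prox$distance[prox$variant_id == "near"], 500)
  expect_equal(got[["edge"]], "within_window")
  expect_equal(got[["far"]], "outside")
  expect_equal(got[["del_span"]], "inside")
  expect_equal(got[["nochrom"]], "outside")
})

test_that("copy number counts planted occurrences in a synthetic genome", {
  withr::local_seed(11)
  rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                            collapse = "")
  probe7 <- rand(400)
  probe1 <- rand(300)
  absent <- rand(350)
  filler <- replicate(8, rand(1500))
  chr1 <- paste0(filler[1], probe7, filler[2], probe7, filler[3], probe7,
                 filler[4], probe1, filler[5])
  chr2 <- paste0(filler[6], probe7, filler[7], probe7, probe7, probe7,
                 filler[8])
  genome <- Biostrings::DNAStringSet(c(g1 = chr1, g2 = chr2))
  queries <- Biostrings::DNAStringSet(
    c(seven = probe7, once = probe1, none = absent))
  cn <- copy_number(queries, genome)
  expect_equal(cn[["seven"]], 7L)
  expect_equal(cn[["once"]], 1L)
  expect_equal(cn[["none"]], 0L)
  expect_error(copy_number(Biostrings::DNAStringSet(c(short = "ACGT")), genome),
               "30 bp")
})

test_that("group comparison recovers implanted feature differences", {
  withr::local_seed(19)
  n_hi <- 120; n_lo <- 120; n <- n_hi + n_lo
  ids <- paste0("v", seq_len(n))
  cls <- rep(c("HIGH", "LOW"), c(n_hi, n_lo))
  scores <- tibble::tibble(
    variant_id = ids,
    f1_alt = ifelse(cls == "HIGH", 0.95, 0.05),
    f1_ref = ifelse(cls == "HIGH", 0.95, 0.05),
    quality_class = cls
  )
  variants <- tibble::tibble(
    id = ids, chrom = "A01", pos = seq_len(n) * 100L,
    svtype = "INS",
    length = as.integer(round(ifelse(cls == "HIGH",
                                     rlnorm(n, log(1800), 0.3),
                                     rlnorm(n, log(700), 0.3)))),
    sequence = NA_character_,
    ci_pos_width = as.integer(round(ifelse(cls == "HIGH",
                                           rexp(n, 1 / 30), rexp(n, 1 / 150)))),
    ci_len_width = 0L
  )
  out <- compare_groups(scores, variants)
  len <- out[out$feature == "length", ]
  expect_gt(len$mean_high, len$mean_low)
  expect_lt(len$p_value, 0.01)
  ci <- out[out$feature == "ci_pos_width", ]
  expect_gt(ci$mean_low, ci$mean_high)
  expect_lt(ci$p_value, 0.01)

  # identical groups: equal means, rank-sum p ~ 1
  v2 <- variants
  v2$length <- rep(variants$length[1:n_hi], 2)
  v2$ci_pos_width <- rep(variants$ci_pos_width[1:n_hi], 2)
  out2 <- compare_groups(scores, v2)
  len2 <- out2[out2$feature == "length", ]
  expect_equal(len2$mean_high, len2$mean_low)
  expect_gt(len2$p_value, 0.9)

  expect_error(compare_groups(scores[cls == "HIGH", ], variants), "LOW")
})
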