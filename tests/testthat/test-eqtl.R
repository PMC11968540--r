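test_that("expression filter applies the mean and detection rules", {
  m <- rbind(
    zeros = rep(0, 10),
    one_hit = c(1.5, rep(0, 9)),          # only one sample >= 1
    low_mean = c(rep(0.09, 10)),          # mean < 0.1
    ok = c(1.2, 1.1, rep(0.05, 8))
  )
  colnames(m) <- paste0("s", 1:10)
  attr(m, "unit") <- "TPM"
  expect_equal(filter_expression(m), "ok")
  expect_error(filter_expression(m[0, , drop = FALSE]), "Empty")

  # brute-force recount on a random fixture
  withr::local_seed(2)
  big <- matrix(rlnorm(30 * 12, -1, 2), 30, 12,
                dimnames = list(paste0("t", 1:30), paste0("s", 1:12)))
  attr(big, "unit") <- "TPM"
  oracle <- rownames(big)[vapply(seq_len(30), function(i) {
    mean(big[i, ]) >= 0.1 && sum(big[i, ] >= 1) >= 2
  }, logical(1))]
  expect_equal(filter_expression(big), oracle)
})

test_that("inverse normal transform maps ranks to Blom quantiles", {
  # middle of three maps to zero; outer values are symmetric
  out <- inverse_normal_transform(c(5, 1, 9))
  expect_equal(out[1], 0)
  q <- qnorm((1 - 3 / 8) / (3 + 1 / 4))
  expect_equal(sort(out), c(q, 0, -q))

  # rank invariance under strictly monotone transforms
  withr::local_seed(4)
  x <- rnorm(25)
  expect_equal(inverse_normal_transform(x),
               inverse_normal_transform(exp(3 * x) + 2))

  # n = 5 closed form
  x5 <- c(10, 3, 8, 1, 6)
  expect_equal(inverse_normal_transform(x5),
               qnorm((rank(x5) - 3 / 8) / (5 + 1 / 4)))

  # per-row matrix behaviour: mean ~ 0, ranks preserved
  m <- matrix(rlnorm(5 * 40), 5, 40,
              dimnames = list(paste0("t", 1:5), paste0("s", 1:40)))
  mi <- inverse_normal_transform(m)
  expect_equal(unname(rowMeans(mi)), rep(0, 5), tolerance = 1e-6)
  for (i in 1:5) expect_equal(rank(mi[i, ]), rank(m[i, ]))

  expect_error(inverse_normal_transform(c(1, 2)), "3")
  expect_error(inverse_normal_transform(rep(1, 10)), "Constant")
})

test_that("scree elbow recovers planted factor count and degenerate cases", {
  # three strong factors + weak noise, through the full covariate builder
  withr::local_seed(8)
  n <- 80
  fac <- matrix(rnorm(3 * n), 3, n)
  lam <- matrix(rnorm(200 * 3, sd = 2), 200, 3)
  expr <- exp(lam %*% fac * 0.3 + matrix(rnorm(200 * n, sd = 0.2), 200, n))
  dimnames(expr) <- list(paste0("t", 1:200), paste0("s", 1:n))
  snps <- matrix(sample(c("REF_HOM", "ALT_HOM"), 300 * n, replace = TRUE),
                 300, n, dimnames = list(paste0("m", 1:300), colnames(expr)))
  cov <- build_covariates(genotype_matrix(snps), expr, n_geno_pcs = 5)
  expect_equal(cov$n_expression_pcs, 3L)
  expect_equal(cov$n_genotype_pcs, 5L)
  expect_equal(ncol(cov$matrix), 8)
  # genotype PC scores are orthogonal
  g <- cov$matrix[, 1:5]
  expect_equal(crossprod(g) - diag(diag(crossprod(g))),
               matrix(0, 5, 5), ignore_attr = TRUE, tolerance = 1e-8)

  # perfectly linear scree: no elbow, minimal model
  expect_equal(select_elbow(seq(10, 1, length.out = 20)), 1L)
  expect_equal(select_elbow(rep(1, 10)), 1L)
})

test_that("association scan equals a per-pair OLS oracle to 1e-8", {
  withr::local_seed(31)
  n <- 60
  samples <- paste0("s", 1:n)
  n_tx <- 25; n_v <- 40
  expr <- matrix(rnorm(n_tx * n), n_tx, n,
                 dimnames = list(paste0("t", 1:n_tx), samples))
  expr_int <- inverse_normal_transform(expr)
  gm <- matrix(sample(c("REF_HOM", "ALT_HOM", "HET", "MISSING"), n_v * n,
                      replace = TRUE, prob = c(0.55, 0.35, 0.04, 0.06)),
               n_v, n, dimnames = list(paste0("v", 1:n_v), samples))
  covars <- matrix(rnorm(n * 3), n, 3,
                   dimnames = list(samples, paste0("c", 1:3)))
  pairs <- tibble::tibble(
    transcript_id = sample(rownames(expr), 200, replace = TRUE),
    variant_id = sample(rownames(gm), 200, replace = TRUE)
  )
  scan <- association_scan(expr_int, genotype_matrix(gm), covars, pairs)
  res <- tidy(scan)
  dos <- dosage_matrix(gm, impute = "mean")
  for (i in seq(1, nrow(res), by = 7)) {
    y <- expr_int[res$transcript_id[i], ]
    g <- dos[res$variant_id[i], ]
    fit <- summary(lm(y ~ g + covars))
    expect_equal(res$beta[i], fit$coefficients["g", "Estimate"],
                 tolerance = 1e-8)
    expect_equal(res$t_stat[i], fit$coefficients["g", "t value"],
                 tolerance = 1e-8)
    expect_equal(res$p[i], fit$coefficients["g", "Pr(>|t|)"],
                 tolerance = 1e-8)
  }
  expect_equal(scan$df, n - 3 - 2)
  expect_equal(res$fdr, p.adjust(res$p, method = "BH"))
})

test_that("scan handles perfect fits and zero-variance variants", {
  n <- 30
  samples <- paste0("s", 1:n)
  g <- rep(c("REF_HOM", "ALT_HOM"), length.out = n)
  gm <- rbind(causal = g, flat = rep("REF_HOM", n))
  colnames(gm) <- samples
  dos <- dosage_matrix(gm)["causal", ]
  expr <- rbind(t1 = 2 * dos)
  colnames(expr) <- samples
  pairs <- tibble::tibble(transcript_id = "t1",
                          variant_id = c("causal", "flat"))
  expect_message(scan <- association_scan(expr, genotype_matrix(gm),
                                          NULL, pairs), "zero dosage")
  res <- tidy(scan)
  expect_equal(nrow(res), 1)
  expect_equal(res$beta, 2, tolerance = 1e-10)
  expect_lt(res$p, 1e-60)
  expect_equal(scan$skipped_variants, "flat")
})

test_that("cis classification partitions the 3 kb neighbourhood on both strands", {
  genes <- fixture_genes()
  for (tx in genes$transcript_id) {
    g <- genes[genes$transcript_id == tx, ]
    minus <- g$strand == "-"
    body <- min(g$tss, g$tts):max(g$tss, g$tts)
    ex <- g$exons[[1]]
    lo <- min(g$tss, g$tts) - 3100
    hi <- max(g$tss, g$tts) + 3100
    pos <- seq(lo, hi, by = 7)
    pos <- unique(c(pos,
                    g$tss, g$tts,
                    if (minus) g$tss + c(1, 3000, 3001) else g$tss - c(1, 3000, 3001),
                    if (minus) g$tts - c(1, 3000, 3001) else g$tts + c(1, 3000, 3001),
                    ex$start, ex$end, ex$start - 1, ex$end + 1))
    pos <- pos[pos >= 1]
    variants <- make_variant(paste0("p", seq_along(pos)), g$chrom, pos,
                             "INS", 1)
    pairs <- tibble::tibble(transcript_id = tx, variant_id = variants$id)
    out <- classify_cis(pairs, variants, genes, window = 3000)
    # independent expectation from the gene definition
    expected <- vapply(pos, function(p) {
      in_exon <- any(p >= ex$start & p <= ex$end)
      in_body <- p %in% body
      updist <- if (minus) p - g$tss else g$tss - p
      downdist <- if (minus) g$tts - p else p - g$tts
      if (in_exon) "exon"
      else if (in_body) "intron"
      else if (updist >= 1 && updist <= 3000) "promoter"
      else if (downdist >= 1 && downdist <= 3000) "downstream"
      else "none"
    }, character(1))
    expect_equal(out$cis_category, expected)
    # partition: every in-window position has exactly one non-none label
    in_window <- pos >= min(g$tss, g$tts) - 3000 & pos <= max(g$tss, g$tts) + 3000
    expect_true(all((out$cis_category != "none") == in_window))
  }
})

test_that("classification examples: promoter distances and spanning deletions", {
  genes <- fixture_genes()
  gp <- genes[genes$strand == "+", ]
  v <- dplyr::bind_rows(
    make_variant("up500", "A01", gp$tss - 500, "INS", 1),
    make_variant("up3500", "A01", gp$tss - 3500, "INS", 1),
    # deletion spanning promoter and first exon: exon precedence
    make_variant("span", "A01", gp$tss - 200, "DEL", 400)
  )
  pairs <- tibble::tibble(transcript_id = gp$transcript_id, variant_id = v$id)
  out <- classify_cis(pairs, v, genes)
  expect_equal(out$cis_category, c("promoter", "none", "exon"))

  # minus-strand gene: numerically *after* the gene end but 5' of its TSS
  gm <- genes[genes$strand == "-", ]
  vm <- make_variant("m_up", "A01", gm$tss + 1200, "INS", 1)
  outm <- classify_cis(tibble::tibble(transcript_id = gm$transcript_id,
                                      variant_id = "m_up"), vm, genes)
  expect_equal(outm$cis_category, "promoter")
})

test_that("lead flagging keeps exact ties and matches argmin", {
  res <- tibble::tibble(
    transcript_id = c("t1", "t2", "t2", "t2", "t3", "t3"),
    variant_id = c("v1", "v2", "v3", "v4", "v5", "v6"),
    p = c(0.5, 1e-6, 1e-6, 0.2, 0.9, 0.3)
  )
  out <- lead_variants(res)
  expect_true(out$is_lead[out$transcript_id == "t1"])
  expect_equal(out$variant_id[out$transcript_id == "t2" & out$is_lead],
               c("v2", "v3"))
  expect_equal(out$variant_id[out$transcript_id == "t3" & out$is_lead], "v6")
  # brute-force argmin agreement on a random fixture
  withr::local_seed(6)
  rnd <- tibble::tibble(
    transcript_id = sample(paste0("t", 1:10), 100, replace = TRUE),
    variant_id = paste0("v", 1:100),
    p = runif(100)
  )
  out2 <- lead_variants(rnd)
  for (tx in unique(rnd$transcript_id)) {
    sub <- out2[out2$transcript_id == tx, ]
    expect_equal(sub$is_lead, sub$p == min(sub$p))
  }
})

test_that("composition test matches the textbook chi-square formula", {
  cls <- rep(c("SNP", "SV"), c(60, 40))
  cat <- c(rep(c("promoter", "exon"), c(20, 40)),
           rep(c("promoter", "exon"), c(25, 15)))
  out <- composition_test(cls, cat)
  tab <- table(cls, cat)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  expect_equal(out$statistic, stat, tolerance = 1e-12)
  expect_equal(out$df, 1L)
  expect_equal(out$p, pchisq(stat, 1, lower.tail = FALSE), tolerance = 1e-12)

  # identical proportions: statistic 0, p 1
  same <- composition_test(rep(c("SNP", "SV"), each = 20),
                           rep(rep(c("a", "b"), each = 10), 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  # sparse table falls back to an exact test
  expect_warning(sp <- composition_test(rep(c("SNP", "SV"), c(200, 2)),
                                        c(rep("a", 199), "b", "a", "b")),
                 "exact")
  expect_equal(sp$method, "fisher")
})

test_that("eQTL set comparison partitions by membership", {
  same <- compare_eqtl_sets(c("a", "b"), c("b", "a"))
  expect_equal(same$counts$n, c(0, 0, 2))
  disj <- compare_eqtl_sets(c("a", "b"), c("c"))
  expect_length(disj$shared, 0)
  mix <- compare_eqtl_sets(c("a", "b", "c"), c("b", "c", "d"))
  expect_setequal(mix$a_only, "a")
  expect_setequal(mix$b_only, "d")
  expect_setequal(mix$shared, c("b", "c"))
})
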