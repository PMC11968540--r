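# direct rank-correlation formula (no ties): 1 - 6*sum(d^2)/(n(n^2-1))
spearman_formula <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

test_that("effect-frequency trend matches the rank-correlation formula", {
  leads <- tibble::tibble(
    transcript_id = paste0("t", 1:12),
    variant_id = paste0("v", 1:12),
    beta = c(2.1, -1.8, 1.2, -0.9, 0.8, -0.6, 0.5, 0.45, -0.4, 0.35, 0.3, -0.28),
    allele_frequency = c(0.03, 0.05, 0.08, 0.12, 0.18, 0.22, 0.28, 0.31,
                         0.36, 0.41, 0.45, 0.49)
  )
  out <- effect_frequency_trend(leads)
  expect_equal(out$trend$rho,
               spearman_formula(leads$allele_frequency, abs(leads$beta)),
               tolerance = 1e-12)
  expect_lt(out$trend$rho, -0.9)
  expect_equal(sum(out$bins$n), nrow(leads))

  # near-constant effect size: no trend
  withr::local_seed(12)
  flat <- dplyr::mutate(leads, beta = 1 + rnorm(12, sd = 1e-3))
  expect_lt(abs(effect_frequency_trend(flat)$trend$rho), 0.5)

  expect_error(effect_frequency_trend(leads[1:5, ]), "10")
  expect_warning(
    out2 <- effect_frequency_trend(dplyr::mutate(leads,
                                                 allele_frequency = 0.2)),
    "undefined")
  expect_true(is.na(out2$trend$rho))
})

test_that("planted frequency-dependent architecture yields a negative trend", {
  withr::local_seed(44)
  n <- 150
  maf <- runif(n, 0.05, 0.5)
  beta <- sample(c(-1, 1), n, TRUE) * (maf / 0.5)^(-0.5) *
    exp(rnorm(n, sd = 0.2))
  leads <- tibble::tibble(transcript_id = paste0("t", 1:n),
                          variant_id = paste0("v", 1:n),
                          beta = beta, allele_frequency = maf)
  out <- effect_frequency_trend(leads)
  expect_lt(out$trend$rho, -0.5)
  expect_lt(out$trend$p, 1e-6)
  # binned means decrease with frequency
  expect_gt(out$bins$mean_abs_beta[1], out$bins$mean_abs_beta[5])

  # null architecture: exponent 0 is unbiased over replicates
  rhos <- vapply(1:50, function(i) {
    b0 <- sample(c(-1, 1), n, TRUE) * exp(rnorm(n, sd = 0.3))
    effect_frequency_trend(
      tibble::tibble(transcript_id = leads$transcript_id,
                     variant_id = leads$variant_id,
                     beta = b0, allele_frequency = runif(n, 0.05, 0.5))
    )$trend$rho
  }, numeric(1))
  se <- sd(rhos) / sqrt(length(rhos))
  expect_lt(abs(mean(rhos)), 2 * se + 1e-8)
})

test_that("TE insertions show more negative effects than deletions when planted", {
  withr::local_seed(55)
  n <- 200
  svtype <- rep(c("INS", "DEL"), each = n / 2)
  te <- rep(c(TRUE, FALSE), n / 2)
  shift <- ifelse(svtype == "INS" & te, -0.8, 0)
  beta <- rnorm(n, mean = shift, sd = 0.4)
  leads <- tibble::tibble(transcript_id = paste0("t", 1:n),
                          variant_id = paste0("v", 1:n),
                          beta = beta, allele_frequency = 0.2)
  variants <- tibble::tibble(id = leads$variant_id, chrom = "A01",
                             pos = 1:n, svtype = svtype,
                             length = 100L, sequence = NA_character_,
                             ci_pos_width = 0L, ci_len_width = 0L)
  te_assign <- tibble::tibble(
    sv_id = leads$variant_id[te],
    family = "Helitron", te_class = "II",
    hit_evalue = 1e-20, hit_bitscore = 100, hit_coverage = 0.9)
  out <- insertion_deletion_effect(leads, variants, te_assign)
  st <- out$strata
  med_ins_te <- st$median_beta[st$svtype == "INS" & st$te_status == "TE"]
  med_del_te <- st$median_beta[st$svtype == "DEL" & st$te_status == "TE"]
  expect_lt(med_ins_te, med_del_te)
  expect_lt(out$tests$p_value[out$tests$te_status == "TE"], 1e-6)
  # no planted shift in the non-TE stratum
  expect_gt(out$tests$p_value[out$tests$te_status == "non-TE"], 0.01)

  # without TE assignments only non-TE strata are reported
  out2 <- insertion_deletion_effect(leads, variants)
  expect_true(all(out2$strata$te_status == "non-TE"))

  expect_error(insertion_deletion_effect(leads[svtype == "INS", ], variants),
               "INS and DEL")
})

test_that("variance explained equals the t-statistic identity", {
  withr::local_seed(66)
  n <- 50
  covars <- matrix(rnorm(n * 3), n, 3)
  g <- rbinom(n, 2, 0.3)
  y <- 0.7 * g + covars %*% c(0.5, -0.3, 0.2) + rnorm(n)
  y <- as.numeric(y)
  r2 <- variance_explained(y, g, covars)
  fit <- summary(lm(y ~ g + covars))
  t <- fit$coefficients["g", "t value"]
  df <- fit$df[2]
  expect_equal(r2, t^2 / (t^2 + df), tolerance = 1e-10)

  # noiseless: all remaining variance from dosage
  expect_equal(variance_explained(2 * g + 1, g), 1, tolerance = 1e-12)
  # independent dosage explains ~ nothing
  expect_lt(variance_explained(rnorm(500), rbinom(500, 2, 0.5)), 0.02)
})

test_that("SV-only transcript fraction recovers a planted LD-free fraction", {
  make_results <- function(n_tx, frac_ld_free, seed) {
    withr::with_seed(seed, {
      tx <- paste0("t", seq_len(n_tx))
      ld_free <- runif(n_tx) < frac_ld_free
      sv <- tibble::tibble(transcript_id = tx,
                           variant_id = paste0("sv", seq_len(n_tx)),
                           p = 1e-8, fdr = 1e-6, is_lead = TRUE)
      snp <- tibble::tibble(transcript_id = tx,
                            variant_id = paste0("snp", seq_len(n_tx)),
                            p = ifelse(ld_free, 0.6, 1e-6),
                            fdr = ifelse(ld_free, 0.9, 1e-4),
                            is_lead = FALSE)
      list(results = dplyr::bind_rows(sv, snp), ld_free = ld_free)
    })
  }
  x <- make_results(400, 0.35, 1)
  classes <- setNames(
    ifelse(grepl("^sv", unique(x$results$variant_id)), "SV", "SNP"),
    unique(x$results$variant_id))
  out <- sv_only_transcripts(x$results, classes, fdr = 0.05)
  expect_equal(out$fraction, mean(x$ld_free), tolerance = 1e-12)
  expect_equal(out$n_sv_lead, 400L)

  # every SV-lead transcript also SNP-tagged -> 0
  y <- make_results(100, 0, 2)
  expect_equal(sv_only_transcripts(y$results, classes, fdr = 0.05)$fraction, 0)

  # no SNPs at all -> 1 with a warning
  sv_only <- x$results[grepl("^sv", x$results$variant_id), ]
  expect_warning(z <- sv_only_transcripts(sv_only, classes, fdr = 0.05),
                 "No SNP")
  expect_equal(z$fraction, 1)
})
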