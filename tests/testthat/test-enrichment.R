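mk_counts <- function(study = "s1", mark = "H3K9me2", role = "input",
                      mapping = 10^6, class_reads = c(TEL_C = 50, TEL_G = 50,
                                                      CEN1 = 40, CEN2 = 40)) {
  sample_counts(study, mark, role,
                mapping_summary(paste(study, role), mapping, mapping, NA),
                class_reads)
}

test_that("class frequencies divide class reads by mapping reads", {
  x <- mk_counts(class_reads = c(TEL_C = 50, TEL_G = 0, CEN1 = 1, CEN2 = 2))
  expect_equal(class_frequency(x, "TEL_C"), 5e-5)
  expect_equal(class_frequency(x, "TEL_G"), 0)
  expect_error(class_frequency(x, "NOPE"), "unknown")
  z <- sample_counts("s", "m", "input", mapping_summary("s", 10, 0, 0),
                     c(TEL_C = 0))
  expect_error(class_frequency(z, "TEL_C"), "no mapping reads")
})

test_that("simulated class frequencies match exhaustive window enumeration", {
  g <- build_genome(tiny_spec(seed = 40))
  classes <- default_motif_classes()
  # exact expected input frequency: classify every possible read placement
  L <- 30000L
  wins <- lapply(names(g$genome), function(nm) {
    Biostrings::extractAt(g$genome[[nm]],
                          IRanges::IRanges(seq_len(L - 99L), width = 100L))
  })
  wins <- do.call(c, wins)
  all_wins <- c(wins, Biostrings::reverseComplement(wins))
  expected <- colMeans(classify_reads(all_wins, classes))
  rd <- simulate_sample(g$genome, g$truth, role = "input",
                        n_reads = 60000, seed = 400)
  cs <- count_sample(rd, study_id = "s", mark = "m", role = "input",
                     mapper = "none")
  for (cl in c("TEL_G", "CEN1")) {
    f <- class_frequency(cs, cl)
    se <- sqrt(expected[[cl]] * (1 - expected[[cl]]) / 60000)
    expect_lt(abs(f - expected[[cl]]), 3.5 * se)
  }
})

test_that("enrichment against the genome is the ratio of frequencies", {
  inp <- mk_counts(role = "input", class_reads = c(TEL_C = 100, TEL_G = 80,
                                                   CEN1 = 40, CEN2 = 40))
  ip <- mk_counts(role = "IP", class_reads = c(TEL_C = 200, TEL_G = 80,
                                               CEN1 = 10, CEN2 = 40))
  expect_equal(enrichment_vs_genome(ip, inp, "TEL_C"), 2)
  expect_equal(enrichment_vs_genome(ip, inp, "TEL_G"), 1)
  expect_equal(enrichment_vs_genome(ip, ip, "CEN1"), 1)
  other <- mk_counts(study = "s2", role = "input")
  expect_error(enrichment_vs_genome(ip, other, "TEL_C"), "same study")
})

test_that("zero class counts are never silent: error or pseudocount", {
  inp <- mk_counts(role = "input", class_reads = c(TEL_C = 0, TEL_G = 10,
                                                   CEN1 = 10, CEN2 = 10))
  ip <- mk_counts(role = "IP", class_reads = c(TEL_C = 5, TEL_G = 10,
                                               CEN1 = 10, CEN2 = 10))
  err <- tryCatch(enrichment_vs_genome(ip, inp, "TEL_C"), error = identity)
  expect_match(conditionMessage(err), "TEL_C")
  expect_match(conditionMessage(err), "pseudocount")
  e <- enrichment_vs_genome(ip, inp, "TEL_C", pseudocount = TRUE)
  expect_equal(e, 5.5 / 0.5)
})

test_that("telomere-versus-satellite ratios divide the two enrichments", {
  expect_equal(enrichment_tel_vs_sat(1, 4), 0.25)
  expect_equal(enrichment_tel_vs_sat(2.4, 2.4), 1)
  expect_error(enrichment_tel_vs_sat(NA, 1), "positive")
  expect_error(enrichment_tel_vs_sat(1, 0), "positive")
})

test_that("a satellite-enriched simulation recovers the tel-vs-sat ratio", {
  g <- build_genome(genome_spec(seed = 41))
  inp <- simulate_sample(g$genome, g$truth, role = "input",
                         n_reads = 200000, seed = 410)
  ip <- simulate_sample(g$genome, g$truth, mark_profile(satellite = 4),
                        role = "IP", n_reads = 200000, seed = 411)
  tb <- counts_table(list(
    count_sample(inp, study_id = "s", mark = "m", role = "input",
                 mapper = "none"),
    count_sample(ip, study_id = "s", mark = "m", role = "IP",
                 mapper = "none")))
  et <- enrichment_table(tb)
  ratio <- et$E_tel_vs_sat[1]
  expect_lt(abs(ratio - 0.25) / 0.25, 0.2)
})

test_that("pooling reports ratio-scale mean and SEM and gates on normality", {
  # normal on the log scale: Student's t chosen
  v1 <- withr::with_seed(7, 2^rnorm(20, 0, 0.1))
  p1 <- pool_and_test(v1, null_value = 1)
  expect_identical(p1$test_used, "t")
  expect_gte(p1$shapiro_p, 0.05)
  expect_equal(p1$mean, mean(v1))
  expect_equal(p1$sem * sqrt(20), sd(v1))
  # heavy-tailed mixture: Shapiro-Wilk rejects, Wilcoxon chosen
  v2 <- withr::with_seed(7, {
    outlier <- runif(20) < 0.1
    2^rnorm(20, mean = ifelse(outlier, 2, 0), sd = 0.05)
  })
  p2 <- pool_and_test(v2, null_value = 1)
  expect_lt(p2$shapiro_p, 0.05)
  expect_identical(p2$test_used, "wilcoxon")
})

test_that("pooling handles degenerate and small inputs without crashing", {
  pd <- pool_and_test(rep(1, 5), null_value = 1)
  expect_equal(pd$p_value, 1)
  expect_equal(pd$mean, 1)
  expect_equal(pd$sem, 0)
  expect_identical(pd$test_used, "none")
  # identical values off the null: rank test path, strong evidence
  pi2 <- pool_and_test(rep(2, 8), null_value = 1)
  expect_identical(pi2$test_used, "wilcoxon")
  expect_lt(pi2$p_value, 0.05)
  # n < 3: descriptive only
  ps <- pool_and_test(c(1.2, 1.4), null_value = 1)
  expect_identical(ps$test_used, "none")
  expect_true(is.na(ps$p_value))
  expect_error(pool_and_test(c(1, -2, 3), null_value = 1), "pseudocount")
})

test_that("pooling is invariant under permutation of the study order", {
  v <- withr::with_seed(9, 2^rnorm(12, 0.5, 0.4))
  a <- pool_and_test(v, 1)
  b <- pool_and_test(withr::with_seed(1, sample(v)), 1)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$mean, b$mean)
  expect_identical(a$test_used, b$test_used)
})

test_that("the linear scale tests raw ratios against the null", {
  v <- withr::with_seed(15, rnorm(15, 1.3, 0.1))
  p <- pool_and_test(v, null_value = 1, scale = "linear")
  expect_identical(p$test_used, "t")
  expect_equal(p$p_value, t.test(v, mu = 1)$p.value)
})

test_that("RMUS comparison gates between t, KS and paired alternatives", {
  iv <- withr::with_seed(3, rnorm(15, 0.85, 0.02))
  pv <- withr::with_seed(4, rnorm(15, 0.65, 0.02))
  r <- compare_rmus(iv, pv)
  expect_identical(r$test_used, "t")
  expect_lt(r$p_value, 0.001)
  expect_lt(r$mean_difference, 0)
  expect_equal(r$p_value, t.test(pv, iv, var.equal = TRUE)$p.value)
  # a tied-heavy group is flagged non-normal: two-sample KS path
  iv2 <- c(rep(0.80, 9), 0.20)
  pv2 <- withr::with_seed(6, rnorm(10, 0.5, 0.05))
  r2 <- compare_rmus(iv2, pv2)
  expect_identical(r2$test_used, "ks")
  # paired path
  rp <- compare_rmus(iv, iv + withr::with_seed(8, rnorm(15, 0.1, 0.01)),
                     paired = TRUE)
  expect_identical(rp$test_used, "t")
  expect_lt(rp$p_value, 0.001)
  expect_error(compare_rmus(iv, pv[1:10], paired = TRUE), "equally many")
  rid <- compare_rmus(c(.5, .6, .7), c(.5, .6, .7), paired = TRUE)
  expect_equal(rid$p_value, 1)
  expect_identical(rid$group_stats["input", "median"],
                   rid$group_stats["ip", "median"])
})

test_that("enrichment tables pair samples and keep ratios per study", {
  cl <- list(
    mk_counts("s1", role = "input"),
    mk_counts("s1", role = "IP",
              class_reads = c(TEL_C = 100, TEL_G = 100, CEN1 = 160,
                              CEN2 = 160)),
    mk_counts("s2", role = "input"))
  tb <- counts_table(cl)
  expect_warning(et <- enrichment_table(tb), "s2")
  expect_identical(unique(et$study_id), "s1")
  expect_equal(et$E_genome[et$class == "TEL_C"], 2)
  expect_equal(et$E_genome[et$class == "CEN1"], 4)
  # combined TEL (200/100) over combined SAT (320/80): 2 / 4
  expect_equal(unique(et$E_tel_vs_sat), 0.5)
})

test_that("pooled tables report one gated test per mark and comparison", {
  withr::local_seed(77)
  cl <- list()
  for (s in 1:6) {
    cl <- c(cl, list(
      mk_counts(paste0("s", s), role = "input"),
      mk_counts(paste0("s", s), role = "IP",
                class_reads = round(c(TEL_C = rnorm(1, 100, 8),
                                      TEL_G = rnorm(1, 100, 8),
                                      CEN1 = rnorm(1, 40, 4),
                                      CEN2 = rnorm(1, 40, 4))))))
  }
  et <- enrichment_table(counts_table(cl))
  pt <- pooled_table(et)
  expect_setequal(pt$comparison,
                  c("TEL_C_vs_genome", "TEL_G_vs_genome", "CEN1_vs_genome",
                    "CEN2_vs_genome", "TEL_vs_SAT"))
  expect_true(all(pt$n == 6))
  expect_true(all(pt$test_used %in% c("t", "wilcoxon")))
  expect_identical(pt$stars, significance_stars(pt$p_value))
})

test_that("significance stars follow the conventional thresholds", {
  expect_identical(significance_stars(c(0.2, 0.04, 0.009, 0.0009, NA)),
                   c("", "*", "**", "***", NA))
})
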