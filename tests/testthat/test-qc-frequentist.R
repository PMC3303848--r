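test_that("Hardy-Weinberg chi-square matches hand computation", {
  exact <- hwe_test(49, 42, 9)       # allele freq 0.7/0.3, exact proportions
  expect_equal(exact$chi2, 0, tolerance = 1e-12)
  expect_equal(exact$p, 1)

  dev <- hwe_test(50, 0, 50)         # no heterozygotes at p = 0.5
  expect_lt(dev$p, 0.005)

  # hand oracle: p_hat = 0.5, expected 25/50/25 -> chi2 = 1 + 2 + 1 = 4
  h <- hwe_test(30, 40, 30)
  expect_equal(h$chi2, 4)
  expect_equal(h$p, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-10)

  expect_error(hwe_test(100, 0, 0), "monomorphic")
})

test_that("Hardy-Weinberg p is invariant to allele relabeling", {
  for (counts in list(c(30, 40, 30), c(50, 30, 20), c(80, 15, 5))) {
    a <- hwe_test(counts[1], counts[2], counts[3])
    b <- hwe_test(counts[3], counts[2], counts[1])
    expect_equal(a$p, b$p, tolerance = 1e-12)
  }
})

test_that("allele association test: chi-square, OR, Woolf CI, Haldane flag", {
  sym <- allele_association_test(10, 10, 10, 10)
  expect_equal(sym$or, 1)
  expect_equal(sym$chi2, 0)

  r <- allele_association_test(10, 90, 20, 80)   # cross product 10*80/(90*20)
  expect_equal(r$or, 4 / 9, tolerance = 1e-12)
  expect_false(r$haldane_corrected)

  z <- allele_association_test(0, 10, 10, 10)
  expect_true(z$haldane_corrected)
  expect_true(is.finite(z$or) && z$or > 0)

  expect_error(allele_association_test(0, 0, 5, 5), "margin")
})

test_that("OR inverts exactly under exposure swap", {
  set.seed(2)
  for (i in 1:20) {
    t <- sample(1:50, 4)
    a <- allele_association_test(t[1], t[2], t[3], t[4])
    b <- allele_association_test(t[2], t[1], t[4], t[3])
    expect_equal(a$or, 1 / b$or, tolerance = 1e-10)
  }
})

test_that("genotype tests expose the genetic model", {
  same <- genotype_association_test(rbind(c(30, 40, 30), c(30, 40, 30)))
  expect_equal(same$chi2[same$model == "overall"], 0)

  # recessive enrichment of the minor homozygote in cases
  rec <- genotype_association_test(rbind(c(30, 40, 60), c(45, 50, 20)))
  p_overall <- rec$p[rec$model == "overall"]
  p_recess <- rec$p[rec$model == "recessive"]
  expect_lt(p_recess, p_overall)

  expect_warning(
    col <- genotype_association_test(rbind(c(30, 40, 0), c(25, 45, 0))),
    "collapsed")
  expect_equal(col$df[col$model == "overall"], 1L)
})

test_that("QC filter removes monomorphic, HWE-in-controls and low-call SNPs", {
  set.seed(31)
  n <- 400
  controls <- c(rep(TRUE, 200), rep(FALSE, 200))
  hwe_geno <- function(n, p) sample(0:2, n, TRUE, c((1 - p)^2, 2 * p * (1 - p), p^2))
  df <- as.data.frame(setNames(
    lapply(1:10, function(i) hwe_geno(n, 0.3)), paste0("s", 1:10)))
  df$s1 <- rep(0L, n)                                   # monomorphic
  df$s2[controls] <- sample(c(0L, 2L), 200, TRUE)       # HWE violation in controls
  df$s3[sample(n, 44)] <- NA                            # call rate 0.89
  df$y <- as.integer(!controls)
  ds <- suppressMessages(bn_dataset(df, targets = "y"))
  res <- qc_filter(ds, controls)
  expect_equal(res$report$removed_monomorphic, "s1")
  expect_equal(res$report$removed_hwe, "s2")
  expect_equal(res$report$removed_callrate, "s3")
  expect_equal(length(res$report$retained), 7)

  # partition property and idempotence on the retained set
  all_snps <- paste0("s", 1:10)
  expect_setequal(c(res$report$removed_monomorphic, res$report$removed_hwe,
                    res$report$removed_callrate, res$report$retained),
                  all_snps)
  again <- qc_filter(res$dataset, controls)
  expect_equal(length(c(again$report$removed_monomorphic,
                        again$report$removed_hwe,
                        again$report$removed_callrate)), 0)

  # HWE violation in cases only is retained: the filter looks at controls
  df2 <- df[, c("s4", "s5", "y")]
  df2$s4[!controls] <- sample(c(0L, 2L), 200, TRUE)
  ds2 <- bn_dataset(df2, targets = "y")
  res2 <- qc_filter(ds2, controls)
  expect_true("s4" %in% res2$report$retained)
})

test_that("Bonferroni threshold and display", {
  b <- bonferroni_threshold(0.05, 102)
  expect_equal(b$threshold, 0.05 / 102)
  expect_equal(b$display, 5e-4)
  expect_equal(bonferroni_threshold(0.05, 1)$threshold, 0.05)
  expect_equal(bonferroni_threshold(0.05, 10)$threshold, 0.005)
  expect_error(bonferroni_threshold(0.05, 0))
})

test_that("haplotype OR from frequencies reconstructs the count table", {
  sym <- haplotype_or_from_frequencies(0.5, 0.5, 100, 100)
  expect_equal(sym$or, 1)
  # the count-based estimate differs in the last digit from a
  # conditional-logistic estimate on the same frequencies; both are reported
  tc <- haplotype_or_from_frequencies(0.251, 0.191, 872, 1530)
  expect_equal(round(tc$or, 2), 1.42)
  expect_error(haplotype_or_from_frequencies(0, 0.5, 100, 100), "between")
})

test_that("logistic interaction fit recovers parameters and flags separation", {
  set.seed(77)
  n <- 5000
  g1 <- sample(0:2, n, TRUE, c(.25, .5, .25))
  g2 <- sample(0:2, n, TRUE, c(.25, .5, .25))
  # null model: interaction CI covers 1
  y0 <- rbinom(n, 1, plogis(-0.5 + 0.3 * g1 + 0.2 * g2))
  f0 <- logistic_interaction_fit(data.frame(g1, g2, y = y0), "y",
                                 c("g1", "g2", "g1:g2"))
  row0 <- f0[f0$term == "g1:g2", ]
  expect_true(row0$ci_low <= 1 && 1 <= row0$ci_high)

  # interaction log-OR 0.5 recovered within 2 SE; the 2-SE event has ~95%
  # coverage per replicate, so require it in at least 4 of 5 replicates
  hits <- 0
  for (r in 1:5) {
    y1 <- rbinom(n, 1, plogis(-1 + 0.2 * g1 + 0.2 * g2 + 0.5 * g1 * g2))
    f1 <- logistic_interaction_fit(data.frame(g1, g2, y = y1), "y",
                                   c("g1", "g2", "g1:g2"))
    row1 <- f1[f1$term == "g1:g2", ]
    se <- (log(row1$ci_high) - log(row1$ci_low)) / (2 * qnorm(0.975))
    hits <- hits + (abs(row1$estimate - 0.5) < 2 * se)
  }
  expect_gte(hits, 4)

  # perfectly separable toy errors out
  sep <- data.frame(x = c(0, 0, 0, 1, 1, 1), y = c(0, 0, 0, 1, 1, 1))
  expect_error(logistic_interaction_fit(sep, "y", "x"), "separation|unstable")
})

test_that("per-SNP association report flags Bonferroni-significant SNPs", {
  set.seed(5)
  n <- 600
  g_null <- sample(0:2, n, TRUE, c(.49, .42, .09))
  g_eff <- sample(0:2, n, TRUE, c(.36, .48, .16))
  y <- rbinom(n, 1, plogis(-1 + 1.5 * g_eff))
  ds <- bn_dataset(data.frame(null_snp = g_null, eff_snp = g_eff, y = y),
                   targets = "y")
  rep <- association_report(ds, "y")
  expect_equal(nrow(rep), 2)
  expect_true(rep$bonferroni_significant[rep$snp == "eff_snp"])
  expect_true(all(rep$or > 0, na.rm = TRUE))
})
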