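test_that("case allele frequency round-trips the odds ratio", {
  expect_identical(case_allele_frequency(0.5, 1), 0.5)
  expect_equal(case_allele_frequency(0.5, 1.1), 0.55 / 1.05)
  # implied OR recovers the input to machine precision
  for (p2 in c(0.01, 0.185, 0.5, 0.9)) {
    for (or in c(0.5, 1.1, 1.48, 3)) {
      p1 <- case_allele_frequency(p2, or)
      expect_equal((p1 / (1 - p1)) / (p2 / (1 - p2)), or,
                   tolerance = 1e-12)
    }
  }
  expect_error(case_allele_frequency(0, 1.2), "inside")
  expect_error(case_allele_frequency(0.2, -1), "positive")
})

test_that("allele design derives counts under Hardy-Weinberg and folds major alleles", {
  d <- allele_design(2500, 4, 0.01, 1.5)
  expect_identical(d$n1, 5000)
  expect_identical(d$n2, 20000)
  expect_equal(d$p1, case_allele_frequency(0.01, 1.5))
  expect_warning(df <- allele_design(100, 1, 0.7, 1.2), "folding")
  expect_equal(df$p2, 0.3)
  expect_error(allele_design(-5, 1, 0.1, 1.2), "positive")
  expect_output(print(d), "alleles")
})

test_that("variance decomposition matches direct evaluation and the equal-group identity", {
  d <- allele_design(2500, 4, 0.01, 1.5)
  v <- variance_decomposition(d)
  # independent re-evaluation of the defining formulas
  p1 <- d$p1; p2 <- d$p2
  pbar <- (5000 * p1 + 20000 * p2) / 25000
  expect_equal(v$phi1, sqrt(p1 * (1 - p1) / 5000 + p2 * (1 - p2) / 20000),
               tolerance = 1e-14)
  expect_equal(v$phi0, sqrt(pbar * (1 - pbar) * (1 / 5000 + 1 / 20000)),
               tolerance = 1e-14)
  # null and alternative SDs coincide exactly at OR = 1
  v0 <- variance_decomposition(allele_design(2500, 4, 0.01, 1))
  expect_identical(v0$phi0, v0$phi1)
  # for equal groups the deviate collapses to the classical
  # sqrt(n)-scaled two-sample expression (algebraic identity)
  de <- allele_design(5000, 1, 0.2, 1.3, alpha = 5e-8)
  ve <- variance_decomposition(de)
  n <- de$n1
  z_classical <- (sqrt(n) * abs(de$p1 - de$p2) -
                    two_sided_crit_value(5e-8) * sqrt(n) * ve$phi0) /
    (sqrt(n) * ve$phi1)
  z_pkg <- qnorm(score_test_power(de))
  expect_equal(z_pkg, z_classical, tolerance = 1e-12)
})

test_that("score-test power hits the worked GWAS numbers", {
  # at the null every convention returns the one-tail alpha/2
  d0 <- allele_design(3000, 7, 0.12, 1, alpha = 1e-4)
  expect_near(score_test_power(d0), 0.5e-4, 1e-12)
  expect_near(wald_test_power(d0), 0.5e-4, 1e-12)
  expect_near(swapped_sd_power(d0), 0.5e-4, 1e-12)
  # the 80%-power OR for 10,000 cases at 1:1, common allele: about 1.13
  d <- allele_design(10000, 1, 0.5, 1.13)
  expect_gt(score_test_power(d), 0.70)
  expect_lt(score_test_power(d), 0.85)
  expect_equal(
    score_test_power(allele_design(10000, 1, 0.5,
                                   min_detectable_or(10000, 1, 0.5))),
    0.8, tolerance = 1e-8)
  # score and Wald differ once OR != 1, in the direction set by phi1 vs phi0
  v <- variance_decomposition(d)
  expect_true(wald_test_power(d) != score_test_power(d))
  expect_identical(wald_test_power(d) < score_test_power(d),
                   v$phi1 > v$phi0)
  # rare-allele design stays in (0,1) for cross-method comparison
  dr <- allele_design(10000, 1, 0.01, 1.74)
  for (p in c(score_test_power(dr), wald_test_power(dr),
              swapped_sd_power(dr))) {
    expect_true(p > 0 && p < 1)
  }
})

test_that("score power is monotone in every design lever", {
  base <- function(...) score_test_power(allele_design(...))
  pw_n <- vapply(c(2500, 5000, 10000, 40000), function(n)
    base(n, 4, 0.1, 1.2), numeric(1))
  expect_true(all(diff(pw_n) > 0))
  pw_j <- vapply(c(1, 2, 4, 10, 50), function(j)
    base(5000, j, 0.1, 1.2), numeric(1))
  expect_true(all(diff(pw_j) > 0))
  pw_or <- vapply(c(1.05, 1.1, 1.2, 1.4), function(or)
    base(5000, 4, 0.1, or), numeric(1))
  expect_true(all(diff(pw_or) > 0))
  # protective effects mirror through |log OR|
  pw_or_prot <- vapply(1 / c(1.05, 1.1, 1.2, 1.4), function(or)
    base(5000, 4, 0.1, or), numeric(1))
  expect_true(all(diff(pw_or_prot) > 0))
  pw_maf <- vapply(c(0.01, 0.05, 0.2, 0.5), function(m)
    base(5000, 4, m, 1.2), numeric(1))
  expect_true(all(diff(pw_maf) > 0))
  pw_a <- vapply(c(3e-12, 5e-8, 2.5e-6, 0.05), function(a)
    score_test_power(allele_design(5000, 4, 0.1, 1.2, alpha = a)),
    numeric(1))
  expect_true(all(diff(pw_a) > 0))
})

test_that("expected p-value reproduces the worked design examples", {
  ep <- function(n, j, or = 1.1) {
    expected_pvalue_gwas(allele_design(n, j, 0.5, or))$median_p
  }
  # doubling the controls at 5,000 and 10,000 cases
  expect_near(ep(5000, 1), 8e-4, 0.5e-4)
  expect_near(ep(5000, 2), 1e-4, 0.5e-4)
  expect_near(ep(10000, 1), 2e-6, 0.5e-6)
  expect_near(ep(10000, 2), 4e-8, 0.5e-8)
  # 4 -> 50 controls/case: the absolute values and the quoted fold
  # reductions (about 8-fold at 5,000 cases, about 60-fold at 10,000)
  expect_near(ep(5000, 4), 2e-5, 0.5e-5)
  expect_near(ep(10000, 4), 2e-9, 0.5e-9)
  expect_near(ep(10000, 50), 3e-11, 0.5e-11)
  expect_near(ep(5000, 4) / ep(5000, 50), 8, 1.5)
  expect_near(ep(10000, 4) / ep(10000, 50), 60, 10)
  # under-powered designs sit above alpha; the OR=1 boundary is p = 1
  expect_gt(ep(5000, 1), 5e-8)
  d_null <- allele_design(5000, 1, 0.5, 1)
  expect_identical(expected_pvalue_gwas(d_null)$median_p, 1)
  expect_false(is.na(expected_pvalue_gwas(d_null)$log10_median_p))
})

test_that("the p-value fold-gain from extra controls grows with the number of cases", {
  fold_1_to_2 <- vapply(c(5000, 10000, 30000), function(n) {
    l1 <- expected_pvalue_gwas(allele_design(n, 1, 0.5, 1.1))$log10_median_p
    l2 <- expected_pvalue_gwas(allele_design(n, 2, 0.5, 1.1))$log10_median_p
    l1 - l2
  }, numeric(1))
  # about 8-fold, 50-fold, 100,000-fold
  expect_true(all(diff(fold_1_to_2) > 0))
  expect_near(10^fold_1_to_2[1], 8, 8 * 0.2)
  expect_near(10^fold_1_to_2[2], 50, 50 * 0.2)
  expect_gt(10^fold_1_to_2[3], 1e4)
})

test_that("minimum detectable OR inverts the power model at its target", {
  # round-trip at assorted designs and all three conventions
  for (m in c("score", "wald", "swapped")) {
    for (cfg in list(c(10000, 1, 0.5), c(2500, 4, 0.01), c(80000, 50, 0.2))) {
      or <- min_detectable_or(cfg[1], cfg[2], cfg[3], method = m)
      d <- allele_design(cfg[1], cfg[2], cfg[3], or)
      pw <- switch(m, score = score_test_power(d),
                   wald = wald_test_power(d), swapped = swapped_sd_power(d))
      expect_equal(pw, 0.8, tolerance = 1e-8)
    }
  }
  # score-convention spot values at the common-allele column
  expect_near(min_detectable_or(10000, 1, 0.5), 1.13, 0.005)
  expect_near(min_detectable_or(10000, 50, 0.5), 1.094, 0.0005)
  expect_near(min_detectable_or(2500, 1, 0.01), 2.74, 0.005)
  # unattainable design errors out explicitly
  expect_error(min_detectable_or(3, 1, 0.01, alpha = 3e-12),
               "unattainable")
  expect_error(min_detectable_or(1000, 1, 0.2, target_power = 0.5,
                                 alpha = 0.6))
})

test_that("GWAS-model OR reductions converge to the ratio-only formula for small effects", {
  # local-alternatives consistency: the explicit model's fractional
  # reduction approaches 1 - sqrt((J+1)/2J) as the 1:1 OR shrinks to 1,
  # and is within 0.01 of it (fraction scale) whenever OR1 <= 1.1
  gaps <- sapply(c(80000, 160000, 320000), function(nc) {
    or1 <- min_detectable_or(nc, 1, 0.5)
    expect_lt(or1, 1.1)
    or50 <- min_detectable_or(nc, 50, 0.5)
    f <- (or1 - or50) / (or1 - 1)
    abs(f - or_reduction_fraction(50))
  })
  expect_true(all(gaps < 0.01))
  # error shrinks monotonically as OR1 -> 1 (cases grow)
  expect_true(all(diff(gaps) < 0))
})
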