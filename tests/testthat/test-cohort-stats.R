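# sample of size n with exactly the requested mean and SD
fixed_moments <- function(n, mean, sd, seed) {
  set.seed(seed)
  z <- rnorm(n)
  mean + sd * (z - mean(z)) / stats::sd(z)
}

test_that("headache-relief classification requires VAS drop > 2 plus QoL gain", {
  expect_true(classify_relief(7, 4, TRUE))
  expect_false(classify_relief(7, 5, TRUE))   # drop of exactly 2
  expect_false(classify_relief(8, 2, FALSE))  # no QoL improvement
  expect_equal(classify_relief(c(7, 7, 8), c(4, 5, 2), c(TRUE, TRUE, FALSE)),
               c(TRUE, FALSE, FALSE))
  expect_error(classify_relief(11, 4, TRUE), "VAS")
})

test_that("CCOS improvement spans totals 13-16 and rates match printed counts", {
  expect_true(ccos_improved(13))
  expect_false(ccos_improved(12))
  expect_true(ccos_improved(16))
  expect_error(ccos_improved(3), "CCOS")
  expect_error(ccos_improved(17), "CCOS")

  expect_equal(improvement_rate(c(rep(TRUE, 38), rep(FALSE, 3))), 92.7)
  expect_equal(improvement_rate(rep(FALSE, 10)), 0)
  expect_equal(improvement_rate(c(rep(TRUE, 4), rep(FALSE, 8))), 33.3)
  expect_error(improvement_rate(logical(0)), "no patients")
})

test_that("KS distance matches the analytic value and the reference oracle", {
  # exact normal quantiles at (i - 0.5)/n against the generating CDF
  for (n in c(10L, 25L, 80L)) {
    x <- qnorm((seq_len(n) - 0.5) / n)
    res <- ks_normality(x, mean = 0, sd = 1)
    expect_equal(res$statistic, 0.5 / n, tolerance = 1e-12)
    expect_true(res$statistic >= 0 && res$statistic <= 1)
  }
  # D agrees with stats::ks.test for a fixed reference
  set.seed(8)
  x <- rnorm(40, 2, 3)
  ours <- ks_normality(x, mean = 2, sd = 3)
  ref <- suppressWarnings(stats::ks.test(x, "pnorm", 2, 3))
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 0.02)

  # strongly bimodal sample is rejected
  set.seed(9)
  bim <- c(rnorm(25, -5, 0.5), rnorm(25, 5, 0.5))
  expect_lt(ks_normality(bim)$p_value, 0.05)

  expect_error(ks_normality(rep(1, 10)), "constant")
  expect_error(ks_normality(rnorm(3)), "at least 5")
})

test_that("summary-statistic t test reproduces the published stroke-volume table", {
  aqu <- t_test_summary(summary_stats(12, 65, 45), summary_stats(29, 32, 24),
                        variant = "welch")
  # frozen values from the closed-form Welch formula checked against
  # stats::t.test on moment-matched samples
  expect_equal(aqu$statistic, 2.4029, tolerance = 1e-4)
  expect_equal(aqu$df, 13.667, tolerance = 1e-4)
  expect_equal(aqu$p_value, 0.031083, tolerance = 1e-4)
  expect_true(aqu$significant)

  c2c3 <- t_test_summary(summary_stats(12, 485, 163),
                         summary_stats(29, 613, 166), variant = "welch")
  expect_equal(c2c3$p_value, 0.033500, tolerance = 1e-4)
  expect_true(c2c3$significant)

  # the three unstarred sites stay above 0.05 under the same variant
  tab <- published_summary_tests()
  expect_equal(tab$significant, c(TRUE, FALSE, FALSE, FALSE, TRUE))

  # degenerate equal groups
  eq <- t_test_summary(summary_stats(5, 10, 0), summary_stats(5, 10, 0))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
})

test_that("both t variants agree with the base-R oracle on raw samples", {
  x <- fixed_moments(12, 65, 45, seed = 21)
  y <- fixed_moments(29, 32, 24, seed = 22)
  for (variant in c("welch", "student")) {
    ours <- t_test_samples(x, y, variant = variant)
    ref <- stats::t.test(x, y, var.equal = (variant == "student"))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-8)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
  # raw-sample and summary-statistic forms agree exactly by construction
  summ <- t_test_summary(summary_stats(length(x), mean(x), sd(x)),
                         summary_stats(length(y), mean(y), sd(y)))
  expect_identical(t_test_samples(x, y)$p_value, summ$p_value)
  # identical samples
  same <- t_test_samples(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("exact Mann-Whitney matches exhaustive permutation enumeration", {
  expect_equal(mann_whitney(c(1, 2), c(3, 4))$statistic, 0)
  expect_equal(mann_whitney(c(1, 2), c(3, 4))$p_value, 1 / 3,
               tolerance = 1e-12)

  # spec'd exhaustive check at n1 = n2 = 3 plus random no-tie inputs with
  # n1 + n2 <= 10
  set.seed(14)
  configs <- list(c(3, 3), c(2, 4), c(4, 4), c(3, 5), c(2, 8), c(5, 5))
  for (cfg in configs) {
    for (rep_i in 1:6) {
      pool <- sample(seq_len(50), sum(cfg))  # distinct values: no ties
      x <- pool[seq_len(cfg[1])]
      y <- pool[-seq_len(cfg[1])]
      expect_equal(mann_whitney(x, y)$p_value, mw_enumerate_p(x, y),
                   tolerance = 1e-12,
                   label = paste("n =", cfg[1], "+", cfg[2]))
    }
  }
})

test_that("Mann-Whitney normal approximation handles ties like the base oracle", {
  set.seed(15)
  x <- round(rnorm(15, 5, 2)); y <- round(rnorm(18, 6, 2))  # forced ties
  ours <- mann_whitney(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = TRUE))
  expect_equal(ours$test, "mann_whitney_normal")
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)

  # extreme shift gives the minimal attainable two-sided exact p
  p_min <- 2 / choose(8, 4)
  expect_equal(mann_whitney(1:4, 101:104)$p_value, p_min, tolerance = 1e-12)
})

test_that("all two-sample tests are symmetric under group exchange", {
  x <- fixed_moments(10, 50, 12, seed = 31)
  y <- fixed_moments(14, 40, 15, seed = 32)
  for (variant in c("welch", "student")) {
    a <- t_test_samples(x, y, variant = variant)
    b <- t_test_samples(y, x, variant = variant)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
    expect_equal(a$statistic, -b$statistic, tolerance = 1e-12)
  }
  mwa <- mann_whitney(x, y); mwb <- mann_whitney(y, x)
  expect_equal(mwa$p_value, mwb$p_value, tolerance = 1e-12)
  expect_equal(mwa$statistic + mwb$statistic, length(x) * length(y))
})

test_that("cohort comparison applies the normality gate and flags sites", {
  d <- generate_cohort(cohort_spec(seed = 5L))
  cmp <- compare_cohort(d)
  expect_equal(nrow(cmp), 7L)
  expect_setequal(cmp$variable,
                  c(paste0("sv_", csf_sites()),
                    "evans_index", "aqueduct_area_mm2"))
  # morphometrics always use the rank test
  expect_true(all(grepl("mann_whitney",
                        cmp$test[cmp$variable %in%
                                 c("evans_index", "aqueduct_area_mm2")])))
  expect_equal(cmp$significant, cmp$p_value <= 0.05)
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))

  one <- d[c(which(d$group == "relieved")[1],
             which(d$group == "not_relieved")), ]
  expect_error(compare_cohort(one), "at least 2")
})

test_that("sites simulated with true group differences are starred more often", {
  # aqu and c2c3 carry real mean differences; ppc/fm/nevrax differences are
  # small relative to their SDs, so their rejection rate must be lower
  hits <- matrix(0L, 0, 5, dimnames = list(NULL, paste0("sv_", csf_sites())))
  for (s in 1:60) {
    d <- generate_cohort(cohort_spec(seed = 3000L + s))
    cmp <- compare_cohort(d)
    hits <- rbind(hits, cmp$significant[match(colnames(hits),
                                              cmp$variable)])
  }
  rate <- colMeans(hits)
  expect_gt(mean(rate[c("sv_aqu", "sv_c2c3")]),
            mean(rate[c("sv_ppc", "sv_fm", "sv_nevrax")]))
})

test_that("threshold exclusivity evaluates each rule's group counts", {
  tab <- data.frame(patient_id = c("a", "b"),
                    group = c("relieved", "not_relieved"),
                    sv_aqu = c(110, 15), sv_ppc = c(1, 1), sv_fm = c(1, 1),
                    sv_nevrax = c(1, 1), sv_c2c3 = c(500, 500))
  rep1 <- threshold_exclusivity(tab)
  expect_true(all(rep1$holds[rep1$variable == "sv_aqu"]))
  expect_equal(rep1$n_relieved[1], 1L)  # sv_aqu > 100

  tab2 <- tab; tab2$sv_aqu[2] <- 120  # non-relieved above the cut-off
  rep2 <- threshold_exclusivity(tab2)
  expect_false(rep2$holds[rep2$variable == "sv_aqu" &
                          rep2$direction == ">"])

  empty <- threshold_exclusivity(tab, rules = default_threshold_rules()[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("Holm adjustment is available but off by default", {
  d <- generate_cohort(cohort_spec(seed = 17L))
  raw <- compare_cohort(d)
  adj <- compare_cohort(d, holm = TRUE)
  expect_false("p_adjusted" %in% names(raw))
  sv_rows <- adj$variable %in% paste0("sv_", csf_sites())
  expect_true(all(adj$p_adjusted[sv_rows] >= adj$p_value[sv_rows]))
})
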