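# ROC / AUC, bootstrap comparison, contingency statistics and classical
# tests. pROC and fisher.test serve as independent cross-check oracles.

test_that("pair-counting AUC handles separation, ties and direction", {
  expect_equal(roc_auc(c(1, 2, 30, 40), c(TRUE, TRUE, FALSE, FALSE), "low"),
               1)
  # responders {1,3}, non-responders {3,5}: 3 concordant pairs + 1 tie
  expect_equal(roc_auc(c(1, 3, 3, 5), c(TRUE, TRUE, FALSE, FALSE), "low"),
               0.875)
  expect_error(roc_auc(1:4, rep(TRUE, 4)),
               class = "rad51score_single_class")
  # complementarity of the two directions on tie-free data
  s <- c(3, 9, 1, 7, 5, 8); lab <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  expect_equal(roc_auc(s, lab, "low") + roc_auc(s, lab, "high"), 1)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  for (s in 1:20) {
    x <- with_seed(s, rnorm(20))
    lab <- with_seed(100 + s, sample(c(rep(TRUE, 8), rep(FALSE, 12))))
    a <- roc_auc(x, lab, "low")
    expect_equal(roc_auc(exp(2 * x) + 1, lab, "low"), a)
    expect_equal(roc_auc(rank(x), lab, "low"), a)
  }
})

test_that("random labels give chance-level AUC", {
  x <- with_seed(5, rnorm(2000))
  lab <- with_seed(6, sample(rep(c(TRUE, FALSE), 1000)))
  expect_lt(abs(roc_auc(x, lab, "low") - 0.5), 0.05)
})

test_that("pair-counting AUC equals the trapezoidal ROC area", {
  for (s in 1:25) {
    n <- 20
    x <- with_seed(s, round(rnorm(n), 1))  # rounding forces ties
    lab <- with_seed(50 + s, sample(c(rep(TRUE, 7), rep(FALSE, n - 7))))
    trap <- as.numeric(pROC::auc(pROC::roc(lab, x, direction = ">",
                                           quiet = TRUE)))
    expect_equal(roc_auc(x, lab, "low"), trap)
  }
})

test_that("sensitivity and specificity use an inclusive cutoff", {
  s <- c(rep(2, 7), rep(50, 21)); lab <- rep(c(TRUE, FALSE), c(7, 21))
  expect_equal(unname(sens_spec_at_cutoff(s, lab, 10, "low")), c(100, 100))
  expect_equal(unname(sens_spec_at_cutoff(rep(c(20, 30), c(4, 4)),
                                          rep(c(TRUE, FALSE), c(4, 4)),
                                          10, "low")), c(0, 100))
  # a responder exactly at the cutoff counts test-positive
  expect_equal(unname(sens_spec_at_cutoff(c(10, 50), c(TRUE, FALSE),
                                          10, "low")), c(100, 100))
})

test_that("bootstrap AUC comparison is reproducible and null-correct", {
  x <- c(1, 2, 3, 20, 30, 40, 50, 60)
  lab <- rep(c(TRUE, FALSE), c(3, 5))
  same <- compare_auc_bootstrap(x, x, lab, directions = c("low", "low"),
                                n_boot = 200, seed = 7)
  expect_equal(same$difference, 0)
  expect_lte(same$ci_low, 0); expect_gte(same$ci_high, 0)
  expect_equal(same$p_value, 1)
  a <- compare_auc_bootstrap(x, rev(x), lab, n_boot = 300, seed = 42)
  b <- compare_auc_bootstrap(x, rev(x), lab, n_boot = 300, seed = 42)
  expect_identical(a, b)
  expect_error(compare_auc_bootstrap(x, x[-1], lab[-1]), "paired")
})

test_that("a discriminating score beats noise in the bootstrap test", {
  co <- simulate_cohort(cohort_spec(n_models = 28, seed = 3))
  noise <- with_seed(4, runif(28, 0, 100))
  cmp <- compare_auc_bootstrap(co$rad51_score, noise, co$responder,
                               directions = c("low", "low"),
                               n_boot = 2000, seed = 5)
  expect_equal(cmp$auc1, 1)
  expect_gt(cmp$difference, 0.2)
  expect_gt(cmp$ci_low, 0)
  expect_lt(cmp$p_value, 0.05)
})

test_that("Haldane-corrected odds ratio matches hand arithmetic", {
  r <- odds_ratio_2x2(c(11, 0, 3, 9))
  expect_equal(signif(r$or, 3), 62.4)
  expect_equal(odds_ratio_2x2(c(1, 1, 1, 1), "none")$or, 1)
  expect_equal(odds_ratio_2x2(c(2, 2, 4, 1))$or,
               (2.5 * 1.5) / (2.5 * 4.5))
  expect_error(odds_ratio_2x2(c(11, 0, 3, 9), "none"), "zero cell")
  # antisymmetry without correction
  expect_equal(odds_ratio_2x2(c(3, 5, 7, 2), "none")$or *
               odds_ratio_2x2(c(5, 3, 2, 7), "none")$or, 1)
})

test_that("Fisher exact p matches enumeration and the base oracle", {
  expect_equal(fisher_exact_p(c(11, 0, 3, 9)), 275 / 817190)
  expect_equal(fisher_exact_p(c(1, 1, 1, 1)), 1)
  expect_equal(fisher_exact_p(c(5, 0, 0, 5)), 2 / 252)
  for (s in 1:30) {
    tab <- with_seed(s, matrix(rpois(4, 4), 2))
    if (sum(tab) == 0 || sum(tab) > 30) next
    expect_equal(fisher_exact_p(tab),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-10)
  }
})

test_that("correlations recover linear and monotone relations", {
  x <- 1:10
  expect_equal(correlate(x, x)$r, 1)
  expect_equal(correlate(x, -2 * x + 5)$r, -1)
  mono <- correlate(x, x^3, "spearman")
  expect_equal(mono$r, 1)
  expect_lt(correlate(x, x^3, "pearson")$r, 1)
  expect_error(correlate(x, rep(1, 10)), "variance")
})

test_that("group comparisons produce the classical statistics", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3), "mann_whitney")
  expect_equal(same$p, 1)
  sep <- compare_groups(1:4, 11:24, "mann_whitney")
  expect_equal(unname(sep$statistic), 0)
  paired <- compare_groups(c(1, 2, 3), c(1, 2, 3), "t_paired")
  expect_equal(paired$statistic, 0)
  expect_equal(paired$p, 1)
  up <- compare_groups(rnorm(5), rnorm(5) + 100, "t_unpaired")
  expect_lt(up$p, 0.01)
  expect_error(compare_groups(1:3, 1:4, "t_paired"), "paired")
})

test_that("discrimination report joins ROC, cutoff and contingency blocks", {
  co <- data.frame(rad51_score = c(rep(2, 7), rep(50, 21)),
                   responder = rep(c(TRUE, FALSE), c(7, 21)))
  rep <- discriminate_report(co, cutoff = 10)
  expect_equal(rep$auc, 1)
  expect_equal(rep$sensitivity, 100)
  expect_equal(rep$specificity, 100)
  expect_equal(rep$table, c(7, 0, 0, 21))
  expect_error(discriminate_report(data.frame(rad51_score = 1:3,
                                              responder = rep(TRUE, 3))),
               class = "rad51score_single_class")
  # JSON round trip preserves every number
  js <- jsonlite::fromJSON(jsonlite::toJSON(unclass(rep), auto_unbox = TRUE,
                                            digits = NA))
  expect_equal(js$auc, rep$auc)
  expect_equal(js$odds_ratio, rep$odds_ratio)
  expect_equal(js$table, rep$table)
})
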