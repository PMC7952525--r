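test_that("ROC and Mann-Whitney AUC match pair enumeration", {
  scores <- c(3, 5, 1, 4)
  labels <- c(1, 1, 0, 0)
  roc <- roc_curve(scores, labels)
  expect_equal(roc$auc, 0.75)
  expect_equal(auc_mann_whitney(scores, labels), 0.75)
  expect_equal(brute_force_auc(scores, labels), 0.75)
  # perfectly separated
  expect_equal(roc_curve(c(1, 2, 8, 9), c(0, 0, 1, 1))$auc, 1.0)
  # all tied scores carry no information
  expect_equal(roc_curve(rep(2, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  expect_equal(auc_mann_whitney(c(2, 2), c(1, 0)), 0.5)
  # label swap mirrors the AUC
  expect_equal(auc_mann_whitney(scores, 1 - labels), 1 - 0.75)
  expect_error(roc_curve(c(1, 2), c(1, 1)), "degenerate")
})

test_that("trapezoidal and Mann-Whitney AUC are identical on tied data", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    scores <- sample(0:11, n, replace = TRUE)  # heavy ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    roc <- roc_curve(scores, labels)
    mw <- auc_mann_whitney(scores, labels)
    expect_equal(roc$auc, mw, tolerance = 1e-12)
    expect_equal(mw, brute_force_auc(scores, labels), tolerance = 1e-12)
    # sensitivity falls and specificity rises along the threshold sweep
    expect_true(all(diff(roc$points$sensitivity) <= 0))
    expect_true(all(diff(roc$points$specificity) >= 0))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(43)
  scores <- rnorm(80)
  labels <- rbinom(80, 1, 0.3)
  base <- roc_curve(scores, labels)
  for (f in list(function(x) 3 * x + 7, exp, function(x) x^3)) {
    tr <- roc_curve(f(scores), labels)
    expect_equal(tr$auc, base$auc, tolerance = 1e-12)
    expect_equal(tr$points$sensitivity, base$points$sensitivity)
    expect_equal(tr$points$specificity, base$points$specificity)
  }
})

test_that("AUC agrees with an established independent implementation", {
  set.seed(47)
  scores <- c(sample(0:11, 40, TRUE), rnorm(20, 6))
  labels <- rbinom(60, 1, 0.4)
  ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores, quiet = TRUE)))
  expect_equal(auc_mann_whitney(scores, labels), as.numeric(ref),
               tolerance = 1e-12)
})

test_that("Youden cut-off selection follows the tie-break rules", {
  cut <- youden_cutoff(roc_curve(c(3, 5, 1, 4), c(1, 1, 0, 0)))
  expect_equal(cut$threshold, 2.0)
  expect_equal(cut$J, 0.5)
  expect_equal(cut$sensitivity, 1.0)
  perf <- youden_cutoff(roc_curve(c(4, 4, 5, 5), c(0, 0, 1, 1)))
  expect_equal(perf$threshold, 4.5)
  expect_equal(perf$J, 1.0)
})

test_that("screening counts reproduce the published performance figures", {
  perf <- performance_from_counts(tp = 19, fp = 6, fn = 2, tn = 36)
  m <- perf$metrics
  est <- setNames(m$estimate, m$metric)
  expect_equal(round(est[["sensitivity"]], 2), 0.90)
  expect_equal(round(est[["specificity"]], 2), 0.86)
  expect_equal(round(est[["ppv"]], 2), 0.76)
  expect_equal(round(est[["npv"]], 2), 0.95)
  expect_equal(est[["sensitivity"]], 19 / 21, tolerance = 1e-12)
  ci <- m[m$metric == "sensitivity", ]
  expect_equal(round(c(ci$ci_low, ci$ci_high), 2), c(0.71, 0.97))
  ci <- m[m$metric == "specificity", ]
  expect_equal(round(c(ci$ci_low, ci$ci_high), 2), c(0.72, 0.93))
  # every interval contains its estimate
  ok <- m$ci_low <= m$estimate & m$estimate <= m$ci_high
  expect_true(all(ok))
})

test_that("degenerate 2x2 margins are flagged, not zeroed", {
  perfect <- performance_from_counts(21, 0, 0, 42)
  expect_true(all(perfect$metrics$estimate == 1))
  # cutoff below every score: everyone tests positive
  perf <- diagnostic_performance(c(5, 6, 7, 8), c(1, 1, 0, 0), cutoff = 0)
  est <- setNames(perf$metrics$estimate, perf$metrics$metric)
  expect_equal(est[["sensitivity"]], 1)
  expect_equal(est[["specificity"]], 0)
  expect_false(perf$metrics$defined[perf$metrics$metric == "npv"])
  expect_true(is.na(est[["npv"]]))
})

test_that("Wilson intervals stay in [0,1], cover the estimate and tighten with n", {
  set.seed(53)
  for (i in 1:50) {
    n <- sample(2:200, 1)
    k <- sample(0:n, 1)
    ci <- wilson_ci(k, n)
    expect_gte(ci[["low"]], 0)
    expect_lte(ci[["high"]], 1)
    expect_lte(ci[["low"]], k / n)
    expect_gte(ci[["high"]], k / n)
    wide <- wilson_ci(round(0.3 * n), n)
    narrow <- wilson_ci(round(0.3 * 4 * n), 4 * n)
    expect_lt(diff(narrow), diff(wide) + 1e-12)
  }
  # agreement with the score-test inversion in prop.test
  ref <- stats::prop.test(19, 21, correct = FALSE)$conf.int
  expect_equal(unname(wilson_ci(19, 21)), as.numeric(ref), tolerance = 1e-10)
})

test_that("Bayes-rule predictive values match hand arithmetic", {
  pv <- predictive_values_from_rates(0.90, 0.86, 21 / 63)
  expect_equal(round(pv$ppv, 3), 0.763)
  expect_equal(round(pv$npv, 3), 0.945)
  pv1 <- predictive_values_from_rates(1, 1, 0.37)
  expect_equal(c(pv1$ppv, pv1$npv), c(1, 1))
  pv2 <- predictive_values_from_rates(0.8, 0.9, 0.5)
  expect_equal(pv2$ppv, 0.888889, tolerance = 1e-6)
  expect_equal(pv2$npv, 0.818182, tolerance = 1e-6)
  deg <- predictive_values_from_rates(0, 1, 1)
  expect_false(deg$ppv_defined)
})

test_that("scheme comparison rows are consistent with the underlying analyses", {
  co <- generate_cohort(cohort_config(seed = 1))
  labels <- as.numeric(co$group == "IBT")
  tab <- compare_schemes(co, list(model5_scheme(), model5_scheme()))
  expect_equal(nrow(tab), 2)
  expect_equal(tab[1, -1], tab[2, -1], ignore_attr = TRUE)
  roc <- roc_curve(co$pda_score, labels)
  cut <- youden_cutoff(roc)
  perf <- diagnostic_performance(co$pda_score, labels, cut$threshold)
  expect_equal(tab$auc[1], roc$auc)
  expect_equal(tab$cutoff[1], cut$threshold)
  expect_equal(tab$sensitivity[1],
               perf$metrics$estimate[perf$metrics$metric == "sensitivity"])
  # calibrated synthetic cohort discriminates within the reported band
  expect_gte(tab$auc[1], 0.88)
  expect_lte(tab$auc[1], 0.99)
})
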