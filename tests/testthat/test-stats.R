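test_that("confusion metrics satisfy their identities on an exhaustive small grid", {
  for (TP in 0:3) for (FN in 0:3) for (TN in 0:3) for (FP in 0:3) {
    if (TP + FN + TN + FP == 0) next
    m <- confusion_metrics(TP, FN, TN, FP)
    if (TP + FN > 0) expect_equal(m$sensitivity, TP / (TP + FN)) else expect_true(is.na(m$sensitivity))
    if (TN + FP > 0) expect_equal(m$specificity, TN / (TN + FP)) else expect_true(is.na(m$specificity))
    expect_equal(m$accuracy, (TP + TN) / (TP + FN + TN + FP))
  }
  m10 <- confusion_metrics(10, 0, 10, 0)
  expect_equal(unlist(m10[c("sensitivity", "specificity", "accuracy", "ppv", "npv")]),
               c(sensitivity = 1, specificity = 1, accuracy = 1, ppv = 1, npv = 1))
  m0 <- confusion_metrics(0, 10, 0, 10)
  expect_equal(m0$sensitivity, 0); expect_equal(m0$specificity, 0)
})

test_that("Wilson interval behaves at boundaries and always contains k/n", {
  expect_equal(wilson_ci(0, 10)[["lower"]], 0, tolerance = 1e-12)
  expect_error(wilson_ci(1, 0), "positive")
  set.seed(8)
  for (rep in 1:50) {
    n <- sample(1:200, 1); k <- sample(0:n, 1)
    ci <- wilson_ci(k, n)
    expect_gte(k / n, ci[["lower"]] - 1e-12)
    expect_lte(k / n, ci[["upper"]] + 1e-12)
    expect_gte(ci[["lower"]], 0); expect_lte(ci[["upper"]], 1)
  }
})

test_that("prevalence-adjusted predictive values follow Bayes' rule", {
  r <- prevalence_ppv_npv(0.9, 0.9, 0.5)
  expect_equal(r$ppv, 0.9); expect_equal(r$npv, 0.9)
  expect_error(prevalence_ppv_npv(0.9, 0.9, 0), "strictly inside")
  expect_error(prevalence_ppv_npv(0.9, 0.9, 1), "strictly inside")
  # internal consistency: at the cohort's empirical prevalence the formulas
  # reproduce the empirical PPV/NPV from the confusion counts
  m <- confusion_metrics(31, 4, 33, 2)
  r2 <- prevalence_ppv_npv(m$sensitivity, m$specificity, 35 / 70)
  expect_equal(r2$ppv, m$ppv, tolerance = 1e-12)
  expect_equal(r2$npv, m$npv, tolerance = 1e-12)
})

test_that("Cohen's d from summaries: pooled SD and equal-mean null", {
  expect_equal(cohens_d(5, 1, 20, 5, 2, 20), 0)
  # equal-n reduces to sqrt((s1^2+s2^2)/2)
  d <- cohens_d(0, 1, 35, 1, 2, 35)
  expect_equal(d, 1 / sqrt((1 + 4) / 2))
  expect_true(is.na(cohens_d(0, 0, 10, 1, 0, 10)))
})

test_that("AUC equals pairwise concordance and AP matches its threshold walk", {
  expect_equal(discrimination_metrics(c(1, 2, 3, 10, 11, 12),
                                      c(0, 0, 0, 1, 1, 1))$auc, 1)
  expect_equal(discrimination_metrics(rep(0.5, 8),
                                      rep(c(0, 1), 4))$auc, 0.5)
  set.seed(31)
  for (rep in 1:30) {
    n <- sample(5:20, 1)
    sc <- round(runif(n), 1)          # ties on purpose
    lb <- rbinom(n, 1, 0.5)
    if (length(unique(lb)) < 2) next
    dm <- discrimination_metrics(sc, lb)
    expect_equal(dm$auc, oracle_auc(sc, lb), tolerance = 1e-12)
    expect_equal(dm$ap, oracle_ap(sc, lb), tolerance = 1e-12)
  }
  p <- discrimination_metrics(c(0.9, 0.8, 0.1), c(1, 1, 0))
  expect_equal(p$ap, 1)
  expect_error(discrimination_metrics(1:3, c(1, 1, 1)), "both classes")
  # independent library cross-check of the rank-statistic AUC
  set.seed(40)
  sc <- rnorm(30); lb <- rbinom(30, 1, 0.5)
  expect_equal(discrimination_metrics(sc, lb)$auc,
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-10)
})

test_that("calibration metrics: closed-form cases", {
  perfect <- calibration_metrics(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(perfect$brier, 0); expect_equal(perfect$ece, 0)
  half <- calibration_metrics(rep(0.5, 10), rep(c(0, 1), 5))
  expect_equal(half$brier, 0.25); expect_equal(half$ece, 0)
  off <- calibration_metrics(rep(0.9, 10), rep(0, 10))
  expect_equal(off$brier, 0.81); expect_equal(off$ece, 0.9)
  expect_error(calibration_metrics(numeric(0), numeric(0)), "empty")
})

test_that("BH step-up matches the brute-force cutoff scan", {
  p <- c(0.01, 0.02, 0.04, 0.8)
  expect_equal(sum(oracle_bh_reject(p, 0.05)), 2)
  expect_equal(sum(p.adjust(p, "BH") <= 0.05), 2)
  set.seed(17)
  for (rep in 1:50) {
    m <- sample(3:20, 1)
    pv <- runif(m)^sample(1:3, 1)
    got <- p.adjust(pv, "BH") <= 0.05
    expect_equal(got, oracle_bh_reject(pv, 0.05))
  }
})

test_that("group comparison gates on normality and adjusts within task families", {
  set.seed(5)
  base <- data.frame(subject_id = sprintf("S%02d", 1:24),
                     group = rep(c("control", "amblyopia"), each = 12))
  agg <- cbind(base, as.data.frame(matrix(NA_real_, 24, 15,
               dimnames = list(NULL, gazescreen:::gs_feature_names))))
  agg$t1_entropy <- c(rnorm(12, 2, 0.3), rnorm(12, 2.8, 0.3))
  agg$t1_regressions <- rep(c(1, 2, 3, 4), 6)  # identical group distributions
  agg$t3_pursuit_gain <- c(rnorm(12, 0.95, 0.04), rnorm(12, 0.8, 0.06))
  tab <- group_compare(agg, feature_cols = c("t1_entropy", "t1_regressions",
                                             "t3_pursuit_gain"))
  expect_lt(tab$p_adj[tab$feature == "t1_entropy"], 0.01)
  expect_equal(tab$p[tab$feature == "t1_regressions"], 1, tolerance = 1e-6)
  expect_equal(tab$effect[tab$feature == "t1_regressions"], 0, tolerance = 1e-9)
  expect_true(all(tab$effect_type %in% c("d", "rank-biserial")))
  # fully separated tiny groups: U = 9 and rank-biserial 1
  expect_equal(rank_biserial(9, 3, 3), 1)
  w <- wilcox.test(c(10, 11, 12), c(1, 2, 3), exact = FALSE)
  expect_equal(unname(w$statistic), 9)
})

test_that("subject-level bootstrap: degenerate and deterministic cases, rough coverage", {
  d <- data.frame(subject_id = sprintf("S%02d", 1:20),
                  label = rep(0:1, 10), value = rep(0.7, 20))
  ci <- bootstrap_ci(function(dd) mean(dd$value), d, B = 200, seed = 2)
  expect_equal(ci$lower, 0.7); expect_equal(ci$upper, 0.7)
  ci2 <- bootstrap_ci(function(dd) mean(dd$value), d, B = 200, seed = 2)
  expect_equal(ci, ci2)
  # approximate nominal coverage for a Bernoulli mean
  set.seed(77)
  hits <- 0; reps <- 60
  for (r in seq_len(reps)) {
    dd <- data.frame(subject_id = sprintf("S%03d", 1:60),
                     label = rep(0:1, 30), value = rbinom(60, 1, 0.4))
    ci <- bootstrap_ci(function(z) mean(z$value), dd, B = 200, seed = r)
    if (ci$lower <= 0.4 && 0.4 <= ci$upper) hits <- hits + 1
  }
  expect_gt(hits / reps, 0.85)
})

test_that("paired Wilcoxon with Pratt zeros and the order-effect table", {
  expect_equal(wilcoxon_pratt(rep(0, 10))$p, 1)
  shifted <- c(rep(0.01, 12), -0.002, 0.015, 0.008)
  expect_lt(wilcoxon_pratt(shifted)$p, 0.01)
  # early/late split: odd counts give the extra trial to the early half
  ft <- data.frame(subject_id = rep("S01", 5), group = "control",
                   task_id = 1L, trial_id = 1:5,
                   invalid_fraction = c(0.1, 0.1, 0.1, 0.3, 0.3),
                   retained = TRUE)
  oe <- order_effect_check(ft)
  expect_equal(oe$delta_mean_pct, (0.3 - 0.1) * 100)
  # identical halves for all subjects: delta 0, p 1
  ft2 <- ft; ft2$invalid_fraction <- 0.2
  oe2 <- order_effect_check(ft2)
  expect_equal(oe2$delta_mean_pct, 0)
  expect_equal(oe2$p, 1)
  # constructed uniform late shift across subjects: positive delta, small p
  ft3 <- do.call(rbind, lapply(1:12, function(i) {
    data.frame(subject_id = sprintf("S%02d", i), group = "control",
               task_id = 1L, trial_id = 1:6,
               invalid_fraction = c(0.05, 0.05, 0.05, 0.06, 0.06, 0.07) +
                 runif(6, 0, 0.002),
               retained = TRUE)
  }))
  oe3 <- order_effect_check(ft3)
  expect_gt(oe3$delta_mean_pct, 0)
  expect_lt(oe3$p, 0.01)
})
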