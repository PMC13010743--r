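test_that("isotonic calibration pools violators and clamps outside the range", {
  # violator pair pooled to the average
  g <- calibrate_isotonic(c(0.6, 0.7), c(1, 0))
  expect_equal(g(0.6), 0.5); expect_equal(g(0.7), 0.5)
  # order-preserving on separable data
  g2 <- calibrate_isotonic(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(g2(0.15), 0); expect_equal(g2(0.85), 1)
  # queries outside the fitted range clamp to boundary values
  expect_equal(g2(-1), g2(0.1))
  expect_equal(g2(2), g2(0.9))
  expect_warning(calibrate_isotonic(c(0.2, 0.4), c(1, 1)), "single-class")
})

test_that("isotonic fit matches a hand pool-adjacent-violators pass and stays monotone", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    raw <- runif(n)
    lab <- rbinom(n, 1, plogis(3 * (raw - 0.5)))
    if (length(unique(lab)) < 2) next
    g <- calibrate_isotonic(raw, lab)
    o <- order(raw)
    expect_equal(unname(g(sort(unique(raw)))),
                 unname(oracle_pava(lab[o])[!duplicated(sort(raw), fromLast = TRUE)]),
                 tolerance = 1e-9)
    q <- sort(runif(50))
    expect_true(all(diff(g(q)) >= -1e-12))
  }
})

test_that("median aggregation and the inclusive threshold rule", {
  expect_equal(aggregate_and_decide(c(0.2, 0.8, 0.9), 0.5)$p_subject, 0.8)
  a <- aggregate_and_decide(c(0.2, 0.4, 0.6, 0.8), 0.5)
  expect_equal(a$p_subject, 0.5)
  expect_equal(a$decision, 1L)       # p == tau decides positive
  expect_true(is.na(aggregate_and_decide(numeric(0), 0.5)$p_subject))
  # shuffling trial order never changes the aggregate
  set.seed(1); p <- runif(9)
  expect_equal(aggregate_and_decide(sample(p), 0.4),
               aggregate_and_decide(p, 0.4))
})

test_that("Youden threshold selection matches an exhaustive scan", {
  th <- select_threshold_youden(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(th$J, 1)
  expect_equal(th$tau, 0.5)          # midpoint rule
  same <- select_threshold_youden(rep(0.4, 6), c(0, 1, 0, 1, 0, 1))
  expect_equal(same$J, 0)
  expect_equal(same$tau, 0.4)
  expect_error(select_threshold_youden(c(0.1, 0.2), c(1, 1)), "both classes")
  set.seed(12)
  for (rep in 1:25) {
    n <- sample(6:20, 1)
    pr <- round(runif(n), 2)
    lb <- rbinom(n, 1, 0.5)
    if (length(unique(lb)) < 2) next
    got <- select_threshold_youden(pr, lb)
    want <- oracle_youden(pr, lb)
    expect_equal(got$J, want$J, tolerance = 1e-9)
    # the selected tau achieves the maximal J
    n1 <- sum(lb == 1); n0 <- sum(lb == 0)
    J_at <- sum(pr >= got$tau & lb == 1) / n1 + sum(pr < got$tau & lb == 0) / n0 - 1
    expect_equal(J_at, want$J, tolerance = 1e-9)
  }
})

test_that("the forest posterior is the average of tree-level posteriors", {
  ftab <- toy_feature_table(n_per_group = 4, k_trials = 8, seed = 5)
  X <- as.matrix(ftab[, paste0("f", 1:6)])
  y <- as.integer(ftab$group == "amblyopia")
  cfg <- model_config(num_trees = 25)
  mdl <- gazescreen:::gs_fit_learner(X, y, cfg, seed = 3)
  pr <- predict(mdl$fit, X[1:10, ], num.threads = 1)$predictions[, "1"]
  all_tree <- predict(mdl$fit, X[1:10, ], num.threads = 1,
                      predict.all = TRUE)$predictions
  expect_equal(pr, rowMeans(all_tree[, 2, ]), tolerance = 1e-10)
})

test_that("fold fitting is deterministic and leakage-free by construction", {
  ftab <- toy_feature_table(n_per_group = 5, k_trials = 6, seed = 2,
                            miss_frac = 0.05)
  cols <- paste0("f", 1:6)
  X <- as.matrix(ftab[, cols])
  y <- as.integer(ftab$group == "amblyopia")
  cfg <- model_config(num_trees = 50, inner_folds = 3)
  b1 <- fit_fold(X, y, ftab$subject_id, cfg, seed = 7)
  b2 <- fit_fold(X, y, ftab$subject_id, cfg, seed = 7)
  probe <- X[1:5, ]
  expect_equal(gazescreen:::gs_bundle_fingerprint(b1, probe),
               gazescreen:::gs_bundle_fingerprint(b2, probe))
  expect_true(all(diff(attr(b1$calibration, "knots_y")) >= -1e-12))
  expect_gte(b1$tau, 0); expect_lte(b1$tau, 1)
  # single-class training set rejected
  expect_error(fit_fold(X[y == 1, ], y[y == 1],
                        ftab$subject_id[y == 1], cfg, seed = 1),
               "two training subjects per class")
})

test_that("zero-variance features are excluded from scaling with a warning", {
  X <- cbind(a = rnorm(20), b = rep(3, 20))
  expect_warning(sc <- gazescreen:::gs_fit_scaler(X), "zero training variance")
  expect_equal(unname(sc$sd["b"]), 1)
  Xs <- gazescreen:::gs_apply_scaler(sc, X)
  expect_false(any(is.na(Xs)))
})

test_that("nested LOSO separates a separable toy cohort and is reproducible", {
  ftab <- toy_feature_table(n_per_group = 6, k_trials = 8, shift = 2, seed = 3)
  cfg <- model_config(num_trees = 60, inner_folds = 3)
  r1 <- nested_loso(ftab, cfg, seed = 4, feature_cols = paste0("f", 1:6))
  r2 <- nested_loso(ftab, cfg, seed = 4, feature_cols = paste0("f", 1:6))
  expect_equal(r1$scores, r2$scores)
  expect_gt(r1$auc, 0.9)
  expect_equal(nrow(r1$scores), 12)  # one outer fold per subject
})

test_that("corrupting held-out subjects never changes the fitted fold artifacts (toy)", {
  ftab <- toy_feature_table(n_per_group = 4, k_trials = 6, seed = 9)
  cfg <- model_config(num_trees = 40, inner_folds = 2)
  cols <- paste0("f", 1:6)
  a <- nested_loso(ftab, cfg, seed = 11, feature_cols = cols, fingerprints = TRUE)
  b <- nested_loso(ftab, cfg, seed = 11, feature_cols = cols,
                   corrupt_heldout = TRUE, fingerprints = TRUE)
  expect_equal(a$fingerprints, b$fingerprints)
  expect_equal(a$scores$p_subject, b$scores$p_subject)
})

test_that("permutation importance ranks informative features above pure noise", {
  # two signal-carrying features plus two pure-noise columns, weak enough
  # that permuting one signal feature visibly hurts the held-out AUC
  ftab <- toy_feature_table(n_per_group = 6, k_trials = 5, p = 2,
                            shift = 1.2, seed = 13)
  set.seed(99)
  ftab$n1 <- rnorm(nrow(ftab)); ftab$n2 <- rnorm(nrow(ftab))
  cols <- c("f1", "f2", "n1", "n2")
  cfg <- model_config(num_trees = 60, inner_folds = 2, calibrate = FALSE)
  imp <- permutation_importance(ftab, cfg, seed = 3, feature_cols = cols,
                                n_repeats = 3)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_lt(mean(imp$auc_drop[imp$feature %in% c("n1", "n2")]),
            mean(imp$auc_drop[imp$feature %in% c("f1", "f2")]))
  imp2 <- permutation_importance(ftab, cfg, seed = 3, feature_cols = cols,
                                 n_repeats = 3)
  expect_equal(imp, imp2)
})
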