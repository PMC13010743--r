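# Calibrated Random Forest screening model under the nested, strictly
# subject-wise protocol. All learned statistics (standardization, imputation,
# forest, isotonic calibration map, operating threshold) are estimated from
# training-subject rows only and applied unchanged to held-out subjects.

#' Default model configuration
#'
#' @param num_trees trees in the forest (default 300).
#' @param mtry per-node feature subsample; default `ceiling(sqrt(p))`.
#' @param min_node_size minimum terminal node size (default 5).
#' @param max_depth 0 means unlimited.
#' @param inner_folds grouped inner cross-validation folds (default 5).
#' @param grid optional data.frame of hyperparameter candidates with columns
#'   `max_depth`, `min_node_size`; default a single row (no tuning).
#' @param learner `"rf"`, `"logistic"`, `"svm"` or `"gbt"`.
#' @param calibrate fit the isotonic map and Youden threshold via the inner
#'   loop (TRUE for the primary protocol); FALSE gives a discrimination-only
#'   fold with raw probabilities.
#' @export
model_config <- function(num_trees = 300, mtry = NULL, min_node_size = 5,
                         max_depth = 0, inner_folds = 5, grid = NULL,
                         learner = "rf", calibrate = TRUE) {
  if (is.null(grid)) {
    grid <- data.frame(max_depth = max_depth, min_node_size = min_node_size)
  }
  list(num_trees = num_trees, mtry = mtry, min_node_size = min_node_size,
       max_depth = max_depth, inner_folds = inner_folds, grid = grid,
       learner = learner, calibrate = calibrate)
}

# ---- preprocessing learned on training rows ---------------------------------

gs_fit_scaler <- function(X) {
  med <- apply(X, 2, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  Ximp <- X
  for (j in seq_len(ncol(X))) Ximp[!is.finite(Ximp[, j]), j] <- med[j]
  mu <- colMeans(Ximp)
  sd <- apply(Ximp, 2, stats::sd)
  zero <- !is.finite(sd) | sd < 1e-12
  if (any(zero)) {
    warning("features with zero training variance excluded from scaling: ",
            paste(colnames(X)[zero], collapse = ", "))
    sd[zero] <- 1
  }
  list(median = med, mu = mu, sd = sd)
}

gs_apply_scaler <- function(sc, X) {
  for (j in seq_len(ncol(X))) X[!is.finite(X[, j]), j] <- sc$median[j]
  sweep(sweep(X, 2, sc$mu, "-"), 2, sc$sd, "/")
}

# ---- learners ---------------------------------------------------------------

gs_fit_learner <- function(X, y, config, seed) {
  tab <- table(factor(y, levels = c(0, 1)))
  w <- as.numeric(length(y) / (2 * tab[as.character(y)]))
  if (config$learner == "rf") {
    cw <- as.numeric(length(y) / (2 * tab))
    fit <- ranger::ranger(x = X, y = factor(y, levels = c(0, 1)),
                          num.trees = config$num_trees,
                          mtry = if (is.null(config$mtry)) ceiling(sqrt(ncol(X))) else config$mtry,
                          min.node.size = config$min_node_size,
                          max.depth = config$max_depth,
                          probability = TRUE, splitrule = "gini",
                          class.weights = cw, seed = seed, num.threads = 1)
    list(kind = "rf", fit = fit)
  } else if (config$learner == "logistic") {
    fit <- glmnet::glmnet(X, factor(y, levels = c(0, 1)), family = "binomial",
                          alpha = 0, lambda = 0.05, weights = w,
                          standardize = FALSE)
    list(kind = "logistic", fit = fit)
  } else if (config$learner == "svm") {
    set.seed(seed)
    cw <- as.numeric(length(y) / (2 * tab))
    fit <- e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "linear",
                      probability = TRUE,
                      class.weights = c("0" = cw[1], "1" = cw[2]),
                      cost = 1, scale = FALSE)
    list(kind = "svm", fit = fit)
  } else if (config$learner == "gbt") {
    dtr <- xgboost::xgb.DMatrix(X, label = y, weight = w)
    fit <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                            max_depth = 4, eta = 0.1,
                                            subsample = 0.8, nthread = 1,
                                            seed = seed),
                              data = dtr, nrounds = 100, verbose = 0)
    list(kind = "gbt", fit = fit)
  } else stop("unknown learner: ", config$learner)
}

gs_predict_learner <- function(model, X) {
  if (model$kind == "rf") {
    predict(model$fit, data = X, num.threads = 1)$predictions[, "1"]
  } else if (model$kind == "logistic") {
    as.numeric(stats::predict(model$fit, X, type = "response"))
  } else if (model$kind == "svm") {
    pr <- attr(stats::predict(model$fit, X, probability = TRUE), "probabilities")
    as.numeric(pr[, "1"])
  } else {
    as.numeric(stats::predict(model$fit, xgboost::xgb.DMatrix(X)))
  }
}

# ---- isotonic calibration ---------------------------------------------------

#' Fit an isotonic probability calibration map
#'
#' Non-decreasing least-squares step function (pool-adjacent-violators) from
#' raw probabilities to calibrated probabilities. Queries outside the fitted
#' range clamp to the boundary values.
#'
#' @param raw raw probabilities.
#' @param labels binary labels (0/1).
#' @return function mapping raw to calibrated probabilities; attributes carry
#'   the fitted knots.
#' @export
calibrate_isotonic <- function(raw, labels) {
  stopifnot(length(raw) == length(labels))
  if (length(unique(labels)) < 2) {
    warning("single-class calibration data; returning degenerate constant map")
    v <- mean(labels)
    f <- function(p) rep(v, length(p))
    attr(f, "knots_x") <- range(raw); attr(f, "knots_y") <- c(v, v)
    return(f)
  }
  o <- order(raw)
  iso <- stats::isoreg(raw[o], labels[o])
  kx <- iso$x; ky <- iso$yf
  u <- !duplicated(kx, fromLast = TRUE)   # last fitted value at each unique x
  kx <- kx[u]; ky <- ky[u]
  f <- function(p) {
    i <- findInterval(p, kx)              # step function: value at largest knot <= p
    out <- ifelse(i == 0, ky[1], ky[pmax(i, 1)])
    as.numeric(out)
  }
  attr(f, "knots_x") <- kx; attr(f, "knots_y") <- ky
  f
}

#' Median-aggregate trial probabilities and decide
#'
#' Subject-level probability is the median of the subject's valid trial
#' probabilities (even counts: mean of the middle pair); the decision is
#' positive iff the aggregated probability is at or above the threshold.
#'
#' @param trial_probs calibrated trial probabilities of one subject.
#' @param tau operating threshold.
#' @return list with `p_subject` and `decision` (0/1); missing if no valid
#'   trials.
#' @export
aggregate_and_decide <- function(trial_probs, tau) {
  trial_probs <- trial_probs[is.finite(trial_probs)]
  if (!length(trial_probs)) return(list(p_subject = NA_real_, decision = NA_integer_))
  p <- stats::median(trial_probs)
  list(p_subject = p, decision = as.integer(p >= tau))
}

#' Select the operating threshold by Youden's J
#'
#' Maximizes J = sensitivity + specificity - 1 over candidate thresholds
#' (midpoints between adjacent sorted unique probabilities plus the
#' boundaries), with decisions positive at `p >= tau`. Ties break to the
#' smallest maximizing threshold.
#'
#' @param probs subject-level probabilities.
#' @param labels binary labels (0/1).
#' @return list with `tau` and `J`.
#' @export
select_threshold_youden <- function(probs, labels) {
  if (length(unique(labels)) < 2) stop("both classes required for threshold selection")
  u <- sort(unique(probs))
  cand <- sort(unique(c(u, u[-length(u)] + diff(u) / 2, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  J <- vapply(cand, function(th) {
    sens <- sum(probs >= th & labels == 1) / n1
    spec <- sum(probs < th & labels == 0) / n0
    sens + spec - 1
  }, numeric(1))
  best <- which(J >= max(J) - 1e-12)[1]
  list(tau = cand[best], J = J[best])
}

# grouped, label-stratified fold assignment over subjects
gs_group_folds <- function(subjects, labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(subjects))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Fit one training fold (the full FoldBundle)
#'
#' Learns imputation medians and z-scoring statistics from the training trial
#' rows, fits the forest (or baseline learner) with inverse-frequency class
#' weights, and runs the grouped inner cross-validation over training subjects
#' to (i) select hyperparameters when a grid is given, (ii) fit the isotonic
#' calibration map on pooled inner out-of-fold trial predictions, and (iii)
#' select the Youden threshold on inner out-of-fold subject-level aggregated
#' calibrated probabilities.
#'
#' @param X trial-by-feature matrix of the training subjects.
#' @param y trial labels (0/1).
#' @param subjects subject id per trial row.
#' @param config a [model_config()].
#' @param seed fold seed.
#' @return list of class `fold_bundle`.
#' @export
fit_fold <- function(X, y, subjects, config = model_config(), seed = 1) {
  subj <- unique(subjects)
  ylab <- vapply(subj, function(s) y[match(s, subjects)], numeric(1))
  if (min(table(factor(ylab, levels = c(0, 1)))) < 2)
    stop("need at least two training subjects per class")
  inner <- NULL
  best_cfg <- config
  if (config$calibrate) {
    k <- min(config$inner_folds, length(subj))
    fold <- gs_group_folds(subj, ylab, k, seed = seed + 1)
    grid_stats <- vector("list", nrow(config$grid))
    for (gi in seq_len(nrow(config$grid))) {
      cfg_g <- config
      cfg_g$max_depth <- config$grid$max_depth[gi]
      cfg_g$min_node_size <- config$grid$min_node_size[gi]
      oof_raw <- rep(NA_real_, length(y))
      for (f in seq_len(k)) {
        tr_s <- subj[fold != f]
        tr <- subjects %in% tr_s
        if (length(unique(y[tr])) < 2) next
        sc <- gs_fit_scaler(X[tr, , drop = FALSE])
        Xtr <- gs_apply_scaler(sc, X[tr, , drop = FALSE])
        mdl <- gs_fit_learner(Xtr, y[tr], cfg_g, seed = seed + 100 + f)
        Xva <- gs_apply_scaler(sc, X[!tr, , drop = FALSE])
        oof_raw[!tr] <- gs_predict_learner(mdl, Xva)
      }
      ok <- is.finite(oof_raw)
      p_subj <- vapply(subj, function(s) {
        pr <- oof_raw[ok & subjects == s]
        if (!length(pr)) NA_real_ else stats::median(pr)
      }, numeric(1))
      auc <- tryCatch(discrimination_metrics(p_subj[is.finite(p_subj)],
                                             ylab[is.finite(p_subj)])$auc,
                      error = function(e) NA_real_)
      grid_stats[[gi]] <- list(oof_raw = oof_raw, auc = auc)
    }
    aucs <- vapply(grid_stats, function(g) g$auc, numeric(1))
    gi <- which.max(ifelse(is.finite(aucs), aucs, -Inf))
    best_cfg$max_depth <- config$grid$max_depth[gi]
    best_cfg$min_node_size <- config$grid$min_node_size[gi]
    oof_raw <- grid_stats[[gi]]$oof_raw
    ok <- is.finite(oof_raw)
    g_map <- calibrate_isotonic(oof_raw[ok], y[ok])
    p_subj <- vapply(subj, function(s) {
      pr <- g_map(oof_raw[ok & subjects == s])
      if (!length(pr)) NA_real_ else stats::median(pr)
    }, numeric(1))
    keep <- is.finite(p_subj)
    th <- select_threshold_youden(p_subj[keep], ylab[keep])
    inner <- list(oof_auc = aucs[gi], folds = fold)
  } else {
    g_map <- identity
    th <- list(tau = 0.5, J = NA_real_)
  }
  sc <- gs_fit_scaler(X)
  mdl <- gs_fit_learner(gs_apply_scaler(sc, X), y, best_cfg, seed = seed)
  structure(list(scaler = sc, model = mdl, calibration = g_map, tau = th$tau,
                 J = th$J, config = best_cfg, inner = inner),
            class = "fold_bundle")
}

#' Apply a fitted fold bundle to new trial rows
#' @param bundle a `fold_bundle`.
#' @param X trial-by-feature matrix.
#' @return list with `raw` and `calibrated` trial probabilities.
#' @export
predict_fold <- function(bundle, X) {
  Xs <- gs_apply_scaler(bundle$scaler, X)
  raw <- gs_predict_learner(bundle$model, Xs)
  list(raw = raw, calibrated = as.numeric(bundle$calibration(raw)))
}

# deterministic fingerprint of everything a fold learned (for the leakage
# tripwire): preprocessing statistics, threshold, calibration knots and the
# forest's predictions on a fixed probe grid
gs_bundle_fingerprint <- function(bundle, probe) {
  pr <- gs_predict_learner(bundle$model, gs_apply_scaler(bundle$scaler, probe))
  list(median = bundle$scaler$median, mu = bundle$scaler$mu, sd = bundle$scaler$sd,
       tau = bundle$tau,
       knots_x = attr(bundle$calibration, "knots_x"),
       knots_y = attr(bundle$calibration, "knots_y"),
       probe_pred = pr)
}

#' Nested leave-one-subject-out evaluation
#'
#' One outer fold per subject: the fold bundle (scaling, imputation, forest,
#' isotonic map, threshold) is fitted on the remaining subjects via
#' [fit_fold()] and applied unchanged to the held-out subject's trials.
#' Returns subject-level calibrated probabilities, decisions and summary
#' metrics.
#'
#' @param features trial feature table ([extract_features()] output or any
#'   data.frame with `subject_id`, `group`, `retained` and feature columns).
#' @param config a [model_config()].
#' @param seed master seed; per-fold seeds are derived deterministically.
#' @param feature_cols columns used as predictors (default the full gaze
#'   feature set).
#' @param corrupt_heldout if TRUE, the held-out subject's feature values are
#'   replaced by random noise before each fold is fitted (leakage tripwire:
#'   fitted artifacts must be identical).
#' @param fingerprints if TRUE, per-fold bundle fingerprints are returned.
#' @return list of class `loso_report`.
#' @export
nested_loso <- function(features, config = model_config(), seed = 1,
                        feature_cols = gs_feature_names,
                        corrupt_heldout = FALSE, fingerprints = FALSE) {
  dat <- features[features$retained, , drop = FALSE]
  X <- as.matrix(dat[, feature_cols, drop = FALSE])
  y <- as.integer(dat$group == "amblyopia")
  subjects <- as.character(dat$subject_id)
  subj <- unique(subjects)
  ylab <- vapply(subj, function(s) y[match(s, subjects)], numeric(1))
  if (min(table(ylab)) < 2) stop("need at least two subjects per class")
  probe <- matrix(rep(apply(X, 2, stats::median, na.rm = TRUE), each = 3), 3,
                  dimnames = list(NULL, colnames(X)))
  probe[2, ] <- probe[2, ] * 0.5; probe[3, ] <- probe[3, ] * 1.5
  res <- list(); fps <- list()
  for (i in seq_along(subj)) {
    s <- subj[i]
    fold_seed <- (seed * 1009L + i * 7919L) %% 2147483647L
    Xi <- X
    if (corrupt_heldout) {
      held <- subjects == s
      rng <- gs_with_seed(fold_seed + 5000L, stats::rnorm(sum(held) * ncol(X)))
      Xi[held, ] <- matrix(rng, sum(held), ncol(X))
    }
    tr <- subjects != s
    bundle <- fit_fold(Xi[tr, , drop = FALSE], y[tr], subjects[tr],
                       config, seed = fold_seed)
    pr <- predict_fold(bundle, X[subjects == s, , drop = FALSE])
    ad <- aggregate_and_decide(pr$calibrated, bundle$tau)
    res[[i]] <- data.frame(subject_id = s, label = ylab[i],
                           p_subject = ad$p_subject, decision = ad$decision,
                           tau = bundle$tau)
    if (fingerprints) fps[[s]] <- gs_bundle_fingerprint(bundle, probe)
  }
  scores <- do.call(rbind, res)
  out <- list(scores = scores, config = config, seed = seed)
  ok <- is.finite(scores$p_subject)
  disc <- discrimination_metrics(scores$p_subject[ok], scores$label[ok])
  cm <- table(factor(scores$decision[ok], levels = c(0, 1)),
              factor(scores$label[ok], levels = c(0, 1)))
  counts <- list(TP = cm["1", "1"], FN = cm["0", "1"],
                 TN = cm["0", "0"], FP = cm["1", "0"])
  out$auc <- disc$auc; out$ap <- disc$ap
  out$counts <- counts
  out$metrics <- confusion_metrics(counts$TP, counts$FN, counts$TN, counts$FP)
  cal <- calibration_metrics(scores$p_subject[ok], scores$label[ok])
  out$brier <- cal$brier; out$ece <- cal$ece
  if (fingerprints) out$fingerprints <- fps
  class(out) <- "loso_report"
  out
}

gs_with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed %% 2147483647L)
  expr
}

#' Permutation importance on held-out subject scores
#'
#' Mean decrease in subject-level AUC when one feature column is permuted at
#' the subject level (each subject's trials receive values drawn from another
#' subject's trials for that feature), repeated `n_repeats` times and
#' normalized to sum to one.
#'
#' @param features trial feature table.
#' @param config,seed,feature_cols as in [nested_loso()].
#' @param n_repeats permutation repeats per feature (default 5).
#' @return data.frame with feature, mean AUC drop and normalized importance.
#' @export
permutation_importance <- function(features, config = model_config(calibrate = FALSE),
                                   seed = 1, feature_cols = gs_feature_names,
                                   n_repeats = 5) {
  base <- nested_loso(features, config, seed, feature_cols)
  drops <- numeric(length(feature_cols))
  names(drops) <- feature_cols
  for (fi in seq_along(feature_cols)) {
    fn <- feature_cols[fi]
    aucs <- numeric(n_repeats)
    for (r in seq_len(n_repeats)) {
      perm <- features
      set.seed(seed * 131 + fi * 17 + r)
      subj <- unique(as.character(perm$subject_id))
      donor <- sample(subj)
      for (k in seq_along(subj)) {
        rows <- which(perm$subject_id == subj[k])
        pool <- features[[fn]][features$subject_id == donor[k]]
        pool <- pool[is.finite(pool)]
        perm[[fn]][rows] <- if (length(pool)) sample(pool, length(rows), replace = TRUE)
                            else NA_real_
      }
      aucs[r] <- nested_loso(perm, config, seed, feature_cols)$auc
    }
    drops[fi] <- base$auc - mean(aucs)
  }
  imp <- pmax(drops, 0)
  data.frame(feature = feature_cols, auc_drop = drops,
             importance = if (sum(imp) > 0) imp / sum(imp) else NA_real_)
}
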