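# Statistical reporting layer: operating-point metrics, Wilson intervals,
# prevalence-adjusted predictive values, effect sizes, group comparisons with
# BH-FDR control, discrimination and calibration metrics, subject-level
# bootstrap, order-effect checks.

#' Operating-point metrics from confusion counts
#'
#' @param TP,FN,TN,FP non-negative integer counts.
#' @return list with sensitivity, specificity, accuracy, PPV, NPV and the
#'   counts; metrics with an empty margin are NA.
#' @export
confusion_metrics <- function(TP, FN, TN, FP) {
  stopifnot(TP >= 0, FN >= 0, TN >= 0, FP >= 0)
  n <- TP + FN + TN + FP
  if (n == 0) stop("empty confusion table")
  sdiv <- function(a, b) if (b > 0) a / b else NA_real_
  list(sensitivity = sdiv(TP, TP + FN), specificity = sdiv(TN, TN + FP),
       accuracy = (TP + TN) / n, ppv = sdiv(TP, TP + FP),
       npv = sdiv(TN, TN + FN),
       counts = list(TP = TP, FN = FN, TN = TN, FP = FP))
}

#' Wilson score interval for a binomial proportion
#'
#' @param k successes, `0 <= k <= n`.
#' @param n trials, `n > 0`.
#' @param level confidence level (default 0.95).
#' @return numeric length-2 vector (lower, upper).
#' @export
wilson_ci <- function(k, n, level = 0.95) {
  if (n <= 0) stop("n must be positive")
  stopifnot(k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, center - half), upper = min(1, center + half))
}

#' Prevalence-adjusted predictive values
#'
#' Expected PPV and NPV at prevalence `pi` by Bayes' rule from an operating
#' point (sensitivity, specificity).
#'
#' @param sens,spec operating-point sensitivity and specificity in [0,1]
#'   (boundary values are legitimate measured operating points).
#' @param pi prevalence, strictly inside (0,1).
#' @return list with `ppv` and `npv`.
#' @export
prevalence_ppv_npv <- function(sens, spec, pi) {
  if (pi <= 0 || pi >= 1) stop("prevalence must be strictly inside (0,1)")
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1)
  ppv <- sens * pi / (sens * pi + (1 - spec) * (1 - pi))
  npv <- spec * (1 - pi) / (spec * (1 - pi) + (1 - sens) * pi)
  list(ppv = ppv, npv = npv)
}

#' Cohen's d from group summaries
#'
#' Pooled-SD standardized mean difference
#' `d = (m2 - m1) / sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#'
#' @param m1,s1,n1 mean, SD, n of group 1.
#' @param m2,s2,n2 mean, SD, n of group 2.
#' @return numeric d.
#' @export
cohens_d <- function(m1, s1, n1, m2, s2, n2) {
  if (s1 <= 0 && s2 <= 0) return(NA_real_)
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  if (sp <= 0) return(NA_real_)
  (m2 - m1) / sp
}

#' Rank-biserial correlation from a Mann-Whitney U statistic
#' @param U the Mann-Whitney U of group 2 over group 1.
#' @param n1,n2 group sizes.
#' @return r in [-1, 1]; `r = 2 U / (n1 n2) - 1`.
#' @export
rank_biserial <- function(U, n1, n2) 2 * U / (n1 * n2) - 1

#' Group comparison table with normality-gated tests and BH-FDR control
#'
#' For each feature: Shapiro-Wilk in both groups; if both p >= 0.05, a
#' two-sided t-test with Cohen's d, otherwise a Mann-Whitney U test with the
#' rank-biserial correlation. Benjamini-Hochberg adjustment is applied within
#' each task's feature family.
#'
#' @param aggregates subject-level feature table ([aggregate_subject()]).
#' @param feature_cols features to test (default the full set).
#' @param q FDR level (recorded; adjustment itself is level-free).
#' @return data.frame with one row per feature.
#' @export
group_compare <- function(aggregates, feature_cols = gs_feature_names, q = 0.05) {
  g1 <- aggregates$group == "control"
  g2 <- aggregates$group == "amblyopia"
  rows <- list()
  for (fn in feature_cols) {
    v1 <- aggregates[[fn]][g1]; v2 <- aggregates[[fn]][g2]
    v1 <- v1[is.finite(v1)]; v2 <- v2[is.finite(v2)]
    if (length(v1) < 3 || length(v2) < 3) next
    if (stats::sd(v1) == 0 && stats::sd(v2) == 0) {
      rows[[fn]] <- data.frame(feature = fn, task = substr(fn, 2, 2),
                               test = "skipped (constant feature)",
                               statistic = NA, p = NA, effect = NA,
                               effect_type = NA)
      next
    }
    sw1 <- tryCatch(stats::shapiro.test(v1)$p.value, error = function(e) 0)
    sw2 <- tryCatch(stats::shapiro.test(v2)$p.value, error = function(e) 0)
    if (sw1 >= 0.05 && sw2 >= 0.05) {
      tt <- stats::t.test(v2, v1, var.equal = TRUE)
      eff <- cohens_d(mean(v1), stats::sd(v1), length(v1),
                      mean(v2), stats::sd(v2), length(v2))
      rows[[fn]] <- data.frame(feature = fn, task = substr(fn, 2, 2),
                               test = "t", statistic = unname(tt$statistic),
                               p = tt$p.value, effect = eff, effect_type = "d")
    } else {
      wt <- stats::wilcox.test(v2, v1, exact = FALSE)
      U <- unname(wt$statistic)
      rows[[fn]] <- data.frame(feature = fn, task = substr(fn, 2, 2),
                               test = "mann-whitney",
                               statistic = U, p = wt$p.value,
                               effect = rank_biserial(U, length(v1), length(v2)),
                               effect_type = "rank-biserial")
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  for (tk in unique(out$task)) {
    sel <- out$task == tk & is.finite(out$p)
    out$p_adj[sel] <- stats::p.adjust(out$p[sel], method = "BH")
  }
  out$q <- q
  rownames(out) <- NULL
  out
}

#' Discrimination metrics: AUC and average precision
#'
#' AUC by the rank-sum statistic with midrank tie correction; AP as
#' precision-weighted recall increments over descending score thresholds.
#'
#' @param scores subject-level scores.
#' @param labels binary labels (0/1).
#' @return list with `auc` and `ap`.
#' @export
discrimination_metrics <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required")
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(1 - l)
  last <- !duplicated(grp, fromLast = TRUE)   # threshold at each distinct score
  tp <- tp[last]; fp <- fp[last]
  rec <- tp / n1; prec <- tp / (tp + fp)
  drec <- diff(c(0, rec))
  ap <- sum(prec * drec)
  list(auc = auc, ap = ap)
}

#' Calibration metrics: expected calibration error and Brier score
#'
#' @param probs probabilities in [0,1].
#' @param labels binary labels (0/1).
#' @param n_bins equal-width bins for the ECE (default 10).
#' @return list with `ece` and `brier`.
#' @export
calibration_metrics <- function(probs, labels, n_bins = 10) {
  if (!length(probs)) stop("empty input")
  stopifnot(all(probs >= 0 & probs <= 1))
  brier <- mean((probs - labels)^2)
  bin <- pmin(n_bins, floor(probs * n_bins) + 1L)
  ece <- 0
  for (b in unique(bin)) {
    idx <- bin == b
    ece <- ece + sum(idx) / length(probs) * abs(mean(labels[idx]) - mean(probs[idx]))
  }
  list(ece = ece, brier = brier)
}

#' Subject-level percentile bootstrap interval
#'
#' Resamples subjects (never trials) with replacement; resamples with a single
#' class are skipped and counted.
#'
#' @param metric_fn function(data subset) -> scalar.
#' @param data data.frame with a `subject_id` column (one or more rows per
#'   subject) and whatever `metric_fn` needs; must contain `label` if class
#'   degeneracy should be detected.
#' @param B bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param level confidence level.
#' @return list with `lower`, `upper`, `skipped`.
#' @export
bootstrap_ci <- function(metric_fn, data, B = 1000, seed = 1, level = 0.95) {
  set.seed(seed)
  subj <- unique(data$subject_id)
  vals <- numeric(0); skipped <- 0L
  for (b in seq_len(B)) {
    take <- sample(subj, length(subj), replace = TRUE)
    idx <- unlist(lapply(take, function(s) which(data$subject_id == s)))
    d <- data[idx, , drop = FALSE]
    if (!is.null(d$label) && length(unique(d$label)) < 2) {
      skipped <- skipped + 1L
      next
    }
    v <- tryCatch(metric_fn(d), error = function(e) NA_real_)
    if (is.finite(v)) vals <- c(vals, v) else skipped <- skipped + 1L
  }
  a <- (1 - level) / 2
  qs <- stats::quantile(vals, c(a, 1 - a), names = FALSE, type = 7)
  list(lower = qs[1], upper = qs[2], skipped = skipped)
}

#' Paired Wilcoxon signed-rank test with Pratt zero handling
#'
#' Zero differences are included in the joint ranking and then discarded from
#' the statistic (Pratt). Normal approximation with tie and zero corrections;
#' all-zero differences give p = 1.
#'
#' @param d vector of paired differences.
#' @return list with `statistic` (W+, sum of positive ranks), `p` (two-sided).
#' @export
wilcoxon_pratt <- function(d) {
  d <- d[is.finite(d)]
  n <- length(d)
  if (n == 0 || all(d == 0)) return(list(statistic = 0, p = 1))
  r <- rank(abs(d))
  nz <- d != 0
  Wp <- sum(r[d > 0])
  m <- sum(nz)
  r0 <- r[!nz]
  mu <- (n * (n + 1) / 2 - sum(r0)) / 2
  ties <- table(r[nz])
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(r0^2) / 4 - sum(ties^3 - ties) / 48
  if (sig2 <= 0) return(list(statistic = Wp, p = 1))
  z <- (Wp - mu) / sqrt(sig2)
  list(statistic = Wp, p = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Order-effect check on per-trial invalid fractions
#'
#' Splits each subject's retained trials within a task into early and late
#' halves (odd counts: the early half receives the extra trial), computes the
#' per-subject late-minus-early mean invalid percentage, and tests it within
#' each group by the paired Wilcoxon signed-rank test (Pratt zeros).
#'
#' @param features trial feature table with `invalid_fraction`, `retained`.
#' @return data.frame per (task, group): mean and SD of the per-subject delta
#'   (percentage points) and the Wilcoxon p-value.
#' @export
order_effect_check <- function(features) {
  out <- list()
  for (tk in sort(unique(features$task_id))) {
    for (gr in unique(features$group)) {
      rows <- features[features$task_id == tk & features$group == gr &
                         features$retained, ]
      deltas <- c()
      for (s in unique(rows$subject_id)) {
        v <- rows$invalid_fraction[rows$subject_id == s][order(rows$trial_id[rows$subject_id == s])]
        if (length(v) < 2) next
        cut <- ceiling(length(v) / 2)
        deltas <- c(deltas, mean(v[-seq_len(cut)]) - mean(v[seq_len(cut)]))
      }
      if (!length(deltas)) next
      wt <- wilcoxon_pratt(deltas)
      out[[paste(tk, gr)]] <- data.frame(task_id = tk, group = gr,
                                         n_subjects = length(deltas),
                                         delta_mean_pct = mean(deltas) * 100,
                                         delta_sd_pct = stats::sd(deltas) * 100,
                                         p = wt$p)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
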