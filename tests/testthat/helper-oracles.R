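# Independent reference implementations used as oracles.

# Exhaustive-window I-DT: dispersion of every window from an explicit
# cummax/cummin table, greedy leftmost-longest selection.
oracle_idt <- function(t, x, y, thr = 1.0, min_dur = 0.1) {
  n <- length(x)
  dt <- if (n > 1) stats::median(diff(t)) else 1 / 30
  min_n <- max(1L, ceiling(min_dur / dt))
  ok <- is.finite(x) & is.finite(y)
  out <- NULL
  i <- 1L
  while (i <= n - min_n + 1L) {
    if (!ok[i]) { i <- i + 1L; next }
    run_end <- i
    while (run_end < n && ok[run_end + 1L]) run_end <- run_end + 1L
    xs <- x[i:run_end]; ys <- y[i:run_end]
    disp <- (cummax(xs) - cummin(xs)) + (cummax(ys) - cummin(ys))
    jmax <- i + max(which(disp <= thr)) - 1L   # window [i, jmax] is maximal
    if (!any(disp <= thr)) jmax <- i - 1L
    if (jmax - i + 1L >= min_n) {
      out <- rbind(out, c(start = i, end = jmax,
                          cx = mean(x[i:jmax]), cy = mean(y[i:jmax])))
      i <- jmax + 1L
    } else i <- i + 1L
  }
  if (is.null(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      cx = numeric(0), cy = numeric(0)))
  }
  as.data.frame(out)
}

# AUC as the pairwise concordance statistic.
oracle_auc <- function(scores, labels) {
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) for (b in s0) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

# Benjamini-Hochberg rejections by a brute-force scan over all cutoffs.
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  ps <- sort(p)
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  if (k == 0) return(logical(m))
  p <= ps[k]
}

# Youden threshold by a dense grid scan (positive decision at p >= tau).
oracle_youden <- function(probs, labels) {
  cand <- sort(unique(c(0, 1, probs, probs - 1e-9, probs + 1e-9,
                        seq(0, 1, by = 0.001))))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  J <- vapply(cand, function(th) {
    sum(probs >= th & labels == 1) / n1 + sum(probs < th & labels == 0) / n0 - 1
  }, numeric(1))
  list(J = max(J), tau = cand[which.max(J)])
}

# Pool-adjacent-violators on (x sorted, y), explicit pooling loop.
oracle_pava <- function(y, w = rep(1, length(y))) {
  vals <- as.list(y); wts <- as.list(w)
  i <- 1L
  while (i < length(vals)) {
    if (mean_of(vals[[i]], wts[[i]]) > mean_of(vals[[i + 1]], wts[[i + 1]]) + 1e-12) {
      vals[[i]] <- c(vals[[i]], vals[[i + 1]])
      wts[[i]] <- c(wts[[i]], wts[[i + 1]])
      vals[[i + 1]] <- NULL; wts[[i + 1]] <- NULL
      if (i > 1L) i <- i - 1L
    } else i <- i + 1L
  }
  unlist(mapply(function(v, w) rep(mean_of(v, w), length(v)),
                vals, wts, SIMPLIFY = FALSE))
}
mean_of <- function(v, w) sum(v * w) / sum(w)

# Shoelace polygon area for an explicitly ordered vertex list.
oracle_shoelace <- function(px, py) {
  n <- length(px)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + px[i] * py[j] - px[j] * py[i]
  }
  abs(s) / 2
}

# Average precision as the area under a step-wise precision-recall walk,
# enumerated threshold by threshold.
oracle_ap <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(labels == 1)
  ap <- 0; prev_rec <- 0
  for (th in ths) {
    sel <- scores >= th
    tp <- sum(labels[sel] == 1)
    rec <- tp / n1; prec <- tp / sum(sel)
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}
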