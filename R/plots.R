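# Static evaluation figures (ROC, precision-recall, reliability diagram,
# per-group probability strip) written as PNG files.

#' Write evaluation figures for a LOSO report
#'
#' @param report a `loso_report` from [nested_loso()].
#' @param dir output directory for `roc.png`, `pr.png`, `reliability.png`,
#'   `probability_strip.png`.
#' @param n_bins reliability-diagram bins.
#' @return the directory, invisibly.
#' @export
plot_evaluation <- function(report, dir, n_bins = 10) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sc <- report$scores[is.finite(report$scores$p_subject), ]
  p <- sc$p_subject; y <- sc$label
  ths <- sort(unique(c(-Inf, p, Inf)), decreasing = TRUE)
  sens <- vapply(ths, function(t) mean(p[y == 1] >= t), numeric(1))
  fpr <- vapply(ths, function(t) mean(p[y == 0] >= t), numeric(1))
  grDevices::png(file.path(dir, "roc.png"), 600, 600)
  plot(fpr, sens, type = "s", xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("ROC (AUC = %.3f)", report$auc))
  abline(0, 1, lty = 2)
  grDevices::dev.off()

  prec <- vapply(ths, function(t) {
    sel <- p >= t
    if (!any(sel)) return(NA_real_)
    mean(y[sel] == 1)
  }, numeric(1))
  grDevices::png(file.path(dir, "pr.png"), 600, 600)
  plot(sens, prec, type = "s", xlab = "recall", ylab = "precision",
       ylim = c(0, 1), main = sprintf("Precision-recall (AP = %.3f)", report$ap))
  abline(h = mean(y), lty = 2)
  grDevices::dev.off()

  bin <- pmin(n_bins, floor(p * n_bins) + 1L)
  conf <- tapply(p, bin, mean); acc <- tapply(y, bin, mean)
  grDevices::png(file.path(dir, "reliability.png"), 600, 600)
  plot(conf, acc, xlim = c(0, 1), ylim = c(0, 1), pch = 19,
       xlab = "mean predicted probability", ylab = "observed fraction",
       main = sprintf("Reliability (ECE = %.3f, Brier = %.3f)",
                      report$ece, report$brier))
  abline(0, 1, lty = 2)
  grDevices::dev.off()

  grDevices::png(file.path(dir, "probability_strip.png"), 600, 600)
  set.seed(1)
  plot(jitter(y, amount = 0.08), p, pch = 19,
       col = ifelse(y == 1, "#d95f02", "#1b9e77"), xaxt = "n",
       xlab = "", ylab = "aggregated calibrated probability",
       main = "Subject probabilities by group")
  axis(1, at = c(0, 1), labels = c("control", "amblyopia"))
  abline(h = stats::median(sc$tau), lty = 2)
  grDevices::dev.off()
  invisible(dir)
}
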