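#!/usr/bin/env Rscript
# Step 5: prevalence-adjusted decision analytics.
#
# The balanced case-control design fixes prevalence at 50%; community
# screening operates at far lower prevalence, so PPV/NPV are re-expressed by
# Bayes' rule across plausible prevalence values using the measured operating
# point from step 4 (falling back to the published one if step 4 has not been
# run).

library(gazescreen)

perf_file <- "results/performance.csv"
if (file.exists(perf_file)) {
  perf <- read.csv(perf_file)
  sens <- perf$estimate[perf$metric == "sensitivity"]
  spec <- perf$estimate[perf$metric == "specificity"]
  message(sprintf("Using measured operating point: sens %.3f spec %.3f",
                  sens, spec))
} else {
  sens <- 0.886; spec <- 0.943
  message("results/performance.csv not found; using the reference operating point")
}

prevs <- c(0.02, 0.05, 0.10, 0.20)
tab <- do.call(rbind, lapply(prevs, function(p) {
  r <- prevalence_ppv_npv(sens, spec, p)
  data.frame(prevalence = p, expected_ppv = r$ppv, expected_npv = r$npv)
}))
print(tab, row.names = FALSE, digits = 3)
dir.create("results", showWarnings = FALSE)
write.csv(tab, "results/prevalence_table.csv", row.names = FALSE)
message("High NPV at low prevalence: the screen is best suited to ruling out",
        " amblyopia and triaging referrals.")
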