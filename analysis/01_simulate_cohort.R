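#!/usr/bin/env Rscript
# Step 1: generate the synthetic study cohort.
#
# 35 children per group (visually normal controls vs unilateral amblyopia),
# binocular gaze at 30 Hz for the three tasks (8 search trials, 72 grating
# trials, 6 pursuit trials), cohort-style clinical covariates, and injected
# blink / glitch / off-screen artifacts. Fully deterministic given the seed.

library(gazescreen)

seed <- as.integer(Sys.getenv("GS_SEED", "1"))
out_dir <- "results/cohort"

spec <- cohort_spec(n_per_group = 35, seed = seed)
cohort <- simulate_cohort(spec)
write_cohort(cohort, out_dir)

message("Subjects: ", nrow(cohort$clinical), " (",
        sum(cohort$clinical$group == "control"), " control / ",
        sum(cohort$clinical$group == "amblyopia"), " amblyopia)")
message("Gaze samples: ", nrow(cohort$gaze))
message("Formal trials: ", nrow(cohort$schedule))

cl <- cohort$clinical
summ <- do.call(rbind, lapply(split(cl, cl$group), function(d) {
  data.frame(group = d$group[1], n = nrow(d),
             age = sprintf("%.1f +- %.1f", mean(d$age), sd(d$age)),
             bcva_worse = sprintf("%.2f +- %.2f", mean(d$bcva_amblyopic),
                                  sd(d$bcva_amblyopic)),
             iod = sprintf("%.2f +- %.2f", mean(d$iod), sd(d$iod)),
             stereo_median = median(d$stereo_arcsec))
}))
print(summ, row.names = FALSE)
dir.create("results", showWarnings = FALSE)
write.csv(summ, "results/clinical_summary.csv", row.names = FALSE)
message("Cohort written to ", out_dir)
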