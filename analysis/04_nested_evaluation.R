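#!/usr/bin/env Rscript
# Step 4: calibrated Random Forest under nested leave-one-subject-out.
#
# One outer fold per subject; inside each training set a grouped 5-fold inner
# CV provides the out-of-fold trial probabilities on which the isotonic
# calibration map is fitted and the subject-level Youden threshold selected.
# All learned artifacts transfer unchanged to the held-out subject. Reports
# discrimination (AUC, AP with subject-level bootstrap CIs), the operating
# point with Wilson intervals, and calibration (Brier, ECE).

library(gazescreen)

seed <- as.integer(Sys.getenv("GS_SEED", "1"))
cohort <- simulate_cohort(cohort_spec(n_per_group = 35, seed = seed))
features <- extract_features(cohort)

report <- nested_loso(features, model_config(), seed = seed)

cm <- report$counts
sens_ci <- wilson_ci(cm$TP, cm$TP + cm$FN)
spec_ci <- wilson_ci(cm$TN, cm$TN + cm$FP)
auc_ci <- bootstrap_ci(function(d) discrimination_metrics(d$p, d$label)$auc,
                       data.frame(subject_id = report$scores$subject_id,
                                  label = report$scores$label,
                                  p = report$scores$p_subject),
                       B = 1000, seed = seed)

message(sprintf("AUC %.3f [%.2f-%.2f], AP %.3f", report$auc,
                auc_ci$lower, auc_ci$upper, report$ap))
message(sprintf("TP %d FN %d TN %d FP %d", cm$TP, cm$FN, cm$TN, cm$FP))
message(sprintf("Sensitivity %.3f [%.2f-%.2f]  Specificity %.3f [%.2f-%.2f]",
                report$metrics$sensitivity, sens_ci[1], sens_ci[2],
                report$metrics$specificity, spec_ci[1], spec_ci[2]))
message(sprintf("Accuracy %.3f  PPV %.3f  NPV %.3f  Brier %.3f  ECE %.3f",
                report$metrics$accuracy, report$metrics$ppv,
                report$metrics$npv, report$brier, report$ece))

dir.create("results", showWarnings = FALSE)
write.csv(report$scores, "results/subject_scores.csv", row.names = FALSE)
perf <- data.frame(
  metric = c("AUC", "AP", "sensitivity", "specificity", "accuracy",
             "PPV", "NPV", "brier", "ECE"),
  estimate = c(report$auc, report$ap, report$metrics$sensitivity,
               report$metrics$specificity, report$metrics$accuracy,
               report$metrics$ppv, report$metrics$npv, report$brier,
               report$ece),
  ci_lower = c(auc_ci$lower, NA, sens_ci[1], spec_ci[1], rep(NA, 5)),
  ci_upper = c(auc_ci$upper, NA, sens_ci[2], spec_ci[2], rep(NA, 5)))
write.csv(perf, "results/performance.csv", row.names = FALSE)

plot_evaluation(report, "results/figures")
message("Figures written to results/figures/")

# optional secondary experiments (slow): GS_EXPERIMENTS=1 enables them
if (Sys.getenv("GS_EXPERIMENTS") == "1") {
  cfg <- model_config(calibrate = FALSE)
  ab <- run_experiment("task_ablation", features = features, config = cfg,
                       seed = seed)
  write.csv(ab, "results/task_ablation.csv", row.names = FALSE)
  streams <- list(
    cyclopean = features,
    amblyopic_eye = extract_features(cohort, stream_kind = "amblyopic_eye"),
    fellow_eye = extract_features(cohort, stream_kind = "fellow_eye"),
    both_valid_only = extract_features(cohort, stream_kind = "both_valid_only"))
  gs <- run_experiment("gaze_stream", streams = streams, config = cfg,
                       seed = seed)
  write.csv(gs, "results/gaze_stream.csv", row.names = FALSE)
  print(ab, row.names = FALSE); print(gs, row.names = FALSE)
}
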