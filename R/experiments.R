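# Secondary experiments run under the identical nested subject-wise protocol:
# baseline learners, task ablations, gaze-stream sensitivity, learning curve,
# clinical-only and clinical+gaze models, preprocessing robustness grid.

gs_task_cols <- function(tasks) {
  unlist(lapply(tasks, function(tk) grep(paste0("^t", tk, "_"), gs_feature_names,
                                         value = TRUE)))
}

#' Clinical feature table
#'
#' Subject-level clinical vectors: BCVA per eye (logMAR), interocular acuity
#' difference, log-transformed stereoacuity, spherical equivalent per eye and
#' anisometropia.
#'
#' @param clinical the cohort's clinical table.
#' @return data.frame shaped like a one-trial-per-subject feature table.
#' @export
clinical_features <- function(clinical) {
  data.frame(subject_id = clinical$subject_id, group = clinical$group,
             task_id = 0L, trial_id = 1L, retained = TRUE,
             cl_bcva_amb = clinical$bcva_amblyopic,
             cl_bcva_fel = clinical$bcva_fellow,
             cl_iod = clinical$iod,
             cl_log_stereo = log10(clinical$stereo_arcsec),
             cl_se_worse = clinical$se_worse,
             cl_se_better = clinical$se_better,
             cl_aniso = abs(clinical$se_worse - clinical$se_better))
}

gs_clinical_cols <- c("cl_bcva_amb", "cl_bcva_fel", "cl_iod", "cl_log_stereo",
                      "cl_se_worse", "cl_se_better", "cl_aniso")

#' Run a named evaluation experiment
#'
#' All modes reuse the nested leave-one-subject-out machinery with one
#' substitution each:
#' \describe{
#'   \item{baselines}{L2 logistic regression, linear SVM and gradient-boosted
#'     trees on the identical gaze feature set.}
#'   \item{task_ablation}{the 7 task subsets T1, T2, T3, T1+T2, T2+T3, T1+T3,
#'     all.}
#'   \item{gaze_stream}{one run per supplied per-stream feature table.}
#'   \item{learning_curve}{nested training subsets of increasing size under a
#'     fixed subject order.}
#'   \item{clinical_only}{regularized logistic regression on subject-level
#'     clinical vectors.}
#'   \item{clinical_plus_gaze}{clinical vectors concatenated with per-task
#'     median-aggregated gaze features.}
#' }
#'
#' @param mode experiment name.
#' @param features trial feature table (gaze modes).
#' @param clinical clinical table (clinical modes).
#' @param streams named list of per-stream feature tables (gaze_stream mode).
#' @param config a [model_config()]; experiment modes other than the primary
#'   default to the discrimination-only fold (no calibration stage) since the
#'   compared quantity is the AUC.
#' @param seed master seed.
#' @param fractions training-set fractions for the learning curve.
#' @param cohort simulated cohort (preprocessing_grid mode, which re-extracts
#'   features under each preprocessing variant).
#' @return data.frame of per-variant AUC (and accuracy where an operating
#'   point is defined).
#' @export
run_experiment <- function(mode, features = NULL, clinical = NULL,
                           streams = NULL, config = model_config(calibrate = FALSE),
                           seed = 1,
                           fractions = c(0.4, 0.6, 0.8, 1.0), cohort = NULL) {
  if (mode == "preprocessing_grid") {
    preprocessing_grid(cohort, config = config, seed = seed)
  } else if (mode == "baselines") {
    out <- lapply(c("logistic", "svm", "gbt", "rf"), function(lr) {
      cfg <- config; cfg$learner <- lr
      rep <- nested_loso(features, cfg, seed)
      data.frame(variant = lr, auc = rep$auc,
                 accuracy = if (config$calibrate) rep$metrics$accuracy else NA_real_)
    })
    do.call(rbind, out)
  } else if (mode == "task_ablation") {
    subsets <- list(T1 = 1, T2 = 2, T3 = 3, `T1+T2` = c(1, 2),
                    `T2+T3` = c(2, 3), `T1+T3` = c(1, 3), all = 1:3)
    out <- lapply(names(subsets), function(nm) {
      cols <- gs_task_cols(subsets[[nm]])
      rep <- nested_loso(features, config, seed, feature_cols = cols)
      data.frame(variant = nm, auc = rep$auc,
                 accuracy = if (config$calibrate) rep$metrics$accuracy else NA_real_)
    })
    do.call(rbind, out)
  } else if (mode == "gaze_stream") {
    stopifnot(is.list(streams), !is.null(names(streams)))
    out <- lapply(names(streams), function(nm) {
      rep <- nested_loso(streams[[nm]], config, seed)
      data.frame(variant = nm, auc = rep$auc,
                 accuracy = if (config$calibrate) rep$metrics$accuracy else NA_real_)
    })
    do.call(rbind, out)
  } else if (mode == "learning_curve") {
    subj <- unique(features[, c("subject_id", "group")])
    ord <- gs_balanced_order(subj, seed)
    out <- lapply(fractions, function(fr) {
      k <- max(4, round(length(ord) * fr))
      take <- ord[seq_len(min(k, length(ord)))]
      sub <- features[features$subject_id %in% take, ]
      rep <- tryCatch(nested_loso(sub, config, seed), error = function(e) NULL)
      data.frame(variant = sprintf("%.0f%%", fr * 100),
                 n_subjects = length(take),
                 auc = if (is.null(rep)) NA_real_ else rep$auc)
    })
    do.call(rbind, out)
  } else if (mode == "clinical_only") {
    cf <- clinical_features(clinical)
    cfg <- config; cfg$learner <- "logistic"
    rep <- nested_loso(cf, cfg, seed, feature_cols = gs_clinical_cols)
    data.frame(variant = "clinical_only", auc = rep$auc,
               accuracy = if (config$calibrate) rep$metrics$accuracy else NA_real_)
  } else if (mode == "clinical_plus_gaze") {
    cf <- clinical_features(clinical)
    agg <- aggregate_subject(features)
    comb <- merge(cf, agg[, c("subject_id", gs_feature_names)], by = "subject_id")
    rep <- nested_loso(comb, config, seed,
                       feature_cols = c(gs_clinical_cols, gs_feature_names))
    data.frame(variant = "clinical_plus_gaze", auc = rep$auc,
               accuracy = if (config$calibrate) rep$metrics$accuracy else NA_real_)
  } else stop("unknown mode: ", mode)
}

# deterministic label-alternating subject order so every learning-curve subset
# is balanced and nested in the next
gs_balanced_order <- function(subj, seed) {
  set.seed(seed)
  a <- sample(subj$subject_id[subj$group == "amblyopia"])
  c0 <- sample(subj$subject_id[subj$group == "control"])
  n <- max(length(a), length(c0))
  ord <- character(0)
  for (i in seq_len(n)) {
    if (i <= length(a)) ord <- c(ord, a[i])
    if (i <= length(c0)) ord <- c(ord, c0[i])
  }
  ord
}

#' Preprocessing robustness grid
#'
#' Re-extracts features under each preprocessing variant and reports the
#' nested-LOSO AUC: I-DT dispersion threshold, minimum fixation duration,
#' smoothing method, and QC exclusion threshold.
#'
#' @param cohort simulated cohort.
#' @param variants data.frame with columns `idt_dispersion`,
#'   `idt_min_duration`, `smooth_method`, `qc_threshold` (one row per variant).
#' @param config,seed as in [nested_loso()].
#' @return data.frame of per-variant AUC.
#' @export
preprocessing_grid <- function(cohort, variants = NULL,
                               config = model_config(calibrate = FALSE),
                               seed = 1) {
  if (is.null(variants)) {
    variants <- data.frame(
      idt_dispersion = c(0.75, 1.0, 1.25, 1.0, 1.0, 1.0, 1.0),
      idt_min_duration = c(0.1, 0.1, 0.1, 0.08, 0.12, 0.1, 0.1),
      smooth_method = c("sgolay", "sgolay", "sgolay", "sgolay", "sgolay",
                        "lowpass", "sgolay"),
      qc_threshold = c(0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.25))
  }
  out <- lapply(seq_len(nrow(variants)), function(i) {
    ft <- extract_features(cohort,
                           qc_threshold = variants$qc_threshold[i],
                           idt_dispersion = variants$idt_dispersion[i],
                           idt_min_duration = variants$idt_min_duration[i],
                           smooth_method = variants$smooth_method[i])
    rep <- nested_loso(ft, config, seed)
    cbind(variants[i, ], auc = rep$auc)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
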