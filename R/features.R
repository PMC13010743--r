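# Trial-level oculomotor feature extraction and subject-level aggregation.

gs_feature_names <- c(
  "t1_fixdur_mean", "t1_fixdur_sd", "t1_rms_dispersion", "t1_refixations",
  "t1_saccade_amp", "t1_regressions", "t1_entropy",
  "t2_latency_ms", "t2_drift_deg", "t2_hull_area", "t2_corrective_rate",
  "t3_tracking_error", "t3_pursuit_gain", "t3_catchup_count", "t3_onset_ms"
)

gs_empty_features <- function() {
  v <- rep(NA_real_, length(gs_feature_names))
  names(v) <- gs_feature_names
  v
}

#' Task 1 (visual search) trial features
#'
#' Fixation-duration mean/SD, mean within-fixation RMS dispersion, refixation
#' count (centroid within `refix_radius` of any non-adjacent earlier fixation),
#' mean saccade amplitude (Euclidean distance between successive centroids),
#' regression count (inter-fixation steps whose horizontal component opposes
#' the predominant scanning direction), and scan-path entropy (plug-in Shannon
#' entropy, base 2, of the empirical distribution of 8x6-grid cell transition
#' pairs). With fewer than two fixations the transition-based features are
#' missing.
#'
#' @param fixations output of [idt_fixations()].
#' @param refix_radius refixation radius in degrees (default 1.0).
#' @return named numeric vector over the full feature space (other tasks NA).
#' @export
task1_features <- function(fixations, refix_radius = 1.0) {
  f <- gs_empty_features()
  nf <- nrow(fixations)
  if (nf == 0) return(f)
  f["t1_fixdur_mean"] <- mean(fixations$duration_ms)
  f["t1_fixdur_sd"] <- if (nf > 1) stats::sd(fixations$duration_ms) else NA_real_
  f["t1_rms_dispersion"] <- mean(fixations$rms)
  refix <- 0L
  if (nf >= 3) {
    for (i in 3:nf) {
      d <- sqrt((fixations$cx[seq_len(i - 2)] - fixations$cx[i])^2 +
                (fixations$cy[seq_len(i - 2)] - fixations$cy[i])^2)
      if (any(d <= refix_radius)) refix <- refix + 1L
    }
  }
  f["t1_refixations"] <- refix
  if (nf >= 2) {
    dx <- diff(fixations$cx); dy <- diff(fixations$cy)
    f["t1_saccade_amp"] <- mean(sqrt(dx^2 + dy^2))
    dom <- sign(sum(dx))
    f["t1_regressions"] <- if (dom == 0) 0 else sum(sign(dx) == -dom & dx != 0)
    f["t1_entropy"] <- transition_entropy(fixations$cell)
  } else {
    f["t1_regressions"] <- 0
    f["t1_refixations"] <- 0
  }
  f
}

# polygon area by the shoelace formula over the convex hull of the points
gs_hull_area <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) return(0)
  h <- grDevices::chull(x, y)
  if (length(h) < 3) return(0)
  hx <- x[h]; hy <- y[h]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

#' Task 2 (grating viewing) trial features
#'
#' Fixation latency (stimulus onset to the first fixation whose centroid lies
#' inside the circular ROI), directional drift (absolute net gaze displacement
#' between the first and last valid in-trial samples, projected on the grating
#' orientation axis), fixation dispersion (convex-hull area of in-ROI
#' samples), and the small-corrective-event rate per minute.
#'
#' @param segment a `trial_segment`.
#' @param fixations output of [idt_fixations()] on the segment.
#' @param events output of [saccade_like_events()] on the segment.
#' @param orientation grating orientation in degrees (0 to 165).
#' @param roi_radius ROI radius in degrees (default 2.0), centered on the
#'   stimulus at the screen center.
#' @return named numeric vector over the full feature space.
#' @export
task2_features <- function(segment, fixations, events, orientation,
                           roi_radius = 2.0) {
  f <- gs_empty_features()
  in_roi <- nrow(fixations) > 0 &
    sqrt(fixations$cx^2 + fixations$cy^2) <= roi_radius
  if (any(in_roi)) {
    f["t2_latency_ms"] <- (fixations$t_start[which(in_roi)[1]] - segment$t_s[1]) * 1000
  }
  ok <- which(is.finite(segment$x))
  if (length(ok) >= 2) {
    u <- c(cos(orientation * pi / 180), sin(orientation * pi / 180))
    dxy <- c(segment$x[ok[length(ok)]] - segment$x[ok[1]],
             segment$y[ok[length(ok)]] - segment$y[ok[1]])
    f["t2_drift_deg"] <- abs(sum(dxy * u))
  }
  roi_samp <- is.finite(segment$x) & sqrt(segment$x^2 + segment$y^2) <= roi_radius
  f["t2_hull_area"] <- gs_hull_area(segment$x[roi_samp], segment$y[roi_samp])
  dur_min <- (segment$t_s[length(segment$t_s)] - segment$t_s[1] +
                segment$dt) / 60
  n_small <- if (nrow(events)) sum(events$class == "small_corrective") else 0L
  f["t2_corrective_rate"] <- n_small / dur_min
  f
}

#' Task 3 (smooth pursuit) trial features
#'
#' Tracking error (mean Euclidean gaze-target distance over valid samples),
#' pursuit gain (median ratio of gaze speed to target speed over samples with
#' target speed above the gate), catch-up saccade count, and pursuit onset
#' latency.
#'
#' @param segment a `trial_segment` covering the motion window.
#' @param target data.frame with frame-aligned `x`, `y`, `vx`, `vy`.
#' @param events output of [saccade_like_events()] on the segment.
#' @param gain_gate minimum target speed (deg/s) for the gain ratio (default 2).
#' @return named numeric vector over the full feature space.
#' @export
task3_features <- function(segment, target, events, gain_gate = 2.0) {
  if (nrow(target) != length(segment$x)) stop("gaze and target must be frame-aligned")
  f <- gs_empty_features()
  err <- sqrt((segment$x - target$x)^2 + (segment$y - target$y)^2)
  f["t3_tracking_error"] <- mean(err, na.rm = TRUE)
  tsp <- sqrt(target$vx^2 + target$vy^2)
  gsp <- segment$speed
  sel <- is.finite(gsp) & tsp > gain_gate
  if (any(sel)) f["t3_pursuit_gain"] <- stats::median(gsp[sel] / tsp[sel])
  f["t3_catchup_count"] <- catch_up_saccades(events, segment$x, segment$y,
                                             target$x, target$y)
  f["t3_onset_ms"] <- pursuit_onset_latency(segment$t_s, segment$vx, segment$vy,
                                            target$vx, target$vy,
                                            t_onset = segment$t_s[1])
  f
}

#' Extract the trial-level feature table for a cohort
#'
#' Slices the gaze stream into trials by the schedule, builds the requested
#' gaze stream, preprocesses each trial and computes its task features.
#' Features of the other tasks are missing by construction (imputed inside
#' model folds, never here).
#'
#' @param cohort output of [simulate_cohort()] (or equivalent tables).
#' @param stream_kind passed to [build_stream()].
#' @param qc_threshold trial exclusion threshold.
#' @param idt_dispersion,idt_min_duration I-DT parameters.
#' @param smooth_method `"sgolay"` or `"lowpass"`.
#' @param event_signal `"raw_forward"` or `"central"` speed signal for event
#'   detection.
#' @return data.frame with one row per (subject, task, trial): keys, QC
#'   columns, trial metadata and the feature columns.
#' @export
extract_features <- function(cohort, stream_kind = "cyclopean",
                             qc_threshold = 0.30, idt_dispersion = 1.0,
                             idt_min_duration = 0.1, smooth_method = "sgolay",
                             event_signal = "raw_forward") {
  screen <- cohort$spec$screen
  out <- list()
  gz <- cohort$gaze
  gz_split <- split(gz, list(gz$subject_id, gz$task_id), drop = TRUE)
  sch_split <- split(cohort$schedule,
                     list(cohort$schedule$subject_id, cohort$schedule$task_id),
                     drop = TRUE)
  side <- stats::setNames(cohort$clinical$amblyopic_side, cohort$clinical$subject_id)
  grp <- stats::setNames(cohort$clinical$group, cohort$clinical$subject_id)
  n_tot <- nrow(cohort$schedule)
  key_sid <- character(n_tot); key_task <- integer(n_tot)
  key_trial <- integer(n_tot); key_or <- key_ct <- numeric(n_tot)
  key_inv <- numeric(n_tot); key_ret <- logical(n_tot)
  fmat <- matrix(NA_real_, n_tot, length(gs_feature_names),
                 dimnames = list(NULL, gs_feature_names))
  ri <- 0L
  for (key in names(gz_split)) {
    rec <- gz_split[[key]]
    sch <- sch_split[[key]]
    sid <- rec$subject_id[1]; task <- rec$task_id[1]
    amb_side <- gs_resolve_side(side[[sid]], grp[[sid]], stream_kind)
    stream <- build_stream(rec, stream_kind, amblyopic_side = amb_side,
                           screen = screen)
    for (r in seq_len(nrow(sch))) {
      sel <- which(stream$t_s >= sch$t_on[r] & stream$t_s < sch$t_off[r])
      seg <- preprocess_trial(stream[sel, ], screen, qc_threshold,
                              smooth_method = smooth_method)
      feats <- gs_empty_features()
      if (seg$retained) {
        if (task == 1) {
          fx <- idt_fixations(seg$t_s, seg$xs, seg$ys, idt_dispersion,
                              idt_min_duration, screen)
          feats <- task1_features(fx)
        } else if (task == 2) {
          fx <- idt_fixations(seg$t_s, seg$xs, seg$ys, idt_dispersion,
                              idt_min_duration, screen)
          ev <- gs_detect_events(seg, event_signal)
          feats <- task2_features(seg, fx, ev, sch$orientation[r])
        } else {
          traj <- make_pursuit_trajectory(sch$t_off[r] - sch$t_on[r],
                                          1 / seg$dt,
                                          phases = c(sch$phase_x[r], sch$phase_y[r]))
          n <- length(seg$x)
          target <- data.frame(x = traj$x[seq_len(n)], y = traj$y[seq_len(n)],
                               vx = traj$vx[seq_len(n)], vy = traj$vy[seq_len(n)])
          ev <- gs_detect_events(seg, event_signal)
          feats <- task3_features(seg, target, ev)
        }
      }
      ri <- ri + 1L
      key_sid[ri] <- sid; key_task[ri] <- task; key_trial[ri] <- sch$trial_id[r]
      key_or[ri] <- sch$orientation[r]; key_ct[ri] <- sch$contrast[r]
      key_inv[ri] <- seg$invalid_fraction; key_ret[ri] <- seg$retained
      fmat[ri, ] <- feats
    }
  }
  res <- data.frame(subject_id = key_sid[seq_len(ri)],
                    group = unname(grp[key_sid[seq_len(ri)]]),
                    task_id = key_task[seq_len(ri)],
                    trial_id = key_trial[seq_len(ri)],
                    orientation = key_or[seq_len(ri)],
                    contrast = key_ct[seq_len(ri)],
                    invalid_fraction = key_inv[seq_len(ri)],
                    retained = key_ret[seq_len(ri)])
  res <- cbind(res, as.data.frame(fmat[seq_len(ri), , drop = FALSE]))
  res[order(res$subject_id, res$task_id, res$trial_id), ]
}

gs_resolve_side <- function(side, group, stream_kind) {
  if (!stream_kind %in% c("amblyopic_eye", "fellow_eye")) return(side)
  # controls have no amblyopic eye; resolve to the recorded worse-acuity side
  if (is.na(side) || !nzchar(side)) "left" else side
}

gs_detect_events <- function(seg, event_signal = "raw_forward") {
  if (event_signal == "raw_forward") {
    saccade_like_events(seg$t_s, seg$x, seg$y)
  } else {
    saccade_like_events(seg$t_s, seg$xs, seg$ys, speed = seg$speed,
                        signal = "central")
  }
}

#' Aggregate trial features to the subject level
#'
#' Per-subject, per-feature median over retained trials within each task;
#' Task 2 features are first medianed within orientation and then averaged
#' across orientations. Subjects with zero retained trials in a task have all
#' of that task's features missing.
#'
#' @param features output of [extract_features()].
#' @return data.frame with one row per subject: `subject_id`, `group`, and the
#'   aggregated feature columns.
#' @export
aggregate_subject <- function(features) {
  subj <- unique(features[, c("subject_id", "group")])
  task_of <- substr(gs_feature_names, 1, 2)
  agg <- matrix(NA_real_, nrow(subj), length(gs_feature_names),
                dimnames = list(subj$subject_id, gs_feature_names))
  for (i in seq_len(nrow(subj))) {
    rows <- features[features$subject_id == subj$subject_id[i] &
                       features$retained, , drop = FALSE]
    for (fn in gs_feature_names) {
      tk <- as.integer(substr(task_of[match(fn, gs_feature_names)], 2, 2))
      tr <- rows[rows$task_id == tk, , drop = FALSE]
      if (!nrow(tr)) next
      v <- tr[[fn]]
      if (tk == 2) {
        med <- tapply(v, tr$orientation, stats::median, na.rm = TRUE)
        agg[i, fn] <- mean(med, na.rm = TRUE)
      } else {
        agg[i, fn] <- stats::median(v, na.rm = TRUE)
      }
    }
  }
  cbind(subj, as.data.frame(agg))
}

#' Orientation-resolved Task 2 feature curves
#'
#' Subject-level medians of each Task 2 feature within every grating
#' orientation (the orientation-tuning curves behind the orientation-averaged
#' summaries).
#'
#' @param features output of [extract_features()].
#' @return data.frame in long format: subject, group, orientation, feature,
#'   value.
#' @export
orientation_curves <- function(features) {
  t2 <- features[features$task_id == 2 & features$retained, ]
  feats <- grep("^t2_", gs_feature_names, value = TRUE)
  out <- list()
  for (fn in feats) {
    a <- stats::aggregate(t2[[fn]],
                          by = list(subject_id = t2$subject_id, group = t2$group,
                                    orientation = t2$orientation),
                          FUN = stats::median, na.rm = TRUE)
    a$feature <- fn
    names(a)[names(a) == "x"] <- "value"
    out[[fn]] <- a
  }
  do.call(rbind, out)
}
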