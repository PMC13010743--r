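#' Screen geometry descriptor
#'
#' Geometry of the presentation display used both by the simulator (degrees to
#' pixels) and by preprocessing (pixels to degrees). The default corresponds to
#' a 24-inch 16:9 panel at 1920 x 1080 viewed from 60 cm, which gives a pixel
#' pitch of ~0.02767 cm/px and a horizontal half-extent of ~23.9 degrees of
#' visual angle.
#'
#' @param width_px,height_px display resolution in pixels.
#' @param width_cm,height_cm physical panel size in cm.
#' @param distance_cm perpendicular viewing distance in cm.
#' @return A list of class `gs_screen`.
#' @export
screen_geometry <- function(width_px = 1920, height_px = 1080,
                            width_cm = 53.13, height_cm = 29.89,
                            distance_cm = 60) {
  stopifnot(width_px > 0, height_px > 0, width_cm > 0, height_cm > 0)
  if (distance_cm <= 0) stop("viewing distance must be positive")
  out <- list(width_px = width_px, height_px = height_px,
              width_cm = width_cm, height_cm = height_cm,
              distance_cm = distance_cm,
              pitch_x = width_cm / width_px,
              pitch_y = height_cm / height_px,
              half_w_deg = atan((width_cm / 2) / distance_cm) * 180 / pi,
              half_h_deg = atan((height_cm / 2) / distance_cm) * 180 / pi)
  class(out) <- "gs_screen"
  out
}

#' Cohort specification for the synthetic study
#'
#' Defines the study conditions under which a synthetic cohort is generated:
#' group sizes, sampling rate, the per-task trial plan (8 formal search trials;
#' 72 grating trials spanning 12 orientations x 3 contrasts x 2 repetitions of
#' 2 s stimulus + 1 s blank; 6 pursuit trials of 20 s preceded by 3 s of
#' fixation), screen geometry, and artifact injection rates.
#'
#' @param n_per_group subjects per group (controls and unilateral amblyopia).
#' @param sampling_rate gaze sampling rate in Hz.
#' @param screen a [screen_geometry()] object.
#' @param artifact_rates list with `blink_rate_hz` (blink onsets per second),
#'   `blink_meanlog_ms`/`blink_sdlog` (log-normal blink duration, ms),
#'   `glitch_prob` (per-sample probability of a single-sample high-velocity
#'   excursion), `offscreen_prob` (per-sample probability of starting a short
#'   off-display run).
#' @param seed master integer seed; every random draw in the cohort is derived
#'   from it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 35, sampling_rate = 30,
                        screen = screen_geometry(),
                        artifact_rates = list(blink_rate_hz = 0.22,
                                              blink_meanlog_ms = log(150),
                                              blink_sdlog = 0.45,
                                              glitch_prob = 0.0015,
                                              offscreen_prob = 0.0012),
                        seed = 1L) {
  stopifnot(n_per_group >= 1, sampling_rate > 0)
  trial_plan <- list(
    task1 = list(n_trials = 8L, max_duration_s = 60),
    task2 = list(orientations = seq(0, 165, by = 15), contrasts = c(0.2, 0.4, 0.8),
                 reps = 2L, stim_s = 2, blank_s = 1),
    task3 = list(n_trials = 6L, duration_s = 20, prefix_s = 3)
  )
  out <- list(n_per_group = as.integer(n_per_group),
              sampling_rate = sampling_rate,
              trial_plan = trial_plan,
              screen = screen,
              artifact_rates = artifact_rates,
              seed = as.integer(seed))
  class(out) <- "cohort_spec"
  out
}

# Group-level targets for the latent oculomotor parameters, on the scale of the
# pipeline-extracted subject-level summaries. Where a published subject-level
# summary exists it is used as the target mean/SD; remaining families
# (fixation durations, within-fixation jitter, corrective-event rate, pursuit
# onset latency) use values typical for school-aged children.
gs_group_targets <- function() {
  list(
    control = list(
      entropy = c(2.126, 0.282), regressions = c(1.914, 1.401),
      amplitude = c(3.303, 0.776),
      fixdur_ms = c(280, 35), fix_jitter = c(0.17, 0.015),
      latency_ms = c(226.5, 20.2), drift = c(0.384, 0.061),
      hull = c(2.737, 0.312), corrective_rate = c(12, 3),
      error = c(0.605, 0.130), gain = c(0.946, 0.046),
      catchup = c(5.22, 2.07), onset_ms = c(180, 28)
    ),
    amblyopia = list(
      entropy = c(2.824, 0.354), regressions = c(3.857, 2.144),
      amplitude = c(4.098, 1.249),
      fixdur_ms = c(310, 45), fix_jitter = c(0.20, 0.02),
      latency_ms = c(272.9, 23.5), drift = c(0.646, 0.104),
      hull = c(3.923, 0.641), corrective_rate = c(22, 5),
      error = c(1.069, 0.210), gain = c(0.799, 0.074),
      catchup = c(11.26, 4.05), onset_ms = c(230, 38)
    )
  )
}

rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  k <- 0L
  while (length(bad) && k < 50L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
    k <- k + 1L
  }
  pmin(pmax(x, lo), hi)
}

#' Draw a latent subject profile
#'
#' Samples the latent oculomotor parameters and clinical covariates for one
#' subject. Amblyopia subjects satisfy the inclusion rules: interocular
#' best-corrected acuity difference of at least 0.2 logMAR and amblyopic-eye
#' BCVA in [0.2, 0.5] logMAR; controls have BCVA of 0.1 logMAR or better in
#' each eye. Latent oculomotor means/SDs default to the subject-level group
#' summaries the cohort is calibrated to reproduce.
#'
#' @param group `"control"` or `"amblyopia"`.
#' @param targets group target list (see `gs_group_targets`); the matching
#'   group's element is used.
#' @return list of class `subject_profile`.
#' @export
draw_subject_profile <- function(group = c("control", "amblyopia"),
                                 targets = gs_group_targets()) {
  group <- match.arg(group)
  tg <- targets[[group]]
  d <- function(nm, lo = -Inf, hi = Inf) rtrunc_norm(1, tg[[nm]][1], tg[[nm]][2], lo, hi)
  prof <- list(
    group = group,
    entropy = d("entropy", 1.2, 4.5),
    regressions = d("regressions", 0, 12),
    amplitude = d("amplitude", 1.6, 8),
    fixdur_ms = d("fixdur_ms", 150, 600),
    fix_jitter = d("fix_jitter", 0.05, 0.3),
    latency_ms = d("latency_ms", 120, 450),
    drift = d("drift", 0.05, 1.6),
    hull = d("hull", 0.8, 8),
    corrective_rate = d("corrective_rate", 1, 30),
    error = d("error", 0.25, 2.2),
    gain = d("gain", 0.3, 1.2),
    catchup = d("catchup", 0.5, 25),
    onset_ms = d("onset_ms", 100, 400)
  )
  # targets are on the extracted-feature scale; the velocity gain actually
  # applied is corrected for the small upward measurement bias of the median
  # speed-ratio estimator under default eye noise
  prof$gain <- prof$gain - gs_cal("gain_bias", group)
  # clinical covariates (published cohort-table structure)
  if (group == "control") {
    worse <- rtrunc_norm(1, 0.03, 0.05, -0.1, 0.1)
    better <- rtrunc_norm(1, 0.02, 0.05, -0.1, worse)
    prof$bcva_amblyopic <- worse
    prof$bcva_fellow <- better
    prof$se_worse <- stats::rnorm(1, -0.25, 0.75)
    prof$se_better <- stats::rnorm(1, -0.15, 0.70)
    prof$stereo_arcsec <- exp(rtrunc_norm(1, log(60), 0.35, log(20), log(200)))
    prof$etiology <- NA_character_
  } else {
    amb <- rtrunc_norm(1, 0.34, 0.09, 0.2, 0.5)
    fel <- rtrunc_norm(1, 0.05, 0.05, -0.1, amb - 0.2)
    prof$bcva_amblyopic <- amb
    prof$bcva_fellow <- fel
    prof$se_worse <- rtrunc_norm(1, 2.0, 2.25, -4, 8)
    prof$se_better <- rtrunc_norm(1, 0.5, 1.5, -4, 6)
    prof$stereo_arcsec <- exp(rtrunc_norm(1, log(400), 0.6, log(100), log(3000)))
    prof$etiology <- sample(c("anisometropic", "strabismic", "mixed"), 1,
                            prob = c(18, 10, 7) / 35)
  }
  prof$amblyopic_side <- sample(c("left", "right"), 1)
  prof$age <- rtrunc_norm(1, if (group == "control") 8.7 else 9.1, 1.65, 6, 12)
  prof$sex <- sample(c("male", "female"), 1)
  class(prof) <- "subject_profile"
  prof
}
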