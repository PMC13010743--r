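# Generator calibration constants.
#
# The simulator is specified by what the *pipeline-extracted* subject-level
# features should look like (the group summary targets in gs_group_targets).
# The mechanistic latent parameters the generator actually uses are related to
# those targets by the constants below (measurement-noise biases, geometric
# coefficients of the Ornstein-Uhlenbeck dispersion, the affine response of
# the drift estimator, the sawtooth coefficient of the pursuit error process,
# detection fractions of injected events). They were measured once with
# large-n calibration simulations during development and are frozen here; they
# are not tunable at run time. Constants that depend on the group's own noise
# regime (the amblyopic-eye instability enters the cyclopean stream of
# amblyopia subjects only) are per-group.
gs_calib <- list(
  # pursuit gain: extracted median speed-ratio minus latent velocity gain
  # (upward bias from velocity measurement noise and correction-step smearing,
  # larger in the amblyopia group whose cyclopean stream carries the
  # amblyopic-eye instability)
  gain_bias = c(control = 0.028, amblyopia = 0.222),
  # convex-hull area of in-ROI samples of the fixational OU process:
  # E[hull] ~ hull_coef * sigma_ou^2 at 60 samples (smoothed, incl. eye noise)
  hull_coef = c(control = 8.6, amblyopia = 8.1),
  # orientation-referenced drift: extracted orientation-averaged magnitude ~
  # drift_a + drift_b * v in the latent drift speed v (deg/s); inverted at
  # generation time (intercept = |projection| noise floor)
  drift_a = c(control = 0.320, amblyopia = 0.285),
  drift_b = 1.31,
  # fixation latency: extracted aggregated latency minus latent glide
  # duration, ms (negative: the first in-ROI fixation forms slightly before
  # the nominal end of the glide)
  latency_offset_ms = c(control = -12, amblyopia = 3),
  # tracking error: time-averaged |error| of the sawtooth error process as a
  # fraction of the small-correction trigger threshold
  error_coef = c(control = 0.658, amblyopia = 0.621),
  # detected fraction of injected corrective events per trial
  corr_detect = 0.90,
  # catch-up counts: aggregated extracted count ~ catch_acq + catch_detect *
  # injected Poisson mean (intercept = initial target-acquisition saccade)
  catch_acq = c(control = 1.17, amblyopia = 0.35),
  catch_detect = 0.776,
  # pursuit onset latency: aggregated extracted minus latent, ms (speed-gate
  # crossings depend on the target phase at motion onset)
  onset_a = c(control = 34, amblyopia = 59),
  # scan-path planner residuals: extracted = a + latent (I-DT splits/merges
  # around sweep returns inflate regression counts and step lengths)
  regress_a = c(control = 0.30, amblyopia = 1.70),
  amp_a = c(control = 0.05, amblyopia = -0.52),
  entropy_a = c(control = -0.04, amblyopia = 0.09), entropy_b = 1,
  # fixation durations: I-DT boundary trimming shortens measured durations
  fixdur_mult = c(control = 1.054, amblyopia = 1.337),
  # within-fixation RMS dispersion: extracted^2 ~ jitter_floor2 + 0.693 *
  # latent^2 (floor: eye noise plus smoothing transients at fixation edges)
  jitter_floor2 = 0.021, jitter_slope2 = 0.693
)

gs_cal <- function(name, group) {
  v <- gs_calib[[name]]
  if (length(v) > 1 && !is.null(names(v))) unname(v[[group]]) else unname(v)
}
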