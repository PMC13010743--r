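# Synthetic binocular gaze generation for the three oculomotor tasks.
#
# The generator is specified "from the outside in": the quantities that the
# downstream pipeline extracts (scan-path entropy, regression counts, pursuit
# gain, convex-hull dispersion, ...) are the calibrated targets, and the
# mechanistic latent processes below are constructed so that large-n group
# means of the extracted features land on those targets (constants in
# R/calibration.R).

gs_dt <- function(spec) 1 / spec$sampling_rate

# orientation multiplier for drift: 1.0 at 0/90 deg, 1.4 at 45/135 deg,
# orientation-average exactly 1.2 over the 12-orientation design
gs_orientation_mult <- function(theta_deg) 1 + 0.4 * sin(2 * theta_deg * pi / 180)^2

# plug-in Shannon entropy (bits) of the empirical distribution of consecutive
# cell-transition pairs; shared definition with the feature module
transition_entropy <- function(cells) {
  if (length(cells) < 2) return(NA_real_)
  pair <- paste(cells[-length(cells)], cells[-1])
  p <- table(pair) / length(pair)
  -sum(p * log2(p))
}

gs_cell_of <- function(x, y, screen, ncol = 8L, nrow = 6L) {
  cw <- 2 * screen$half_w_deg / ncol
  ch <- 2 * screen$half_h_deg / nrow
  col <- pmin(ncol - 1L, pmax(0L, floor((x + screen$half_w_deg) / cw)))
  row <- pmin(nrow - 1L, pmax(0L, floor((y + screen$half_h_deg) / ch)))
  as.integer(col + ncol * row)
}

# ---- Task 1: fixation-saccade scan path over an icon array ------------------

# Construct a fixation sequence whose transition-pair entropy, leftward
# (regressive) step count and mean inter-fixation amplitude approximate the
# subject's latent targets. The path is a repeated left-to-right sweep (the
# predominant scanning direction) over the same icons; sweep returns are the
# regressions. Candidate sweep lengths / step scales / one- vs two-row layouts
# are enumerated and scored against the targets on the actual quantized grid.
plan_scanpath <- function(H, n_regress, amp, screen) {
  s <- max(1L, n_regress + 1L)          # sweeps; returns = s - 1 regressions
  cw <- 2 * screen$half_w_deg / 8
  ch <- 2 * screen$half_h_deg / 6
  rows_y <- -screen$half_h_deg + ch * (seq_len(6) - 0.5)
  best <- NULL; best_score <- Inf
  for (L in 3:13) {
    for (fs in c(0.65, 0.8, 1.0)) {
      for (zig in c(FALSE, TRUE)) {
        step <- amp * fs
        span <- (L - 1) * step
        if (span > 2 * screen$half_w_deg - 6) next
        xs <- -span / 2 + step * (0:(L - 1))
        ys <- if (zig) rep(c(0, ch), length.out = L) else rep(0, L)
        # nudge the whole sweep away from vertical cell boundaries
        shifts <- seq(-cw / 2, cw / 2, length.out = 9)
        bdist <- vapply(shifts, function(d) {
          fx <- (xs + d + screen$half_w_deg) / cw
          min(abs(fx - round(fx)))
        }, numeric(1))
        xs <- xs + shifts[which.max(bdist)]
        for (base_row in 3:4) {
          y0 <- rows_y[base_row]
          px <- rep(xs, s); py <- rep(y0 + ys, s)
          cells <- gs_cell_of(px, py, screen)
          Hc <- transition_entropy(cells)
          d <- sqrt(diff(px)^2 + diff(py)^2)
          Ac <- mean(d)
          score <- abs(Hc - H) + 0.25 * abs(Ac - amp) / max(amp, 1)
          if (score < best_score) {
            best_score <- score
            best <- data.frame(x = px, y = py)
          }
        }
      }
    }
  }
  best
}

simulate_task1_trial <- function(profile, spec) {
  dt <- gs_dt(spec)
  r_lat <- max(0, profile$regressions - gs_cal("regress_a", profile$group))
  n_reg <- floor(r_lat) + stats::rbinom(1, 1, r_lat - floor(r_lat))
  h_lat <- (profile$entropy - gs_cal("entropy_a", profile$group)) / gs_calib$entropy_b
  amp_lat <- max(1.2, profile$amplitude - gs_cal("amp_a", profile$group))
  path <- plan_scanpath(h_lat, n_reg, amp_lat, spec$screen)
  nf <- nrow(path)
  # per-sweep positional jitter keeps revisits within the refixation radius
  sweep_len <- nf / (n_reg + 1)
  sweep_id <- rep(seq_len(n_reg + 1), each = sweep_len)[seq_len(nf)]
  off <- matrix(stats::runif(2 * (n_reg + 1), -0.3, 0.3), ncol = 2)
  cx <- path$x + off[sweep_id, 1]
  cy <- path$y + off[sweep_id, 2]
  dur_mean <- profile$fixdur_ms * gs_cal("fixdur_mult", profile$group) / 1000
  dur <- exp(stats::rnorm(nf, log(dur_mean), 0.2))
  nsamp <- pmax(4L, round(dur / dt))
  # invert the dispersion response (noise floor + attenuation) to a per-axis SD
  sj <- sqrt(max(profile$fix_jitter^2 - gs_calib$jitter_floor2, 0.004) /
               gs_calib$jitter_slope2) / sqrt(2)
  xs <- ys <- vector("list", 2 * nf - 1)
  for (i in seq_len(nf)) {
    n <- nsamp[i]
    jx <- as.numeric(stats::filter(stats::rnorm(n, 0, sj * sqrt(1 - 0.5^2)), 0.5,
                                   method = "recursive"))
    jy <- as.numeric(stats::filter(stats::rnorm(n, 0, sj * sqrt(1 - 0.5^2)), 0.5,
                                   method = "recursive"))
    xs[[2 * i - 1]] <- cx[i] + jx
    ys[[2 * i - 1]] <- cy[i] + jy
    if (i < nf) {  # one transit sample mid-saccade
      xs[[2 * i]] <- (cx[i] + cx[i + 1]) / 2
      ys[[2 * i]] <- (cy[i] + cy[i + 1]) / 2
    }
  }
  x <- unlist(xs); y <- unlist(ys)
  max_n <- round(spec$trial_plan$task1$max_duration_s / dt)
  if (length(x) > max_n) { x <- x[seq_len(max_n)]; y <- y[seq_len(max_n)] }
  data.frame(x = x, y = y)
}

# ---- Task 2: fixational drift around a central grating ----------------------

simulate_task2_trial <- function(profile, spec, orientation) {
  dt <- gs_dt(spec)
  n_stim <- round(spec$trial_plan$task2$stim_s / dt)
  n_blank <- round(spec$trial_plan$task2$blank_s / dt)
  lat_s <- max(0.067, (profile$latency_ms - gs_cal("latency_offset_ms", profile$group)) / 1000)
  n_lat <- max(2L, round(lat_s / dt))
  sigma_ou <- sqrt(max(profile$hull, 0.3) / gs_cal("hull_coef", profile$group))
  rho <- exp(-3 * dt)                       # OU time constant ~1/3 s
  v_drift <- max(0, (profile$drift - gs_cal("drift_a", profile$group)) / gs_calib$drift_b)
  u <- c(cos(orientation * pi / 180), sin(orientation * pi / 180))
  vd <- v_drift * gs_orientation_mult(orientation) / 1.2
  # stabilization latency realized as a smooth glide onto the stimulus from a
  # point displaced along the axis perpendicular to the grating orientation:
  # the moving samples defeat the I-DT dispersion criterion (no in-ROI
  # fixation before arrival), stay nearly collinear (negligible hull area),
  # and project onto the orientation axis only through a small angular jitter
  perp_sign <- sample(c(-1, 1), 1)
  ang <- (orientation + 90) * pi / 180 + stats::runif(1, -3, 3) * pi / 180
  r0 <- 0.62 * n_lat         # fixed glide speed keeps every 3-sample window
  off0 <- perp_sign * r0 * c(cos(ang), sin(ang))   # above the I-DT threshold
  frac <- rev(seq_len(n_lat)) / n_lat       # 1 -> 1/n_lat, arrives at center
  xa <- off0[1] * frac + stats::rnorm(n_lat, 0, 0.06)
  ya <- off0[2] * frac + stats::rnorm(n_lat, 0, 0.06)
  n_b <- n_stim - n_lat
  if (n_b < 1) { n_b <- 1L; n_lat <- n_stim - 1L }
  drift_path <- vd * (seq_len(n_b) - 1) * dt
  mx <- drift_path * u[1]; my <- drift_path * u[2]
  ou1 <- as.numeric(stats::filter(stats::rnorm(n_b, 0, sigma_ou * sqrt(1 - rho^2)),
                                  rho, method = "recursive"))
  ou2 <- as.numeric(stats::filter(stats::rnorm(n_b, 0, sigma_ou * sqrt(1 - rho^2)),
                                  rho, method = "recursive"))
  # settle onto the drifted locus over the last samples of the stimulus
  # window (keeps the net-displacement endpoint from being dominated by the
  # instantaneous OU excursion)
  shrink <- rep(1, n_b)
  ns <- min(4L, n_b)
  shrink[(n_b - ns + 1L):n_b] <- rev(c(1, 0.6, 0.35, 0.2)[seq_len(ns)])
  xb <- mx + ou1 * shrink; yb <- my + ou2 * shrink
  x <- c(xa, xb); y <- c(ya, yb)
  # overshooting small corrective events: two supra-threshold intervals whose
  # flanking net displacement is the 0.3-1.0 deg amplitude of interest
  lam <- (profile$corrective_rate / gs_calib$corr_detect) *
    spec$trial_plan$task2$stim_s / 60
  n_ev <- stats::rpois(1, lam)
  if (n_ev > 0) {
    cand <- which(seq_len(n_stim) > n_lat + 2 & seq_len(n_stim) < n_stim - 2)
    if (length(cand) >= n_ev) {
      ks <- sort(sample(cand, n_ev))
      ks <- ks[c(TRUE, diff(ks) > 3)]
      for (k in ks) {
        delta <- stats::runif(1, 0.35, 0.95)
        thd <- stats::runif(1, 0, 2 * pi); dvec <- c(cos(thd), sin(thd))
        o <- 2.3 + delta
        base <- c(x[k - 1], y[k - 1])
        x[k] <- base[1] + o * dvec[1];  y[k] <- base[2] + o * dvec[2]
        x[k + 1] <- base[1] + delta * dvec[1]
        y[k + 1] <- base[2] + delta * dvec[2]
      }
    }
  }
  # blank interval: gaze relaxes away from the stimulus
  thb <- stats::runif(1, 0, 2 * pi)
  bx <- x[n_stim] + cumsum(stats::rnorm(n_blank, 0.04 * cos(thb), 0.15))
  by <- y[n_stim] + cumsum(stats::rnorm(n_blank, 0.04 * sin(thb), 0.15))
  data.frame(x = c(x, bx), y = c(y, by))
}

# ---- Task 3: smooth pursuit with catch-up saccades --------------------------

simulate_task3_trial <- function(profile, spec, phases) {
  dt <- gs_dt(spec)
  plan <- spec$trial_plan$task3
  n_pre <- round(plan$prefix_s / dt)
  traj <- make_pursuit_trajectory(plan$duration_s, spec$sampling_rate,
                                  phases = phases)
  n <- length(traj$t)
  g <- profile$gain          # latent velocity gain; calibration handled by caller
  theta_s <- min(profile$error / gs_cal("error_coef", profile$group), 3.4)
  lam <- max(0, profile$catchup - gs_cal("catch_acq", profile$group)) / gs_calib$catch_detect
  n_cu <- stats::rpois(1, lam)
  cu_idx <- integer(0)
  if (n_cu > 0) {
    cand <- seq(20L, n - 10L)
    cu_idx <- sort(sample(cand, min(n_cu, length(cand))))
    cu_idx <- cu_idx[c(TRUE, diff(cu_idx) > 8)]
  }
  onset_gen <- max(100, profile$onset_ms - gs_cal("onset_a", profile$group))
  n_lat <- max(1L, round(onset_gen / 1000 / dt))
  ex <- ey <- numeric(n)                 # error = target - gaze
  gx <- gy <- numeric(n)
  # latency: gaze frozen at center while the target moves
  idx_lat <- seq_len(min(n_lat, n))
  gx[idx_lat] <- 0; gy[idx_lat] <- 0
  ex[idx_lat] <- traj$x[idx_lat]; ey[idx_lat] <- traj$y[idx_lat]
  # acquisition: fast 3-sample ramp onto the target
  k0 <- n_lat + 1L
  acq <- min(3L, n - n_lat)
  if (k0 <= n) {
    tgt <- c(traj$x[min(n, n_lat + acq)], traj$y[min(n, n_lat + acq)])
    for (j in seq_len(acq)) {
      k <- n_lat + j
      frac <- j / acq
      gx[k] <- (1 - frac) * 0 + frac * (tgt[1] - 0.25)
      gy[k] <- (1 - frac) * 0 + frac * tgt[2]
      ex[k] <- traj$x[k] - gx[k]; ey[k] <- traj$y[k] - gy[k]
    }
  }
  start <- n_lat + acq + 1L
  cu_state <- 0L
  sig_e <- 0.05
  if (start <= n) {
    for (k in start:n) {
      dex <- (1 - g) * traj$vx[k] * dt + stats::rnorm(1, 0, sig_e * sqrt(dt))
      dey <- (1 - g) * traj$vy[k] * dt + stats::rnorm(1, 0, sig_e * sqrt(dt))
      exk <- ex[k - 1] + dex; eyk <- ey[k - 1] + dey
      emag <- sqrt(exk^2 + eyk^2)
      if (k %in% cu_idx || cu_state > 0L) {
        # two-interval sub-threshold outward drift to ~2.45 deg error, then a
        # single supra-threshold corrective jump (the detectable catch-up)
        if (cu_state == 0L) cu_state <- 3L
        if (cu_state == 3L || cu_state == 2L) {
          need <- (2.45 - emag) / (cu_state - 1)
          if (need > 0) {
            dir <- if (emag > 1e-6) c(exk, eyk) / emag else c(1, 0)
            step <- min(need, 1.5)
            exk <- exk + step * dir[1]; eyk <- eyk + step * dir[2]
          }
          cu_state <- cu_state - 1L
        } else {                       # the jump itself
          exk <- 0.11 * exk; eyk <- 0.11 * eyk
          cu_state <- 0L
        }
      } else if (emag > theta_s) {
        # small corrective steps, each kept below the 60 deg/s event gate
        resid <- 0.15 * emag
        move <- emag - resid
        dir <- c(exk, eyk) / emag
        step <- min(move, 1.5)
        exk <- exk - step * dir[1]; eyk <- eyk - step * dir[2]
      }
      ex[k] <- exk; ey[k] <- eyk
      gx[k] <- traj$x[k] - exk; gy[k] <- traj$y[k] - eyk
    }
  }
  pre <- data.frame(x = stats::rnorm(n_pre, 0, 0.08),
                    y = stats::rnorm(n_pre, 0, 0.08))
  list(gaze = data.frame(x = c(pre$x, gx), y = c(pre$y, gy)),
       n_pre = n_pre, traj = traj)
}

# ---- binocular emission and artifact injection ------------------------------

gs_deg2px <- function(x_deg, y_deg, screen) {
  px <- screen$width_px / 2 +
    tan(x_deg * pi / 180) * screen$distance_cm / screen$pitch_x
  py <- screen$height_px / 2 -
    tan(y_deg * pi / 180) * screen$distance_cm / screen$pitch_y
  list(px = px, py = py)
}

# Latent cyclopean trace -> left/right pixel streams with validity flags and
# injected artifacts. Returns the sample table plus the per-sample audit mask
# of injected-invalid samples (blink, glitch incl. kinematic neighbours,
# off-screen, tracking lapse).
emit_binocular <- function(latent, spec, profile, eye_noise = TRUE) {
  n <- nrow(latent)
  dt <- gs_dt(spec)
  ar <- spec$artifact_rates
  sd_base <- if (eye_noise) 0.10 else 0
  amb_left <- identical(profile$amblyopic_side, "left")
  is_amb <- identical(profile$group, "amblyopia")
  sd_l <- sd_base * if (is_amb && amb_left) 1.5 else 1
  sd_r <- sd_base * if (is_amb && !amb_left) 1.5 else 1
  lx <- latent$x + stats::rnorm(n, 0, sd_l); ly <- latent$y + stats::rnorm(n, 0, sd_l)
  rx <- latent$x + stats::rnorm(n, 0, sd_r); ry <- latent$y + stats::rnorm(n, 0, sd_r)
  if (eye_noise && is_amb) {
    # amblyopic-eye-specific high-frequency instability: the disease signature
    # that makes the amblyopic-eye stream the most informative one
    sd_x <- 0.22
    if (amb_left) {
      lx <- lx + stats::rnorm(n, 0, sd_x); ly <- ly + stats::rnorm(n, 0, sd_x)
    } else {
      rx <- rx + stats::rnorm(n, 0, sd_x); ry <- ry + stats::rnorm(n, 0, sd_x)
    }
  }
  l_valid <- rep(1L, n); r_valid <- rep(1L, n)
  injected <- rep(FALSE, n)
  if (!is.null(ar) && isTRUE(ar$blink_rate_hz > 0)) {
    t_end <- n * dt
    tb <- cumsum(stats::rexp(max(4, ceiling(t_end * ar$blink_rate_hz * 3)),
                             ar$blink_rate_hz))
    tb <- tb[tb < t_end]
    for (t0 in tb) {
      dur <- exp(stats::rnorm(1, ar$blink_meanlog_ms, ar$blink_sdlog)) / 1000
      i0 <- max(1L, ceiling(t0 / dt)); i1 <- min(n, i0 + round(dur / dt))
      idx <- i0:i1
      l_valid[idx] <- 0L; r_valid[idx] <- 0L
      lx[idx] <- NA; ly[idx] <- NA; rx[idx] <- NA; ry[idx] <- NA
      injected[idx] <- TRUE
    }
  }
  if (!is.null(ar$lapse_prob) && stats::runif(1) < ar$lapse_prob && n > 20) {
    len <- round(n * stats::runif(1, 0.2, 0.45))
    i0 <- sample.int(n - len, 1); idx <- i0:(i0 + len - 1)
    l_valid[idx] <- 0L; r_valid[idx] <- 0L
    lx[idx] <- NA; ly[idx] <- NA; rx[idx] <- NA; ry[idx] <- NA
    injected[idx] <- TRUE
  }
  if (isTRUE(ar$glitch_prob > 0)) {
    gl <- which(stats::runif(n) < ar$glitch_prob)
    gl <- gl[gl > 1 & gl < n]
    for (k in gl) {
      if (any(!is.finite(c(lx[k], rx[k])))) next
      th <- stats::runif(1, 0, 2 * pi)
      dx <- 40 * cos(th); dy <- 40 * sin(th)
      lx[k] <- lx[k] + dx; ly[k] <- ly[k] + dy
      rx[k] <- rx[k] + dx; ry[k] <- ry[k] + dy
      injected[max(1, k - 1):min(n, k + 1)] <- TRUE   # kinematic rule flags both intervals
    }
  }
  if (isTRUE(ar$offscreen_prob > 0)) {
    os <- which(stats::runif(n) < ar$offscreen_prob)
    for (k in os) {
      len <- sample(1:3, 1); idx <- k:min(n, k + len - 1)
      edge <- spec$screen$half_w_deg + stats::runif(1, 1, 2.5)
      sgn <- sample(c(-1, 1), 1)
      lx[idx] <- sgn * edge; rx[idx] <- sgn * edge
      ly[idx] <- ifelse(is.na(ly[idx]), 0, ly[idx])
      ry[idx] <- ifelse(is.na(ry[idx]), 0, ry[idx])
      l_valid[idx] <- 1L; r_valid[idx] <- 1L
      injected[idx] <- TRUE
    }
  }
  pl <- gs_deg2px(lx, ly, spec$screen)
  pr <- gs_deg2px(rx, ry, spec$screen)
  data.frame(t_s = (seq_len(n) - 1) * dt,
             lx_px = pl$px, ly_px = pl$py, l_valid = l_valid,
             rx_px = pr$px, ry_px = pr$py, r_valid = r_valid,
             injected = injected)
}

#' Simulate the binocular gaze stream of one subject on one task
#'
#' Emits the raw sample table (pixel coordinates, per-eye validity) together
#' with the trial schedule and the per-sample artifact audit mask. Task 1 is a
#' fixation-saccade scan over an icon array; Task 2 is Ornstein-Uhlenbeck
#' fixational drift with an orientation-referenced drift component and injected
#' overshooting corrective events; Task 3 is velocity-gain-limited pursuit of
#' the sinusoidal target with small corrective steps and detectable catch-up
#' saccades.
#'
#' @param profile a [draw_subject_profile()] object.
#' @param spec a [cohort_spec()].
#' @param task_id 1, 2 or 3.
#' @param seed integer seed for this subject/task.
#' @param eye_noise logical; disable to obtain the noise-free latent trace in
#'   both eyes (artifacts are controlled separately via `spec$artifact_rates`).
#' @return list with `samples` (one row per 33-ms sample), `schedule` (one row
#'   per formal trial) and the injected-artifact audit.
#' @export
simulate_subject_gaze <- function(profile, spec, task_id, seed,
                                  eye_noise = TRUE) {
  if (!task_id %in% 1:3) stop("unknown task_id: ", task_id)
  set.seed(as.integer(seed %% 2147483647))
  dt <- gs_dt(spec)
  trials <- list(); sched <- list()
  t_cursor <- 0
  if (task_id == 1) {
    for (tr in seq_len(spec$trial_plan$task1$n_trials)) {
      g <- simulate_task1_trial(profile, spec)
      trials[[tr]] <- g
      sched[[tr]] <- data.frame(trial_id = tr, t_on = t_cursor,
                                t_off = t_cursor + nrow(g) * dt,
                                orientation = NA_real_, contrast = NA_real_,
                                phase_x = NA_real_, phase_y = NA_real_)
      t_cursor <- t_cursor + nrow(g) * dt
    }
  } else if (task_id == 2) {
    plan <- spec$trial_plan$task2
    grid <- expand.grid(orientation = plan$orientations,
                        contrast = plan$contrasts, rep = seq_len(plan$reps))
    grid <- grid[sample.int(nrow(grid)), ]
    for (tr in seq_len(nrow(grid))) {
      g <- simulate_task2_trial(profile, spec, grid$orientation[tr])
      trials[[tr]] <- g
      sched[[tr]] <- data.frame(trial_id = tr, t_on = t_cursor,
                                t_off = t_cursor + plan$stim_s,
                                orientation = grid$orientation[tr],
                                contrast = grid$contrast[tr],
                                phase_x = NA_real_, phase_y = NA_real_)
      t_cursor <- t_cursor + nrow(g) * dt
    }
  } else {
    plan <- spec$trial_plan$task3
    for (tr in seq_len(plan$n_trials)) {
      ph <- stats::runif(2, 0, 2 * pi)
      g3 <- simulate_task3_trial(profile, spec, ph)
      trials[[tr]] <- g3$gaze
      sched[[tr]] <- data.frame(trial_id = tr,
                                t_on = t_cursor + plan$prefix_s,
                                t_off = t_cursor + plan$prefix_s + plan$duration_s,
                                orientation = NA_real_, contrast = NA_real_,
                                phase_x = ph[1], phase_y = ph[2])
      t_cursor <- t_cursor + nrow(g3$gaze) * dt
    }
  }
  latent <- do.call(rbind, trials)
  samples <- emit_binocular(latent, spec, profile, eye_noise = eye_noise)
  schedule <- do.call(rbind, sched)
  schedule$task_id <- task_id
  samples$task_id <- task_id
  list(samples = samples, schedule = schedule)
}

#' Simulate a labeled cohort
#'
#' Generates `n_per_group` control and amblyopia subjects with binocular gaze
#' for all three tasks, clinical covariates, trial schedules and the artifact
#' audit. Fully deterministic given `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param tasks which tasks to simulate (default all three).
#' @param eye_noise passed to [simulate_subject_gaze()].
#' @return list with `gaze` (sample table across subjects), `schedule`,
#'   `clinical` (one row per subject), and `profiles` (latent parameters, for
#'   parameter-recovery checks).
#' @export
simulate_cohort <- function(spec, tasks = 1:3, eye_noise = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  groups <- rep(c("control", "amblyopia"), each = spec$n_per_group)
  profiles <- lapply(groups, function(g) draw_subject_profile(g))
  ids <- sprintf("S%03d", seq_along(groups))
  gaze <- list(); sched <- list(); clin <- list()
  for (i in seq_along(ids)) {
    prof <- profiles[[i]]
    for (tk in tasks) {
      subseed <- (spec$seed * 131L + i * 7919L + tk * 104729L) %% 2147483647L
      res <- simulate_subject_gaze(prof, spec, tk, subseed, eye_noise = eye_noise)
      res$samples$subject_id <- ids[i]
      res$samples$group <- prof$group
      res$schedule$subject_id <- ids[i]
      gaze[[length(gaze) + 1]] <- res$samples
      sched[[length(sched) + 1]] <- res$schedule
    }
    clin[[i]] <- data.frame(
      subject_id = ids[i], group = prof$group, age = prof$age, sex = prof$sex,
      bcva_amblyopic = prof$bcva_amblyopic, bcva_fellow = prof$bcva_fellow,
      iod = prof$bcva_amblyopic - prof$bcva_fellow,
      se_worse = prof$se_worse, se_better = prof$se_better,
      stereo_arcsec = prof$stereo_arcsec,
      etiology = prof$etiology, amblyopic_side = prof$amblyopic_side
    )
  }
  names(profiles) <- ids
  list(spec = spec,
       gaze = do.call(rbind, gaze),
       schedule = do.call(rbind, sched),
       clinical = do.call(rbind, clin),
       profiles = profiles)
}
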