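# Oculomotor event detection: I-DT fixations, saccade-like events, catch-up
# saccades, pursuit onset latency.

#' I-DT fixation segmentation
#'
#' Dispersion-threshold identification: maximal windows whose dispersion
#' (x-range + y-range) stays at or below the threshold for at least the
#' minimum duration, grown greedily left to right. Missing samples break
#' candidate windows. Duration of an n-sample window is n/rate.
#'
#' @param t,x,y trial samples (degrees); NA positions are window breakers.
#' @param dispersion_threshold degrees (default 1.0).
#' @param min_duration_s seconds (default 0.1).
#' @param screen a [screen_geometry()] for the display-grid cell.
#' @return data.frame with one row per fixation: start/end indices and times,
#'   duration (ms), centroid, RMS dispersion (root mean square distance to the
#'   centroid), and the 8x6 display-grid cell of the centroid.
#' @export
idt_fixations <- function(t, x, y, dispersion_threshold = 1.0,
                          min_duration_s = 0.1, screen = screen_geometry()) {
  n <- length(x)
  dt <- if (n > 1) stats::median(diff(t)) else 1 / 30
  min_n <- max(1L, ceiling(min_duration_s / dt))
  starts <- ends <- integer(0)
  ok <- is.finite(x) & is.finite(y)
  i <- 1L
  while (i <= n - min_n + 1L) {
    if (!ok[i]) { i <- i + 1L; next }
    # grow the window while dispersion stays within threshold
    xmin <- x[i]; xmax <- x[i]; ymin <- y[i]; ymax <- y[i]
    j <- i
    while (j < n && ok[j + 1L]) {
      nx <- x[j + 1L]; ny <- y[j + 1L]
      xmn <- min(xmin, nx); xmx <- max(xmax, nx)
      ymn <- min(ymin, ny); ymx <- max(ymax, ny)
      if ((xmx - xmn) + (ymx - ymn) > dispersion_threshold) break
      xmin <- xmn; xmax <- xmx; ymin <- ymn; ymax <- ymx
      j <- j + 1L
    }
    if (j - i + 1L >= min_n) {
      starts <- c(starts, i); ends <- c(ends, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  nf <- length(starts)
  cx <- cy <- rms <- numeric(nf)
  for (k in seq_len(nf)) {
    idx <- starts[k]:ends[k]
    cx[k] <- mean(x[idx]); cy[k] <- mean(y[idx])
    rms[k] <- sqrt(mean((x[idx] - cx[k])^2 + (y[idx] - cy[k])^2))
  }
  data.frame(start = starts, end = ends,
             t_start = t[starts], t_end = t[ends],
             duration_ms = (ends - starts + 1L) * dt * 1000,
             cx = cx, cy = cy, rms = rms,
             cell = if (nf) gs_cell_of(cx, cy, screen) else integer(0))
}

# raw forward-difference speed; value at index k describes the interval k->k+1
gs_raw_speed <- function(t, x, y) {
  sp <- sqrt(diff(x)^2 + diff(y)^2) / diff(t)
  c(sp, NA_real_)
}

#' Saccade-like event detection by velocity thresholding
#'
#' One event per maximal run of samples whose instantaneous speed exceeds the
#' threshold. With the default raw forward-difference signal, the run of
#' supra-threshold intervals `a..b` spans the motion from sample `a` to sample
#' `b+1`, and the amplitude is the position change between the samples
#' immediately before and after the crossing. Events abutting the segment
#' edges (no flanking sub-threshold sample) are discarded. Amplitude classes:
#' small corrective (0.3 to 1.0 deg), catch-up candidate (> 1.5 deg), other.
#'
#' @param t,x,y cleaned positions (pre-smoothing for the default signal).
#' @param speed precomputed speed signal; defaults to raw forward differences
#'   of `x`,`y`. Pass a smoothed central-difference speed to switch signals.
#' @param speed_threshold deg/s (default 60).
#' @param signal `"raw_forward"` (interval-indexed) or `"central"`
#'   (sample-indexed) interpretation of `speed`.
#' @return data.frame with onset/offset flank indices, amplitude, peak speed
#'   and class.
#' @export
saccade_like_events <- function(t, x, y, speed = NULL, speed_threshold = 60,
                                signal = c("raw_forward", "central")) {
  signal <- match.arg(signal)
  n <- length(x)
  if (is.null(speed)) speed <- gs_raw_speed(t, x, y)
  supra <- is.finite(speed) & speed > speed_threshold
  r <- rle(supra)
  rends <- cumsum(r$lengths); rstarts <- rends - r$lengths + 1L
  onset <- offset <- integer(0); amp <- pk <- numeric(0)
  for (j in which(r$values)) {
    a <- rstarts[j]; b <- rends[j]
    if (signal == "raw_forward") {
      # supra-threshold intervals a..b span the motion from sample a to b+1;
      # require a sub-threshold interval on both sides (edge events discarded)
      if (a < 2L || b > n - 2L) next
      pre <- a; post <- b + 1L
    } else {
      if (a < 2L || b > n - 1L) next
      pre <- a - 1L; post <- b + 1L
    }
    if (!is.finite(x[pre]) || !is.finite(x[post])) next
    onset <- c(onset, pre); offset <- c(offset, post)
    amp <- c(amp, sqrt((x[post] - x[pre])^2 + (y[post] - y[pre])^2))
    pk <- c(pk, max(speed[a:b]))
  }
  cls <- ifelse(amp >= 0.3 & amp <= 1.0, "small_corrective",
                ifelse(amp > 1.5, "catch_up_candidate", "other"))
  data.frame(onset = onset, offset = offset, amplitude = amp,
             peak_speed = pk, class = as.character(cls))
}

#' Count catch-up saccades during pursuit
#'
#' Catch-up saccades are detected events with amplitude > 1.5 deg that
#' strictly reduce the instantaneous gaze-target position error between the
#' nearest valid samples before onset and after offset.
#'
#' @param events output of [saccade_like_events()].
#' @param x,y gaze positions aligned with `tx`,`ty`.
#' @param tx,ty target positions, frame-aligned with the gaze.
#' @return integer count.
#' @export
catch_up_saccades <- function(events, x, y, tx, ty) {
  if (length(x) != length(tx)) stop("gaze and target must be frame-aligned")
  if (!nrow(events)) return(0L)
  err <- sqrt((x - tx)^2 + (y - ty)^2)
  cnt <- 0L
  for (i in seq_len(nrow(events))) {
    if (events$amplitude[i] <= 1.5) next
    pre <- events$onset[i]; post <- events$offset[i]
    while (pre >= 1 && !is.finite(err[pre])) pre <- pre - 1L
    while (post <= length(err) && !is.finite(err[post])) post <- post + 1L
    if (pre < 1 || post > length(err)) next
    if (err[post] < err[pre]) cnt <- cnt + 1L
  }
  cnt
}

#' Pursuit onset latency
#'
#' First time after motion onset at which gaze speed exceeds the speed gate
#' and the gaze velocity is directionally consistent with the target velocity
#' (positive dot product) for at least `run_length` consecutive samples.
#'
#' @param t sample times (s), with motion onset at `t_onset`.
#' @param vx,vy gaze velocity (deg/s).
#' @param tvx,tvy target velocity, frame-aligned.
#' @param t_onset motion onset time (s).
#' @param speed_gate deg/s (default 5).
#' @param run_length consecutive samples required (default 3).
#' @return latency in ms, or NA if the criterion is never met.
#' @export
pursuit_onset_latency <- function(t, vx, vy, tvx, tvy, t_onset = t[1],
                                  speed_gate = 5, run_length = 3L) {
  sp <- sqrt(vx^2 + vy^2)
  good <- is.finite(sp) & sp > speed_gate & (vx * tvx + vy * tvy) > 0 &
    t >= t_onset
  good[is.na(good)] <- FALSE
  r <- rle(good)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= run_length)
  if (!length(hit)) return(NA_real_)
  (t[starts[hit[1]]] - t_onset) * 1000
}
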