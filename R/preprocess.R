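# Preprocessing: pixels -> degrees, cyclopean stream construction, validity
# screening, gap interpolation, trial QC, Savitzky-Golay smoothing and
# central-difference velocity.

#' Convert screen pixels to degrees of visual angle
#'
#' Signed per-axis arctangent about the screen center with a perpendicular
#' viewing axis: `deg = atan(physical offset / viewing distance)`. Pixel input
#' uses the raster convention (origin top-left, y down); degree output has the
#' origin at screen center, x rightward, y upward.
#'
#' @param px,py pixel coordinates (vectors).
#' @param screen a [screen_geometry()].
#' @return data.frame with `x_deg`, `y_deg`.
#' @export
px_to_deg <- function(px, py, screen) {
  if (screen$distance_cm <= 0) stop("viewing distance must be positive")
  dx_cm <- (px - screen$width_px / 2) * screen$pitch_x
  dy_cm <- (screen$height_px / 2 - py) * screen$pitch_y
  data.frame(x_deg = atan(dx_cm / screen$distance_cm) * 180 / pi,
             y_deg = atan(dy_cm / screen$distance_cm) * 180 / pi)
}

#' Build a monocular or cyclopean gaze stream from binocular samples
#'
#' The cyclopean stream is the sample-wise mean of the two eye positions when
#' both are valid; when only one eye is valid that eye's sample is used; when
#' neither is valid the sample is missing. `both_valid_only` keeps only
#' timestamps at which both eyes are valid. For eye-specific streams of control
#' subjects, the "amblyopic" eye resolves to the worse-acuity eye (ties to the
#' left) so that every subject has a defined stream.
#'
#' @param rec data.frame with `lx_px, ly_px, l_valid, rx_px, ry_px, r_valid`
#'   (or already-converted `lx, ly, rx, ry` in degrees via `unit = "deg"`).
#' @param stream_kind one of `"cyclopean"`, `"amblyopic_eye"`, `"fellow_eye"`,
#'   `"both_valid_only"`.
#' @param amblyopic_side `"left"` or `"right"`; required for eye-specific kinds.
#' @param screen a [screen_geometry()] used for the pixel-to-degree conversion.
#' @return data.frame with `t_s`, `x`, `y` (degrees; NA when missing) and
#'   `valid`.
#' @export
build_stream <- function(rec, stream_kind = c("cyclopean", "amblyopic_eye",
                                              "fellow_eye", "both_valid_only"),
                         amblyopic_side = NULL, screen = screen_geometry()) {
  stream_kind <- match.arg(stream_kind)
  L <- px_to_deg(rec$lx_px, rec$ly_px, screen)
  R <- px_to_deg(rec$rx_px, rec$ry_px, screen)
  lv <- rec$l_valid == 1 & is.finite(L$x_deg)
  rv <- rec$r_valid == 1 & is.finite(R$x_deg)
  if (stream_kind %in% c("amblyopic_eye", "fellow_eye")) {
    if (is.null(amblyopic_side)) stop("amblyopic_side required for eye-specific streams")
    use_left <- (amblyopic_side == "left") == (stream_kind == "amblyopic_eye")
    x <- if (use_left) L$x_deg else R$x_deg
    y <- if (use_left) L$y_deg else R$y_deg
    valid <- if (use_left) lv else rv
  } else if (stream_kind == "both_valid_only") {
    valid <- lv & rv
    x <- (L$x_deg + R$x_deg) / 2
    y <- (L$y_deg + R$y_deg) / 2
  } else {
    valid <- lv | rv
    x <- ifelse(lv & rv, (L$x_deg + R$x_deg) / 2, ifelse(lv, L$x_deg, R$x_deg))
    y <- ifelse(lv & rv, (L$y_deg + R$y_deg) / 2, ifelse(lv, L$y_deg, R$y_deg))
  }
  x[!valid] <- NA_real_; y[!valid] <- NA_real_
  data.frame(t_s = rec$t_s, x = x, y = y, valid = valid)
}

#' Flag invalid samples
#'
#' Marks device-invalid samples, samples outside the display region, samples
#' bounding an inter-sample displacement whose raw speed exceeds the velocity
#' limit (glitch rejection on the unsmoothed stream, forward differences), and
#' everything within a margin of frames around any invalid run (blink-edge
#' artifacts).
#'
#' @param stream output of [build_stream()].
#' @param screen a [screen_geometry()] giving the display bounds in degrees.
#' @param velocity_limit raw speed limit in deg/s (default 1000).
#' @param margin frames to exclude around invalid runs (default 1).
#' @return logical vector, TRUE where invalid.
#' @export
flag_invalid <- function(stream, screen = screen_geometry(),
                         velocity_limit = 1000, margin = 1L) {
  n <- nrow(stream)
  bad <- !stream$valid | !is.finite(stream$x)
  off <- !bad & (abs(stream$x) > screen$half_w_deg | abs(stream$y) > screen$half_h_deg)
  bad <- bad | off
  dtv <- diff(stream$t_s)
  sp <- sqrt(diff(stream$x)^2 + diff(stream$y)^2) / dtv
  fast <- which(is.finite(sp) & sp > velocity_limit)
  bad[fast] <- TRUE
  bad[fast + 1L] <- TRUE
  if (margin > 0 && any(bad)) {
    idx <- which(bad)
    for (m in seq_len(margin)) {
      bad[pmax(1L, idx - m)] <- TRUE
      bad[pmin(n, idx + m)] <- TRUE
    }
  }
  bad
}

#' Linearly interpolate short interior gaps
#'
#' Bridges interior missing runs of at most `max_gap_samples` samples between
#' their flanking valid samples; longer gaps and gaps touching the segment
#' edges remain missing. Originally valid samples are never altered.
#'
#' @param x,y position vectors with NA at missing samples.
#' @param missing logical mask of missing samples.
#' @param max_gap_samples largest bridgeable run (default 6, i.e. 200 ms at 30 Hz).
#' @return list with filled `x`, `y` and the updated `missing` mask.
#' @export
interpolate_gaps <- function(x, y, missing = !is.finite(x), max_gap_samples = 6L) {
  n <- length(x)
  r <- rle(missing)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    len <- r$lengths[j]
    if (len > max_gap_samples) next
    a <- starts[j] - 1L; b <- ends[j] + 1L
    if (a < 1L || b > n) next       # edge gap: no flanking anchor
    w <- seq_len(len) / (len + 1L)
    idx <- starts[j]:ends[j]
    x[idx] <- x[a] + w * (x[b] - x[a])
    y[idx] <- y[a] + w * (y[b] - y[a])
    missing[idx] <- FALSE
  }
  list(x = x, y = y, missing = missing)
}

#' Trial-level quality control
#'
#' A trial is retained iff its invalid fraction is at most the threshold
#' (strictly more than 30 percent invalid excludes; exactly 30 percent is
#' retained).
#'
#' @param invalid logical mask after flagging (before interpolation).
#' @param threshold exclusion threshold as a proportion (default 0.30).
#' @return list with `invalid_fraction` and `retained`.
#' @export
qc_trial <- function(invalid, threshold = 0.30) {
  if (length(invalid) == 0) return(list(invalid_fraction = 1, retained = FALSE))
  f <- mean(invalid)
  list(invalid_fraction = f, retained = f <= threshold)
}

#' Savitzky-Golay smoothing and central-difference velocity
#'
#' Applies local least-squares polynomial smoothing (default window 5 samples,
#' order 2) to each contiguous valid run; runs shorter than the window pass
#' through unsmoothed. Velocity is the central finite difference of the
#' smoothed positions, defined only at samples whose two neighbours lie in the
#' same valid run. A `"lowpass"` alternative (moving average of the same window
#' length) is available for the robustness grid.
#'
#' @param x,y position vectors with NA at missing samples.
#' @param dt inter-sample interval in seconds.
#' @param window,polyorder filter parameters.
#' @param method `"sgolay"` or `"lowpass"`.
#' @return data.frame with `xs`, `ys` (smoothed), `vx`, `vy` (deg/s), `speed`.
#' @export
smooth_and_differentiate <- function(x, y, dt, window = 5L, polyorder = 2L,
                                     method = c("sgolay", "lowpass")) {
  method <- match.arg(method)
  if (method == "sgolay" && polyorder >= window) stop("polyorder must be < window")
  n <- length(x)
  xs <- x; ys <- y
  ok <- is.finite(x) & is.finite(y)
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (j in seq_along(r$values)) {
    if (!r$values[j] || r$lengths[j] < window) next
    idx <- starts[j]:ends[j]
    if (method == "sgolay") {
      xs[idx] <- signal::sgolayfilt(x[idx], p = polyorder, n = window)
      ys[idx] <- signal::sgolayfilt(y[idx], p = polyorder, n = window)
    } else {
      k <- rep(1 / window, window)
      pad <- (window - 1L) / 2L
      padv <- function(v) c(rep(v[1], pad), v, rep(v[length(v)], pad))
      xs[idx] <- stats::filter(padv(x[idx]), k, sides = 2)[(pad + 1L):(pad + length(idx))]
      ys[idx] <- stats::filter(padv(y[idx]), k, sides = 2)[(pad + 1L):(pad + length(idx))]
    }
  }
  vx <- vy <- rep(NA_real_, n)
  for (j in seq_along(r$values)) {
    if (!r$values[j] || r$lengths[j] < 3L) next
    idx <- starts[j]:ends[j]
    core <- idx[-c(1L, length(idx))]
    vx[core] <- (xs[core + 1L] - xs[core - 1L]) / (2 * dt)
    vy[core] <- (ys[core + 1L] - ys[core - 1L]) / (2 * dt)
  }
  data.frame(xs = xs, ys = ys, vx = vx, vy = vy,
             speed = sqrt(vx^2 + vy^2))
}

#' Preprocess one trial segment
#'
#' Runs the full chain (stream construction is done by the caller): flagging,
#' interpolation, QC, smoothing, velocity. Raw positions are kept alongside
#' smoothed ones because event detection uses the raw stream by default.
#'
#' @param stream output of [build_stream()] already sliced to one trial.
#' @param screen a [screen_geometry()].
#' @param qc_threshold trial exclusion threshold on the invalid fraction.
#' @param velocity_limit,margin see [flag_invalid()].
#' @param smooth_window,smooth_polyorder,smooth_method see
#'   [smooth_and_differentiate()].
#' @return list of class `trial_segment` with positions, velocities, masks and
#'   QC results.
#' @export
preprocess_trial <- function(stream, screen = screen_geometry(),
                             qc_threshold = 0.30, velocity_limit = 1000,
                             margin = 1L, smooth_window = 5L,
                             smooth_polyorder = 2L, smooth_method = "sgolay") {
  if (nrow(stream) == 0) {
    return(structure(list(retained = FALSE, invalid_fraction = 1,
                          reason = "empty segment"), class = "trial_segment"))
  }
  inv <- flag_invalid(stream, screen, velocity_limit, margin)
  qc <- qc_trial(inv, qc_threshold)
  x <- stream$x; y <- stream$y
  x[inv] <- NA_real_; y[inv] <- NA_real_
  gap <- interpolate_gaps(x, y, missing = inv)
  dt <- stats::median(diff(stream$t_s))
  sm <- smooth_and_differentiate(gap$x, gap$y, dt, smooth_window,
                                 smooth_polyorder, smooth_method)
  structure(list(t_s = stream$t_s, x = gap$x, y = gap$y,
                 xs = sm$xs, ys = sm$ys, vx = sm$vx, vy = sm$vy,
                 speed = sm$speed, missing = gap$missing, flagged = inv,
                 invalid_fraction = qc$invalid_fraction, retained = qc$retained,
                 dt = dt),
            class = "trial_segment")
}
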