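#' Sinusoidal pursuit target trajectory
#'
#' Two-dimensional Lissajous path used by the smooth-pursuit task:
#' `x(t) = 15 sin(2 pi f_x t + phi_x)`, `y(t) = 7.5 sin(2 pi f_y t + phi_y)`
#' (degrees of visual angle, origin at screen center). The default frequencies
#' (0.08 Hz horizontal, 0.16 Hz vertical) give a peak tangential speed of
#' approximately 10 deg/s. Velocities are analytic derivatives, not finite
#' differences.
#'
#' @param duration trajectory duration in seconds.
#' @param sampling_rate sampling rate in Hz.
#' @param frequencies length-2 numeric, horizontal and vertical frequency (Hz).
#' @param phases length-2 numeric, phase offsets (radians).
#' @param amplitudes length-2 numeric, half-amplitudes in degrees.
#' @return list of class `target_trajectory` with `t`, `x`, `y`, `vx`, `vy`
#'   (velocities in deg/s) and the generating parameters.
#' @export
make_pursuit_trajectory <- function(duration, sampling_rate = 30,
                                    frequencies = c(0.08, 0.16),
                                    phases = c(0, 0),
                                    amplitudes = c(15, 7.5)) {
  if (duration <= 0) stop("duration must be positive")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (any(frequencies <= 0)) stop("frequencies must be positive")
  t <- seq(0, duration - 1 / sampling_rate, by = 1 / sampling_rate)
  wx <- 2 * pi * frequencies[1]; wy <- 2 * pi * frequencies[2]
  out <- list(t = t,
              x = amplitudes[1] * sin(wx * t + phases[1]),
              y = amplitudes[2] * sin(wy * t + phases[2]),
              vx = amplitudes[1] * wx * cos(wx * t + phases[1]),
              vy = amplitudes[2] * wy * cos(wy * t + phases[2]),
              frequencies = frequencies, phases = phases,
              amplitudes = amplitudes, sampling_rate = sampling_rate)
  class(out) <- "target_trajectory"
  out
}

#' Evaluate target position/velocity at arbitrary times
#' @param traj a [make_pursuit_trajectory()] object.
#' @param t numeric vector of times (s).
#' @return data.frame with x, y, vx, vy.
#' @export
eval_trajectory <- function(traj, t) {
  wx <- 2 * pi * traj$frequencies[1]; wy <- 2 * pi * traj$frequencies[2]
  data.frame(
    x = traj$amplitudes[1] * sin(wx * t + traj$phases[1]),
    y = traj$amplitudes[2] * sin(wy * t + traj$phases[2]),
    vx = traj$amplitudes[1] * wx * cos(wx * t + traj$phases[1]),
    vy = traj$amplitudes[2] * wy * cos(wy * t + traj$phases[2])
  )
}
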