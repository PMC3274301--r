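#' Construct a two-sensor stream object
#'
#' @param t time grid in seconds.
#' @param a1x,a1y,a2x,a2y equivalent accelerations of sensors S1 and S2
#'   resolved in the rod-local frame, m/s^2.
#' @param fs sampling rate in Hz.
#' @param mount a [mount_spec()].
#' @param segment optional segment label.
#' @param standing_windows optional list of `c(start, end)` still windows.
#' @return An object of class `sensor_stream`.
#' @export
sensor_stream <- function(t, a1x, a1y, a2x, a2y, fs, mount = mount_spec(),
                          segment = NA_character_, standing_windows = NULL) {
  n <- length(t)
  if (any(vapply(list(a1x, a1y, a2x, a2y), length, 1L) != n)) {
    stop("all channels must have the same length as t", call. = FALSE)
  }
  structure(list(t = t, a1x = a1x, a1y = a1y, a2x = a2x, a2y = a2y,
                 fs = fs, mount = mount, segment = segment,
                 standing_windows = standing_windows),
            class = "sensor_stream")
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("sensor_stream: %d samples at %g Hz (%.2f s), l = %g m, segment = %s\n",
              length(x$t), x$fs, length(x$t) / x$fs, x$mount$l, x$segment))
  invisible(x)
}

#' Forward-model the two accelerometers on a rigid rod
#'
#' Computes the noise-free equivalent accelerations `a_i = r_i'' - g` of the
#' two sensors at positions `r_1 = r_0 - l/2` and `r_2 = r_0 + l/2` along the
#' rod axis, resolved in the rod-local frame. The local frame has its y axis
#' along the rod (from S1 toward S2) and is obtained from the fixed frame by
#' rotation through the segment angle `phi`; with gravity `(0, -g)` a static
#' upright rod therefore reads `(0, +g)` on both sensors, which is what makes
#' static inclinometry well defined.
#'
#' @param traj a [segment_trajectory()].
#' @param mount a [mount_spec()]; a mounting misalignment rotates the rod
#'   (and both sensors) relative to the true segment angle.
#' @param gravity magnitude of gravity in m/s^2 (default 9.81).
#' @return A noise-free [sensor_stream()].
#' @export
forward_accelerometer <- function(traj, mount = mount_spec(), gravity = GRAVITY) {
  stopifnot(inherits(traj, "segment_trajectory"))
  if (length(traj$t) < 3L) {
    stop("need at least 3 samples to differentiate", call. = FALSE)
  }
  phi <- traj$phi + mount$mis_angle
  cphi <- cos(phi); sphi <- sin(phi)
  # second derivative of the rod-local y axis expressed in world coordinates
  ddiy_x <- traj$ddphi * cphi - traj$dphi^2 * sphi
  ddiy_y <- -traj$ddphi * sphi - traj$dphi^2 * cphi
  half_l <- mount$l / 2
  gx <- 0; gy <- -gravity
  # world-frame equivalent accelerations
  w1x <- traj$ddr0x - half_l * ddiy_x - gx
  w1y <- traj$ddr0y - half_l * ddiy_y - gy
  w2x <- traj$ddr0x + half_l * ddiy_x - gx
  w2y <- traj$ddr0y + half_l * ddiy_y - gy
  # resolve in the rod-local frame: x_local = (cos, -sin), y_local = (sin, cos)
  sensor_stream(
    t = traj$t,
    a1x = w1x * cphi - w1y * sphi, a1y = w1x * sphi + w1y * cphi,
    a2x = w2x * cphi - w2y * sphi, a2y = w2x * sphi + w2y * cphi,
    fs = traj$fs, mount = mount)
}

#' Apply sensor noise, bias drift, clipping and ADC quantization
#'
#' Corrupts a noise-free stream the way the modeled 12-bit digital
#' accelerometers would: per-channel i.i.d. Gaussian noise, a per-channel
#' random-walk bias (MEMS bias instability), clipping to the full-scale
#' range, and uniform quantization. Deterministic given the seed.
#'
#' @param stream a [sensor_stream()].
#' @param config a [gait_config()] supplying `noise_sd`, `bias_walk_sd`,
#'   `adc_bits`, `adc_range_g` and the default seed.
#' @param seed RNG seed; defaults to `config$seed`.
#' @return The corrupted [sensor_stream()].
#' @export
corrupt_stream <- function(stream, config, seed = config$seed) {
  stopifnot(inherits(stream, "sensor_stream"))
  n <- length(stream$t)
  out <- stream
  chans <- c("a1x", "a1y", "a2x", "a2y")
  step_sd <- config$bias_walk_sd / sqrt(stream$fs)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  for (ch in chans) {
    x <- out[[ch]]
    if (config$noise_sd > 0) x <- x + rnorm(n, 0, config$noise_sd)
    if (config$bias_walk_sd > 0) x <- x + cumsum(rnorm(n, 0, step_sd))
    out[[ch]] <- x
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  full <- config$adc_range_g * GRAVITY
  for (ch in chans) {
    x <- pmin(pmax(out[[ch]], -full), full)
    if (is.finite(config$adc_bits)) {
      q <- 2 * full / 2^config$adc_bits
      x <- round(x / q) * q
    }
    out[[ch]] <- x
  }
  out
}

# heel-strike impact bursts: Gaussian-windowed acceleration transients at
# each foot contact, mostly common-mode (whole-rod shake) with a small
# differential component standing in for rod vibration. Not part of the
# ground-truth angle.
add_impacts <- function(stream, impact_times, amp, width, diff_frac,
                        attenuation = 1, seed = 1L) {
  if (amp <= 0 || length(impact_times) == 0) return(stream)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  dirs <- runif(length(impact_times), 0, 2 * pi)
  signs <- sample(c(-1, 1), length(impact_times), replace = TRUE)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  t <- stream$t
  for (i in seq_along(impact_times)) {
    burst <- attenuation * amp * exp(-(t - impact_times[i])^2 / (2 * width^2))
    cx <- cos(dirs[i]) * burst
    cy <- sin(dirs[i]) * burst
    dx <- signs[i] * diff_frac * burst / 2
    stream$a1x <- stream$a1x + cx - dx
    stream$a2x <- stream$a2x + cx + dx
    stream$a1y <- stream$a1y + cy
    stream$a2y <- stream$a2y + cy
  }
  stream
}

#' Simulate a complete instrumented gait trial
#'
#' Generates ground-truth trajectories, forward-models the two-sensor rod on
#' each segment, optionally injects heel-strike impact bursts, and applies
#' sensor corruption. The result bundles the measured streams with the exact
#' ground-truth angles, stride boundaries and standing windows.
#'
#' @param config a [gait_config()].
#' @param gravity gravity magnitude in m/s^2.
#' @return An object of class `gait_trial`: list with `streams` (named list
#'   of [sensor_stream()]), `truth` (data frame with `time_s`, per-segment
#'   `phi_*_deg`, `knee_deg`, `ankle_deg`), `stride_bounds`,
#'   `standing_windows`, `config`.
#' @export
simulate_trial <- function(config, gravity = GRAVITY) {
  traj <- generate_gait_trajectories(config)
  sw <- attr(traj, "standing_windows")
  strides <- attr(traj, "stride_bounds")
  segs <- c("thigh", "shank", "foot")
  atten <- c(thigh = 0.3, shank = 0.6, foot = 1)
  streams <- list()
  for (i in seq_along(segs)) {
    s <- segs[i]
    st <- forward_accelerometer(traj[[s]], config$mount, gravity)
    st$segment <- s
    st$standing_windows <- sw
    if (config$impact_amp > 0) {
      st <- add_impacts(st, head(strides, -1), config$impact_amp,
                        config$impact_width_s, config$impact_diff_frac,
                        attenuation = atten[[s]],
                        seed = config$seed + 7000L + i)
    }
    streams[[s]] <- corrupt_stream(st, config, seed = config$seed + 1000L * i)
  }
  r2d <- 180 / pi
  truth <- data.frame(
    time_s = traj$thigh$t,
    phi_thigh_deg = traj$thigh$phi * r2d,
    phi_shank_deg = traj$shank$phi * r2d,
    phi_foot_deg = traj$foot$phi * r2d,
    knee_deg = (traj$thigh$phi - traj$shank$phi) * r2d,
    ankle_deg = (traj$shank$phi - traj$foot$phi) * r2d
  )
  structure(list(streams = streams, truth = truth, trajectories = traj,
                 stride_bounds = strides, standing_windows = sw,
                 config = config),
            class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  print(x$config)
  cat(sprintf("  truth ranges: knee %.1f deg p-p, ankle %.1f deg p-p\n",
              diff(range(x$truth$knee_deg)), diff(range(x$truth$ankle_deg))))
  invisible(x)
}
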