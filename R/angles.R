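#' Differential signals of a two-sensor rod
#'
#' Differencing the two accelerometers on the rod cancels gravity and the
#' acceleration of the rod centroid exactly; what remains is the second
#' derivative of the inter-sensor vector. Resolved in the rod-local frame,
#' the perpendicular (x) component divided by the inter-sensor distance `l`
#' estimates the angular acceleration `alpha`, and the along-rod (y)
#' component divided by `l` estimates `-omega^2`.
#'
#' @param stream a [sensor_stream()].
#' @return Object of class `differential_signals` with fields `t`,
#'   `alpha_est` (rad/s^2), `negsqomega_est` (rad^2/s^2, non-positive during
#'   smooth motion up to noise), `fs`, `l`.
#' @export
differential_signals <- function(stream) {
  stopifnot(inherits(stream, "sensor_stream"))
  l <- stream$mount$l
  if (is.null(l) || l <= 0) {
    stop("inter-sensor distance `l` must be positive", call. = FALSE)
  }
  structure(list(t = stream$t,
                 alpha_est = (stream$a2x - stream$a1x) / l,
                 negsqomega_est = (stream$a2y - stream$a1y) / l,
                 fs = stream$fs, l = l),
            class = "differential_signals")
}

#' Cadence-adaptive cutoff selection
#'
#' For knee angles the useful cutoff range is one third to one half of the
#' gait-cycle frequency; the default pick is the geometric midpoint
#' `f_gc/sqrt(6)`. Ankle angles tolerate (and benefit from) a cutoff about
#' twice as high because the ankle waveform is dominated by its second
#' harmonic. Both picks respect `f0 < f_gc`.
#'
#' @param f_gc gait-cycle (stride) frequency in Hz.
#' @param joint `"knee"` or `"ankle"`.
#' @return Cutoff frequency `f0` in Hz.
#' @examples
#' select_cutoff(1, "knee")   # 0.408 Hz
#' select_cutoff(1, "ankle")  # 0.816 Hz
#' @export
select_cutoff <- function(f_gc, joint = c("knee", "ankle")) {
  joint <- match.arg(joint)
  if (!is.numeric(f_gc) || length(f_gc) != 1L || f_gc <= 0) {
    stop("`f_gc` must be a positive number", call. = FALSE)
  }
  f0 <- f_gc / sqrt(6)
  if (joint == "ankle") f0 <- 2 * f0
  f0
}

#' Estimate the gait-cycle frequency from the angular-acceleration spectrum
#'
#' During walking the angular acceleration is nearly periodic, with spectral
#' lines at integer multiples of the stride frequency. The estimator takes
#' the magnitude spectrum of the angular-acceleration estimate over the
#' walking window (Hann-windowed, zero-padded to at least 0.02 Hz
#' resolution), finds the largest peak below a ceiling, and then checks the
#' subharmonics `f/2` and `f/3` of that peak: if a subharmonic carries at
#' least `subharmonic_frac` of the peak magnitude it is taken as the stride
#' fundamental (angular acceleration weights harmonics by `omega^2`, so for
#' some segments the second harmonic is the tallest line).
#'
#' @param diff a [differential_signals()] object.
#' @param window optional `c(start, end)` in seconds restricting the analysis
#'   to the walking portion; default uses the full record.
#' @param ceiling_hz search ceiling in Hz (default 3).
#' @param floor_hz lowest admissible stride frequency in Hz (default 0.2).
#' @param resolution_hz required spectral resolution (default 0.02 Hz).
#' @param prominence required ratio of the peak to the median in-band
#'   magnitude; below it, detection fails with an error of class
#'   `gaitrod_no_gait_error` (a standing-only record has no periodicity to
#'   detect).
#' @param subharmonic_frac threshold for the fundamental-refinement step.
#' @return Estimated gait-cycle frequency `f_gc` in Hz.
#' @export
estimate_stride_frequency <- function(diff, window = NULL, ceiling_hz = 3,
                                      floor_hz = 0.2, resolution_hz = 0.02,
                                      prominence = 8, subharmonic_frac = 0.25) {
  stopifnot(inherits(diff, "differential_signals"))
  x <- diff$alpha_est
  t <- diff$t
  if (!is.null(window)) {
    keep <- t >= window[1] & t <= window[2]
    x <- x[keep]
  }
  n <- length(x)
  if (n < 16L) stop("walking window too short for spectral analysis", call. = FALSE)
  x <- (x - mean(x)) * (0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1)))
  nfft <- 2^ceiling(log2(max(n, diff$fs / resolution_hz)))
  mag <- Mod(fft(c(x, numeric(nfft - n))))[seq_len(nfft %/% 2)]
  f <- (seq_len(nfft %/% 2) - 1) * diff$fs / nfft
  band <- f >= floor_hz & f <= ceiling_hz
  mb <- mag[band]; fb <- f[band]
  i_pk <- which.max(mb)
  if (mb[i_pk] < prominence * median(mb)) {
    stop(errorCondition(
      "no periodic gait component detected in the angular-acceleration spectrum",
      class = c("gaitrod_no_gait_error", "error", "condition")))
  }
  f_pk <- fb[i_pk]
  # fundamental refinement: prefer the lowest subharmonic that is a real line
  for (k in 3:2) {
    cand <- f_pk / k
    if (cand < floor_hz) next
    near <- abs(fb - cand) <= max(0.05 * f_pk, 2 * diff$fs / nfft)
    if (any(near) && max(mb[near]) >= subharmonic_frac * mb[i_pk]) {
      return(fb[near][which.max(mb[near])])
    }
  }
  f_pk
}

#' Static inclinometric self-calibration
#'
#' While the rod is immobile each accelerometer reads the gravity vector in
#' the rod-local frame, so the rod inclination follows from
#' `atan2(-a_x, a_y)` of the time-averaged readings; the two sensors are
#' averaged. Filtering removes the static component of the reconstructed
#' angle; this calibration restores it.
#'
#' @param stream a [sensor_stream()].
#' @param window `c(start, end)` in seconds of the standing-still interval;
#'   defaults to the first annotated standing window of the stream.
#' @param min_duration minimum stillness duration in seconds (default 2).
#' @param sd_max stillness threshold: maximum per-channel standard deviation
#'   in m/s^2 (default 0.2, comfortably above sensor noise and below any
#'   actual movement).
#' @return Rod inclination in degrees.
#' @export
static_calibration <- function(stream, window = NULL, min_duration = 2,
                               sd_max = 0.2) {
  stopifnot(inherits(stream, "sensor_stream"))
  if (is.null(window)) {
    if (length(stream$standing_windows) == 0) {
      stop("no standing window supplied or annotated", call. = FALSE)
    }
    window <- stream$standing_windows[[1]]
  }
  keep <- stream$t >= window[1] & stream$t <= window[2]
  if (sum(keep) < min_duration * stream$fs) {
    stop(errorCondition(
      sprintf("calibration window shorter than %g s of data", min_duration),
      class = c("gaitrod_calibration_error", "error", "condition")))
  }
  sds <- vapply(c("a1x", "a1y", "a2x", "a2y"),
                function(ch) sd(stream[[ch]][keep]), numeric(1))
  if (any(sds > sd_max)) {
    stop(errorCondition(
      sprintf("calibration window is not still (channel SD up to %.3g m/s^2 > %.3g)",
              max(sds), sd_max),
      class = c("gaitrod_calibration_error", "error", "condition")))
  }
  incl1 <- atan2(-mean(stream$a1x[keep]), mean(stream$a1y[keep]))
  incl2 <- atan2(-mean(stream$a2x[keep]), mean(stream$a2y[keep]))
  (incl1 + incl2) / 2 * 180 / pi
}

#' Detect still windows in a sensor stream
#'
#' Rolling-window stillness detection: a window is still when every channel's
#' standard deviation stays below `sd_max`.
#'
#' @param stream a [sensor_stream()].
#' @param sd_max per-channel SD threshold in m/s^2.
#' @param win_s rolling window length in seconds (default 0.5).
#' @param min_duration minimum still duration to report, seconds.
#' @return List of `c(start, end)` windows in seconds (possibly empty).
#' @export
detect_still_windows <- function(stream, sd_max = 0.2, win_s = 0.5,
                                 min_duration = 2) {
  n <- length(stream$t)
  w <- max(3L, round(win_s * stream$fs))
  roll_sd_max <- rep(Inf, n)
  mags <- lapply(c("a1x", "a1y", "a2x", "a2y"), function(ch) stream[[ch]])
  # rolling SD via cumulative sums, per channel, take the worst channel
  worst <- rep(0, n - w + 1L)
  for (x in mags) {
    cs <- cumsum(c(0, x)); cs2 <- cumsum(c(0, x^2))
    m <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
    v <- (cs2[(w + 1):(n + 1)] - cs2[1:(n - w + 1)]) / w - m^2
    worst <- pmax(worst, sqrt(pmax(v, 0) * w / (w - 1)))
  }
  still <- worst < sd_max
  out <- list()
  r <- rle(still)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    t0 <- stream$t[starts[i]]
    t1 <- stream$t[min(n, ends[i] + w - 1L)]
    if (t1 - t0 >= min_duration) out[[length(out) + 1L]] <- c(t0, t1)
  }
  out
}

new_angle_series <- function(t, angle_deg, dc_offset_deg, kind, f0_used) {
  structure(list(t = t, angle_deg = angle_deg, dc_offset_deg = dc_offset_deg,
                 kind = kind, f0_used = f0_used),
            class = "angle_series")
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf("angle_series (%s): %d samples, f0 = %.3g Hz, DC offset %.2f deg, range [%.1f, %.1f] deg\n",
              x$kind, length(x$t), x$f0_used, x$dc_offset_deg,
              min(x$angle_deg), max(x$angle_deg)))
  invisible(x)
}

#' Reconstruct the absolute angle of one segment
#'
#' Pseudo double integration of the angular-acceleration estimate of one rod,
#' with the static offset restored from inclinometric self-calibration.
#'
#' @param stream a [sensor_stream()].
#' @param spec a [design_pseudo_integrator()] filter specification.
#' @param calib inclination offset in degrees; computed by
#'   [static_calibration()] on `standing_window` when `NULL`.
#' @param standing_window optional `c(start, end)` for the calibration.
#' @return An `angle_series` with `kind = "segment_absolute"`.
#' @export
absolute_segment_angle <- function(stream, spec, calib = NULL,
                                   standing_window = NULL) {
  d <- differential_signals(stream)
  if (is.null(calib)) calib <- static_calibration(stream, standing_window)
  ang <- pseudo_double_integrate(d$alpha_est, spec) * 180 / pi + calib
  new_angle_series(d$t, ang, calib, "segment_absolute", spec$f0)
}

#' Reconstruct a joint angle from two adjacent rods
#'
#' The joint angle is the difference of the absolute angles of the two
#' adjacent segments (knee: thigh minus shank; ankle: shank minus foot). The
#' filtering is applied to the difference of the two angular-acceleration
#' estimates - not to each segment separately - and the static offset is
#' restored from the difference of the two inclinometric calibrations, the
#' composition consistent with the linearity of the whole chain.
#'
#' @param stream_proximal,stream_distal [sensor_stream()]s of the proximal
#'   and distal segment, on a common time grid.
#' @param joint `"knee"` or `"ankle"`.
#' @param spec a [design_pseudo_integrator()] specification.
#' @param calib optional numeric `c(proximal, distal)` inclinations in
#'   degrees, else computed from each stream's standing window.
#' @param standing_window optional `c(start, end)` for the calibrations.
#' @return An `angle_series` with `kind = joint`.
#' @export
joint_angle <- function(stream_proximal, stream_distal,
                        joint = c("knee", "ankle"), spec, calib = NULL,
                        standing_window = NULL) {
  joint <- match.arg(joint)
  if (length(stream_proximal$t) != length(stream_distal$t) ||
      max(abs(stream_proximal$t - stream_distal$t)) > 1e-9) {
    stop("streams are not on a common time grid", call. = FALSE)
  }
  dp <- differential_signals(stream_proximal)
  dd <- differential_signals(stream_distal)
  if (is.null(calib)) {
    calib <- c(static_calibration(stream_proximal, standing_window),
               static_calibration(stream_distal, standing_window))
  }
  dc <- calib[1] - calib[2]
  ang <- pseudo_double_integrate(dp$alpha_est - dd$alpha_est, spec) * 180 / pi + dc
  new_angle_series(dp$t, ang, dc, joint, spec$f0)
}
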