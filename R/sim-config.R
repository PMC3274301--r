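# gravity magnitude used throughout (m/s^2)
GRAVITY <- 9.81

#' Sensor-rod mounting geometry
#'
#' @param l distance between the centers of the two accelerometers on the
#'   rod, in meters. Default 0.055 m.
#' @param mis_angle fixed mounting misalignment between the rod axis and the
#'   true segment line, in radians. Default 0.
#' @return An object of class `mount_spec`.
#' @export
mount_spec <- function(l = 0.055, mis_angle = 0) {
  if (!is.numeric(l) || length(l) != 1L || l <= 0) {
    stop("inter-sensor distance `l` must be a positive number", call. = FALSE)
  }
  structure(list(l = l, mis_angle = mis_angle), class = "mount_spec")
}

#' Default harmonic library for sagittal gait waveforms
#'
#' Per-segment truncated Fourier series (amplitude in radians, phase in
#' radians per harmonic of the stride frequency) describing the oscillatory
#' part of the absolute segment angles of thigh, shank and foot during steady
#' walking. The library is constructed from the waveforms one actually cares
#' about: the thigh excursion (about 40 degrees peak-to-peak, dominated by
#' the stride fundamental) and the knee (about 60 degrees peak-to-peak,
#' strong fundamental plus second harmonic) and ankle (about 25 degrees
#' peak-to-peak, dominated by the second harmonic, as the double-bump
#' flexion pattern of walking dictates) joint excursions. Shank and foot
#' series are derived by per-harmonic complex subtraction
#' (shank = thigh - knee, foot = shank - ankle), so the simulated joint
#' angles have exactly the intended spectra.
#'
#' @return Named list with elements `thigh`, `shank`, `foot`, each a data
#'   frame with columns `amp` (rad) and `phase` (rad), plus an attribute
#'   `stand_deg`: the standing posture of each segment in degrees.
#' @export
default_gait_harmonics <- function() {
  # h(t) = sum_k amp_k * sin(k*W*t + phase_k)  <=>  Im(c_k e^{ikWt}), c = amp*e^{i*phase}
  thigh_c <- c(0.32, 0.05, 0.020, 0.008) * exp(1i * c(0.0, 1.3, -0.8, 0.5))
  knee_c  <- c(0.40, 0.18, 0.045, 0.015) * exp(1i * c(-1.0, 0.9, 0.3, -0.6))
  ankle_c <- c(0.035, 0.155, 0.040, 0.012) * exp(1i * c(0.5, 2.0, -0.9, 0.8))
  shank_c <- thigh_c - knee_c
  foot_c  <- shank_c - ankle_c
  as_df <- function(cc) data.frame(amp = Mod(cc), phase = Arg(cc))
  out <- list(thigh = as_df(thigh_c), shank = as_df(shank_c),
              foot = as_df(foot_c))
  attr(out, "stand_deg") <- c(thigh = 0, shank = 0, foot = 90)
  out
}

#' Configuration of the synthetic gait benchmark
#'
#' Bundles every tunable of the rigid-body gait simulator: stride timing,
#' per-segment harmonic content, sensor noise and quantization, heel-strike
#' impact bursts, standing padding and the RNG seed.
#'
#' @param stride_period stride period T in seconds (gait-cycle frequency is
#'   `1/T`).
#' @param n_strides number of strides in the walking window.
#' @param fs sampling rate in Hz. Default 100.
#' @param harmonics per-segment Fourier series as produced by
#'   [default_gait_harmonics()].
#' @param rom_deg optional named numeric vector (subset of `thigh`, `shank`,
#'   `foot`): target peak-to-peak range of motion in degrees; the segment's
#'   harmonic set is rescaled to match. `NULL` (default) uses the library
#'   amplitudes as-is.
#' @param walk_speed forward speed of the hip in m/s. Default `1.4 /
#'   stride_period` (a typical 1.4 m stride length).
#' @param noise_sd accelerometer white-noise standard deviation, m/s^2 per
#'   channel. Default 0.05.
#' @param bias_walk_sd random-walk intensity of the slowly varying sensor
#'   bias, m/s^2 per sqrt(second) per channel; emulates MEMS bias
#'   instability, the error source that makes naive double integration
#'   drift. Default 0.001. The true noise figures of the modeled sensors are
#'   not documented, so both noise defaults are engineering choices.
#' @param adc_bits quantizer resolution in bits; `Inf` disables quantization.
#'   Default 12.
#' @param adc_range_g full-scale range in g; the modeled accelerometers offer
#'   2 or 6. Default 6.
#' @param standing_pad_s still standing time prepended and appended, seconds;
#'   at least 2 s is required by the self-calibration protocol. Default 2.
#' @param impact_amp peak amplitude of heel-strike acceleration bursts,
#'   m/s^2; 0 (default) disables impacts.
#' @param impact_width_s Gaussian width of each impact burst, seconds.
#' @param impact_diff_frac fraction of the burst that appears differentially
#'   between the two sensors (rod vibration) rather than as common mode.
#' @param segment_lengths named vector of segment lengths in meters used to
#'   chain thigh, shank and foot kinematically.
#' @param hip_height standing hip height in meters.
#' @param mount a [mount_spec()].
#' @param seed integer RNG seed driving noise, bias walk and impact
#'   directions.
#' @return An object of class `gait_config`.
#' @export
gait_config <- function(stride_period = 1, n_strides = 10, fs = 100,
                        harmonics = default_gait_harmonics(),
                        rom_deg = NULL,
                        walk_speed = NULL,
                        noise_sd = 0.05,
                        bias_walk_sd = 0.001,
                        adc_bits = 12, adc_range_g = 6,
                        standing_pad_s = 2,
                        impact_amp = 0, impact_width_s = 0.02,
                        impact_diff_frac = 0.25,
                        segment_lengths = c(thigh = 0.41, shank = 0.42,
                                            foot = 0.25),
                        hip_height = 0.92,
                        mount = mount_spec(),
                        seed = 1L) {
  if (stride_period <= 0) stop("`stride_period` must be positive", call. = FALSE)
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  if (n_strides < 1) stop("`n_strides` must be at least 1", call. = FALSE)
  if (standing_pad_s < 0) stop("`standing_pad_s` must be non-negative", call. = FALSE)
  if (is.finite(adc_bits) && !(adc_range_g %in% c(2, 6))) {
    stop("`adc_range_g` must be 2 or 6", call. = FALSE)
  }
  segs <- c("thigh", "shank", "foot")
  if (!all(segs %in% names(harmonics))) {
    stop("`harmonics` must contain thigh, shank and foot entries", call. = FALSE)
  }
  for (s in segs) {
    h <- harmonics[[s]]
    if (!is.data.frame(h) || nrow(h) < 1 ||
        !all(c("amp", "phase") %in% names(h))) {
      stop("each harmonic set needs a non-empty data frame with amp and phase",
           call. = FALSE)
    }
  }
  if (is.null(walk_speed)) walk_speed <- 1.4 / stride_period
  structure(list(
    stride_period = stride_period, n_strides = n_strides, fs = fs,
    harmonics = harmonics, rom_deg = rom_deg, walk_speed = walk_speed,
    noise_sd = noise_sd, bias_walk_sd = bias_walk_sd,
    adc_bits = adc_bits, adc_range_g = adc_range_g,
    standing_pad_s = standing_pad_s,
    impact_amp = impact_amp, impact_width_s = impact_width_s,
    impact_diff_frac = impact_diff_frac,
    segment_lengths = segment_lengths, hip_height = hip_height,
    mount = mount, seed = as.integer(seed)
  ), class = "gait_config")
}

#' @export
print.gait_config <- function(x, ...) {
  cat(sprintf(
    "gait benchmark: T = %.3g s (f_gc = %.3g Hz), %d strides + 2 x %.3g s standing, fs = %g Hz\n",
    x$stride_period, 1 / x$stride_period, x$n_strides, x$standing_pad_s, x$fs))
  cat(sprintf("  sensors: l = %g m, noise %.3g m/s^2, bias walk %.3g m/s^2/sqrt(s), %s-bit +/-%g g, seed %d\n",
              x$mount$l, x$noise_sd, x$bias_walk_sd,
              ifelse(is.finite(x$adc_bits), format(x$adc_bits), "inf"),
              x$adc_range_g, x$seed))
  invisible(x)
}

#' Read a gait configuration from a YAML or JSON file
#'
#' Keys mirror the arguments of [gait_config()]; `harmonics` may be given as
#' per-segment lists of `amp`/`phase` vectors; `mount` as a list with `l` and
#' `mis_angle`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A [gait_config()] object.
#' @export
read_gait_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$harmonics)) {
    raw$harmonics <- lapply(raw$harmonics, function(h) {
      as.data.frame(lapply(h, as.numeric))
    })
    if (is.null(attr(raw$harmonics, "stand_deg"))) {
      attr(raw$harmonics, "stand_deg") <-
        attr(default_gait_harmonics(), "stand_deg")
    }
  }
  if (!is.null(raw$mount)) raw$mount <- do.call(mount_spec, raw$mount)
  if (!is.null(raw$segment_lengths)) {
    raw$segment_lengths <- unlist(raw$segment_lengths)
  }
  if (!is.null(raw$rom_deg)) raw$rom_deg <- unlist(raw$rom_deg)
  do.call(gait_config, raw)
}
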