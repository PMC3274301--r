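sidecar_path <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    sub("\\.csv$", ".json", path, ignore.case = TRUE)
  } else {
    paste0(path, ".json")
  }
}

#' Write a sensor stream to CSV with a JSON metadata sidecar
#'
#' One row per sample with columns `time_s, a1x, a1y, a2x, a2y` (m/s^2), plus
#' a sidecar JSON (same path with `.json` extension) carrying the sampling
#' rate, geometry, segment label, standing windows, seed and provenance.
#'
#' @param stream a [sensor_stream()].
#' @param path output CSV path.
#' @param seed optional RNG seed to record.
#' @param provenance free-text provenance tag (e.g. `"simulated"` or
#'   `"recorded"`).
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path, seed = NULL, provenance = "simulated") {
  stopifnot(inherits(stream, "sensor_stream"))
  df <- data.frame(time_s = stream$t, a1x = stream$a1x, a1y = stream$a1y,
                   a2x = stream$a2x, a2y = stream$a2y)
  write.csv(df, path, row.names = FALSE)
  meta <- list(fs = stream$fs, l = stream$mount$l,
               mis_angle = stream$mount$mis_angle,
               segment = stream$segment,
               standing_windows = stream$standing_windows,
               seed = seed, provenance = provenance)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a sensor stream written by [write_stream()]
#'
#' Validates the header, uniform sampling (maximum jitter below 1e-6 s) and
#' the metadata sidecar, and reattaches geometry and standing windows. The
#' same reader accepts real recordings saved in this format.
#'
#' @param path CSV path; the sidecar is looked up next to it.
#' @return A [sensor_stream()].
#' @export
read_stream <- function(path) {
  if (!file.exists(path)) stop("stream file not found: ", path, call. = FALSE)
  df <- read.csv(path)
  need <- c("time_s", "a1x", "a1y", "a2x", "a2y")
  if (!all(need %in% names(df))) {
    stop("stream CSV is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  dt <- diff(df$time_s)
  if (length(dt) < 2L || any(dt <= 0) || max(abs(dt - median(dt))) > 1e-6) {
    stop("stream time grid is not uniform (jitter above 1e-6 s)", call. = FALSE)
  }
  sp <- sidecar_path(path)
  if (!file.exists(sp)) {
    stop("metadata sidecar not found: ", sp, call. = FALSE)
  }
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (is.null(meta$l) || meta$l <= 0) {
    stop("sidecar declares a non-positive inter-sensor distance", call. = FALSE)
  }
  sw <- meta$standing_windows
  if (!is.null(sw)) {
    if (is.matrix(sw)) sw <- lapply(seq_len(nrow(sw)), function(i) sw[i, ])
    if (is.numeric(sw)) sw <- list(sw)
  }
  sensor_stream(df$time_s, df$a1x, df$a1y, df$a2x, df$a2y,
                fs = if (!is.null(meta$fs)) meta$fs else 1 / median(dt),
                mount = mount_spec(meta$l,
                                   if (is.null(meta$mis_angle)) 0 else meta$mis_angle),
                segment = if (is.null(meta$segment)) NA_character_ else meta$segment,
                standing_windows = sw)
}

#' Write ground-truth angles to CSV
#'
#' @param truth the `truth` data frame of a [simulate_trial()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' Estimate knee and ankle angles from segment streams
#'
#' The estimation stage of the pipeline: estimates the gait-cycle frequency
#' from the thigh differential signal (unless given), selects the cutoffs by
#' the cadence rule, self-calibrates each segment from its standing window,
#' and reconstructs the requested joint angles. If a requested or estimated
#' cutoff does not satisfy `f0 < f_gc`, a warning is emitted and the run
#' proceeds.
#'
#' @param streams named list with `thigh`, `shank` and optionally `foot`
#'   [sensor_stream()]s on a common grid.
#' @param f0 `"auto"` (cadence rule, default) or a numeric cutoff in Hz used
#'   for the knee (the ankle uses twice the knee value).
#' @param f_gc optional known gait-cycle frequency in Hz; estimated when
#'   `NULL`.
#' @param joints character vector among `"knee"`, `"ankle"`.
#' @return List with `angles` (data frame `time_s`, `knee_deg`, `ankle_deg`
#'   as available), `report` (list: `f_gc`, per-joint `f0`, calibration
#'   offsets in degrees), and the `angle_series` objects.
#' @export
estimate_joint_angles <- function(streams, f0 = "auto", f_gc = NULL,
                                  joints = c("knee", "ankle")) {
  if (!all(c("thigh", "shank") %in% names(streams))) {
    stop("`streams` must contain at least thigh and shank", call. = FALSE)
  }
  joints <- match.arg(joints, several.ok = TRUE)
  if ("ankle" %in% joints && is.null(streams$foot)) {
    joints <- setdiff(joints, "ankle")
  }
  fs <- streams$thigh$fs
  if (is.null(f_gc)) {
    f_gc <- estimate_stride_frequency(differential_signals(streams$thigh))
  }
  f0_knee <- if (identical(f0, "auto")) select_cutoff(f_gc, "knee") else f0
  f0_ankle <- 2 * f0_knee
  if (f0_knee >= f_gc) {
    warning(sprintf(
      "knee cutoff f0 = %.3g Hz is not below f_gc = %.3g Hz; the lowest gait harmonic falls in the pass band and the reconstruction will be distorted",
      f0_knee, f_gc), call. = FALSE)
  }
  calib <- vapply(streams, static_calibration, numeric(1))
  out <- list(time_s = streams$thigh$t)
  series <- list()
  if ("knee" %in% joints) {
    spec <- design_pseudo_integrator(min(f0_knee, 0.49 * fs), fs)
    series$knee <- joint_angle(streams$thigh, streams$shank, "knee", spec,
                               calib = c(calib[["thigh"]], calib[["shank"]]))
    out$knee_deg <- series$knee$angle_deg
  }
  if ("ankle" %in% joints) {
    spec <- design_pseudo_integrator(min(f0_ankle, 0.49 * fs), fs)
    series$ankle <- joint_angle(streams$shank, streams$foot, "ankle", spec,
                                calib = c(calib[["shank"]], calib[["foot"]]))
    out$ankle_deg <- series$ankle$angle_deg
  }
  list(angles = as.data.frame(out),
       report = list(f_gc = f_gc, f0_knee = f0_knee,
                     f0_ankle = if ("ankle" %in% joints) f0_ankle else NULL,
                     calibration_deg = as.list(calib)),
       series = series)
}
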