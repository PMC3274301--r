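#' Ground-truth kinematics of one segment
#'
#' Container for the sagittal-plane trajectory of one instrumented segment:
#' absolute angle `phi` (radians, measured between the rod-local x axis and
#' the fixed horizontal x' axis; a vertical, upright rod has `phi = 0`) and
#' the rod-centroid position in the fixed frame. First and second derivatives
#' may be supplied in closed form (the gait generator does, keeping ground
#' truth exact); otherwise they are filled in by central differences.
#'
#' @param t uniform time grid in seconds.
#' @param phi absolute segment angle in radians.
#' @param r0x,r0y rod-centroid position in meters.
#' @param dphi,ddphi optional analytic first/second derivatives of `phi`.
#' @param ddr0x,ddr0y optional analytic second derivatives of the centroid.
#' @return An object of class `segment_trajectory`.
#' @export
segment_trajectory <- function(t, phi, r0x, r0y,
                               dphi = NULL, ddphi = NULL,
                               ddr0x = NULL, ddr0y = NULL) {
  n <- length(t)
  if (n < 3L) stop("need at least 3 samples to differentiate", call. = FALSE)
  if (length(phi) != n || length(r0x) != n || length(r0y) != n) {
    stop("phi, r0x, r0y must have the same length as t", call. = FALSE)
  }
  dt <- diff(t)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-9) {
    stop("time grid must be strictly increasing with constant step", call. = FALSE)
  }
  h <- dt[1]
  if (is.null(dphi)) dphi <- central_diff(phi, h)
  if (is.null(ddphi)) ddphi <- central_diff2(phi, h)
  if (is.null(ddr0x)) ddr0x <- central_diff2(r0x, h)
  if (is.null(ddr0y)) ddr0y <- central_diff2(r0y, h)
  structure(list(t = t, phi = phi, r0x = r0x, r0y = r0y,
                 dphi = dphi, ddphi = ddphi, ddr0x = ddr0x, ddr0y = ddr0y,
                 fs = 1 / h),
            class = "segment_trajectory")
}

central_diff <- function(x, h) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * h)
  d[1] <- (-3 * x[1] + 4 * x[2] - x[3]) / (2 * h)
  d[n] <- (3 * x[n] - 4 * x[n - 1] + x[n - 2]) / (2 * h)
  d
}

central_diff2 <- function(x, h) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) / h^2
  d[1] <- d[2]
  d[n] <- d[n - 1]
  d
}

# raised-cosine on/off envelope of the walking oscillation and its two
# derivatives, ramping over one stride at each end of the walking window
walk_envelope <- function(t, t_on, t_off, ramp) {
  e <- numeric(length(t))
  de <- numeric(length(t))
  dde <- numeric(length(t))
  up <- t >= t_on & t < t_on + ramp
  on <- t >= t_on + ramp & t <= t_off - ramp
  dn <- t > t_off - ramp & t <= t_off
  xu <- (t[up] - t_on) / ramp
  e[up] <- 0.5 * (1 - cos(pi * xu))
  de[up] <- 0.5 * pi / ramp * sin(pi * xu)
  dde[up] <- 0.5 * (pi / ramp)^2 * cos(pi * xu)
  e[on] <- 1
  xd <- (t_off - t[dn]) / ramp
  e[dn] <- 0.5 * (1 - cos(pi * xd))
  de[dn] <- -0.5 * pi / ramp * sin(pi * xd)
  dde[dn] <- 0.5 * (pi / ramp)^2 * cos(pi * xd)
  list(e = e, de = de, dde = dde)
}

# integral of the envelope (for hip displacement at constant walking speed)
walk_envelope_integral <- function(t, t_on, t_off, ramp) {
  ramp_int <- function(x) 0.5 * (x - (ramp / pi) * sin(pi * x / ramp))
  E <- numeric(length(t))
  up <- t >= t_on & t < t_on + ramp
  on <- t >= t_on + ramp & t <= t_off - ramp
  dn <- t > t_off - ramp & t <= t_off
  post <- t > t_off
  E[up] <- ramp_int(t[up] - t_on)
  E_up_full <- ramp_int(ramp)
  E[on] <- E_up_full + (t[on] - t_on - ramp)
  plateau <- (t_off - ramp) - (t_on + ramp)
  E[dn] <- E_up_full + plateau + (E_up_full - ramp_int(t_off - t[dn]))
  E[post] <- 2 * E_up_full + plateau
  E
}

# oscillation h(t) = sum_k amp_k sin(k W tau + phase_k) and derivatives
harmonic_series <- function(tau, harm, T) {
  W <- 2 * pi / T
  h <- dh <- ddh <- numeric(length(tau))
  for (k in seq_len(nrow(harm))) {
    A <- harm$amp[k]; ph <- harm$phase[k]; wk <- k * W
    arg <- wk * tau + ph
    h <- h + A * sin(arg)
    dh <- dh + A * wk * cos(arg)
    ddh <- ddh - A * wk^2 * sin(arg)
  }
  list(h = h, dh = dh, ddh = ddh)
}

#' Generate ground-truth gait trajectories for thigh, shank and foot
#'
#' Builds sagittal-plane trajectories of the three instrumented leg segments
#' for a trial consisting of quiet standing, `n_strides` strides of periodic
#' walking, and quiet standing again. Each segment angle is
#' `phi(t) = phi_stand + e(t) * h(t)` with `h` a truncated Fourier series in
#' the stride frequency and `e` a raised-cosine envelope that ramps over the
#' first and last stride (which the evaluation protocol excludes anyway).
#' Segment positions are chained hip -> knee -> ankle so adjacent segments
#' share joint positions, and the hip translates forward at the configured
#' walking speed. All derivatives are computed analytically, so the ground
#' truth carries no numerical differentiation error.
#'
#' @param config a [gait_config()].
#' @return A list of class `gait_trajectories` with elements `thigh`,
#'   `shank`, `foot` (each a [segment_trajectory()]), and attributes
#'   `standing_windows` (list of `c(start, end)` in seconds),
#'   `stride_bounds` (stride boundary times) and `walking_window`.
#' @export
generate_gait_trajectories <- function(config) {
  stopifnot(inherits(config, "gait_config"))
  T <- config$stride_period
  fs <- config$fs
  pad <- config$standing_pad_s
  n_samp <- round((config$n_strides * T + 2 * pad) * fs)
  t <- seq(0, n_samp - 1) / fs
  t_on <- pad
  t_off <- pad + config$n_strides * T
  ramp <- min(T, (t_off - t_on) / 2)
  env <- walk_envelope(t, t_on, t_off, ramp)
  Ewalk <- walk_envelope_integral(t, t_on, t_off, ramp)

  stand_deg <- attr(config$harmonics, "stand_deg")
  if (is.null(stand_deg)) stand_deg <- c(thigh = 0, shank = 0, foot = 90)

  segs <- c("thigh", "shank", "foot")
  phi <- dphi <- ddphi <- list()
  for (s in segs) {
    harm <- config$harmonics[[s]]
    if (!is.null(config$rom_deg) && s %in% names(config$rom_deg)) {
      hs <- harmonic_series(seq(0, T, length.out = 400), harm, T)
      pp <- diff(range(hs$h))
      harm$amp <- harm$amp * (config$rom_deg[[s]] * pi / 180) / pp
    }
    hs <- harmonic_series(t - t_on, harm, T)
    phi0 <- stand_deg[[s]] * pi / 180
    phi[[s]] <- phi0 + env$e * hs$h
    dphi[[s]] <- env$de * hs$h + env$e * hs$dh
    ddphi[[s]] <- env$dde * hs$h + 2 * env$de * hs$dh + env$e * hs$ddh
  }

  # rod-local y axis in world coordinates and its second derivative
  iy <- function(s) list(x = sin(phi[[s]]), y = cos(phi[[s]]))
  ddiy <- function(s) {
    cx <- cos(phi[[s]]); sx <- sin(phi[[s]])
    # d2/dt2 (sin phi, cos phi) = ddphi*(cos, -sin) - dphi^2*(sin, cos)
    list(x = ddphi[[s]] * cx - dphi[[s]]^2 * sx,
         y = -ddphi[[s]] * sx - dphi[[s]]^2 * cx)
  }

  L <- config$segment_lengths
  hip_x <- config$walk_speed * Ewalk
  hip_y <- rep(config$hip_height, n_samp)
  ddhip_x <- config$walk_speed * env$de
  ddhip_y <- numeric(n_samp)

  iy_t <- iy("thigh"); dd_t <- ddiy("thigh")
  iy_s <- iy("shank"); dd_s <- ddiy("shank")
  iy_f <- iy("foot");  dd_f <- ddiy("foot")

  knee_x <- hip_x - L[["thigh"]] * iy_t$x
  knee_y <- hip_y - L[["thigh"]] * iy_t$y
  ddknee_x <- ddhip_x - L[["thigh"]] * dd_t$x
  ddknee_y <- ddhip_y - L[["thigh"]] * dd_t$y
  ankle_x <- knee_x - L[["shank"]] * iy_s$x
  ankle_y <- knee_y - L[["shank"]] * iy_s$y
  ddankle_x <- ddknee_x - L[["shank"]] * dd_s$x
  ddankle_y <- ddknee_y - L[["shank"]] * dd_s$y

  traj <- list(
    thigh = segment_trajectory(
      t, phi$thigh,
      hip_x - L[["thigh"]] / 2 * iy_t$x, hip_y - L[["thigh"]] / 2 * iy_t$y,
      dphi = dphi$thigh, ddphi = ddphi$thigh,
      ddr0x = ddhip_x - L[["thigh"]] / 2 * dd_t$x,
      ddr0y = ddhip_y - L[["thigh"]] / 2 * dd_t$y),
    shank = segment_trajectory(
      t, phi$shank,
      knee_x - L[["shank"]] / 2 * iy_s$x, knee_y - L[["shank"]] / 2 * iy_s$y,
      dphi = dphi$shank, ddphi = ddphi$shank,
      ddr0x = ddknee_x - L[["shank"]] / 2 * dd_s$x,
      ddr0y = ddknee_y - L[["shank"]] / 2 * dd_s$y),
    foot = segment_trajectory(
      t, phi$foot,
      ankle_x + L[["foot"]] / 2 * iy_f$x, ankle_y + L[["foot"]] / 2 * iy_f$y,
      dphi = dphi$foot, ddphi = ddphi$foot,
      ddr0x = ddankle_x + L[["foot"]] / 2 * dd_f$x,
      ddr0y = ddankle_y + L[["foot"]] / 2 * dd_f$y)
  )
  attr(traj, "standing_windows") <- list(c(0, t_on), c(t_off, t[n_samp]))
  attr(traj, "stride_bounds") <- t_on + (0:config$n_strides) * T
  attr(traj, "walking_window") <- c(t_on, t_off)
  attr(traj, "joints") <- list(hip = cbind(hip_x, hip_y),
                               knee = cbind(knee_x, knee_y),
                               ankle = cbind(ankle_x, ankle_y))
  class(traj) <- "gait_trajectories"
  traj
}
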