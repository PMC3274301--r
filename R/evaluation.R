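as_angle_vector <- function(x) {
  if (inherits(x, "angle_series")) return(list(t = x$t, a = x$angle_deg))
  if (is.data.frame(x)) {
    tc <- intersect(c("t", "time_s"), names(x))[1]
    ac <- setdiff(names(x), c("t", "time_s"))[1]
    return(list(t = x[[tc]], a = x[[ac]]))
  }
  stop("expected an angle_series or a two-column data frame", call. = FALSE)
}

#' Agreement between an estimated and a reference angle series
#'
#' Root-mean-square error (degrees) and Pearson correlation between the two
#' series, computed over the interior strides only: the first and the last
#' stride of the trial are excluded, so ramp-in/ramp-out transients do not
#' contaminate the comparison.
#'
#' @param est,ref `angle_series` objects (or data frames with a time column
#'   and an angle column) on a common time grid.
#' @param stride_bounds numeric vector of stride boundary times in seconds
#'   (length `n_strides + 1`); at least 3 strides are required so an interior
#'   remains after exclusion.
#' @return Object of class `agreement_report`: list with `rmse_deg`, `pcc`,
#'   `n_samples`, `strides_excluded`.
#' @export
agreement <- function(est, ref, stride_bounds) {
  e <- as_angle_vector(est)
  r <- as_angle_vector(ref)
  if (length(e$t) != length(r$t) || max(abs(e$t - r$t)) > 1e-9) {
    stop("estimate and reference are not on a common time grid", call. = FALSE)
  }
  if (length(stride_bounds) < 4L) {
    stop("need at least 3 strides to exclude the first and last", call. = FALSE)
  }
  lo <- stride_bounds[2]
  hi <- stride_bounds[length(stride_bounds) - 1L]
  keep <- e$t >= lo & e$t < hi
  if (sum(keep) < 4L) stop("interior strides contain too few samples", call. = FALSE)
  err <- e$a[keep] - r$a[keep]
  structure(list(rmse_deg = sqrt(mean(err^2)),
                 pcc = cor(e$a[keep], r$a[keep]),
                 n_samples = sum(keep), strides_excluded = 2L),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("agreement: RMSE %.2f deg, PCC %.4f (%d samples, %d strides excluded)\n",
              x$rmse_deg, x$pcc, x$n_samples, x$strides_excluded))
  invisible(x)
}

truth_series <- function(trial, joint) {
  data.frame(time_s = trial$truth$time_s,
             angle_deg = trial$truth[[paste0(joint, "_deg")]])
}

joint_streams <- function(trial, joint) {
  if (joint == "knee") list(prox = trial$streams$thigh, dist = trial$streams$shank)
  else list(prox = trial$streams$shank, dist = trial$streams$foot)
}

#' Reconstruction error as a function of the cutoff frequency
#'
#' Runs the joint-angle reconstruction of a simulated trial across a grid of
#' cutoff frequencies and reports the RMSE and PCC curves against ground
#' truth, together with the optimal cutoff. The primary optimality criterion
#' is minimum RMSE (ties resolved toward the lower cutoff, since the curves
#' have broad minima); the maximum-PCC cutoff is reported separately.
#'
#' @param trial a [simulate_trial()] result.
#' @param joint `"knee"` or `"ankle"`.
#' @param f_gc gait-cycle frequency of the trial in Hz (defaults to
#'   `1/stride_period` of the trial's config).
#' @param f0_grid cutoff grid in Hz; default 16 points spanning
#'   `[0.15, 0.9] * f_gc`, clipped below so every cutoff leaves at least
#'   three filter settling lengths inside the record.
#' @return Object of class `sweep_result`: list with `f0_grid`, `rmse_curve`,
#'   `pcc_curve`, `f0_opt`, `f0_pcc_opt`, `f_gc`, `joint`.
#' @export
cutoff_sweep <- function(trial, joint = c("knee", "ankle"), f_gc = NULL,
                         f0_grid = NULL) {
  joint <- match.arg(joint)
  stopifnot(inherits(trial, "gait_trial"))
  if (is.null(f_gc)) f_gc <- 1 / trial$config$stride_period
  fs <- trial$config$fs
  n <- nrow(trial$truth)
  if (is.null(f0_grid)) {
    f0_min <- max(0.15 * f_gc, 3.2 * fs / n)
    f0_grid <- seq(f0_min, 0.9 * f_gc, length.out = 16)
  }
  if (any(f0_grid <= 0) || any(f0_grid >= f_gc)) {
    stop("cutoff grid must lie inside (0, f_gc)", call. = FALSE)
  }
  ss <- joint_streams(trial, joint)
  ref <- truth_series(trial, joint)
  rmse <- pcc <- numeric(length(f0_grid))
  for (i in seq_along(f0_grid)) {
    spec <- design_pseudo_integrator(f0_grid[i], fs)
    est <- joint_angle(ss$prox, ss$dist, joint, spec)
    rep_i <- agreement(est, ref, trial$stride_bounds)
    rmse[i] <- rep_i$rmse_deg
    pcc[i] <- rep_i$pcc
  }
  structure(list(f0_grid = f0_grid, rmse_curve = rmse, pcc_curve = pcc,
                 f0_opt = f0_grid[which.min(rmse)],
                 f0_pcc_opt = f0_grid[which.max(pcc)],
                 f_gc = f_gc, joint = joint),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("cutoff sweep (%s, f_gc = %.3g Hz): f0_opt = %.3g Hz (min RMSE %.2f deg), max-PCC f0 = %.3g Hz\n",
              x$joint, x$f_gc, x$f0_opt, min(x$rmse_curve), x$f0_pcc_opt))
  invisible(x)
}

#' Linear fit of the optimal cutoff versus gait-cycle frequency
#'
#' Least-squares line `f0_opt = slope * f_gc + intercept` fitted per joint
#' across sweeps at different cadences.
#'
#' @param sweeps list of [cutoff_sweep()] results (may mix joints).
#' @return Data frame with one row per joint: `joint`, `slope`, `intercept`,
#'   `n`.
#' @export
optimal_cutoff_fit <- function(sweeps) {
  joints <- vapply(sweeps, function(s) s$joint, character(1))
  out <- lapply(unique(joints), function(j) {
    sel <- sweeps[joints == j]
    fg <- vapply(sel, function(s) s$f_gc, numeric(1))
    fo <- vapply(sel, function(s) s$f0_opt, numeric(1))
    if (length(unique(fg)) < 3L) {
      stop("need sweeps at >= 3 distinct gait-cycle frequencies per joint",
           call. = FALSE)
    }
    fit <- lm(fo ~ fg)
    data.frame(joint = j, slope = unname(coef(fit)[2]),
               intercept = unname(coef(fit)[1]), n = length(fg))
  })
  do.call(rbind, out)
}
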