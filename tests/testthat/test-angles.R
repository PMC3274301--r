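test_that("differential signals vanish for a noise-free static stream", {
  st <- forward_accelerometer(static_trajectory(0.3))
  d <- differential_signals(st)
  expect_equal(max(abs(d$alpha_est)), 0, tolerance = 1e-10)
  expect_equal(max(abs(d$negsqomega_est)), 0, tolerance = 1e-10)
})

test_that("pure rotation maps to -omega^2 with the geometry constant", {
  st <- forward_accelerometer(rotation_trajectory(2), mount_spec(l = 0.055))
  d <- differential_signals(st)
  expect_equal(d$negsqomega_est, rep(-4, length(d$t)), tolerance = 1e-9)
  expect_equal(max(abs(st$a2y - st$a1y)), 0.22, tolerance = 1e-9)
})

test_that("geometry errors are rejected", {
  st <- forward_accelerometer(static_trajectory(0))
  st$mount$l <- -1
  expect_error(differential_signals(st), "positive")
  expect_error(mount_spec(l = 0), "positive")
})

test_that("alpha estimate tracks the analytic angular acceleration of simulated gait", {
  h <- default_gait_harmonics()
  h$thigh <- data.frame(amp = 0.3, phase = 0)
  attr(h, "stand_deg") <- c(thigh = 0, shank = 0, foot = 90)
  cfg <- clean_config(harmonics = h, n_strides = 8)
  trial <- simulate_trial(cfg)
  traj <- trial$trajectories$thigh
  d <- differential_signals(trial$streams$thigh)
  core <- d$t > 3 & d$t < 11
  rel_rms <- sqrt(mean((d$alpha_est[core] - traj$ddphi[core])^2)) /
    sqrt(mean(traj$ddphi[core]^2))
  expect_lt(rel_rms, 0.02)
})

test_that("cutoff selection follows the cadence heuristics", {
  f0 <- select_cutoff(1, "knee")
  expect_gte(f0, 1 / 3)
  expect_lte(f0, 1 / 2)
  expect_equal(f0, 1 / sqrt(6))
  expect_equal(select_cutoff(1, "ankle"), 2 / sqrt(6), tolerance = 1e-12)
  expect_lt(select_cutoff(1, "ankle"), 1)  # f0 < f_gc always
  expect_error(select_cutoff(0, "knee"), "positive")
})

test_that("stride frequency is recovered from the acceleration spectrum", {
  for (T in c(1.25, 0.5)) {
    trial <- simulate_trial(gait_config(stride_period = T, seed = 3))
    d <- differential_signals(trial$streams$thigh)
    fgc <- estimate_stride_frequency(d, window = c(2, 2 + 10 * T))
    expect_equal(fgc, 1 / T, tolerance = 0.02 / (1 / T))
  }
})

test_that("a standing-only stream yields a distinct detection failure", {
  st <- forward_accelerometer(static_trajectory(0.1, n = 1000))
  st <- corrupt_stream(st, gait_config(), seed = 9)
  expect_error(estimate_stride_frequency(differential_signals(st)),
               class = "gaitrod_no_gait_error")
})

test_that("static calibration recovers known inclinations", {
  cfg <- gait_config()
  up <- corrupt_stream(forward_accelerometer(static_trajectory(0, n = 300)),
                       cfg, seed = 5)
  expect_equal(static_calibration(up, window = c(0, 2.99)), 0, tolerance = 0.1)
  tilt <- corrupt_stream(
    forward_accelerometer(static_trajectory(10 * pi / 180, n = 300)),
    cfg, seed = 6)
  expect_equal(static_calibration(tilt, window = c(0, 2.99)), 10,
               tolerance = 0.1)
})

test_that("calibration refuses short or moving windows", {
  st <- forward_accelerometer(static_trajectory(0, n = 300))
  expect_error(static_calibration(st, window = c(0, 0.5)),
               class = "gaitrod_calibration_error")
  trial <- default_trial()
  expect_error(static_calibration(trial$streams$thigh, window = c(5, 8)),
               class = "gaitrod_calibration_error")
  st$standing_windows <- NULL
  expect_error(static_calibration(st), "standing window")
})

test_that("still-window detection finds the standing pads of a trial", {
  trial <- default_trial(seed = 4)
  wins <- detect_still_windows(trial$streams$shank)
  expect_gte(length(wins), 2)
  expect_lt(wins[[1]][1], 0.2)
  expect_gt(wins[[1]][2], 1.8)
})

test_that("a static-only trial reconstructs a constant angle at the calibration", {
  st <- corrupt_stream(
    forward_accelerometer(static_trajectory(10 * pi / 180, n = 1500)),
    gait_config(noise_sd = 0.01, bias_walk_sd = 0), seed = 2)
  st$standing_windows <- list(c(0, 14.99))
  spec <- design_pseudo_integrator(0.4, 100)
  ang <- absolute_segment_angle(st, spec)
  expect_equal(ang$dc_offset_deg, 10, tolerance = 0.1)
  expect_lt(diff(range(ang$angle_deg)), 1)
  expect_equal(mean(ang$angle_deg[st$t <= 2]), ang$dc_offset_deg,
               tolerance = 0.3)
})

test_that("absolute angle of a single-harmonic segment is accurate in the roll-off", {
  # lowest (only) harmonic at 2.45 x f0 under the knee rule
  h <- default_gait_harmonics()
  h$thigh <- data.frame(amp = 0.25, phase = 0)
  attr(h, "stand_deg") <- c(thigh = 0, shank = 0, foot = 90)
  cfg <- gait_config(harmonics = h, noise_sd = 0.01, bias_walk_sd = 0,
                     seed = 7)
  trial <- simulate_trial(cfg)
  spec <- design_pseudo_integrator(select_cutoff(1, "knee"), 100)
  ang <- absolute_segment_angle(trial$streams$thigh, spec)
  ref <- data.frame(time_s = trial$truth$time_s,
                    angle_deg = trial$truth$phi_thigh_deg)
  rep1 <- agreement(ang, ref, trial$stride_bounds)
  # residual is dominated by the known 14% first-harmonic attenuation
  expect_lt(rep1$rmse_deg, 0.15 * 0.25 * 180 / pi)
  expect_gt(rep1$pcc, 0.99)
})

test_that("a cutoff above f_gc distorts the reconstruction", {
  trial <- default_trial(seed = 8)
  ref <- data.frame(time_s = trial$truth$time_s,
                    angle_deg = trial$truth$phi_thigh_deg)
  good <- agreement(
    absolute_segment_angle(trial$streams$thigh,
                           design_pseudo_integrator(select_cutoff(1, "knee"), 100)),
    ref, trial$stride_bounds)
  bad <- agreement(
    absolute_segment_angle(trial$streams$thigh,
                           design_pseudo_integrator(2.5, 100)),
    ref, trial$stride_bounds)
  expect_gt(bad$rmse_deg, 3 * good$rmse_deg)
})

test_that("identical streams on both segments give a zero joint angle", {
  trial <- default_trial(seed = 10)
  spec <- design_pseudo_integrator(0.4, 100)
  ja <- joint_angle(trial$streams$thigh, trial$streams$thigh, "knee", spec)
  expect_equal(max(abs(ja$angle_deg)), 0, tolerance = 1e-9)
})

test_that("joint angle requires a common time grid", {
  trial <- default_trial()
  a <- trial$streams$thigh
  b <- trial$streams$shank
  b$t <- b$t + 0.001
  spec <- design_pseudo_integrator(0.4, 100)
  expect_error(joint_angle(a, b, "knee", spec), "common time grid")
})
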