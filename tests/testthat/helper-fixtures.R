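# shared fixtures: small, fast trials built in code

clean_config <- function(...) {
  # noise-free, unquantized: isolates the deterministic part of the chain
  gait_config(noise_sd = 0, bias_walk_sd = 0, adc_bits = Inf, ...)
}

default_trial <- function(fgc = 1, seed = 1, ...) {
  simulate_trial(gait_config(stride_period = 1 / fgc, seed = seed, ...))
}

knee_truth <- function(trial) {
  data.frame(time_s = trial$truth$time_s, angle_deg = trial$truth$knee_deg)
}

ankle_truth <- function(trial) {
  data.frame(time_s = trial$truth$time_s, angle_deg = trial$truth$ankle_deg)
}

# static trajectory of a rod held at a fixed inclination (radians)
static_trajectory <- function(phi0 = 0, n = 500, fs = 100) {
  t <- seq(0, n - 1) / fs
  segment_trajectory(t, phi = rep(phi0, n),
                     r0x = rep(0.3, n), r0y = rep(0.8, n),
                     dphi = rep(0, n), ddphi = rep(0, n),
                     ddr0x = rep(0, n), ddr0y = rep(0, n))
}

# rod spinning at constant angular velocity about a fixed centroid
rotation_trajectory <- function(omega, n = 500, fs = 100) {
  t <- seq(0, n - 1) / fs
  segment_trajectory(t, phi = omega * t,
                     r0x = rep(0, n), r0y = rep(1, n),
                     dphi = rep(omega, n), ddphi = rep(0, n),
                     ddr0x = rep(0, n), ddr0y = rep(0, n))
}
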