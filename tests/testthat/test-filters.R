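test_that("biquad-cascade design matches the closed-form Butterworth magnitude", {
  fs <- 100
  for (case in list(list(n = 8, fc = 0.2, type = "high"),
                    list(n = 8, fc = 0.07, type = "high"),
                    list(n = 3, fc = 1.5, type = "low"))) {
    sos <- butter_sos(case$n, case$fc, fs, case$type)
    f <- c(0.01, 0.05, case$fc, 0.5, 2, 10, 40)
    emp <- Mod(sos_freq_response(sos, f))
    # closed form in the pre-warped analog frequency, as the bilinear maps it
    wa <- tan(pi * f / fs)
    wc <- tan(pi * case$fc / fs)
    theo <- if (case$type == "high") {
      1 / sqrt(1 + (wc / wa)^(2 * case$n))
    } else {
      1 / sqrt(1 + (wa / wc)^(2 * case$n))
    }
    expect_equal(emp, theo, tolerance = 1e-10)
  }
})

test_that("biquad cascade agrees with signal::butter where (b,a) is stable", {
  fs <- 100
  sos <- butter_sos(4, 5, fs, "high")
  ba <- signal::butter(4, 5 / (fs / 2), "high")
  f <- seq(0.5, 45, by = 0.5)
  h_sos <- Mod(sos_freq_response(sos, f))
  h_ba <- Mod(signal::freqz(ba$b, ba$a, 2 * pi * f / fs)$h)
  expect_equal(h_sos, h_ba, tolerance = 1e-8)
})

test_that("biquad cascade stays stable where the (b,a) form explodes", {
  sos <- butter_sos(8, 0.2, 100, "high")
  x <- sin(2 * pi * 2 * (0:9999) / 100)
  y <- x
  for (s in sos$sections) y <- as.numeric(signal::filter(s$b, s$a, y))
  expect_lt(max(abs(y)), 1.5)
  expect_equal(max(abs(y[5000:10000])), 1, tolerance = 5e-3)
})

test_that("bidirectional low-pass has the stated squared-magnitude response", {
  fs <- 100; f0 <- 0.5
  spec <- design_pseudo_integrator(f0, fs)
  w0 <- 2 * pi * f0
  gain_at <- function(f_sig) {
    t <- (0:19999) / fs
    y <- pseudo_double_integrate(sin(2 * pi * f_sig * t), spec)
    seg <- 8001:16000  # steady-state amplitude by projection on the sinusoid
    2 * abs(mean(y[seg] * exp(-1i * 2 * pi * f_sig * t[seg]))) * w0^2
  }
  # power form of the transfer function: 1/((w/w0)^2 + 1); at 10x the cutoff
  # the frequency ratio is evaluated through the bilinear pre-warp the
  # discrete design uses
  expect_equal(gain_at(f0), 0.5, tolerance = 1e-4)
  rw <- tan(pi * 10 * f0 / fs) / tan(pi * f0 / fs)
  expect_equal(gain_at(10 * f0), 1 / (1 + rw^2), tolerance = 1e-4)
  expect_equal(1 / (1 + rw^2), 1 / 101, tolerance = 0.02)  # approx w0^2/w^2
})

test_that("pseudo-integrator amplitude follows its closed-form response", {
  # implemented response: bidirectional 1st-order low-pass, so the ratio to
  # exact double integration is 1/(1 + (w0/w)^2); at w = 3 w0 that is 0.9 dB
  fs <- 100; f0 <- 0.4
  spec <- design_pseudo_integrator(f0, fs)
  t <- (0:19999) / fs
  for (ratio in c(2, 3, 5)) {
    w <- 2 * pi * f0 * ratio
    A <- 0.3
    alpha <- -A * w^2 * sin(w * t)   # exact second derivative of A sin(wt)
    y <- pseudo_double_integrate(alpha, spec)
    seg <- 8001:16000
    amp <- 2 * abs(mean(y[seg] * exp(-1i * w * t[seg])))
    rw <- tan(pi * f0 * ratio / fs) / tan(pi * f0 / fs)  # pre-warped ratio
    expect_equal(amp, A * ratio^2 / (1 + rw^2), tolerance = 1e-4)
  }
})

test_that("pseudo-integration of zero input is zero and has zero group delay", {
  spec <- design_pseudo_integrator(0.4, 100)
  expect_equal(pseudo_double_integrate(numeric(2000), spec), numeric(2000))
  # zero phase: the reconstructed sinusoid peaks at the same lag as the truth
  t <- (0:7999) / 100
  w <- 2 * pi * 1.2
  truth <- 0.3 * sin(w * t)
  y <- pseudo_double_integrate(-0.3 * w^2 * sin(w * t), spec)
  cc <- ccf(y[2000:6000], truth[2000:6000], lag.max = 30, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("filter design rejects invalid specifications", {
  expect_error(design_pseudo_integrator(60, 100), "Nyquist")
  expect_error(design_pseudo_integrator(0.5, 100, hp_cutoff = 0.5), "hp_cutoff")
  expect_error(design_pseudo_integrator(-1, 100), "positive")
  expect_error(butter_sos(0, 1, 100), "order")
  expect_error(pseudo_double_integrate(numeric(100),
                                       design_pseudo_integrator(0.4, 100)),
               "too short")
})

test_that("naive double integration reproduces the parabolic bias drift", {
  fs <- 100; D <- 20
  t <- seq(0, D, by = 1 / fs)
  b <- 0.05
  d <- structure(list(t = t, alpha_est = rep(b, length(t)), fs = fs),
                 class = "differential_signals")
  out <- naive_double_integration(d)
  expect_equal(out$angle_rad[length(t)], b * D^2 / 2, tolerance = 1e-6)
  expect_equal(out$angle_rad[1], 0)
})

test_that("drift stays bounded under pseudo-integration but grows without bound naively", {
  fs <- 100
  spec <- design_pseudo_integrator(0.4, fs)
  bias <- 0.05
  naive_end <- pseudo_max <- numeric(0)
  for (n_str in c(10, 30, 100)) {
    t <- seq(0, n_str * 1, by = 1 / fs)
    alpha <- rep(bias, length(t))
    d <- structure(list(t = t, alpha_est = alpha, fs = fs),
                   class = "differential_signals")
    naive_end <- c(naive_end, abs(tail(naive_double_integration(d)$angle_rad, 1)))
    pseudo_max <- c(pseudo_max, max(abs(pseudo_double_integrate(alpha, spec))))
  }
  expect_true(all(diff(naive_end) > 0))
  expect_gt(naive_end[3] / naive_end[1], 50)       # ~quadratic growth
  expect_lt(max(pseudo_max), 0.05)                  # bounded, small
  expect_lt(pseudo_max[3], pseudo_max[1] * 2 + 1e-6)  # not accumulating
})

test_that("analytic roll-off error is positive, decreasing, and vanishes at infinity", {
  r <- seq(1.01, 60, by = 0.01)
  e <- filter_error_db(r)
  expect_true(all(e > 0))
  expect_true(all(diff(e) < 0))
  expect_lt(filter_error_db(1000), 1e-4)
  expect_error(filter_error_db(c(1, -2)), "positive")
})
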