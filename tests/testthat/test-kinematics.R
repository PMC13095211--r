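fs <- 300

test_that("zero-phase filter has unit DC gain and the specified band edges", {
  n <- 3 * fs
  expect_lt(max(abs(filter_position(rep(0.7, n), fs) - 0.7)), 1e-3)

  t <- (0:(n - 1)) / fs
  s1 <- sin(2 * pi * 1 * t)
  f1 <- filter_position(s1, fs)
  core <- (fs + 1):(2 * fs)   # away from the edges
  # amplitude attenuation < 1%, phase shift < 1 degree
  fit <- stats::lm(f1[core] ~ sin(2 * pi * t[core]) + cos(2 * pi * t[core]) - 1)
  amp <- sqrt(sum(stats::coef(fit)^2))
  phase <- atan2(stats::coef(fit)[2], stats::coef(fit)[1]) * 180 / pi
  expect_lt(abs(amp - 1), 0.01)
  expect_lt(abs(phase), 1)

  s30 <- sin(2 * pi * 30 * t)
  f30 <- filter_position(s30, fs)
  expect_lt(max(abs(f30[core])), 0.01)   # > 99% attenuation
})

test_that("filtering is idempotent on band-limited signals", {
  t <- (0:(3 * fs - 1)) / fs
  s <- 0.8 * sin(2 * pi * 1.0 * t) + 0.2 * cos(2 * pi * 0.4 * t)
  f1 <- filter_position(s, fs)
  f2 <- filter_position(f1, fs)
  core <- (fs + 1):(2 * fs)   # away from edge transients
  expect_lt(max(abs(f2[core] - f1[core])), 1e-6)
})

test_that("filter rejects too-short series", {
  expect_error(filter_position(rnorm(10), fs), "short")
})

test_that("differentiation: ramp, antisymmetry, and the minimum-jerk oracle", {
  t <- (0:299) / fs
  d <- differentiate(3 * t, fs)
  expect_equal(d$velocity[2:299], rep(3, 298), tolerance = 1e-9)
  expect_equal(d$acceleration[3:298], rep(0, 296), tolerance = 1e-6)

  q <- sin(2 * pi * t)
  expect_equal(differentiate(rev(q), fs)$velocity,
               rev(-differentiate(q, fs)$velocity), tolerance = 1e-9)

  # central-difference truncation error is |q'''| h^2 / 6 <= 60 A / xi^3 * h^2 / 6
  t2 <- (0:299) / fs
  mj <- minimum_jerk(0, 0.8, 1.0, t2)
  v <- differentiate(mj$position, fs)$velocity
  expect_lt(max(abs(v[2:299] - mj$velocity[2:299])), 1e-4)
})

test_that("segmentation recovers the analytic 5% threshold span", {
  cfg <- session_config(quantize = FALSE)
  xi <- 0.7
  tr <- generate_minimum_jerk_trial(0, 1.2, xi, 0.2, cfg, noise_sd = 0)
  seg <- segment_movements(tr, filter = FALSE)
  expect_equal(nrow(seg), 1L)
  expect_lt(abs(seg$duration - analytic_span(xi)), 2 / fs)
  expect_equal(seg$direction, "extension")
  expect_equal(seg$peak_velocity, 1.875 * 1.2 / xi, tolerance = 1e-2)
})

test_that("a trial without movement yields zero segments, not an error", {
  t <- (0:(3 * fs)) / fs
  tr <- make_trial(t, rep(0.2, length(t)),
                   data.frame(target_onset = 1, target_index = 1L,
                              amplitude = 0.3, direction = "extension"),
                   fs)
  expect_equal(nrow(segment_movements(tr)), 0L)
})

test_that("two back-to-back movements give two non-overlapping segments", {
  t <- (0:(8 * 300 - 1)) / 300
  q <- minimum_jerk(0, 0.8, 0.6, t - 1)$position +
    minimum_jerk(0, 0.8, 0.6, t - 4)$position
  tr <- make_trial(t, q,
                   data.frame(target_onset = c(0.8, 3.8),
                              target_index = c(2L, 2L),
                              amplitude = 0.8,
                              direction = "extension"),
                   300)
  seg <- segment_movements(tr)
  expect_equal(nrow(seg), 2L)
  expect_lt(seg$t_end[1], seg$t_start[2])
})

test_that("reaction time matches a constructed onset and handles absence of movement", {
  cfg <- session_config(quantize = FALSE)
  tr <- generate_minimum_jerk_trial(0, 1.5, 0.5, 0.2, cfg, noise_sd = 0)
  rt <- reaction_time(tr, filter = FALSE)
  # the minimum-jerk speed crosses 0.01 rad/s at z = sqrt(0.01 xi / (30 A))
  cross <- sqrt(0.01 * 0.5 / (30 * 1.5)) * 0.5
  expect_lt(abs(rt - (0.2 + cross)), 2 / fs)

  t <- (0:(3 * fs)) / fs
  still <- make_trial(t, rep(0, length(t)),
                      data.frame(target_onset = 1, target_index = 1L,
                                 amplitude = 0.3, direction = "extension"),
                      fs)
  expect_true(is.na(reaction_time(still, filter = FALSE)))
})

test_that("reaction time is robust to noise small against the threshold", {
  cfg <- session_config(quantize = FALSE, seed = 42)
  tr0 <- generate_minimum_jerk_trial(0, 1.5, 0.5, 0.2, cfg, noise_sd = 0)
  set.seed(42)
  trn <- tr0
  trn$q <- trn$q + rnorm(length(trn$q), 0, 1e-5)
  r0 <- reaction_time(tr0, filter = FALSE)
  rn <- reaction_time(trn, filter = FALSE)
  expect_lt(abs(rn - r0), 2 / fs)
})

test_that("amplitude-duration regression reproduces exact affine data", {
  amps <- target_amplitudes()
  segs <- data.frame(amplitude = amps, duration = 0.314 * amps + 0.298,
                     target_index = 1:5)
  fit <- fit_amplitude_duration(segs)
  expect_equal(fit$slope, 0.314, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.298, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("degenerate equal durations are flagged with zero slope", {
  segs <- data.frame(amplitude = target_amplitudes(), duration = 0.5,
                     target_index = 1:5)
  fit <- fit_amplitude_duration(segs)
  expect_true(fit$degenerate)
  expect_equal(fit$slope, 0)
  expect_equal(fit$r_squared, 0)
})

test_that("regression on noisy affine data recovers the slope", {
  set.seed(11)
  amps <- target_amplitudes()
  n <- 1000
  segs <- data.frame(
    amplitude = rep(amps, each = n),
    duration = rep(0.314 * amps + 0.298, each = n) * rlnorm(5 * n, 0, 0.1),
    target_index = rep(1:5, each = n))
  fit <- fit_amplitude_duration(segs)
  expect_lt(abs(fit$slope / 0.314 - 1), 0.02)
})

test_that("mean absolute interaction torque: constants, sign changes, label swap", {
  t <- (0:599) / 300
  mk <- function(tau) {
    make_trial(t, cbind(rep(0, 600), rep(0, 600)),
               data.frame(target_onset = 0.2, target_index = 1L,
                          amplitude = 0.3, direction = "extension"),
               300, tau_interaction = tau)
  }
  seg <- list(t_start = 0.5, t_end = 1.5)
  expect_equal(mean_abs_interaction_torque(seg, mk(rep(0.05, 600))), 0.05)
  sq <- rep(c(0.1, -0.1), 300)
  expect_equal(mean_abs_interaction_torque(seg, mk(sq)), 0.1)
  # swapping partner labels flips the torque sign only
  expect_equal(mean_abs_interaction_torque(seg, mk(-sq)),
               mean_abs_interaction_torque(seg, mk(sq)))
  expect_error(mean_abs_interaction_torque(seg, mk(NULL)), "torque")
})

test_that("quadrature oracle for the interaction-torque average", {
  t <- (0:899) / 300
  tau <- 0.08 * sin(2 * pi * 1.1 * t)
  tr <- make_trial(t, cbind(rep(0, 900), rep(0, 900)),
                   data.frame(target_onset = 0.2, target_index = 1L,
                              amplitude = 0.3, direction = "extension"),
                   300, tau_interaction = tau)
  seg <- list(t_start = 0.3, t_end = 2.7)
  idx <- t >= 0.3 & t <= 2.7
  oracle <- mean(abs(tau[idx]))
  expect_equal(mean_abs_interaction_torque(seg, tr), oracle, tolerance = 1e-6)
})

test_that("spectral smoothness ranks a clean profile above one with a submovement", {
  fs2 <- 300
  t <- seq(0, 1, by = 1 / fs2)
  v1 <- minimum_jerk(0, 1, 1, t)$velocity
  v2 <- v1 + 0.25 * minimum_jerk(0, 0.2, 0.25, t - 0.7)$velocity
  s1 <- spectral_smoothness(v1, fs2)
  s2 <- spectral_smoothness(v2, fs2)
  expect_gt(s1, s2)   # less negative = smoother
})

test_that("spectral smoothness is nearly invariant to time rescaling", {
  fs2 <- 300
  v1 <- minimum_jerk(0, 1, 0.5, seq(0, 0.5, by = 1 / fs2))$velocity
  v2 <- minimum_jerk(0, 1, 1.0, seq(0, 1.0, by = 1 / fs2))$velocity
  s1 <- spectral_smoothness(v1, fs2)
  s2 <- spectral_smoothness(v2, fs2)
  expect_lt(abs(s1 / s2 - 1), 0.02)
})

test_that("spectral smoothness returns NA for degenerate segments", {
  expect_true(is.na(spectral_smoothness(rep(0, 100), 300)))
  expect_true(is.na(spectral_smoothness(rnorm(10), 300)))
})
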