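test_that("movement durations follow the affine law with log-normal jitter", {
  pr <- subject_profile(ad_slope = 0.314, ad_intercept = 0.298,
                        duration_cv = 0)
  expect_equal(sample_movement_duration(pr, pi / 2),
               0.314 * pi / 2 + 0.298, tolerance = 1e-12)
  # affine limit for vanishing amplitude
  expect_equal(sample_movement_duration(pr, 1e-9), 0.298, tolerance = 1e-6)
  expect_error(sample_movement_duration(pr, -0.1), "positive")

  pr2 <- subject_profile(duration_cv = 0.1)
  set.seed(99)
  d <- sample_movement_duration(pr2, 1, n = 10000)
  nominal <- 0.314 + 0.298
  expect_lt(abs(mean(d) / nominal - 1), 0.01)
  expect_lt(abs(stats::sd(d) / mean(d) / 0.1 - 1), 0.1)
})

test_that("generated trials obey the minimum-jerk boundary conditions", {
  cfg <- session_config(quantize = FALSE)
  tr <- generate_minimum_jerk_trial(0.1, 0.9, 0.6, 0.25, cfg, noise_sd = 0,
                                    target_onset = 2)
  t0 <- 2 + 0.25
  i_start <- which.min(abs(tr$t - t0))
  i_end <- which.min(abs(tr$t - (t0 + 0.6)))
  expect_equal(tr$q[i_start], 0.1, tolerance = 1e-6)
  expect_equal(tr$q[i_end], 1.0, tolerance = 1e-6)
  expect_true(all(abs(tr$q[tr$t < 2]) - 0.1 < 1e-12))
  # noiseless trace equals the closed form on the grid
  expect_equal(tr$q, minimum_jerk(0.1, 0.9, 0.6, tr$t - t0)$position,
               tolerance = 1e-10)
})

test_that("too-coarse grids are rejected", {
  cfg <- session_config(sample_rate = 30)
  expect_error(generate_minimum_jerk_trial(0, 1, 0.5, 0.2, cfg), "coarse")
})

test_that("encoder quantization snaps angles to the count grid", {
  cfg <- session_config(quantize = TRUE, encoder_counts = 6400)
  tr <- generate_minimum_jerk_trial(0, 1, 0.5, 0.2, cfg, noise_sd = 0)
  step <- 2 * pi / 6400
  expect_true(all(abs(tr$q / step - round(tr$q / step)) < 1e-9))
})

test_that("solo sessions have the protocol trial structure and are seed-deterministic", {
  pr <- subject_profile(duration_cv = 0.05)
  cfg <- session_config(seed = 21)
  s1 <- generate_solo_session(pr, cfg, load_inflation = 1)
  expect_equal(length(s1), 100L)
  tab <- table(vapply(s1, function(tr) tr$markers$target_index, 1L),
               vapply(s1, function(tr) tr$markers$direction, ""))
  expect_true(all(tab == 10L))

  s2 <- generate_solo_session(pr, cfg, load_inflation = 1)
  expect_identical(s1, s2)
})

test_that("viscous loads slow every target, by construction of the inflation factors", {
  pr <- subject_profile(duration_cv = 0.05)
  for (seed in 1:10) {
    cfg0 <- session_config(seed = seed, trials_per_target_per_direction = 1)
    cfgv <- session_config(seed = seed, trials_per_target_per_direction = 1,
                           viscosity = 0.15)
    s0 <- generate_solo_session(pr, cfg0)
    sv <- generate_solo_session(pr, cfgv)
    d0 <- vapply(split(seq_along(s0),
                       vapply(s0, function(tr) tr$markers$target_index, 1L)),
                 function(i) mean(vapply(s0[i], function(tr) {
                   seg <- segment_movements(tr); seg$duration[1]
                 }, numeric(1))), numeric(1))
    dv <- vapply(split(seq_along(sv),
                       vapply(sv, function(tr) tr$markers$target_index, 1L)),
                 function(i) mean(vapply(sv[i], function(tr) {
                   seg <- segment_movements(tr); seg$duration[1]
                 }, numeric(1))), numeric(1))
    expect_true(all(dv > d0))
  }
})

test_that("coupled trials satisfy the interaction-torque identity pointwise", {
  cfg <- session_config(trials_per_target_per_direction = 1, seed = 3,
                        stiffness = 0.5)
  dt <- generate_dyad_session(subject_profile("F", 0.235, 0.285, 0.03),
                              subject_profile("S", 0.35, 0.323, 0.03),
                              cfg, "co_activity", load_inflation = 1)
  for (tr in dt) {
    expect_lt(max(abs(tr$tau_interaction - 0.5 * (tr$q[, 1] - tr$q[, 2]))),
              1e-12)
  }
})

test_that("identical partners sharing a plan exchange no torque", {
  pr <- subject_profile("X", 0.3, 0.3, 0, noise_sd = 0)
  cfg <- session_config(trials_per_target_per_direction = 1, seed = 5,
                        stiffness = 1.6, quantize = FALSE)
  dt <- generate_dyad_session(pr, pr, cfg, "common_plan", load_inflation = 1)
  for (tr in dt) expect_lt(mean(abs(tr$tau_interaction)), 1e-6)
})

test_that("independent plans stretch the band more when it is stiffer", {
  prf <- subject_profile("F", 0.235, 0.285, 0, noise_sd = 0)
  prs <- subject_profile("S", 0.35, 0.323, 0, noise_sd = 0)
  mean_tau <- function(kappa) {
    cfg <- session_config(trials_per_target_per_direction = 1, seed = 8,
                          stiffness = kappa, quantize = FALSE)
    dt <- generate_dyad_session(prf, prs, cfg, "co_activity",
                                load_inflation = 1)
    mean(vapply(dt, function(tr) mean(abs(tr$tau_interaction)), numeric(1)))
  }
  expect_gt(mean_tau(1.6), mean_tau(0.5))
})

test_that("dyad generation is seed-deterministic", {
  prf <- subject_profile("F", 0.235, 0.285, 0.05)
  prs <- subject_profile("S", 0.35, 0.323, 0.05)
  cfg <- session_config(trials_per_target_per_direction = 1, seed = 17,
                        stiffness = 0.5)
  d1 <- generate_dyad_session(prf, prs, cfg, "leader_fast", load_inflation = 1)
  d2 <- generate_dyad_session(prf, prs, cfg, "leader_fast", load_inflation = 1)
  expect_identical(d1, d2)
})

test_that("cohort round trip recovers the generating amplitude-duration slope", {
  # duration_cv = 0.05, 10 trials per target; bias assessed on the mean
  # slope across seeds (single-seed estimates carry ~3% sampling noise)
  errs <- vapply(1:10, function(seed) {
    pr <- subject_profile(ad_slope = 0.314, ad_intercept = 0.298,
                          duration_cv = 0.05)
    cfg <- session_config(seed = seed, trials_per_target_per_direction = 5)
    s <- generate_solo_session(pr, cfg, load_inflation = 1)
    fit <- fit_amplitude_duration(session_segments(s))
    fit$slope / 0.314 - 1
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.03)
})

test_that("sessions survive a disk round trip", {
  cfg <- session_config(trials_per_target_per_direction = 1, seed = 2,
                        stiffness = 0.5)
  dt <- generate_dyad_session(subject_profile("F", 0.235, 0.285, 0.05),
                              subject_profile("S", 0.35, 0.323, 0.05),
                              cfg, "weighted", load_inflation = 1)
  dir <- withr::local_tempdir()
  write_session(dt, dir, cfg, subjects = c("F", "S"))
  back <- read_session(dir)
  expect_equal(length(back), length(dt))
  expect_equal(back[[3]]$q[, 1], dt[[3]]$q[, 1], tolerance = 1e-9)
  expect_equal(back[[3]]$tau_interaction, dt[[3]]$tau_interaction,
               tolerance = 1e-9)
  expect_equal(back[[3]]$markers$target_index, dt[[3]]$markers$target_index)
})
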