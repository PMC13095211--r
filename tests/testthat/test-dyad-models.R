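test_that("expected cost reduces to the solo cost without coupling", {
  sl <- slow_partner_distribution(sigma = rep(0.2, 5))
  cfg <- ia_config()
  ia <- solve_interactive_adaptation(cfg, sl, coupling_params(0.5), 2,
                                     t_range = fast_search$t_range,
                                     coarse_n = fast_search$coarse_n)
  traj <- list(t = ia$t, state = ia$state, control = ia$control)
  ec0 <- expected_cost(traj, cfg, sl, coupling_params(0), 2, sl$amplitudes[2])
  expect_equal(ec0$total, ec0$alone)
  expect_equal(ec0$tracking, 0)
  expect_equal(ec0$uncertainty, 0)

  # sigma = 0 and no process noise: uncertainty terms vanish
  sl0 <- slow_partner_distribution(sigma = rep(0, 5))
  ec1 <- expected_cost(traj, cfg, sl0, coupling_params(0.5), 2,
                       sl$amplitudes[2])
  expect_equal(ec1$uncertainty, 0)
  expect_equal(ec1$process, 0)
  expect_gt(ec1$tracking, 0)
})

test_that("deterministic-equivalent cost matches Monte-Carlo within the linearization bound", {
  # sigma/mu ~ 0.09 at the middle target
  sl <- slow_partner_distribution(sigma = rep(0.06, 5))
  cfg <- ia_config()
  cp <- coupling_params(0.5)
  k <- 3
  ia <- solve_interactive_adaptation(cfg, sl, cp, k,
                                     t_range = fast_search$t_range,
                                     coarse_n = fast_search$coarse_n)
  traj <- list(t = ia$t, state = ia$state, control = ia$control)
  det <- expected_cost(traj, cfg, sl, cp, k, sl$amplitudes[k])
  mc <- monte_carlo_expected_cost(traj, cfg, sl, cp, k, sl$amplitudes[k],
                                  n = 10000, seed = 4)
  det_int <- det$tracking + det$uncertainty

  # a-posteriori first-order bound: sample the linearization remainder
  # R(t, xi) = qdot_s(xi) - qdot_s(mu) - J(t)(xi - mu) on the same grid
  mu <- sl$mu[k]; sig <- sl$sigma[k]; A <- sl$amplitudes[k]
  ts <- traj$t
  wi <- rep(diff(ts[1:2]), length(ts)); wi[1] <- wi[length(wi)] <- wi[1] / 2
  e <- traj$state[2, ] - minimum_jerk(0, A, mu, ts)$velocity
  J <- duration_sensitivity(0, A, mu, ts)
  set.seed(4)
  xis <- rnorm(2000, mu, sig); xis <- xis[xis > 0.05]
  bound_t <- numeric(length(ts))
  mean_dxi <- mean(xis - mu)
  for (xi in xis) {
    R <- minimum_jerk(0, A, xi, ts)$velocity -
      minimum_jerk(0, A, mu, ts)$velocity - J * (xi - mu)
    bound_t <- bound_t + 2 * abs(e - J * (xi - mu)) * abs(R) + R^2
  }
  bound_t <- bound_t / length(xis) + abs(2 * e * J * mean_dxi)
  bound <- cfg$Q_tau * cp$stiffness^2 * sum(wi * bound_t)
  expect_lt(abs(det_int - mc$interaction), bound + 3 * mc$interaction_se)
})

test_that("interactive adaptation with vanishing coupling equals the solo prediction", {
  sl <- slow_partner_distribution(sigma = rep(0.2, 5))
  cfg <- ia_config()
  ia <- solve_interactive_adaptation(cfg, sl, coupling_params(1e-9), 4,
                                     t_range = fast_search$t_range,
                                     coarse_n = fast_search$coarse_n)
  solo <- solve_free_time_oc(wrist_dynamics(), effort_params(),
                             cfg$fast_cost_of_time, sl$amplitudes[4],
                             t_range = fast_search$t_range,
                             coarse_n = fast_search$coarse_n,
                             fix_final_torque = FALSE)
  expect_lt(abs(ia$predicted_T - solo$duration), 2e-3)
})

test_that("predicted dyad duration decreases when the slow partner speeds up", {
  cfg <- ia_config()
  cp <- coupling_params(0.5)
  base_mu <- 0.35 * target_amplitudes() + 0.323
  Ts <- vapply(c(1.0, 0.85, 0.7), function(scale) {
    sl <- slow_partner_distribution(mu = base_mu * scale,
                                    sigma = sigma_schedule(0))
    solve_interactive_adaptation(cfg, sl, cp, 4,
                                 t_range = fast_search$t_range,
                                 coarse_n = fast_search$coarse_n)$predicted_T
  }, numeric(1))
  expect_true(all(diff(Ts) < 0))
})

test_that("the timing-uncertainty penalty accumulates with movement time", {
  sl <- slow_partner_distribution(sigma = rep(0.2, 5))
  cfg <- ia_config()
  cp <- coupling_params(0.5)
  k <- 3
  unc <- vapply(c(0.3, 0.45, 0.6), function(T) {
    n <- 151
    traj <- list(t = seq(0, T, length.out = n),
                 state = matrix(0, 3, n), control = numeric(n))
    expected_cost(traj, cfg, sl, cp, k, sl$amplitudes[k])$uncertainty
  }, numeric(1))
  expect_true(all(diff(unc) > 0))
})

test_that("fast cost-of-time scale 1 leaves the prediction unchanged", {
  sl <- slow_partner_distribution(sigma = sigma_schedule(0))
  sens <- sensitivity_fast_cost_of_time(ia_config(), sl, coupling_params(0.5),
                                        scale = 1, target_indices = 2,
                                        t_range = fast_search$t_range,
                                        coarse_n = fast_search$coarse_n)
  expect_equal(sens$delta_T, 0, tolerance = 1e-9)
})

test_that("co-activity with identical plans produces no interaction torque", {
  f <- list(slope = 0.3, intercept = 0.3)
  p <- simulate_co_activity(f, f, coupling_params(0.5), pi / 2)
  expect_lt(p$mean_abs_tau_i, 1e-4)
})

test_that("co-activity interaction torque grows with the partners' vigor gap", {
  gaps <- seq(0, 0.115, length.out = 5)
  taus <- vapply(gaps, function(g) {
    simulate_co_activity(list(slope = 0.235, intercept = 0.285),
                         list(slope = 0.235 + g, intercept = 0.285),
                         coupling_params(0.5), pi / 2)$mean_abs_tau_i
  }, numeric(1))
  expect_true(all(diff(taus) > 0))
})

test_that("prediction table enumerates every condition for every hypothesis", {
  p <- predict_all_conditions(hypotheses = c("leader_fast", "weighted"),
                              alpha = 0.5,
                              coarse_n = fast_search$coarse_n,
                              t_range = fast_search$t_range)
  expect_equal(unname(table(p$hypothesis)), c(30L, 30L), ignore_attr = TRUE)
  expect_equal(nrow(unique(p[, c("condition", "target_index")])), 30L)
  # leader rows equal the solo free-time durations (independent recompute)
  lf <- p[p$hypothesis == "leader_fast" & p$viscosity == 0 &
            p$target_index == 3, ]
  solo <- solve_free_time_oc(wrist_dynamics(), effort_params(),
                             wrist_population("fast")$cost_of_time,
                             target_amplitudes()[3],
                             t_range = fast_search$t_range,
                             coarse_n = fast_search$coarse_n)
  expect_equal(unique(lf$predicted_T), solo$duration, tolerance = 1e-9)
  # weighted is the convex mix of the leader baselines
  w <- p[p$hypothesis == "weighted", ]
  expect_true(all(w$predicted_T > 0))
})

test_that("interactive adaptation beats the fast leader at the larger no-load targets", {
  p <- predict_all_conditions(hypotheses = c("leader_fast",
                                             "interactive_adaptation"),
                              coarse_n = fast_search$coarse_n,
                              t_range = fast_search$t_range)
  ia <- p[p$hypothesis == "interactive_adaptation" & p$condition == "KL" &
            p$target_index >= 3, ]
  lf <- p[p$hypothesis == "leader_fast" & p$condition == "KL" &
            p$target_index >= 3, ]
  m <- merge(ia, lf, by = "target_index")
  expect_true(all(m$predicted_T.x < m$predicted_T.y))
})
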