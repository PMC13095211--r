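## Forward models of the four dyadic coordination hypotheses over the
## coupled wrist dynamics: co-activity (independent plans realized through a
## finite-horizon tracking LQR), leader-follower and weighted baselines, and
## the interactive-adaptation stochastic free-final-time optimal control in
## which the dyad minimizes the fast partner's solo cost plus the expected
## variation of the interaction torque against a distribution of the slow
## partner's minimum-jerk trajectories.

#' Distribution of the slow partner's trajectories
#'
#' The slow partner is represented by minimum-jerk trajectories whose
#' duration \eqn{\xi_k} is random with mean `mu` and sd `sigma` per target;
#' only these two moments enter the deterministic-equivalent cost. Defaults
#' for `mu` come from the slow-group amplitude--duration law.
#'
#' @param amplitudes Target amplitudes, rad.
#' @param mu Mean durations per target, s; default the slow-group law.
#' @param sigma Duration sd per target, s (>= 0).
#' @param q0 Start angle, rad.
#' @return Object of class `slow_partner_distribution`.
#' @export
slow_partner_distribution <- function(amplitudes = target_amplitudes(),
                                      mu = NULL, sigma = rep(0.2, length(amplitudes)),
                                      q0 = 0) {
  if (is.null(mu)) {
    g <- wrist_population("slow")
    mu <- g$ad_slope * amplitudes + g$ad_intercept
  }
  sigma <- rep_len(sigma, length(amplitudes))
  stopifnot(all(mu > 0), all(sigma >= 0), length(mu) == length(amplitudes))
  if (length(amplitudes) > 1 && any(diff(mu[order(amplitudes)]) < 0)) {
    stop("slow_partner_distribution: mu must be non-decreasing in amplitude")
  }
  structure(list(amplitudes = amplitudes, mu = mu, sigma = sigma, q0 = q0),
            class = "slow_partner_distribution")
}

#' Timing-uncertainty schedule per condition family
#'
#' Standard deviations of the slow partner's movement duration, linearly
#' spaced over the five targets (increasing with amplitude) within the range
#' used for each condition family: `[0.15, 0.25]` s without load (KL, KH),
#' `[0.2, 0.3]` s under the light load (KLVL, KHVL) and `[0.32, 0.4]` s
#' under the heavy load (KLVH, KHVH).
#'
#' @param viscosity Load level, Nm s/rad.
#' @param n_targets Number of targets.
#' @return Numeric vector of sigmas, s.
#' @export
sigma_schedule <- function(viscosity, n_targets = 5) {
  rng <- if (viscosity == 0) c(0.15, 0.25) else
    if (viscosity <= 0.1) c(0.2, 0.3) else c(0.32, 0.4)
  seq(rng[1], rng[2], length.out = n_targets)
}

#' Interactive-adaptation configuration
#'
#' @param Q_tau Weight on the expected interaction-torque variation
#'   (dimensionless), default 3; the same value serves all amplitudes and
#'   conditions.
#' @param process_noise Intensity of additive process noise on the
#'   torque-change channel, (Nm/s)^2 s; 0 (the default) removes the state
#'   covariance term from the cost.
#' @param fast_cost_of_time [cost_of_time()] of the fast partner.
#' @param effort [effort_params()] shared by the dyad.
#' @param dyn Base [wrist_dynamics()].
#' @return Object of class `ia_config`.
#' @export
ia_config <- function(Q_tau = 3, process_noise = 0,
                      fast_cost_of_time = wrist_population("fast")$cost_of_time,
                      effort = effort_params(), dyn = wrist_dynamics()) {
  stopifnot(Q_tau >= 0, process_noise >= 0,
            inherits(fast_cost_of_time, "cost_of_time"))
  structure(list(Q_tau = Q_tau, process_noise = process_noise,
                 fast_cost_of_time = fast_cost_of_time,
                 effort = effort, dyn = dyn),
            class = "ia_config")
}

# Velocity-component state covariance from torque-change process noise:
# Pdot = A P + P A' + B c B', integrated by Euler on the solve grid.
ia_velocity_covariance <- function(dyn, kappa, ts, intensity) {
  if (intensity <= 0) return(numeric(length(ts)))
  sys <- oc_system(dyn, kappa)
  A <- sys$A; Bc <- sys$B
  P <- matrix(0, 3, 3)
  out <- numeric(length(ts))
  for (i in seq_along(ts)[-1]) {
    dt <- ts[i] - ts[i - 1]
    P <- P + dt * (A %*% P + P %*% t(A) + intensity * tcrossprod(Bc))
    out[i] <- P[2, 2]
  }
  out
}

# Fixed-duration interactive-adaptation transcription: returns the
# deterministic-equivalent cost (without the fast cost of time) and the
# solution pieces.
ia_fixed <- function(cfg, slow, coupling, amplitude, target_index, T,
                     stage = c("fine", "coarse")) {
  stage <- match.arg(stage)
  kappa <- coupling$stiffness
  dyn <- wrist_dynamics(cfg$dyn$inertia, cfg$dyn$damping, coupling$viscosity)
  N <- if (stage == "coarse") oc_nodes(T, h = 0.005, nmax = 301) else oc_nodes(T)
  ts <- seq(0, T, length.out = N)
  mu <- slow$mu[target_index]; sigma <- slow$sigma[target_index]
  ref <- minimum_jerk(0, amplitude, mu, ts)
  wv <- cfg$Q_tau * kappa^2
  dsens <- duration_sensitivity(0, amplitude, mu, ts)
  Pv <- ia_velocity_covariance(dyn, kappa, ts, cfg$process_noise)
  extra <- wv * (dsens^2 * sigma^2 + Pv)
  wq <- cfg$effort$q_weight_scale / amplitude
  r <- oc_transcribe(dyn, amplitude, T, wq = wq, beta = cfg$effort$beta,
                     N = N, kappa = kappa, qref = ref$position,
                     vref = ref$velocity, wv = wv,
                     fix_final_velocity = TRUE, fix_final_torque = FALSE,
                     extra_running = extra)
  r$ref <- ref
  r
}

#' Deterministic-equivalent expected cost of a dyadic plan
#'
#' Evaluates, for a given fast-partner trajectory over `[0, T]`, the
#' deterministic equivalent of the expected dyadic cost: the fast partner's
#' solo cost (minimum-torque-change effort plus their cost of time at `T`)
#' plus \eqn{Q_\tau \kappa^2 \int (\dot q^f - \dot q^s(\mu))^2 +
#' P_{\dot q} + (\partial\dot q^s/\partial\xi|_\mu)^2 \sigma^2 \, dt}
#' (cross-covariance terms neglected). With `kappa = 0` this reduces
#' exactly to the fast partner's solo cost; with `sigma = 0` and no process
#' noise the uncertainty terms vanish.
#'
#' @param trajectory List with `t`, `state` (3 x N), `control` --- e.g. an
#'   `oc_solution` or the internal solve of
#'   [solve_interactive_adaptation()].
#' @param cfg An [ia_config()].
#' @param slow A [slow_partner_distribution()].
#' @param coupling A [coupling_params()].
#' @param target_index Which target of `slow` applies.
#' @param amplitude Amplitude, rad.
#' @return List with `total`, `alone` (effort + time cost), `tracking`
#'   (expected torque-variation term), `uncertainty` and `process` parts.
#' @export
expected_cost <- function(trajectory, cfg, slow, coupling, target_index,
                          amplitude) {
  ts <- trajectory$t
  T <- ts[length(ts)]
  if (T < 0.01 || T > 10) stop("expected_cost: T must lie in [0.01, 10] s")
  kappa <- coupling$stiffness
  mu <- slow$mu[target_index]; sigma <- slow$sigma[target_index]
  wi <- rep(diff(ts[1:2]), length(ts)); wi[1] <- wi[length(wi)] <- wi[1] / 2
  wq <- cfg$effort$q_weight_scale / amplitude
  q <- trajectory$state[1, ]; v <- trajectory$state[2, ]
  u <- trajectory$control
  effort <- sum(wi * (wq * (amplitude - q)^2 + cfg$effort$beta * u^2))
  alone <- effort + cfg$fast_cost_of_time$G(T)
  ref_v <- minimum_jerk(0, amplitude, mu, ts)$velocity
  tracking <- cfg$Q_tau * kappa^2 * sum(wi * (v - ref_v)^2)
  dsens <- duration_sensitivity(0, amplitude, mu, ts)
  uncertainty <- cfg$Q_tau * kappa^2 * sum(wi * dsens^2 * sigma^2)
  dynv <- wrist_dynamics(cfg$dyn$inertia, cfg$dyn$damping, coupling$viscosity)
  Pv <- ia_velocity_covariance(dynv, kappa, ts, cfg$process_noise)
  process <- cfg$Q_tau * kappa^2 * sum(wi * Pv)
  list(total = alone + tracking + uncertainty + process,
       alone = alone, tracking = tracking, uncertainty = uncertainty,
       process = process)
}

#' Monte-Carlo estimate of the expected dyadic cost
#'
#' Samples the slow partner's duration \eqn{\xi} from a truncated normal
#' (support above `xi_min`), evaluates the exact (non-linearized)
#' interaction-torque-variation integral
#' \eqn{Q_\tau \int \kappa^2 (\dot q^f - \dot q^s(\xi))^2 dt} per draw, and
#' averages. Used as the sampling oracle against which the
#' deterministic-equivalent form of [expected_cost()] is validated (they
#' agree to first order in \eqn{\sigma/\mu}).
#'
#' @inheritParams expected_cost
#' @param n Number of draws.
#' @param seed Seed (local to this call).
#' @param xi_min Truncation bound for the sampled duration, s.
#' @return List with `total`, `alone`, `interaction` (MC mean) and
#'   `interaction_se`.
#' @export
monte_carlo_expected_cost <- function(trajectory, cfg, slow, coupling,
                                      target_index, amplitude,
                                      n = 10000, seed = 1, xi_min = 0.05) {
  ts <- trajectory$t
  T <- ts[length(ts)]
  kappa <- coupling$stiffness
  mu <- slow$mu[target_index]; sigma <- slow$sigma[target_index]
  wi <- rep(diff(ts[1:2]), length(ts)); wi[1] <- wi[length(wi)] <- wi[1] / 2
  wq <- cfg$effort$q_weight_scale / amplitude
  q <- trajectory$state[1, ]; v <- trajectory$state[2, ]
  u <- trajectory$control
  effort <- sum(wi * (wq * (amplitude - q)^2 + cfg$effort$beta * u^2))
  alone <- effort + cfg$fast_cost_of_time$G(T)
  xis <- with_local_seed(seed, {
    out <- numeric(0)
    while (length(out) < n) {
      draw <- stats::rnorm(n, mu, sigma)
      out <- c(out, draw[draw > xi_min])
    }
    out[seq_len(n)]
  })
  vals <- vapply(xis, function(xi) {
    rv <- minimum_jerk(0, amplitude, xi, ts)$velocity
    cfg$Q_tau * kappa^2 * sum(wi * (v - rv)^2)
  }, numeric(1))
  list(total = alone + mean(vals), alone = alone,
       interaction = mean(vals),
       interaction_se = stats::sd(vals) / sqrt(n))
}

#' Solve the interactive-adaptation model for one condition
#'
#' Minimizes the deterministic-equivalent expected dyadic cost over the
#' fast-side control and the free final time: the fast partner's
#' minimum-torque-change effort and cost of time, plus the expected
#' interaction-torque variation against the slow partner's mean minimum-jerk
#' trajectory and its timing-uncertainty term. The fast-side dynamics
#' include the elastic pull \eqn{-\kappa(q^f - q^s(\mu))}. Transcription is
#' trapezoidal; terminal position and velocity are constrained (torque
#' free); the duration search reuses the coarse-grid + refinement scheme of
#' [solve_free_time_oc()].
#'
#' @inheritParams expected_cost
#' @param t_range,coarse_n,tie_tol Duration-search controls.
#' @return Object of class `dyad_prediction`: `hypothesis`, `condition`,
#'   `target_index`, `predicted_T` (s), `mean_abs_tau_i` (Nm, against the
#'   mean slow trajectory), `cost` breakdown, `tie_flag`, and the solve
#'   (`t`, `state`, `control`).
#' @export
solve_interactive_adaptation <- function(cfg, slow, coupling, target_index,
                                         amplitude = NULL,
                                         t_range = c(0.01, 10),
                                         coarse_n = 60, tie_tol = 0.005) {
  stopifnot(inherits(cfg, "ia_config"),
            inherits(slow, "slow_partner_distribution"),
            inherits(coupling, "coupling_params"))
  if (is.null(amplitude)) amplitude <- slow$amplitudes[target_index]
  G <- cfg$fast_cost_of_time
  total <- function(T, stage) {
    r <- ia_fixed(cfg, slow, coupling, amplitude, target_index, T, stage)
    if (!isTRUE(r$converged)) return(NA_real_)
    G$G(T) + r$effort_cost
  }
  sr <- free_time_search(function(T) total(T, "coarse"),
                         function(T) total(T, "fine"),
                         t_range = t_range, coarse_n = coarse_n,
                         tie_tol = tie_tol)
  r <- ia_fixed(cfg, slow, coupling, amplitude, target_index, sr$T, "fine")
  wi <- r$weights
  taui <- coupling$stiffness * (r$state[1, ] - r$ref$position)
  out <- list(hypothesis = "interactive_adaptation",
              condition = condition_label(coupling$stiffness,
                                          coupling$viscosity),
              target_index = target_index,
              amplitude = amplitude,
              predicted_T = sr$T,
              mean_abs_tau_i = sum(wi * abs(taui)) / sum(wi),
              total_cost = sr$value,
              tie_flag = sr$n_near > 1,
              t = r$t, state = r$state, control = r$control,
              converged = isTRUE(r$converged))
  class(out) <- "dyad_prediction"
  out
}

#' @export
print.dyad_prediction <- function(x, ...) {
  cat(sprintf("Dyad prediction [%s, %s, target %d]: T = %.3f s, mean |tau_i| = %.4f Nm\n",
              x$hypothesis, x$condition, x$target_index, x$predicted_T,
              x$mean_abs_tau_i))
  invisible(x)
}

#' Sensitivity of the dyadic duration to the fast partner's cost of time
#'
#' Re-solves the interactive-adaptation model with the fast cost-of-time
#' magnitude scaled (`p1` multiplied by `scale`) and reports the absolute
#' change in predicted duration per target. Small changes here mean the
#' fast partner's vigor hardly moves the dyad's optimal timing.
#'
#' @inheritParams solve_interactive_adaptation
#' @param scale Multiplier on `p1` (> 0).
#' @param target_indices Targets to evaluate.
#' @return Data frame with `target_index`, `T_baseline`, `T_scaled`,
#'   `delta_T` (s, absolute).
#' @export
sensitivity_fast_cost_of_time <- function(cfg, slow, coupling, scale,
                                          target_indices = seq_along(slow$amplitudes),
                                          ...) {
  stopifnot(scale > 0)
  p2 <- cfg$fast_cost_of_time$p
  p2[1] <- scale * p2[1]
  cfg2 <- ia_config(Q_tau = cfg$Q_tau, process_noise = cfg$process_noise,
                    fast_cost_of_time = cost_of_time(p2),
                    effort = cfg$effort, dyn = cfg$dyn)
  rows <- lapply(target_indices, function(k) {
    b <- solve_interactive_adaptation(cfg, slow, coupling, k, ...)
    s <- solve_interactive_adaptation(cfg2, slow, coupling, k, ...)
    data.frame(target_index = k, T_baseline = b$predicted_T,
               T_scaled = s$predicted_T,
               delta_T = abs(s$predicted_T - b$predicted_T))
  })
  do.call(rbind, rows)
}

#' Co-activity simulation: independent plans under coupling
#'
#' Each partner plans a minimum-jerk trajectory with the duration given by
#' their own amplitude--duration fit; the fast partner's reference is held
#' at the target past its completion. Both partners track their references
#' through a finite-horizon time-varying LQR on the coupled state
#' \eqn{(q^f, \dot q^f, q^s, \dot q^s)} with `Q = diag(100, 0.1, 100, 0.1)`
#' and `R = I`, realized on the Euler-discretized coupled dynamics at 1 kHz
#' (affine backward Riccati recursion tracking the time-varying reference).
#' Reported is the mean absolute interaction torque over the slow partner's
#' movement.
#'
#' @param fit_f,fit_s Amplitude--duration fits (or lists with `slope`,
#'   `intercept`) for the fast and slow partner.
#' @param coupling A [coupling_params()] with `stiffness > 0`.
#' @param amplitude Amplitude, rad.
#' @param target_index Bookkeeping index.
#' @param dyn Base [wrist_dynamics()].
#' @param dt Simulation step, s.
#' @return A `dyad_prediction` with the simulated state trajectory in
#'   `$state` (4 x N) and `$taui` the interaction-torque profile.
#' @export
simulate_co_activity <- function(fit_f, fit_s, coupling, amplitude,
                                 target_index = NA_integer_,
                                 dyn = wrist_dynamics(), dt = 1e-3) {
  stopifnot(coupling$stiffness > 0)
  kappa <- coupling$stiffness; nu <- coupling$viscosity
  I <- dyn$inertia; D <- dyn$damping
  Tf <- fit_f$slope * amplitude + fit_f$intercept
  Ts <- fit_s$slope * amplitude + fit_s$intercept
  Tend <- max(Tf, Ts)
  n <- round(Tend / dt) + 1L
  ts <- (0:(n - 1)) * dt
  ref <- rbind(minimum_jerk(0, amplitude, Tf, ts)$position,
               minimum_jerk(0, amplitude, Tf, ts)$velocity,
               minimum_jerk(0, amplitude, Ts, ts)$position,
               minimum_jerk(0, amplitude, Ts, ts)$velocity)
  Ac <- matrix(0, 4, 4)
  Ac[1, 2] <- 1; Ac[3, 4] <- 1
  Ac[2, ] <- c(-kappa / I, -(D + nu) / I, kappa / I, 0)
  Ac[4, ] <- c(kappa / I, 0, -kappa / I, -(D + nu) / I)
  Bc <- matrix(0, 4, 2); Bc[2, 1] <- 1 / I; Bc[4, 2] <- 1 / I
  Ad <- diag(4) + dt * Ac; Bd <- dt * Bc
  Q <- diag(c(100, 0.1, 100, 0.1)); R <- diag(2)

  S <- Q; sv <- Q %*% ref[, n]
  Ks <- vector("list", n - 1); kv <- vector("list", n - 1)
  diverged <- FALSE
  for (k in (n - 1):1) {
    Gm <- R + t(Bd) %*% S %*% Bd
    Ki <- solve(Gm, t(Bd) %*% S %*% Ad)
    ki <- solve(Gm, t(Bd) %*% sv)
    Ks[[k]] <- Ki; kv[[k]] <- ki
    S <- Q + t(Ad) %*% S %*% Ad - t(Ad) %*% S %*% Bd %*% Ki
    S <- (S + t(S)) / 2
    sv <- Q %*% ref[, k] + t(Ad - Bd %*% Ki) %*% sv
    if (!all(is.finite(S))) { diverged <- TRUE; break }
  }
  x <- numeric(4)
  X <- matrix(0, 4, n)
  taui <- numeric(n)
  if (!diverged) {
    for (k in 1:(n - 1)) {
      u <- -Ks[[k]] %*% x + kv[[k]]
      taui[k] <- kappa * (x[1] - x[3])
      x <- as.numeric(Ad %*% x + Bd %*% u)
      X[, k + 1] <- x
    }
    taui[n] <- kappa * (x[1] - x[3])
  }
  slow_span <- ts <= Ts
  out <- list(hypothesis = "co_activity",
              condition = condition_label(kappa, nu),
              target_index = target_index, amplitude = amplitude,
              predicted_T = Ts,
              mean_abs_tau_i = mean(abs(taui[slow_span])),
              t = ts, state = X, taui = taui,
              duration_fast = Tf, duration_slow = Ts,
              converged = !diverged)
  if (diverged) warning("simulate_co_activity: Riccati backward pass diverged")
  class(out) <- "dyad_prediction"
  out
}

#' Predict all conditions under every coordination hypothesis
#'
#' Enumerates the 5 targets x 2 stiffness x 3 viscous loads and produces
#' one predicted dyadic duration (and, where the hypothesis defines one, an
#' interaction-torque summary) per condition per hypothesis. Leader
#' baselines are the respective partners' solo free-final-time durations;
#' the weighted baseline mixes the two durations with weight `alpha`;
#' co-activity takes the slow partner's plan duration and the LQR-simulated
#' interaction torque; interactive adaptation runs the full stochastic
#' free-final-time solve with [sigma_schedule()] per load level.
#'
#' @param cfg An [ia_config()].
#' @param fit_f,fit_s Fast/slow amplitude--duration fits (for the
#'   co-activity references).
#' @param G_fast,G_slow [cost_of_time()] objects for the leader baselines.
#' @param hypotheses Character vector of hypotheses to run.
#' @param alpha Weighted-adaptation weight.
#' @param amplitudes Targets, rad.
#' @param mu_slow Mean slow durations per target (defaults to the slow fit).
#' @param coarse_n,t_range Duration-search controls passed to the
#'   free-final-time solvers.
#' @return Data frame: `hypothesis`, `condition`, `stiffness`, `viscosity`,
#'   `target_index`, `amplitude`, `predicted_T`, `mean_abs_tau_i`,
#'   `tie_flag`.
#' @export
predict_all_conditions <- function(cfg = ia_config(),
                                   fit_f = wrist_population("fast"),
                                   fit_s = wrist_population("slow"),
                                   G_fast = wrist_population("fast")$cost_of_time,
                                   G_slow = wrist_population("slow")$cost_of_time,
                                   hypotheses = c("co_activity", "leader_fast",
                                                  "leader_slow", "weighted",
                                                  "interactive_adaptation"),
                                   alpha = 0.5,
                                   amplitudes = target_amplitudes(),
                                   mu_slow = NULL,
                                   coarse_n = 60, t_range = c(0.01, 10)) {
  conds <- condition_table(amplitudes)
  nus <- unique(conds$viscosity)
  # Solo free-time durations per load level, shared across stiffness
  solo <- function(G) {
    out <- matrix(NA_real_, length(nus), length(amplitudes),
                  dimnames = list(as.character(nus), NULL))
    for (i in seq_along(nus)) {
      d <- wrist_dynamics(cfg$dyn$inertia, cfg$dyn$damping, nus[i])
      out[i, ] <- vapply(amplitudes, function(a)
        solve_free_time_oc(d, cfg$effort, G, a, coarse_n = coarse_n,
                           t_range = t_range)$duration, numeric(1))
    }
    out
  }
  Tf_tab <- if (any(hypotheses %in% c("leader_fast", "weighted"))) solo(G_fast) else NULL
  Ts_tab <- if (any(hypotheses %in% c("leader_slow", "weighted"))) solo(G_slow) else NULL

  if (is.null(mu_slow)) mu_slow <- fit_s$ad_slope %||% fit_s$slope
  mu_vec <- if (length(mu_slow) == 1) mu_slow * amplitudes +
    (fit_s$ad_intercept %||% fit_s$intercept) else mu_slow

  rows <- list()
  for (hy in hypotheses) {
    for (r in seq_len(nrow(conds))) {
      k <- conds$target_index[r]; a <- conds$amplitude[r]
      cp <- coupling_params(conds$stiffness[r], conds$viscosity[r])
      irow <- match(as.character(cp$viscosity), as.character(nus))
      res <- switch(hy,
        co_activity = {
          ff <- list(slope = fit_f$ad_slope %||% fit_f$slope,
                     intercept = fit_f$ad_intercept %||% fit_f$intercept)
          ss <- list(slope = fit_s$ad_slope %||% fit_s$slope,
                     intercept = fit_s$ad_intercept %||% fit_s$intercept)
          infl <- load_inflation_factors(cp$viscosity, a)
          ff$intercept <- ff$intercept * infl; ff$slope <- ff$slope * infl
          ss$intercept <- ss$intercept * infl; ss$slope <- ss$slope * infl
          p <- simulate_co_activity(ff, ss, cp, a, target_index = k,
                                    dyn = cfg$dyn)
          list(T = p$predicted_T, tau = p$mean_abs_tau_i, tie = FALSE)
        },
        leader_fast = list(T = Tf_tab[irow, k], tau = 0, tie = FALSE),
        leader_slow = list(T = Ts_tab[irow, k], tau = 0, tie = FALSE),
        weighted = list(T = alpha * Tf_tab[irow, k] +
                          (1 - alpha) * Ts_tab[irow, k],
                        tau = 0, tie = FALSE),
        interactive_adaptation = {
          sl <- slow_partner_distribution(amplitudes, mu = mu_vec,
                                          sigma = sigma_schedule(cp$viscosity,
                                                                 length(amplitudes)))
          p <- solve_interactive_adaptation(cfg, sl, cp, k,
                                            coarse_n = coarse_n,
                                            t_range = t_range)
          list(T = p$predicted_T, tau = p$mean_abs_tau_i, tie = p$tie_flag)
        })
      rows[[length(rows) + 1L]] <- data.frame(
        hypothesis = hy, condition = conds$condition[r],
        stiffness = cp$stiffness, viscosity = cp$viscosity,
        target_index = k, amplitude = a,
        predicted_T = res$T, mean_abs_tau_i = res$tau,
        tie_flag = res$tie, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
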