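## Synthetic session generator. Emulates the statistical structure of the
## wrist-reaching experiment: five targets, affine per-subject
## amplitude-duration laws with log-normal trial-to-trial jitter, reaction
## times, uniform inter-trial onset jitter, viscous loads, elastic coupling,
## sensor noise and encoder quantization. All randomness flows from the
## session seed, so identical configurations reproduce byte-identical data.

#' Subject profile
#'
#' Per-subject parameters of the generator: the affine amplitude--duration
#' law \eqn{T(A) = a A + b} that encodes the subject's vigor, trial-to-trial
#' duration variability, reaction-time statistics and sensor noise.
#'
#' @param subject_id Label.
#' @param ad_slope Slope a, s/rad (> 0).
#' @param ad_intercept Intercept b, s (> 0).
#' @param duration_cv Trial-to-trial coefficient of variation of duration,
#'   in `[0, 0.5]`.
#' @param reaction_mean,reaction_sd Reaction-time mean and sd, s.
#' @param noise_sd Additive sensor noise on the angle, rad.
#' @return Object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id = "S1", ad_slope = 0.314,
                            ad_intercept = 0.298, duration_cv = 0.08,
                            reaction_mean = 0.225, reaction_sd = 0.04,
                            noise_sd = 2e-4) {
  stopifnot(ad_slope > 0, ad_intercept > 0,
            duration_cv >= 0, duration_cv <= 0.5,
            reaction_mean > 0, reaction_sd >= 0, noise_sd >= 0)
  structure(list(subject_id = subject_id, ad_slope = ad_slope,
                 ad_intercept = ad_intercept, duration_cv = duration_cv,
                 reaction_mean = reaction_mean, reaction_sd = reaction_sd,
                 noise_sd = noise_sd),
            class = "subject_profile")
}

#' Session configuration
#'
#' @param targets Target amplitudes, rad.
#' @param trials_per_target_per_direction Repetitions per target and
#'   direction (default 10, i.e. 100 trials over 5 targets).
#' @param viscosity Viscous load nu, Nm s/rad.
#' @param stiffness Coupling stiffness kappa, Nm/rad (0 for solo sessions).
#' @param hold_duration Nominal hold at the start position before the target
#'   appears, s; the actual hold is drawn uniformly from
#'   `hold_duration + c(-1, 1) * hold_jitter` per trial.
#' @param hold_jitter Half-width of the onset jitter, s.
#' @param sample_rate Hz.
#' @param seed Integer seed fixing the whole session.
#' @param quantize Apply encoder quantization to the recorded angles.
#' @param encoder_counts Encoder resolution, counts per turn.
#' @return Object of class `session_config`.
#' @export
session_config <- function(targets = target_amplitudes(),
                           trials_per_target_per_direction = 10,
                           viscosity = 0, stiffness = 0,
                           hold_duration = 2, hold_jitter = 0.15,
                           sample_rate = 300, seed = 1,
                           quantize = TRUE, encoder_counts = 6400) {
  stopifnot(sample_rate > 0, trials_per_target_per_direction >= 1,
            all(targets > 0), viscosity >= 0, stiffness >= 0,
            hold_duration > hold_jitter, hold_jitter >= 0)
  structure(list(targets = targets,
                 trials_per_target_per_direction = trials_per_target_per_direction,
                 viscosity = viscosity, stiffness = stiffness,
                 hold_duration = hold_duration, hold_jitter = hold_jitter,
                 sample_rate = sample_rate, seed = as.integer(seed),
                 quantize = quantize, encoder_counts = encoder_counts),
            class = "session_config")
}

condition_label <- function(stiffness, viscosity) {
  k <- if (stiffness == 0) "" else if (stiffness <= 1) "KL" else "KH"
  v <- if (viscosity == 0) if (k == "") "NF" else "" else
    if (viscosity <= 0.1) "VL" else "VH"
  paste0(k, v)
}

#' Sample a movement duration from a subject's amplitude--duration law
#'
#' The nominal duration is the affine law at the given amplitude; the drawn
#' duration multiplies it by a log-normal factor with mean 1 and coefficient
#' of variation `profile$duration_cv` (log-normal because durations are
#' positive and right-skewed).
#'
#' @param profile A [subject_profile()].
#' @param amplitude Amplitude, rad (> 0).
#' @param n Number of draws (uses the current RNG stream).
#' @return Duration(s), s.
#' @export
sample_movement_duration <- function(profile, amplitude, n = 1) {
  if (any(amplitude <= 0)) stop("sample_movement_duration: amplitude must be positive")
  nominal <- profile$ad_slope * amplitude + profile$ad_intercept
  cv <- profile$duration_cv
  if (cv == 0) return(rep(nominal, n))
  sdlog <- sqrt(log(1 + cv^2))
  nominal * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

quantize_angle <- function(q, counts) {
  step <- 2 * pi / counts
  round(q / step) * step
}

#' Generate one minimum-jerk reaching trial
#'
#' A noiseless trace holds at `q0`, follows the minimum-jerk profile from
#' `target_onset + reaction_time` over `duration`, and holds at
#' `q0 + amplitude` afterwards; Gaussian sensor noise and optional encoder
#' quantization are applied last.
#'
#' @param q0 Start angle, rad.
#' @param amplitude Signed displacement, rad.
#' @param duration Movement duration, s (> 0; the grid must resolve it with
#'   at least 20 samples).
#' @param reaction_time Delay between target onset and movement start, s.
#' @param cfg A [session_config()].
#' @param noise_sd Sensor noise sd, rad (0 disables noise).
#' @param target_onset Target onset time, s; default the configured hold
#'   duration.
#' @param tail Hold time recorded after movement end, s.
#' @param target_index,condition Bookkeeping fields stored in the trial.
#' @return Object of class `trial_time_series`: `t`, `q` (vector), `markers`
#'   (data frame with `target_onset`, `target_index`, `amplitude`,
#'   `direction`), `sample_rate`, `condition`.
#' @export
generate_minimum_jerk_trial <- function(q0, amplitude, duration,
                                        reaction_time, cfg,
                                        noise_sd = 0, target_onset = NULL,
                                        tail = 0.6, target_index = NA_integer_,
                                        condition = "NF") {
  stopifnot(duration > 0, reaction_time >= 0)
  if (duration * cfg$sample_rate < 20) {
    stop("generate_minimum_jerk_trial: grid too coarse to resolve the movement")
  }
  if (is.null(target_onset)) target_onset <- cfg$hold_duration
  t_end <- target_onset + reaction_time + duration + tail
  n <- floor(t_end * cfg$sample_rate) + 1L
  t <- (0:(n - 1)) / cfg$sample_rate
  mj <- minimum_jerk(q0, amplitude, duration, t - target_onset - reaction_time)
  q <- mj$position
  if (noise_sd > 0) q <- q + stats::rnorm(n, 0, noise_sd)
  if (isTRUE(cfg$quantize)) q <- quantize_angle(q, cfg$encoder_counts)
  trial <- list(t = t, q = q, tau_interaction = NULL,
                markers = data.frame(target_onset = target_onset,
                                     target_index = target_index,
                                     amplitude = abs(amplitude),
                                     direction = if (amplitude >= 0) "extension" else "flexion",
                                     stringsAsFactors = FALSE),
                sample_rate = cfg$sample_rate, condition = condition,
                stiffness = cfg$stiffness, viscosity = cfg$viscosity)
  class(trial) <- "trial_time_series"
  trial
}

trial_channel <- function(trial, channel = 1) {
  if (is.matrix(trial$q)) trial$q[, channel] else trial$q
}

# Pseudo-random trial order: each target appears once per direction per
# repetition block, shuffled.
trial_schedule <- function(cfg) {
  base <- expand.grid(target_index = seq_along(cfg$targets),
                      direction = c(1, -1))
  sched <- do.call(rbind, lapply(seq_len(cfg$trials_per_target_per_direction),
                                 function(r) base[sample.int(nrow(base)), ]))
  rownames(sched) <- NULL
  sched
}

# Duration inflation factors under viscous load, derived from free-time
# optimal-control predictions with the average cost of time (cached).
.dyadvigor_cache <- new.env(parent = emptyenv())

# Calibration of the generator against the measurement chain: the
# 5%-threshold span of a filtered minimum-jerk trace is almost, but not
# exactly, the analytic fraction of its duration (the zero-phase low-pass
# smears the velocity flanks). Measure clean probes once, fit the affine
# map span = a * xi + b, and invert it when converting a target measured
# duration into a plan duration.
span_calibration <- function(sample_rate, quantize = FALSE) {
  key <- sprintf("spancal_%g", sample_rate)
  if (!is.null(.dyadvigor_cache[[key]])) return(.dyadvigor_cache[[key]])
  cfg <- session_config(sample_rate = sample_rate, quantize = FALSE)
  xis <- seq(0.3, 1.6, length.out = 5)
  spans <- vapply(xis, function(xi) {
    tr <- generate_minimum_jerk_trial(0, 1, xi, 0.2, cfg, noise_sd = 0)
    s <- segment_movements(tr)
    if (!nrow(s)) return(NA_real_)
    s$duration[1]
  }, numeric(1))
  fit <- stats::lm(spans ~ xis)
  cal <- c(a = unname(stats::coef(fit)[2]), b = unname(stats::coef(fit)[1]))
  .dyadvigor_cache[[key]] <- cal
  cal
}

# Plan duration whose measured (5%-threshold, filtered) span equals T_meas.
plan_duration <- function(T_meas, sample_rate, span_correction = TRUE) {
  if (!span_correction) return(T_meas)
  cal <- span_calibration(sample_rate)
  pmax(0.1, (T_meas - cal["b"]) / cal["a"])
}

#' Viscous-load duration inflation factors
#'
#' Ratio of the predicted free-final-time movement duration under a viscous
#' load to the null-field prediction, per amplitude, computed with the
#' reference average cost of time and cached. These factors keep the
#' synthetic data consistent with the optimal-control model: loaded
#' synthetic movements slow down exactly as the forward model predicts.
#'
#' @param viscosity Load, Nm s/rad.
#' @param amplitudes Amplitudes, rad.
#' @return Numeric vector of factors (all 1 for `viscosity = 0`).
#' @export
load_inflation_factors <- function(viscosity, amplitudes = target_amplitudes()) {
  if (viscosity == 0) return(rep(1, length(amplitudes)))
  key <- paste0("infl_", signif(viscosity, 6), "_",
                paste(signif(amplitudes, 6), collapse = "_"))
  if (!is.null(.dyadvigor_cache[[key]])) return(.dyadvigor_cache[[key]])
  G <- wrist_population("average")$cost_of_time
  base <- vapply(amplitudes, function(a)
    solve_free_time_oc(wrist_dynamics(), effort_params(), G, a)$duration,
    numeric(1))
  loaded <- vapply(amplitudes, function(a)
    solve_free_time_oc(wrist_dynamics(viscosity = viscosity),
                       effort_params(), G, a)$duration, numeric(1))
  f <- loaded / base
  .dyadvigor_cache[[key]] <- f
  f
}

draw_reaction <- function(profile, n = 1) {
  pmax(0.05, stats::rnorm(n, profile$reaction_mean, profile$reaction_sd))
}

#' Generate a solo session
#'
#' Trials follow a seed-fixed pseudo-random target order; each trial holds,
#' reacts, and executes a minimum-jerk movement whose duration is drawn from
#' the subject's amplitude--duration law, inflated under viscous load by
#' [load_inflation_factors()] (or by the factors supplied).
#'
#' @param profile A [subject_profile()].
#' @param cfg A [session_config()] with `stiffness = 0`.
#' @param load_inflation Optional numeric vector of per-target inflation
#'   factors (recycled), or `NULL` to derive them from the forward
#'   optimal-control model.
#' @param span_correction Divide the drawn (measured-scale) duration by
#'   [minimum_jerk_span_fraction()] when building the trajectory, so that
#'   5%-threshold segmentation of the generated data recovers the profile's
#'   amplitude--duration law.
#' @return List of `trial_time_series`.
#' @export
generate_solo_session <- function(profile, cfg, load_inflation = NULL,
                                  span_correction = TRUE) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(cfg, "session_config"))
  if (cfg$stiffness != 0) stop("generate_solo_session: cfg$stiffness must be 0")
  infl <- if (is.null(load_inflation)) {
    load_inflation_factors(cfg$viscosity, cfg$targets)
  } else rep_len(load_inflation, length(cfg$targets))
  cond <- condition_label(0, cfg$viscosity)
  if (span_correction) span_calibration(cfg$sample_rate)
  with_local_seed(cfg$seed, {
    sched <- trial_schedule(cfg)
    lapply(seq_len(nrow(sched)), function(i) {
      k <- sched$target_index[i]
      amp <- cfg$targets[k] * sched$direction[i]
      dur <- plan_duration(sample_movement_duration(profile, cfg$targets[k]) * infl[k],
                           cfg$sample_rate, span_correction)
      rt <- draw_reaction(profile)
      onset <- stats::runif(1, cfg$hold_duration - cfg$hold_jitter,
                            cfg$hold_duration + cfg$hold_jitter)
      generate_minimum_jerk_trial(0, amp, dur, rt, cfg,
                                  noise_sd = profile$noise_sd,
                                  target_onset = onset, target_index = k,
                                  condition = cond)
    })
  })
}

#' Generate a coupled (dyadic) session
#'
#' Per trial, each partner is assigned a reference trajectory according to
#' the coordination hypothesis, then both track their references with a PD
#' servo (with inertia/damping feedforward) while the coupled dynamics
#' \deqn{I\ddot q^j = \tau^j - (D+\nu)\dot q^j - \kappa(q^j - q^{j'})}
#' are integrated by explicit Euler at the sample rate. The recorded
#' interaction torque is \eqn{\kappa(q^f - q^s)} computed from the stored
#' angle channels.
#'
#' Hypotheses: `co_activity` (independent minimum-jerk plans with each
#' partner's own drawn duration), `leader_fast` / `leader_slow` (both track
#' the named partner's plan), `weighted` (shared duration
#' \eqn{\alpha T^f + (1-\alpha) T^s}), `common_plan` (shared duration from
#' `shared_duration`, defaulting to the mean of the partners' draws).
#'
#' @param profile_f,profile_s Fast and slow [subject_profile()]s.
#' @param cfg A [session_config()] with `stiffness > 0`.
#' @param coordination Coordination hypothesis label.
#' @param alpha Weight for `weighted` coordination.
#' @param shared_duration Optional `function(amplitude, target_index)`
#'   returning the common-plan duration.
#' @param load_inflation As in [generate_solo_session()].
#' @param kp,kd Tracking servo gains (Nm/rad, Nm s/rad).
#' @param dyn Base [wrist_dynamics()] (inertia and damping).
#' @return List of `trial_time_series` with two angle channels and
#'   `tau_interaction`; trials whose integration diverges (|q| > 10 rad) are
#'   flagged with attribute `flagged` and a warning.
#' @export
generate_dyad_session <- function(profile_f, profile_s, cfg,
                                  coordination = c("co_activity", "leader_fast",
                                                   "leader_slow", "weighted",
                                                   "common_plan"),
                                  alpha = 0.5, shared_duration = NULL,
                                  load_inflation = NULL, span_correction = TRUE,
                                  kp = 5, kd = 0.3, dyn = wrist_dynamics()) {
  coordination <- match.arg(coordination)
  stopifnot(inherits(cfg, "session_config"))
  if (cfg$stiffness <= 0) stop("generate_dyad_session: cfg$stiffness must be > 0")
  infl <- if (is.null(load_inflation)) {
    load_inflation_factors(cfg$viscosity, cfg$targets)
  } else rep_len(load_inflation, length(cfg$targets))
  cond <- condition_label(cfg$stiffness, cfg$viscosity)
  fs <- cfg$sample_rate
  dt <- 1 / fs
  kappa <- cfg$stiffness
  nu <- cfg$viscosity
  I <- dyn$inertia; D <- dyn$damping

  if (span_correction) span_calibration(cfg$sample_rate)
  with_local_seed(cfg$seed, {
    sched <- trial_schedule(cfg)
    lapply(seq_len(nrow(sched)), function(i) {
      k <- sched$target_index[i]
      A <- cfg$targets[k] * sched$direction[i]
      Tf <- plan_duration(sample_movement_duration(profile_f, cfg$targets[k]) * infl[k],
                          cfg$sample_rate, span_correction)
      Ts <- plan_duration(sample_movement_duration(profile_s, cfg$targets[k]) * infl[k],
                          cfg$sample_rate, span_correction)
      durs <- switch(coordination,
        co_activity = c(Tf, Ts),
        leader_fast = c(Tf, Tf),
        leader_slow = c(Ts, Ts),
        weighted = rep(alpha * Tf + (1 - alpha) * Ts, 2),
        common_plan = {
          d <- if (is.null(shared_duration)) mean(c(Tf, Ts)) else
            shared_duration(cfg$targets[k], k)
          c(d, d)
        })
      rt <- min(draw_reaction(profile_f), draw_reaction(profile_s))
      onset <- stats::runif(1, cfg$hold_duration - cfg$hold_jitter,
                            cfg$hold_duration + cfg$hold_jitter)
      t0 <- onset + rt
      t_end <- t0 + max(durs) + 0.6
      n <- floor(t_end * fs) + 1L
      t <- (0:(n - 1)) * dt

      refs <- lapply(durs, function(d) minimum_jerk(0, A, d, t - t0))
      accs <- lapply(seq_len(2), function(j) {
        differentiate(refs[[j]]$velocity, fs)$velocity
      })
      Q <- matrix(0, n, 2); V <- matrix(0, n, 2)
      q <- c(0, 0); v <- c(0, 0)
      flagged <- FALSE
      for (s in seq_len(n - 1)) {
        taui <- kappa * (q[1] - q[2])
        tau <- vapply(1:2, function(j) {
          kp * (refs[[j]]$position[s] - q[j]) +
            kd * (refs[[j]]$velocity[s] - v[j]) +
            I * accs[[j]][s] + (D + nu) * refs[[j]]$velocity[s]
        }, numeric(1))
        a1 <- (tau[1] - (D + nu) * v[1] - taui) / I
        a2 <- (tau[2] - (D + nu) * v[2] + taui) / I
        q <- q + dt * v
        v <- v + dt * c(a1, a2)
        Q[s + 1, ] <- q; V[s + 1, ] <- v
        if (any(abs(q) > 10)) { flagged <- TRUE; break }
      }
      noise <- profile_f$noise_sd
      Qn <- Q
      if (noise > 0) Qn <- Qn + matrix(stats::rnorm(2 * n, 0, noise), n, 2)
      if (isTRUE(cfg$quantize)) Qn <- quantize_angle(Qn, cfg$encoder_counts)
      trial <- list(t = t, q = Qn,
                    tau_interaction = kappa * (Qn[, 1] - Qn[, 2]),
                    markers = data.frame(target_onset = onset,
                                         target_index = k,
                                         amplitude = abs(A),
                                         direction = if (A >= 0) "extension" else "flexion",
                                         stringsAsFactors = FALSE),
                    sample_rate = fs, condition = cond,
                    stiffness = kappa, viscosity = nu,
                    coordination = coordination)
      class(trial) <- "trial_time_series"
      if (flagged) {
        attr(trial, "flagged") <- TRUE
        warning(sprintf("dyad trial %d diverged (|q| > 10 rad); flagged", i))
      }
      trial
    })
  })
}

#' Write a session to disk
#'
#' One CSV per trial (columns `t`, `q_f`, optionally `q_s` and `tau_i`) plus
#' a `manifest.json` describing every trial (onset, target, direction,
#' condition) and echoing the configuration and seed.
#'
#' @param trials List of `trial_time_series`.
#' @param dir Output directory (created if needed).
#' @param cfg The [session_config()] used (echoed into the manifest).
#' @param subjects Character vector of subject labels.
#' @return `dir`, invisibly.
#' @export
write_session <- function(trials, dir, cfg, subjects = "S1") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    file <- sprintf("trial_%03d.csv", i)
    df <- data.frame(t = tr$t)
    if (is.matrix(tr$q)) {
      df$q_f <- tr$q[, 1]; df$q_s <- tr$q[, 2]; df$tau_i <- tr$tau_interaction
    } else df$q_f <- tr$q
    utils::write.csv(df, file.path(dir, file), row.names = FALSE)
    c(as.list(tr$markers),
      list(file = file, condition = tr$condition,
           stiffness = tr$stiffness, viscosity = tr$viscosity,
           sample_rate = tr$sample_rate))
  })
  manifest <- list(subjects = subjects, seed = cfg$seed,
                   config = unclass(cfg), trials = meta)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir Session directory.
#' @return List of `trial_time_series`.
#' @export
read_session <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  lapply(seq_len(nrow(manifest$trials)), function(i) {
    m <- manifest$trials[i, ]
    df <- utils::read.csv(file.path(dir, m$file))
    q <- if ("q_s" %in% names(df)) cbind(df$q_f, df$q_s) else df$q_f
    trial <- list(t = df$t, q = q,
                  tau_interaction = if ("tau_i" %in% names(df)) df$tau_i else NULL,
                  markers = data.frame(target_onset = m$target_onset,
                                       target_index = m$target_index,
                                       amplitude = m$amplitude,
                                       direction = m$direction,
                                       stringsAsFactors = FALSE),
                  sample_rate = m$sample_rate, condition = m$condition,
                  stiffness = m$stiffness, viscosity = m$viscosity)
    class(trial) <- "trial_time_series"
    trial
  })
}
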