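## Inverse-optimal-control identification of the cost of time.
##
## Rationale: at a freely chosen movement duration T*, first-order optimality
## of G(T) + V(T) (time cost plus minimum effort at fixed duration) requires
## dG/dt(T*) = -dV/dT(T*) = -H(T*), the negated (constant) Hamiltonian of the
## fixed-time problem. Observed amplitude-duration laws therefore pin the
## derivative of G at one duration per amplitude, and fitting the sigmoid
## derivative through those points recovers G up to its integration constant
## (G(0) = 0).

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Identify an individual cost of time from an amplitude--duration law
#'
#' For each target amplitude, solves the fixed-final-time
#' minimum-torque-change problem at the duration prescribed by the
#' amplitude--duration fit, collects the pairs
#' \eqn{(T_k, -H_k)} of duration and negated Hamiltonian, and fits the
#' sigmoid derivative \eqn{g(t; p) = dG/dt} of [cost_of_time()] to them by
#' nonlinear least squares on the log scale (the Hamiltonians span several
#' decades). The fit is non-convex, so a multi-start Levenberg--Marquardt
#' scheme is used with `p4` bounded in `[1e-6, 10]`.
#'
#' @param ad_fit An [fit_amplitude_duration()] object, or any list with
#'   numeric `slope` (s/rad) and `intercept` (s).
#' @param dyn Null-field [wrist_dynamics()] (`viscosity` must be 0).
#' @param cost An [effort_params()] object.
#' @param amplitudes Target amplitudes, rad.
#' @param n_starts Number of random multi-starts (a data-driven heuristic
#'   start is always included).
#' @param seed Seed for the multi-start draws (local; the caller's RNG state
#'   is untouched).
#' @param residual_warn Warn if the RMS residual of the fit, relative to
#'   the largest Hamiltonian magnitude, exceeds this value.
#' @return An object of class `cot_fit`: the identified [cost_of_time()] in
#'   `$cost_of_time`, parameters `$p`, the identification data
#'   `$data` (columns `duration`, `neg_hamiltonian`, `fitted`), the log-RMS
#'   `$residual_rms`, and the inputs. Methods: `print`, `coef`, `predict`
#'   (forward free-final-time durations), `plot`, `fitted`, `residuals`.
#' @seealso [solve_free_time_oc()] for the forward problem.
#' @export
identify_cost_of_time <- function(ad_fit, dyn = wrist_dynamics(),
                                  cost = effort_params(),
                                  amplitudes = target_amplitudes(),
                                  n_starts = 20, seed = 1,
                                  residual_warn = 0.2) {
  if (dyn$viscosity != 0) {
    stop("identify_cost_of_time: identification requires null-field dynamics (viscosity 0)")
  }
  slope <- ad_fit$slope
  intercept <- ad_fit$intercept
  stopifnot(is.numeric(slope), is.numeric(intercept), length(amplitudes) >= 2)
  Tk <- slope * amplitudes + intercept
  if (any(Tk <= 0)) stop("amplitude-duration law yields non-positive durations")

  negH <- vapply(seq_along(amplitudes), function(k) {
    s <- solve_fixed_time_oc(dyn, cost, amplitudes[k], Tk[k])
    -s$hamiltonian_final
  }, numeric(1))
  # The Hamiltonian can be numerically ~0 (or marginally negative) where the
  # effort-vs-duration curve plateaus; clamp for reporting.
  y <- pmax(negH, 1e-6)

  # Plain least squares on the natural scale: the near-zero plateau points
  # carry little information about G and must not dominate the fit (a
  # log-scale fit does exactly that, flattening G past the plateau and
  # destroying the forward self-consistency of the identification).
  resfun <- function(theta) {
    p <- exp(theta)
    time_cost_rate(p, Tk) - y
  }
  lower <- log(c(1e-6, 0.5, 0.02, 1e-6))
  upper <- log(c(1e9, 30, 5, 10))

  heur <- c(p1 = 2 * max(y) * max(Tk), p2 = 7, p3 = stats::median(Tk), p4 = 1)
  starts <- with_local_seed(seed, {
    c(list(log(heur)), lapply(seq_len(n_starts), function(i) {
      log(c(exp(stats::runif(1, log(0.05), log(500))),
            stats::runif(1, 2, 15),
            exp(stats::runif(1, log(0.1), log(2))),
            exp(stats::runif(1, log(1e-3), log(5)))))
    }))
  })
  sols <- list()
  for (th0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(th0, lower), upper), fn = resfun,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sols[[length(sols) + 1L]] <- list(par = fit$par, ss = sum(resfun(fit$par)^2))
  }
  if (!length(sols)) stop("identify_cost_of_time: all sigmoid fits failed")
  # The fit is nearly degenerate (five points, four parameters): local
  # optima with small transversality residuals can differ wildly in their
  # tail exponent p2 * p4, which the data barely constrain but which
  # governs the forward free-final-time behaviour (Hamiltonian values on
  # the effort plateau are noise-level, and chasing them exactly buys a
  # pathological tail). The transversality residual is only the first-order
  # surrogate of the inverse problem, so the returned fit is the distinct
  # local optimum whose forward replay best reproduces the input
  # amplitude-duration law.
  keys <- vapply(sols, function(s) paste(round(s$par, 2), collapse = "|"), "")
  cand <- sols[!duplicated(keys)]
  cand <- cand[order(vapply(cand, `[[`, numeric(1), "ss"))]
  cand <- cand[seq_len(min(4L, length(cand)))]
  replay_err <- function(par) {
    Gc <- cost_of_time(exp(par))
    fw <- vapply(amplitudes, function(a) {
      solve_free_time_oc(dyn, cost, Gc, a, t_range = c(0.05, 3),
                         coarse_n = 40)$duration
    }, numeric(1))
    mean(abs(log(fw / Tk)))
  }
  if (length(cand) > 1) {
    re <- vapply(cand, function(s) replay_err(s$par), numeric(1))
    best <- cand[[which.min(re)]]
  } else best <- cand[[1]]
  p <- exp(best$par)
  names(p) <- c("p1", "p2", "p3", "p4")
  rms <- sqrt(best$ss / length(Tk)) / max(y)
  if (rms > residual_warn) {
    warning(sprintf(paste0("cost-of-time fit residual is large (relative RMS %.3f; ",
                           "per-point residuals: %s)"),
                    rms, paste(sprintf("%.3g", resfun(best$fit$par)), collapse = ", ")))
  }
  out <- list(
    p = unname(p),
    cost_of_time = cost_of_time(unname(p)),
    data = data.frame(amplitude = amplitudes, duration = Tk,
                      neg_hamiltonian = negH,
                      fitted = time_cost_rate(p, Tk)),
    residual_rms = rms,
    ad_fit = list(slope = slope, intercept = intercept),
    dyn = dyn, cost = cost
  )
  class(out) <- "cot_fit"
  out
}

#' @export
print.cot_fit <- function(x, ...) {
  cat("Identified cost of time (inverse optimal control)\n")
  cat(sprintf("  amplitude-duration law: T(A) = %.4g A + %.4g\n",
              x$ad_fit$slope, x$ad_fit$intercept))
  cat(sprintf("  p = (%.5g, %.5g, %.5g, %.5g)   relative RMS residual = %.3g\n",
              x$p[1], x$p[2], x$p[3], x$p[4], x$residual_rms))
  invisible(x)
}

#' @export
coef.cot_fit <- function(object, ...) {
  stats::setNames(object$p, c("p1", "p2", "p3", "p4"))
}

#' @export
fitted.cot_fit <- function(object, ...) object$data$fitted

#' @export
residuals.cot_fit <- function(object, ...) {
  object$data$neg_hamiltonian - object$data$fitted
}

#' Forward predictions from an identified cost of time
#'
#' Solves the free-final-time problem with the identified cost of time at
#' the requested amplitudes; the self-consistency of the identification is
#' how closely these durations reproduce the input amplitude--duration law.
#'
#' @param object A `cot_fit`.
#' @param amplitudes Amplitudes, rad (default: those used in the fit).
#' @param ... Passed to [solve_free_time_oc()].
#' @return Data frame with `amplitude`, `duration`, `tie_flag`.
#' @export
predict.cot_fit <- function(object, amplitudes = NULL, ...) {
  if (is.null(amplitudes)) amplitudes <- object$data$amplitude
  rows <- lapply(amplitudes, function(a) {
    s <- solve_free_time_oc(object$dyn, object$cost, object$cost_of_time, a, ...)
    data.frame(amplitude = a, duration = s$duration,
               tie_flag = isTRUE(s$tie_flag))
  })
  do.call(rbind, rows)
}

#' @export
plot.cot_fit <- function(x, ...) {
  tt <- seq(0.8 * min(x$data$duration), 1.2 * max(x$data$duration),
            length.out = 200)
  graphics::plot(x$data$duration, x$data$neg_hamiltonian, log = "y",
                 xlab = "duration (s)", ylab = "-Hamiltonian / dG/dt",
                 pch = 19, ...)
  graphics::lines(tt, pmax(time_cost_rate(x$p, tt), 1e-12), col = 2)
  invisible(x)
}
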