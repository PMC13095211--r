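#' Minimum-jerk trajectory with terminal hold
#'
#' The quintic point-to-point profile
#' \deqn{q(t) = q_0 + A \zeta^3 (10 - 15\zeta + 6\zeta^2), \quad \zeta = t/\xi,}
#' for \eqn{t \in [0, \xi]}, held at \eqn{q_0 + A} with zero velocity for
#' \eqn{t > \xi} and at \eqn{q_0} for \eqn{t < 0}.
#'
#' @param q0 Start angle, rad.
#' @param A Amplitude, rad (signed).
#' @param xi Movement duration, s (> 0).
#' @param t Time(s), s.
#' @return List with vectors `position` (rad) and `velocity` (rad/s).
#' @examples
#' minimum_jerk(0, pi / 2, 0.8, 0.4)$velocity  # peak = 1.875 * A / xi
#' @export
minimum_jerk <- function(q0, A, xi, t) {
  stopifnot(xi > 0)
  z <- t / xi
  zc <- pmin(pmax(z, 0), 1)
  pos <- q0 + A * zc^3 * (10 - 15 * zc + 6 * zc^2)
  vel <- ifelse(z >= 0 & z <= 1, A / xi * 30 * z^2 * (1 - z)^2, 0)
  list(position = pos, velocity = vel)
}

#' Fraction of a minimum-jerk movement spanned by a velocity threshold
#'
#' Velocity-threshold segmentation marks a movement between the first and
#' last crossing of `threshold` times the peak speed. For a minimum-jerk
#' profile those crossings sit at the roots of
#' \eqn{30 z^2 (1-z)^2 = 1.875\,\mathrm{threshold}}, so the measured span
#' is a fixed fraction of the true duration (0.8811 at the standard 5%
#' threshold). Amplitude--duration laws estimated from thresholded data are
#' therefore laws of the *measured* duration; the session generators divide
#' by this fraction so that segmented synthetic data reproduce the subject's
#' law.
#'
#' @param threshold Fraction of peak speed, in (0, 1).
#' @return Span fraction in (0, 1).
#' @export
minimum_jerk_span_fraction <- function(threshold = 0.05) {
  stopifnot(threshold > 0, threshold < 1)
  # 16 z^2 (1-z)^2 = threshold  =>  z(1-z) = sqrt(threshold)/4
  s <- sqrt(threshold) / 4
  sqrt(1 - 4 * s)
}

#' Sensitivity of minimum-jerk velocity to its duration
#'
#' Analytic partial derivative \eqn{\partial \dot q / \partial \xi} of the
#' minimum-jerk velocity with respect to the movement duration, evaluated at
#' \eqn{\xi = \mu}; zero outside \eqn{(0, \mu)}. This linearization term
#' converts a partner's timing uncertainty (sd of \eqn{\xi}) into velocity
#' --- and hence interaction-torque-change --- uncertainty.
#'
#' With \eqn{z = t/\mu}:
#' \deqn{\partial \dot q/\partial \xi = -(A/\mu^2)\, 30 z^2 (1-z)(3-5z).}
#'
#' @param q0 Start angle (unused; kept for interface symmetry), rad.
#' @param A Amplitude, rad.
#' @param mu Mean duration, s (> 0).
#' @param t Time(s), s.
#' @return Sensitivity in (rad/s)/s, same length as `t`.
#' @export
duration_sensitivity <- function(q0, A, mu, t) {
  stopifnot(mu > 0)
  z <- t / mu
  ifelse(z > 0 & z < 1, -(A / mu^2) * 30 * z^2 * (1 - z) * (3 - 5 * z), 0)
}
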