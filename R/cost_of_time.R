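#' Cost-of-time function
#'
#' Constructs the four-parameter sigmoid-integral cost of time
#' \deqn{G(t) = p_1 \left(1 - \left[1 + (t/p_3)^{p_2}\right]^{-p_4}\right),}
#' a monotone non-decreasing penalty on movement duration used in
#' free-final-time trajectory optimization. Its derivative
#' \eqn{g(t) = dG/dt} equals the negated Hamiltonian of the fixed-final-time
#' effort problem at an individual's preferred durations (transversality),
#' which is what [identify_cost_of_time()] exploits.
#'
#' @param p Numeric vector of length 4, `c(p1, p2, p3, p4)`. `p1` is the
#'   asymptotic cost (cost units), `p2` and `p4` are dimensionless shape
#'   exponents, `p3` is a time scale in seconds.
#' @return An object of class `cost_of_time`: a list with element `p` and
#'   vectorized evaluators `G(t)` and `g(t)`.
#' @examples
#' ct <- cost_of_time(c(1.5713, 6.9723, 0.4497, 1))
#' ct$G(c(0.3, 0.6, 0.9))
#' @export
cost_of_time <- function(p) {
  stopifnot(is.numeric(p), length(p) == 4L, all(is.finite(p)))
  if (p[3] <= 0) stop("cost_of_time: time scale p3 must be positive")
  if (p[1] < 0 || p[2] <= 0 || p[4] < 0) {
    stop("cost_of_time: p1 >= 0, p2 > 0 and p4 >= 0 are required")
  }
  obj <- list(
    p = as.numeric(p),
    G = function(t) time_cost(p, t),
    g = function(t) time_cost_rate(p, t)
  )
  class(obj) <- "cost_of_time"
  obj
}

#' Evaluate the cost of time G(t)
#'
#' Numerically stable for extreme parameter values (for instance very large
#' `p1` combined with very small `p4`): computed as
#' `-p1 * expm1(-p4 * log1p((t/p3)^p2))`.
#'
#' @param p Parameter vector `c(p1, p2, p3, p4)` or a `cost_of_time` object.
#' @param t Time(s) in seconds, non-negative.
#' @return G(t), same length as `t`.
#' @export
time_cost <- function(p, t) {
  if (inherits(p, "cost_of_time")) p <- p$p
  stopifnot(all(t >= 0))
  -p[1] * expm1(-p[4] * log1p(exp(p[2] * (log(t) - log(p[3])))))
}

#' Evaluate the cost-of-time derivative g(t) = dG/dt
#'
#' @inheritParams time_cost
#' @return g(t) in cost units per second; `0` at `t = 0`.
#' @export
time_cost_rate <- function(p, t) {
  if (inherits(p, "cost_of_time")) p <- p$p
  stopifnot(all(t >= 0))
  # g = p1 p2 p4 x / (t (1+x)^(p4+1)), x = (t/p3)^p2; evaluated in logs
  out <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  lx <- p[2] * (log(tp) - log(p[3]))
  out[pos] <- exp(log(p[1]) + log(p[2]) + log(p[4]) + lx - log(tp) -
                    (p[4] + 1) * log1p(exp(lx)))
  out
}

#' @export
print.cost_of_time <- function(x, ...) {
  cat("Cost of time G(t) = p1 (1 - [1 + (t/p3)^p2]^-p4)\n")
  cat(sprintf("  p = (%.6g, %.6g, %.6g, %.6g)\n",
              x$p[1], x$p[2], x$p[3], x$p[4]))
  invisible(x)
}

#' Reference population parameters for wrist reaching
#'
#' Amplitude--duration laws and cost-of-time parameters describing the
#' behaviour of a reference population of young adults performing self-paced
#' wrist flexion/extension reaching (targets 18--90 degrees): the
#' population-average law \eqn{T(A) = 0.314 A + 0.298} (A in radians, T in
#' seconds) and the group laws of the faster (\eqn{0.235 A + 0.285}) and
#' slower (\eqn{0.35 A + 0.323}) partners of coupled dyads, together with the
#' cost-of-time parameter vectors identified for each by inverse optimal
#' control under the minimum-torque-change effort model.
#'
#' @param group One of `"average"`, `"fast"`, `"slow"`.
#' @return A list with `ad_slope` (s/rad), `ad_intercept` (s), and
#'   `cost_of_time` (a [cost_of_time()] object).
#' @examples
#' wrist_population("fast")$ad_slope
#' @export
wrist_population <- function(group = c("average", "fast", "slow")) {
  group <- match.arg(group)
  tab <- list(
    average = list(ad_slope = 0.314, ad_intercept = 0.298,
                   p = c(1.5713, 6.9723, 0.4497, 1)),
    fast    = list(ad_slope = 0.235, ad_intercept = 0.285,
                   p = c(3.9615, 5.8958, 0.4459, 1)),
    slow    = list(ad_slope = 0.35, ad_intercept = 0.323,
                   p = c(1.0184e7, 11.2958, 1.9980, 1.4447e-5))
  )[[group]]
  list(ad_slope = tab$ad_slope, ad_intercept = tab$ad_intercept,
       cost_of_time = cost_of_time(tab$p))
}

#' Standard target amplitudes
#'
#' The five target amplitudes 18, 36, 54, 72, 90 degrees, in radians.
#' @return Numeric vector of length 5 (radians).
#' @export
target_amplitudes <- function() c(18, 36, 54, 72, 90) * pi / 180
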