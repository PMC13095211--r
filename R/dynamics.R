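#' Wrist dynamics parameters
#'
#' Single-joint wrist + exoskeleton dynamics
#' \deqn{I \ddot q = \tau - D \dot q - \nu \dot q,}
#' with inertia `I` (Nm s^2), intrinsic damping `D` (Nm s) and an optional
#' resistive viscous load `nu` (Nm s/rad) applied by the robot.
#'
#' @param inertia Total hand + robot inertia, Nm s^2.
#' @param damping Intrinsic wrist damping, Nm s.
#' @param viscosity Commanded viscous load, Nm s/rad (0, 0.075 or 0.15 in the
#'   standard protocol; any non-negative value is accepted).
#' @return An object of class `wrist_dynamics`.
#' @export
wrist_dynamics <- function(inertia = 9.2e-3, damping = 0.03, viscosity = 0) {
  stopifnot(inertia > 0, damping >= 0, viscosity >= 0)
  structure(list(inertia = inertia, damping = damping, viscosity = viscosity),
            class = "wrist_dynamics")
}

#' @export
print.wrist_dynamics <- function(x, ...) {
  cat(sprintf("Wrist dynamics: I = %.4g Nm s^2, D = %.4g Nm s, nu = %.4g Nm s/rad\n",
              x$inertia, x$damping, x$viscosity))
  invisible(x)
}

#' Effort cost parameters
#'
#' Parameters of the minimum-torque-change effort cost
#' \deqn{E(u) = \int_0^T (x_e - x)' Q_k (x_e - x) + \beta u^2 \, dt,}
#' on the state \eqn{x = (q, \dot q, \tau)} with control \eqn{u = \dot\tau}.
#' The position-error weight is amplitude-dependent,
#' \eqn{Q_k = \mathrm{diag}(w/A_k, 0, 0)} with `w = q_weight_scale`, so that
#' short and long reaches trade accuracy against effort comparably.
#'
#' @param beta Weight on squared torque change (dimensionless), default 0.95.
#' @param q_weight_scale Numerator of the position-error weight, default 15.5;
#'   the weight applied at amplitude `A` (rad) is `q_weight_scale / A`.
#' @return An object of class `effort_params`.
#' @export
effort_params <- function(beta = 0.95, q_weight_scale = 15.5) {
  stopifnot(beta > 0, q_weight_scale > 0)
  structure(list(beta = beta, q_weight_scale = q_weight_scale),
            class = "effort_params")
}

#' Coupling parameters of the virtual elastic band
#'
#' @param stiffness Elastic stiffness kappa in Nm/rad (0.5 for the low, 1.6
#'   for the high-stiffness connection).
#' @param viscosity Shared viscous load nu in Nm s/rad.
#' @return An object of class `coupling_params`.
#' @export
coupling_params <- function(stiffness, viscosity = 0) {
  stopifnot(stiffness >= 0, viscosity >= 0)
  structure(list(stiffness = stiffness, viscosity = viscosity),
            class = "coupling_params")
}

#' Experimental condition table
#'
#' Enumerates the six coupled conditions (2 stiffness x 3 viscous loads) per
#' target amplitude. Condition labels follow the session nomenclature: KL/KH
#' for the low/high-stiffness band, suffixed VL/VH for the light/heavy
#' viscous load.
#'
#' @param amplitudes Target amplitudes in radians.
#' @return A data frame with columns `condition`, `stiffness`, `viscosity`,
#'   `target_index`, `amplitude`.
#' @export
condition_table <- function(amplitudes = target_amplitudes()) {
  kappa <- c(KL = 0.5, KH = 1.6)
  nu <- c(0, 0.075, 0.15)
  nu_tag <- c("", "VL", "VH")
  grid <- expand.grid(k = seq_along(kappa), v = seq_along(nu),
                      a = seq_along(amplitudes))
  data.frame(
    condition = paste0(names(kappa)[grid$k], nu_tag[grid$v]),
    stiffness = unname(kappa[grid$k]),
    viscosity = unname(nu[grid$v]),
    target_index = grid$a,
    amplitude = amplitudes[grid$a],
    stringsAsFactors = FALSE
  )
}
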