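## Trapezoidal-collocation solver for the linear-quadratic optimal-control
## problems used throughout: minimum-torque-change reaching on the state
## x = (q, qdot, tau) with control u = taudot. Because the dynamics are
## linear and the running cost quadratic, the transcribed problem is an
## equality-constrained QP solved exactly through its sparse KKT system;
## the dynamics multipliers provide the costate and hence the Hamiltonian.

# Continuous-time system matrices for one wrist, optionally elastically
# coupled (stiffness kappa) to an exogenous reference position.
oc_system <- function(dyn, kappa = 0) {
  I <- dyn$inertia
  A <- matrix(c(0, 1, 0,
                -kappa / I, -(dyn$damping + dyn$viscosity) / I, 1 / I,
                0, 0, 0), 3, 3, byrow = TRUE)
  list(A = A, B = c(0, 0, 1))
}

# Node count giving a target step of `h` seconds, clamped to [nmin, nmax].
oc_nodes <- function(T, h = 0.002, nmin = 101, nmax = 601) {
  min(nmax, max(nmin, round(T / h) + 1L))
}

# Core transcription. Running cost:
#   wq (qe - q)^2 + wv (vref(t) - qdot)^2 + beta u^2 + const(t)
# Dynamics: xdot = A x + B u + d(t), d(t) = (0, kappa qref(t)/I, 0).
# Boundary: x(0) = x0; q(T) = qe always; qdot(T) and tau(T) optionally fixed.
oc_transcribe <- function(dyn, amplitude, T, wq, beta, N,
                          kappa = 0, qref = NULL, vref = NULL, wv = 0,
                          fix_final_velocity = TRUE, fix_final_torque = TRUE,
                          tau_final = 0, extra_running = NULL) {
  sys <- oc_system(dyn, kappa)
  A <- sys$A
  h <- T / (N - 1)
  ts <- seq(0, T, length.out = N)
  qe <- amplitude
  if (is.null(qref)) qref <- numeric(N)
  if (is.null(vref)) vref <- numeric(N)

  wi <- rep(h, N); wi[1] <- wi[N] <- h / 2
  nz <- 4L * N

  # Quadratic cost: z' Hm z - 2 cvec' z + const
  Hx <- rbind(wi * wq, wi * wv, 0)
  Hm <- Matrix::Diagonal(x = c(as.numeric(Hx), wi * beta))
  cx <- rbind(wi * wq * qe, wi * wv * vref, 0)
  cvec <- c(as.numeric(cx), numeric(N))

  # Dynamics defects, vectorized triplet assembly
  M1 <- -diag(3) - h / 2 * A
  M2 <- diag(3) - h / 2 * A
  ni <- N - 1L
  idx <- 0:(ni - 1L)
  rblk <- rep(rep(1:3, 3), ni); cblk <- rep(rep(1:3, each = 3), ni)
  off <- rep(3L * idx, each = 9L)
  ii <- c(off + rblk, off + rblk,
          3L * idx + 3L, 3L * idx + 3L)
  jj <- c(off + cblk, off + cblk + 3L,
          3L * N + idx + 1L, 3L * N + idx + 2L)
  vv <- c(rep(as.vector(M1), ni), rep(as.vector(M2), ni),
          rep(-h / 2, ni), rep(-h / 2, ni))
  dcurve <- kappa * qref / dyn$inertia
  bdyn <- numeric(3L * ni)
  bdyn[3L * idx + 2L] <- h / 2 * (dcurve[1:ni] + dcurve[2:N])

  # Boundary conditions
  bc_col <- c(1L, 2L, 3L, 3L * (N - 1L) + 1L)
  bc_val <- c(0, 0, 0, qe)
  if (fix_final_velocity) { bc_col <- c(bc_col, 3L * (N - 1L) + 2L); bc_val <- c(bc_val, 0) }
  if (fix_final_torque)   { bc_col <- c(bc_col, 3L * (N - 1L) + 3L); bc_val <- c(bc_val, tau_final) }
  nb <- length(bc_col)
  ii <- c(ii, 3L * ni + seq_len(nb))
  jj <- c(jj, bc_col)
  vv <- c(vv, rep(1, nb))
  m <- 3L * ni + nb
  E <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(m, nz))
  b <- c(bdyn, bc_val)

  KKT <- rbind(cbind(2 * Hm, Matrix::t(E)),
               cbind(E, Matrix::Matrix(0, m, m)))
  sol <- tryCatch(as.numeric(Matrix::solve(KKT, c(2 * cvec, b))),
                  error = function(e) NULL)
  if (is.null(sol)) {
    return(list(converged = FALSE, T = T))
  }
  z <- sol[1:nz]
  mult <- sol[(nz + 1):(nz + m)]
  X <- matrix(z[1:(3 * N)], nrow = 3)
  u <- z[(3 * N + 1):(4 * N)]

  L <- wq * (qe - X[1, ])^2 + wv * (vref - X[2, ])^2 + beta * u^2
  if (!is.null(extra_running)) L <- L + extra_running
  J <- sum(wi * L)

  # Costate from the defect multipliers; interior-node Hamiltonian
  NU <- matrix(mult[1:(3 * ni)], nrow = 3)
  interior <- 2:(N - 1)
  lam <- -(NU[, interior - 1L, drop = FALSE] + NU[, interior, drop = FALSE]) / 2
  f <- A %*% X[, interior, drop = FALSE]
  f[2, ] <- f[2, ] + dcurve[interior]
  f[3, ] <- f[3, ] + u[interior]
  ham <- L[interior] + colSums(lam * f)

  list(converged = TRUE, t = ts, state = X, control = u,
       effort_cost = J, running = L, weights = wi,
       hamiltonian = ham, costate = lam, T = T)
}

#' Solve the fixed-final-time minimum-torque-change problem
#'
#' Minimizes \eqn{\int_0^T (x_e - x)' Q_k (x_e - x) + \beta u^2 \, dt} on
#' the wrist dynamics, with \eqn{Q_k = \mathrm{diag}(w/A_k, 0, 0)}, from rest
#' at 0 to rest at `amplitude`, by direct transcription with trapezoidal
#' collocation (the transcribed problem is a convex QP and is solved exactly
#' via its KKT system). The initial and final torque are the steady-state
#' torque holding the posture (zero for this load-free plant).
#'
#' The problem is autonomous, so the Hamiltonian is constant along the
#' optimal trajectory; its value equals \eqn{-dV/dT}, the marginal effort
#' saved by moving slower, which drives [identify_cost_of_time()].
#'
#' @param dyn A [wrist_dynamics()] object.
#' @param cost An [effort_params()] object.
#' @param amplitude Movement amplitude in radians (>= 0).
#' @param T Movement duration in seconds, in `[0.01, 10]`.
#' @param nodes Number of collocation nodes; default targets a 2 ms step,
#'   at least 101 nodes.
#' @param fix_final_velocity,fix_final_torque Whether the terminal velocity
#'   and torque are constrained (both `TRUE` for the solo rest-to-rest
#'   problem).
#' @return An object of class `oc_solution` with elements `t`, `state`
#'   (3 x N matrix: position, velocity, torque), `control`, `effort_cost`,
#'   `hamiltonian` (interior nodes), `hamiltonian_final` (its median),
#'   `duration` and `converged`.
#' @examples
#' sol <- solve_fixed_time_oc(wrist_dynamics(), effort_params(),
#'                            amplitude = pi / 2, T = 0.79)
#' sol$effort_cost
#' @export
solve_fixed_time_oc <- function(dyn, cost, amplitude, T, nodes = NULL,
                                fix_final_velocity = TRUE,
                                fix_final_torque = TRUE) {
  stopifnot(inherits(dyn, "wrist_dynamics"), inherits(cost, "effort_params"))
  if (T < 0.01 - 1e-9 || T > 10 + 1e-9) stop("duration T must lie in [0.01, 10] s")
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (amplitude == 0) {
    N <- if (is.null(nodes)) oc_nodes(T) else nodes
    ts <- seq(0, T, length.out = N)
    out <- list(converged = TRUE, t = ts, state = matrix(0, 3, N),
                control = numeric(N), effort_cost = 0,
                hamiltonian = numeric(N - 2), hamiltonian_final = 0,
                duration = T)
    class(out) <- "oc_solution"
    return(out)
  }
  N <- if (is.null(nodes)) oc_nodes(T) else nodes
  wq <- cost$q_weight_scale / amplitude
  r <- oc_transcribe(dyn, amplitude, T, wq = wq, beta = cost$beta, N = N,
                     fix_final_velocity = fix_final_velocity,
                     fix_final_torque = fix_final_torque)
  if (!isTRUE(r$converged)) {
    out <- list(converged = FALSE, duration = T)
    class(out) <- "oc_solution"
    return(out)
  }
  out <- list(converged = TRUE, t = r$t, state = r$state, control = r$control,
              effort_cost = r$effort_cost, hamiltonian = r$hamiltonian,
              hamiltonian_final = stats::median(r$hamiltonian),
              duration = T)
  class(out) <- "oc_solution"
  out
}

#' @export
print.oc_solution <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("Optimal-control solution: NOT converged\n")
    return(invisible(x))
  }
  cat(sprintf("Optimal-control solution: T = %.4f s, effort cost = %.5g",
              x$duration, x$effort_cost))
  if (!is.null(x$total_cost)) cat(sprintf(", total cost = %.5g", x$total_cost))
  cat("\n")
  if (!is.null(x$tie_flag) && x$tie_flag) {
    cat("  note: multiple near-optimal durations; smallest returned\n")
  }
  invisible(x)
}

# Internal: effort cost as a function of duration, at coarse or fine mesh.
oc_effort_of_T <- function(dyn, cost, amplitude, stage = c("fine", "coarse")) {
  stage <- match.arg(stage)
  force(dyn); force(cost); force(amplitude)
  function(T) {
    N <- if (stage == "coarse") oc_nodes(T, h = 0.005, nmax = 301) else oc_nodes(T)
    s <- solve_fixed_time_oc(dyn, cost, amplitude, T, nodes = N)
    if (!isTRUE(s$converged)) return(NA_real_)
    s$effort_cost
  }
}

# Internal: minimize total(T) over T by coarse grid + local Brent refinement
# of every grid-local minimum; among refined minima within `tie_tol` relative
# cost of the best, the smallest duration wins (flagged when several tie).
free_time_search <- function(total_coarse, total_fine,
                             t_range = c(0.01, 10), coarse_n = 60,
                             tie_tol = 0.005) {
  Tg <- exp(seq(log(t_range[1]), log(t_range[2]), length.out = coarse_n))
  vg <- vapply(Tg, total_coarse, numeric(1))
  ok <- is.finite(vg)
  d2 <- diff(sign(diff(vg)))
  locs <- which(d2 > 0) + 1L
  if (ok[1] && vg[1] < vg[2]) locs <- c(1L, locs)
  if (ok[coarse_n] && vg[coarse_n] < vg[coarse_n - 1]) locs <- c(locs, coarse_n)
  if (!length(locs)) locs <- which.min(vg)
  cands <- t(vapply(locs, function(i) {
    lo <- Tg[max(1L, i - 1L)]; hi <- Tg[min(coarse_n, i + 1L)]
    o <- stats::optimize(total_fine, c(lo, hi), tol = 5e-5)
    c(o$minimum, o$objective)
  }, numeric(2)))
  best <- min(cands[, 2])
  near <- cands[, 2] <= best * (1 + tie_tol)
  list(T = min(cands[near, 1]), value = cands[which(near)[which.min(cands[near, 1])], 2],
       n_near = sum(near), candidates = cands)
}

#' Solve the free-final-time reaching problem
#'
#' Minimizes total cost \eqn{G(T) + E(u, T)} over both the control and the
#' movement duration, where `G` is a [cost_of_time()] and `E` the
#' minimum-torque-change effort of [solve_fixed_time_oc()]. The outer scalar
#' minimization over `T` evaluates a log-spaced coarse grid over the search
#' interval, refines every grid-local minimum by Brent search on a fine mesh,
#' and returns the smallest duration among candidates whose cost lies within
#' a small relative tolerance of the best (the total cost can be extremely
#' flat in `T`, with distinct near-degenerate minima; such ties are resolved
#' to the faster movement and flagged).
#'
#' @inheritParams solve_fixed_time_oc
#' @param G A [cost_of_time()] object.
#' @param t_range Search interval for the duration, default `c(0.01, 10)` s.
#' @param coarse_n Number of coarse-grid points (log-spaced), >= 40.
#' @param tie_tol Relative cost tolerance under which near-optimal durations
#'   are treated as ties; default 0.005 (five times the transcription
#'   accuracy bound).
#' @return An `oc_solution` for the optimal duration, with extra fields
#'   `total_cost`, `time_cost`, `tie_flag` and `candidates` (matrix of
#'   refined local minima: duration, total cost).
#' @export
solve_free_time_oc <- function(dyn, cost, G, amplitude,
                               t_range = c(0.01, 10), coarse_n = 60,
                               tie_tol = 0.005, fix_final_velocity = TRUE,
                               fix_final_torque = TRUE) {
  stopifnot(inherits(G, "cost_of_time"))
  eff_c <- function(T) {
    N <- oc_nodes(T, h = 0.005, nmax = 301)
    s <- solve_fixed_time_oc(dyn, cost, amplitude, T, nodes = N,
                             fix_final_velocity = fix_final_velocity,
                             fix_final_torque = fix_final_torque)
    if (!isTRUE(s$converged)) return(NA_real_)
    s$effort_cost
  }
  eff_f <- function(T) {
    s <- solve_fixed_time_oc(dyn, cost, amplitude, T,
                             fix_final_velocity = fix_final_velocity,
                             fix_final_torque = fix_final_torque)
    if (!isTRUE(s$converged)) return(NA_real_)
    s$effort_cost
  }
  sr <- free_time_search(function(T) G$G(T) + eff_c(T),
                         function(T) G$G(T) + eff_f(T),
                         t_range = t_range, coarse_n = coarse_n,
                         tie_tol = tie_tol)
  sol <- solve_fixed_time_oc(dyn, cost, amplitude, sr$T,
                             fix_final_velocity = fix_final_velocity,
                             fix_final_torque = fix_final_torque)
  sol$duration <- sr$T
  sol$time_cost <- G$G(sr$T)
  sol$total_cost <- sol$effort_cost + sol$time_cost
  sol$tie_flag <- sr$n_near > 1
  sol$candidates <- sr$candidates
  sol
}

#' Predict movement durations under viscous loads
#'
#' Batch wrapper over [solve_free_time_oc()]: for each amplitude and each
#' viscous-load level, solves the free-final-time problem and reports the
#' optimal duration, effort cost and the mechanical work
#' \eqn{\int \tau \dot q \, dt} of the optimal trajectory.
#'
#' @param G A [cost_of_time()] object.
#' @param amplitudes Amplitudes in radians.
#' @param nu_levels Viscous loads in Nm s/rad.
#' @param dyn Base dynamics (its `viscosity` field is replaced per level).
#' @param cost An [effort_params()] object.
#' @param ... Passed to [solve_free_time_oc()].
#' @return Data frame with columns `viscosity`, `amplitude`, `duration`,
#'   `effort`, `work`, `tie_flag`.
#' @export
predict_loaded_durations <- function(G, amplitudes = target_amplitudes(),
                                     nu_levels = c(0, 0.075, 0.15),
                                     dyn = wrist_dynamics(),
                                     cost = effort_params(), ...) {
  rows <- list()
  for (nu in nu_levels) {
    d <- wrist_dynamics(dyn$inertia, dyn$damping, nu)
    for (a in amplitudes) {
      s <- solve_free_time_oc(d, cost, G, a, ...)
      work <- if (isTRUE(s$converged)) {
        wi <- rep(diff(s$t[1:2]), length(s$t)); wi[1] <- wi[length(wi)] <- wi[1] / 2
        sum(wi * s$state[3, ] * s$state[2, ])
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        viscosity = nu, amplitude = a, duration = s$duration,
        effort = s$effort_cost, work = work, tie_flag = isTRUE(s$tie_flag))
    }
  }
  do.call(rbind, rows)
}
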