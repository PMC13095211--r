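## Kinematic processing of wrist-angle time series: zero-phase filtering,
## numerical differentiation, velocity-threshold segmentation, reaction
## times, amplitude-duration regression and spectral smoothness.

#' Zero-phase low-pass filter for position data
#'
#' Forward--backward (zero-phase) fifth-order Butterworth filter with 5 Hz
#' cutoff, the standard pre-processing step before numerical
#' differentiation of wrist angles.
#'
#' @param q Angle series, rad.
#' @param sample_rate Sampling rate, Hz (> 10).
#' @param cutoff Cutoff frequency, Hz.
#' @param order Filter order.
#' @return Filtered series, same length.
#' @export
filter_position <- function(q, sample_rate, cutoff = 5, order = 5) {
  stopifnot(sample_rate > 10)
  if (length(q) <= 3 * order) {
    stop("filter_position: series too short for zero-phase filtering ",
         "(need length > 3 x filter order)")
  }
  bf <- signal::butter(order, cutoff / (sample_rate / 2), type = "low")
  # Odd-reflection edge padding keeps the zero-phase pass free of the end
  # transients that plain zero-padding produces on series not ending at 0.
  n <- length(q)
  np <- min(n - 1L, max(3L * order, ceiling(4 * sample_rate / cutoff)))
  head_pad <- 2 * q[1] - q[(np + 1L):2L]
  tail_pad <- 2 * q[n] - q[(n - 1L):(n - np)]
  qf <- signal::filtfilt(bf, c(head_pad, q, tail_pad))
  as.numeric(qf[(np + 1L):(np + n)])
}

#' Numerical differentiation
#'
#' Central differences at interior samples, one-sided differences at the
#' ends; applied twice for acceleration.
#'
#' @param q Angle series, rad (filtering recommended first).
#' @param sample_rate Sampling rate, Hz.
#' @return List with `velocity` (rad/s) and `acceleration` (rad/s^2).
#' @export
differentiate <- function(q, sample_rate) {
  n <- length(q)
  stopifnot(n >= 3)
  h <- 1 / sample_rate
  d1 <- function(x) {
    v <- numeric(n)
    v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * h)
    v[1] <- (x[2] - x[1]) / h
    v[n] <- (x[n] - x[n - 1]) / h
    v
  }
  v <- d1(q)
  list(velocity = v, acceleration = d1(v))
}

#' Segment movements from a trial
#'
#' Coarse windows are taken from the target timing (onset to onset + 1.9 s,
#' respecting the 2 s target display), then movement start and end are the
#' first and last crossing of 5% of the within-window peak speed. Windows
#' whose peak speed is below a floor are dropped. Flexion and extension
#' movements are distinguished by the sign of the displacement and pooled
#' downstream.
#'
#' @param trial A `trial_time_series` (see [generate_minimum_jerk_trial()]).
#' @param channel Which angle channel to segment (1 = solo / fast partner,
#'   2 = slow partner).
#' @param threshold_frac Fraction of peak speed defining start/end.
#' @param speed_floor Minimum peak speed (rad/s) for a window to count as a
#'   movement.
#' @param window Search-window length after target onset, s.
#' @param filter Logical; low-pass filter the angle before differentiating.
#' @return Data frame of movement segments (possibly 0 rows): `t_start`,
#'   `t_end`, `duration`, `amplitude` (unsigned), `direction`,
#'   `peak_velocity`, `target_index`, `mean_abs_tau_i` (NA for solo trials),
#'   `smoothness`.
#' @export
segment_movements <- function(trial, channel = 1, threshold_frac = 0.05,
                              speed_floor = 0.02, window = 1.9,
                              filter = TRUE) {
  stopifnot(inherits(trial, "trial_time_series"))
  q <- trial_channel(trial, channel)
  fs <- trial$sample_rate
  qf <- if (filter) filter_position(q, fs) else q
  v <- differentiate(qf, fs)$velocity
  t <- trial$t

  out <- list()
  for (m in seq_len(nrow(trial$markers))) {
    onset <- trial$markers$target_onset[m]
    iwin <- which(t >= onset & t <= onset + window)
    if (length(iwin) < 3) next
    sp <- abs(v[iwin])
    pk <- max(sp)
    if (pk < speed_floor) next
    thr <- threshold_frac * pk
    # First/last crossing of the contiguous suprathreshold region holding
    # the peak: walk outward from the peak until the speed drops below
    # threshold (robust to subthreshold noise elsewhere in the window).
    ipk <- which.max(sp)
    a <- ipk; while (a > 1 && sp[a - 1] >= thr) a <- a - 1
    b <- ipk; while (b < length(sp) && sp[b + 1] >= thr) b <- b + 1
    i1 <- iwin[a]                        # first crossing (earlier sample)
    i2 <- iwin[b]                        # last crossing (later sample)
    if (i2 <= i1) next
    disp <- qf[i2] - qf[i1]
    seg_v <- v[i1:i2]
    tau <- NA_real_
    if (!is.null(trial$tau_interaction)) {
      tau <- mean(abs(trial$tau_interaction[i1:i2]))
    }
    out[[length(out) + 1L]] <- data.frame(
      t_start = t[i1], t_end = t[i2], duration = t[i2] - t[i1],
      amplitude = abs(disp),
      direction = if (disp >= 0) "extension" else "flexion",
      peak_velocity = pk,
      target_index = trial$markers$target_index[m],
      mean_abs_tau_i = tau,
      smoothness = spectral_smoothness(seg_v, fs),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      duration = numeric(0), amplitude = numeric(0),
                      direction = character(0), peak_velocity = numeric(0),
                      target_index = integer(0), mean_abs_tau_i = numeric(0),
                      smoothness = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Reaction time of a trial
#'
#' Time from target onset to the first instant at which the absolute wrist
#' angular velocity exceeds a threshold (0.01 rad/s).
#'
#' @inheritParams segment_movements
#' @param threshold Velocity threshold, rad/s.
#' @return Reaction time in seconds, or `NA` if the velocity never exceeds
#'   the threshold after onset.
#' @export
reaction_time <- function(trial, channel = 1, threshold = 0.01,
                          filter = TRUE) {
  stopifnot(inherits(trial, "trial_time_series"))
  q <- trial_channel(trial, channel)
  fs <- trial$sample_rate
  qf <- if (filter) filter_position(q, fs) else q
  v <- differentiate(qf, fs)$velocity
  onset <- trial$markers$target_onset[1]
  idx <- which(trial$t >= onset & abs(v) > threshold)
  if (!length(idx)) return(NA_real_)
  trial$t[idx[1]] - onset
}

#' Fit the affine amplitude--duration relation
#'
#' Durations and amplitudes are first averaged per target (and, when a
#' `participant` column is present, per participant per target and then
#' across participants), and the per-target means are regressed by ordinary
#' least squares: \eqn{T(A) = a A + b}.
#'
#' @param segments Data frame with columns `amplitude`, `duration`,
#'   `target_index`, optionally `participant`.
#' @return Object of class `ad_fit`: `slope` (s/rad), `intercept` (s),
#'   `r_squared`, `n_points`, and `degenerate` (`TRUE` when all mean
#'   durations are equal, in which case the slope is 0 and `r_squared` is
#'   reported as 0 with the flag set).
#' @export
fit_amplitude_duration <- function(segments) {
  stopifnot(all(c("amplitude", "duration", "target_index") %in% names(segments)))
  if (length(unique(segments$target_index)) < 2) {
    stop("fit_amplitude_duration: need segments for at least 2 distinct targets")
  }
  if ("participant" %in% names(segments)) {
    per <- stats::aggregate(cbind(amplitude, duration) ~ participant + target_index,
                            data = segments, FUN = mean)
    agg <- stats::aggregate(cbind(amplitude, duration) ~ target_index,
                            data = per, FUN = mean)
  } else {
    agg <- stats::aggregate(cbind(amplitude, duration) ~ target_index,
                            data = segments, FUN = mean)
  }
  degenerate <- stats::var(agg$duration) < .Machine$double.eps
  fit <- stats::lm(duration ~ amplitude, data = agg)
  # exact affine data are a legitimate input; silence the perfect-fit note
  r2 <- if (degenerate) 0 else suppressWarnings(summary(fit)$r.squared)
  out <- list(slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]),
              r_squared = r2, n_points = nrow(agg),
              degenerate = degenerate, means = agg)
  if (degenerate) out$slope <- 0
  class(out) <- "ad_fit"
  out
}

#' @export
print.ad_fit <- function(x, ...) {
  cat(sprintf("Amplitude-duration fit: T(A) = %.4g A + %.4g  (r2 = %.3f, %d targets%s)\n",
              x$slope, x$intercept, x$r_squared, x$n_points,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' @export
coef.ad_fit <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' Mean absolute interaction torque over a movement
#'
#' Time-average of the absolute elastic-band torque over a movement segment
#' of a coupled trial. Invariant under swapping partner labels (the torque
#' magnitude is shared).
#'
#' @param segment A single-row data frame (or list) with `t_start`, `t_end`.
#' @param trial A coupled `trial_time_series` (with `tau_interaction`).
#' @return Mean absolute torque, Nm.
#' @export
mean_abs_interaction_torque <- function(segment, trial) {
  stopifnot(inherits(trial, "trial_time_series"))
  if (is.null(trial$tau_interaction)) {
    stop("mean_abs_interaction_torque: trial has no interaction-torque channel")
  }
  idx <- which(trial$t >= segment$t_start & trial$t <= segment$t_end)
  mean(abs(trial$tau_interaction[idx]))
}

#' Spectral arc-length smoothness of a speed profile
#'
#' Smoothness score of a movement's speed profile: the negative arc length
#' of its amplitude-normalized Fourier magnitude spectrum, computed on a
#' zero-padded FFT (next power of two at least four times the segment
#' length). The band runs from 0 Hz up to an adaptive cutoff --- the
#' highest frequency at which the normalized magnitude still exceeds
#' `amp_threshold`, capped at `f_max` --- and the frequency axis is
#' normalized by that cutoff, which makes the score insensitive to
#' amplitude scaling and to time rescaling of the profile. Scores are
#' negative; values closer to zero indicate smoother movements.
#'
#' @param velocity Speed or velocity samples of one movement segment.
#' @param sample_rate Hz.
#' @param f_max Upper cap on the adaptive band limit, Hz.
#' @param amp_threshold Normalized-magnitude threshold defining the
#'   adaptive cutoff.
#' @param pad_factor Zero-padding factor.
#' @param min_length Minimum segment length in samples.
#' @return Negative arc length (dimensionless), or `NA` for too-short or
#'   zero-velocity segments.
#' @export
spectral_smoothness <- function(velocity, sample_rate, f_max = 10,
                                amp_threshold = 0.05,
                                pad_factor = 4, min_length = 32) {
  n <- length(velocity)
  if (n < min_length) return(NA_real_)
  sp <- abs(velocity)
  if (max(sp) <= 0) return(NA_real_)
  nfft <- 2^ceiling(log2(pad_factor * n))
  Vf <- abs(stats::fft(c(sp, numeric(nfft - n))))
  f <- (0:(nfft - 1)) * sample_rate / nfft
  keep <- f <= f_max
  Vf <- Vf[keep]; f <- f[keep]
  Vn <- Vf / max(Vf)
  ic <- which(Vn >= amp_threshold)
  fc <- f[min(max(ic) + 1L, length(f))]
  sel <- f <= fc
  Vs <- Vn[sel]
  df <- diff(f[sel]) / fc
  -sum(sqrt(df^2 + diff(Vs)^2))
}

#' Segment every trial of a session
#'
#' Convenience wrapper running [segment_movements()] over a list of trials,
#' stacking the result with trial and participant bookkeeping columns.
#'
#' @param trials List of `trial_time_series`.
#' @param channel Angle channel to segment.
#' @param participant Label stored in the `participant` column.
#' @param ... Passed to [segment_movements()].
#' @return Data frame of segments.
#' @export
session_segments <- function(trials, channel = 1, participant = "S1", ...) {
  segs <- lapply(seq_along(trials), function(i) {
    s <- segment_movements(trials[[i]], channel = channel, ...)
    if (nrow(s)) {
      s$trial <- i
      s$condition <- trials[[i]]$condition
      s$participant <- participant
    }
    s
  })
  out <- do.call(rbind, segs[vapply(segs, nrow, 1L) > 0])
  if (is.null(out)) {
    out <- data.frame(t_start = numeric(0), t_end = numeric(0),
                      duration = numeric(0), amplitude = numeric(0),
                      direction = character(0), peak_velocity = numeric(0),
                      target_index = integer(0), mean_abs_tau_i = numeric(0),
                      smoothness = numeric(0), trial = integer(0),
                      condition = character(0), participant = character(0))
  }
  out
}
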