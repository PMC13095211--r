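## End-to-end orchestration: generate a synthetic cohort, process its
## kinematics, score vigor, identify the cost of time, predict the dyadic
## conditions under every hypothesis, and compare.

#' Pipeline configuration
#'
#' @param seed Master seed; every stage derives its randomness from it.
#' @param out_dir Output directory (`NULL` for none: results only returned).
#' @param stages Which stages to run, a subset of
#'   `c("generate", "kinematics", "vigor", "identify", "predict", "compare")`.
#'   Later stages require the earlier ones.
#' @param n_dyads Number of synthetic dyads.
#' @param trials_per_target_per_direction Repetitions in generated sessions
#'   (kept small by default; the full protocol uses 10).
#' @param hypotheses Hypotheses for the prediction stage.
#' @param alpha Weighted-adaptation weight.
#' @param amplitudes Target amplitudes, rad.
#' @param duration_cv Trial-to-trial duration variability of the synthetic
#'   subjects.
#' @param quality `"fast"` (coarser duration search for the optimal-control
#'   stages) or `"standard"`.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, out_dir = NULL,
                       stages = c("generate", "kinematics", "vigor",
                                  "identify", "predict", "compare"),
                       n_dyads = 5, trials_per_target_per_direction = 2,
                       hypotheses = c("co_activity", "leader_fast",
                                      "leader_slow", "weighted",
                                      "interactive_adaptation"),
                       alpha = 0.5, amplitudes = target_amplitudes(),
                       duration_cv = 0.05,
                       quality = c("fast", "standard")) {
  quality <- match.arg(quality)
  structure(list(seed = as.integer(seed), out_dir = out_dir, stages = stages,
                 n_dyads = n_dyads,
                 trials_per_target_per_direction = trials_per_target_per_direction,
                 hypotheses = hypotheses, alpha = alpha,
                 amplitudes = amplitudes, duration_cv = duration_cv,
                 quality = quality),
            class = "run_config")
}

# Synthetic cohort of dyads: per-subject affine laws spread around the fast
# and slow group laws.
cohort_profiles <- function(config) {
  with_local_seed(config$seed + 1L, {
    lapply(seq_len(config$n_dyads), function(d) {
      f <- wrist_population("fast"); s <- wrist_population("slow")
      list(
        fast = subject_profile(sprintf("D%02dF", d),
                               ad_slope = f$ad_slope * stats::runif(1, 0.85, 1.15),
                               ad_intercept = f$ad_intercept * stats::runif(1, 0.9, 1.1),
                               duration_cv = config$duration_cv),
        slow = subject_profile(sprintf("D%02dS", d),
                               ad_slope = s$ad_slope * stats::runif(1, 0.85, 1.15),
                               ad_intercept = s$ad_intercept * stats::runif(1, 0.9, 1.1),
                               duration_cv = config$duration_cv))
    })
  })
}

#' Run the analysis pipeline
#'
#' Deterministic given the seed. Stage outputs are returned in a named list
#' and, when `out_dir` is set, written as CSV/JSON artifacts together with a
#' manifest capturing the configuration.
#'
#' @param config A [run_config()].
#' @return List with (depending on stages) `profiles`, `segments`, `fits`,
#'   `vigor`, `cot_fit`, `predictions`, `comparison`, plus `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  known <- c("generate", "kinematics", "vigor", "identify", "predict", "compare")
  if (!all(config$stages %in% known)) {
    stop("run_pipeline: unknown stage(s): ",
         paste(setdiff(config$stages, known), collapse = ", "))
  }
  res <- list(manifest = list(seed = config$seed,
                              stages = config$stages,
                              n_dyads = config$n_dyads,
                              quality = config$quality,
                              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  coarse_n <- if (config$quality == "fast") 40 else 60
  t_range <- if (config$quality == "fast") c(0.05, 3) else c(0.01, 10)

  run <- function(stage) stage %in% config$stages

  if (run("generate")) {
    res$profiles <- cohort_profiles(config)
    res$solo_sessions <- lapply(seq_along(res$profiles), function(d) {
      pr <- res$profiles[[d]]
      cfg <- session_config(targets = config$amplitudes,
                            trials_per_target_per_direction =
                              config$trials_per_target_per_direction,
                            seed = config$seed + 100L + d)
      list(fast = generate_solo_session(pr$fast, cfg, load_inflation = 1),
           slow = generate_solo_session(pr$slow,
                                        session_config(targets = config$amplitudes,
                                                       trials_per_target_per_direction =
                                                         config$trials_per_target_per_direction,
                                                       seed = config$seed + 200L + d),
                                        load_inflation = 1))
    })
  }
  if (run("kinematics")) {
    if (is.null(res$solo_sessions)) stop("kinematics stage requires generate")
    segs <- list()
    for (d in seq_along(res$solo_sessions)) {
      for (role in c("fast", "slow")) {
        id <- res$profiles[[d]][[role]]$subject_id
        s <- session_segments(res$solo_sessions[[d]][[role]], participant = id)
        s$dyad <- d; s$role <- role
        segs[[length(segs) + 1L]] <- s
      }
    }
    res$segments <- do.call(rbind, segs)
    fits <- lapply(split(res$segments, res$segments$participant),
                   fit_amplitude_duration)
    res$fits <- data.frame(
      participant = names(fits),
      slope = vapply(fits, `[[`, numeric(1), "slope"),
      intercept = vapply(fits, `[[`, numeric(1), "intercept"),
      r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
      stringsAsFactors = FALSE)
    res$group_fit <- fit_amplitude_duration(res$segments)
  }
  if (run("vigor")) {
    if (is.null(res$fits)) stop("vigor stage requires kinematics")
    A <- config$amplitudes
    Tbar <- res$group_fit$slope * A + res$group_fit$intercept
    res$vigor <- do.call(rbind, lapply(seq_len(nrow(res$fits)), function(i) {
      Ti <- res$fits$slope[i] * A + res$fits$intercept[i]
      data.frame(participant = res$fits$participant[i],
                 v = as.numeric(vigor_score(Ti, Tbar)))
    }))
  }
  if (run("identify")) {
    if (is.null(res$group_fit)) stop("identify stage requires kinematics")
    res$cot_fit <- identify_cost_of_time(res$group_fit,
                                         amplitudes = config$amplitudes,
                                         seed = config$seed)
  }
  if (run("predict")) {
    res$predictions <- predict_all_conditions(
      hypotheses = config$hypotheses, alpha = config$alpha,
      amplitudes = config$amplitudes,
      coarse_n = coarse_n, t_range = t_range)
  }
  if (run("compare")) {
    if (is.null(res$predictions)) stop("compare stage requires predict")
    observed <- synthetic_observed_durations(res$predictions, config$seed)
    res$comparison <- compare_hypotheses(res$predictions, observed)
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wj <- function(x, f) jsonlite::write_json(x, file.path(config$out_dir, f),
                                              auto_unbox = TRUE, digits = NA,
                                              pretty = TRUE)
    wj(res$manifest, "manifest.json")
    if (!is.null(res$segments))
      utils::write.csv(res$segments, file.path(config$out_dir, "segments.csv"),
                       row.names = FALSE)
    if (!is.null(res$fits))
      utils::write.csv(res$fits, file.path(config$out_dir, "fits.csv"),
                       row.names = FALSE)
    if (!is.null(res$vigor))
      utils::write.csv(res$vigor, file.path(config$out_dir, "vigor.csv"),
                       row.names = FALSE)
    if (!is.null(res$cot_fit))
      wj(list(p = res$cot_fit$p, residual_rms = res$cot_fit$residual_rms),
         "cost_of_time.json")
    if (!is.null(res$predictions))
      utils::write.csv(res$predictions,
                       file.path(config$out_dir, "predictions.csv"),
                       row.names = FALSE)
    if (!is.null(res$comparison)) wj(res$comparison, "comparison.json")
  }
  res
}

# Default observed durations for the comparison stage: the
# interactive-adaptation predictions perturbed by small timing noise ---
# i.e. a synthetic "measured" cohort generated under that model.
synthetic_observed_durations <- function(predictions, seed) {
  ia <- predictions[predictions$hypothesis == "interactive_adaptation", ]
  if (!nrow(ia)) ia <- predictions[predictions$hypothesis == "leader_fast", ]
  with_local_seed(seed + 999L, {
    data.frame(condition = ia$condition, target_index = ia$target_index,
               observed_T = ia$predicted_T * stats::rlnorm(nrow(ia), 0, 0.01))
  })
}

#' Compare coordination hypotheses against observed durations
#'
#' Computes, per hypothesis, the median absolute duration prediction error
#' split by stiffness family (KL-prefixed vs KH-prefixed conditions), plus a
#' qualitative checklist derived from the computed tables: whether the
#' hypothesis' interaction force is low (mean predicted |interaction torque|
#' below half the co-activity baseline), and whether the dyad is predicted
#' faster than the fast-leader baseline in the no-load conditions for the
#' larger targets.
#'
#' Observed durations may come from the synthetic cohort (the default in
#' [run_pipeline()]) or from an external table of measured dyadic movement
#' durations shaped as `condition`, `target_index`, `observed_T` --- e.g.
#' processed exports of a real coupled-reaching dataset; such external
#' validation is optional and never required by the package's tests.
#'
#' @param predictions Prediction table from [predict_all_conditions()].
#' @param observed Data frame with `condition`, `target_index`,
#'   `observed_T` (s).
#' @return List of class `comparison_report`: `median_error` (data frame:
#'   hypothesis, median_error_low_stiffness_ms, median_error_high_stiffness_ms,
#'   n_matched), `checklist`, and `missing` (unmatched keys, if any).
#' @export
compare_hypotheses <- function(predictions, observed) {
  stopifnot(all(c("condition", "target_index", "observed_T") %in% names(observed)))
  key <- function(d) paste(d$condition, d$target_index)
  merged <- merge(predictions, observed, by = c("condition", "target_index"),
                  all.x = TRUE)
  missing <- unique(key(merged[is.na(merged$observed_T), ]))
  merged <- merged[!is.na(merged$observed_T), ]
  if (!nrow(merged)) stop("compare_hypotheses: no matching condition/target keys")

  med <- do.call(rbind, lapply(split(merged, merged$hypothesis), function(d) {
    lo <- startsWith(d$condition, "KL"); hi <- startsWith(d$condition, "KH")
    data.frame(hypothesis = d$hypothesis[1],
               median_error_low_stiffness_ms =
                 1000 * stats::median(abs(d$predicted_T - d$observed_T)[lo]),
               median_error_high_stiffness_ms =
                 1000 * stats::median(abs(d$predicted_T - d$observed_T)[hi]),
               n_matched = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(med) <- NULL

  lf <- merged[merged$hypothesis == "leader_fast", ]
  checklist <- lapply(split(merged, merged$hypothesis), function(d) {
    # empirical bound: measured dyads kept |tau_i| below ~0.1 Nm throughout
    noload <- d[d$viscosity == 0, ]
    low_force <- if (nrow(noload)) {
      mean(noload$mean_abs_tau_i, na.rm = TRUE) < 0.1
    } else NA
    faster <- if (nrow(lf)) {
      dn <- d[d$viscosity == 0 & d$target_index >= 3, ]
      ln <- lf[lf$viscosity == 0 & lf$target_index >= 3, ]
      m <- merge(dn, ln, by = c("condition", "target_index"))
      nrow(m) > 0 && mean(m$predicted_T.x < m$predicted_T.y) > 0.5
    } else NA
    list(low_interaction_force = low_force,
         dyad_faster_than_fast_no_load = faster)
  })
  out <- list(median_error = med, checklist = checklist,
              missing = if (length(missing)) missing else NULL)
  if (length(missing)) {
    warning("compare_hypotheses: unmatched keys dropped: ",
            paste(missing, collapse = "; "))
  }
  class(out) <- "comparison_report"
  out
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Hypothesis comparison (median |T_pred - T_obs|)\n")
  print(x$median_error, row.names = FALSE)
  invisible(x)
}
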