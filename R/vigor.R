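## Vigor scoring and its population statistics.

#' Vigor score of a participant or dyad
#'
#' \deqn{v = \frac{\sum_k \bar T(A_k)^2}{\sum_k T(A_k)\, \bar T(A_k)},}
#' the ratio comparing an entity's per-target movement durations `T_entity`
#' to the population means `T_bar` over the same targets. An entity moving
#' exactly at the population pace has vigor 1; moving uniformly twice as
#' slowly halves the vigor. The reference `T_bar` is taken from the relevant
#' null-field condition family (NF1 for solo; the KL or KH block for the
#' loaded coupled conditions).
#'
#' @param T_entity Entity durations per target, s (> 0).
#' @param T_bar Population mean durations per target, s (> 0), same targets
#'   in the same order.
#' @param entity_id,condition Optional labels stored as attributes.
#' @return Numeric vigor score (> 0) of class `vigor_score`.
#' @export
vigor_score <- function(T_entity, T_bar, entity_id = NULL, condition = NULL) {
  if (length(T_entity) != length(T_bar) || !length(T_bar)) {
    stop("vigor_score: T_entity and T_bar must cover the same >= 1 targets")
  }
  if (any(T_entity <= 0) || any(T_bar <= 0)) {
    stop("vigor_score: durations must be positive")
  }
  v <- sum(T_bar^2) / sum(T_entity * T_bar)
  structure(v, class = "vigor_score", entity_id = entity_id,
            condition = condition)
}

#' @export
print.vigor_score <- function(x, ...) {
  id <- attr(x, "entity_id"); cond <- attr(x, "condition")
  cat(sprintf("Vigor score%s%s: %.4f\n",
              if (!is.null(id)) paste0(" ", id) else "",
              if (!is.null(cond)) paste0(" (", cond, ")") else "",
              as.numeric(x)))
  invisible(x)
}

#' Dyadic vigor
#'
#' Vigor score of a coupled pair, computed from the per-target mean of the
#' two partners' movement durations.
#'
#' @param T_f,T_s Fast and slow partners' durations per target, s.
#' @inheritParams vigor_score
#' @return A `vigor_score`.
#' @export
dyadic_vigor <- function(T_f, T_s, T_bar, entity_id = NULL, condition = NULL) {
  if (length(T_f) != length(T_s)) stop("dyadic_vigor: partner duration vectors differ in length")
  vigor_score((T_f + T_s) / 2, T_bar, entity_id = entity_id,
              condition = condition)
}

#' Inter- vs intra-entity variance decomposition
#'
#' One-way sum-of-squares split of a measure (vigor or duration) by entity
#' across conditions:
#' \deqn{\mathrm{Var_{inter}} = 100\, \mathrm{SS_{inter}} /
#'   (\mathrm{SS_{inter}} + \mathrm{SS_{intra}}),}
#' where the inter component comes from entity means about the grand mean
#' and the intra component is the residual within entities.
#'
#' @param data Data frame with columns `entity`, `condition`, `value`.
#' @return List of class `variance_decomposition` with `ss_inter`,
#'   `ss_intra`, `pct_inter` and `zero_variance` (flag set, and `pct_inter`
#'   reported as 0, when the data carry no variance at all).
#' @export
variance_decomposition <- function(data) {
  stopifnot(all(c("entity", "condition", "value") %in% names(data)))
  if (length(unique(data$entity)) < 2) {
    stop("variance_decomposition: need at least 2 entities")
  }
  if (length(unique(data$condition)) < 2) {
    stop("variance_decomposition: need at least 2 conditions")
  }
  fit <- stats::lm(value ~ factor(entity), data = data)
  an <- suppressWarnings(stats::anova(fit))  # perfect fits are legitimate here
  ss_inter <- an[["Sum Sq"]][1]
  ss_intra <- an[["Sum Sq"]][2]
  tot <- ss_inter + ss_intra
  zero <- tot < .Machine$double.eps
  out <- list(ss_inter = ss_inter, ss_intra = ss_intra,
              pct_inter = if (zero) 0 else 100 * ss_inter / tot,
              zero_variance = zero)
  class(out) <- "variance_decomposition"
  out
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf("Variance decomposition: %.1f%% inter-entity (SS %.4g vs %.4g)%s\n",
              x$pct_inter, x$ss_inter, x$ss_intra,
              if (x$zero_variance) " [zero variance]" else ""))
  invisible(x)
}

#' Linear mixed model of dyadic vigor
#'
#' Fits \eqn{v^d \sim \gamma^f v^f + \gamma^s v^s} with per-condition
#' coefficients and a random intercept per dyad, by maximum likelihood, and
#' applies a Bonferroni--Holm correction to the per-condition p-values of
#' each predictor across conditions. A positive significant \eqn{\gamma^s}
#' with null \eqn{\gamma^f} is the signature that only the slower partner's
#' vigor shapes dyadic vigor.
#'
#' @param data Data frame with columns `dyad`, `condition`, `v_d`, `v_f`,
#'   `v_s` (one row per dyad x condition).
#' @param intercept Include per-condition intercepts (the bare model has
#'   none; both variants are worth inspecting).
#' @return Object of class `dyadic_vigor_model`: coefficient `table` (one
#'   row per condition: estimates, standard errors, raw and Holm-adjusted
#'   p-values for both predictors), the underlying fit, and flags
#'   `non_identifiable` (fast and slow vigors collinear) and `singular`.
#' @export
fit_dyadic_vigor_lmm <- function(data, intercept = FALSE) {
  stopifnot(all(c("dyad", "condition", "v_d", "v_f", "v_s") %in% names(data)))
  if (length(unique(data$dyad)) < 5) {
    stop("fit_dyadic_vigor_lmm: need at least 5 dyads")
  }
  data$condition <- factor(data$condition)
  non_id <- isTRUE(abs(stats::cor(data$v_f, data$v_s)) > 1 - 1e-10)
  fml <- if (intercept) {
    v_d ~ 0 + condition + condition:v_f + condition:v_s + (1 | dyad)
  } else {
    v_d ~ 0 + condition:v_f + condition:v_s + (1 | dyad)
  }
  singular <- FALSE
  fit <- tryCatch(
    withCallingHandlers(
      lmerTest::lmer(fml, data = data, REML = FALSE),
      message = function(m) invokeRestart("muffleMessage"),
      warning = function(w) {
        if (grepl("singular", conditionMessage(w))) singular <<- TRUE
        invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)

  if (!is.null(fit)) {
    singular <- singular || lme4::isSingular(fit, tol = 1e-5)
    sm <- suppressWarnings(stats::coef(summary(fit)))
    est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
    pv <- sm[, "Pr(>|t|)"]
  } else {
    # Degenerate data (e.g. exactly noiseless) can defeat the mixed model;
    # fall back to the fixed-effects regression.
    lmfml <- if (intercept) v_d ~ 0 + condition + condition:v_f + condition:v_s
             else v_d ~ 0 + condition:v_f + condition:v_s
    lf <- stats::lm(lmfml, data = data)
    sm <- stats::coef(summary(lf))
    est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
    pv <- sm[, "Pr(>|t|)"]
    singular <- TRUE
    fit <- lf
  }
  conds <- levels(data$condition)
  pick <- function(pred) {
    nm <- paste0("condition", conds, ":", pred)
    idx <- match(nm, names(est))
    list(est = est[idx], se = se[idx], p = pv[idx])
  }
  f <- pick("v_f"); s <- pick("v_s")
  tab <- data.frame(condition = conds,
                    gamma_f = unname(f$est), se_f = unname(f$se),
                    p_f = unname(f$p),
                    p_f_adj = stats::p.adjust(unname(f$p), method = "holm"),
                    gamma_s = unname(s$est), se_s = unname(s$se),
                    p_s = unname(s$p),
                    p_s_adj = stats::p.adjust(unname(s$p), method = "holm"),
                    stringsAsFactors = FALSE)
  if (non_id) tab[, -1] <- NA_real_
  out <- list(table = tab, fit = fit, intercept = intercept,
              non_identifiable = non_id, singular = singular)
  class(out) <- "dyadic_vigor_model"
  out
}

#' @export
print.dyadic_vigor_model <- function(x, digits = 3, ...) {
  cat("Dyadic vigor mixed model: v_d ~ gamma_f v_f + gamma_s v_s",
      if (x$intercept) "+ intercept", "(random intercept per dyad, ML)\n")
  if (x$non_identifiable) {
    cat("  NOT IDENTIFIABLE: fast and slow vigors are collinear\n")
    return(invisible(x))
  }
  print(cbind(condition = x$table$condition,
              round(x$table[, -1], digits)), row.names = FALSE)
  if (x$singular) cat("  note: random-effect variance at boundary (singular fit)\n")
  invisible(x)
}

#' @export
coef.dyadic_vigor_model <- function(object, ...) object$table

#' Weighted-adaptation prediction of dyadic vigor
#'
#' Convex combination \eqn{v^d = \alpha v^f + (1-\alpha) v^s}. The limits
#' `alpha = 1` and `alpha = 0` are the leader--follower predictions with a
#' fast and slow leader respectively.
#'
#' @param v_f,v_s Fast and slow partners' vigor scores.
#' @param alpha Weight in `[0, 1]`.
#' @return Predicted dyadic vigor, vectorized over the inputs.
#' @export
weighted_adaptation_prediction <- function(v_f, v_s, alpha) {
  if (any(alpha < 0 | alpha > 1)) {
    stop("weighted_adaptation_prediction: alpha must lie in [0, 1]")
  }
  alpha * as.numeric(v_f) + (1 - alpha) * as.numeric(v_s)
}
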