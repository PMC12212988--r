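#' Evaluation point for marginal-effect (derivative) tests
#'
#' The point on the fitted quadratic surface at which the partial
#' derivatives are evaluated. Defaults to the sample means of `e0` and
#' `|delta e|` in the fitted table; arbitrary points may be supplied for
#' sensitivity analysis.
#'
#' @param e0_value Developmental-environment value (rank proportion or
#'   mm/month).
#' @param abs_delta_value Mismatch magnitude, same units; must be
#'   non-negative.
#' @return A list with class `eval_point`.
#' @export
eval_point <- function(e0_value, abs_delta_value) {
  if (abs_delta_value < 0) stop("abs_delta_value must be >= 0.", call. = FALSE)
  structure(list(e0 = as.numeric(e0_value),
                 abs_delta = as.numeric(abs_delta_value)),
            class = "eval_point")
}

default_eval_point <- function(fit) {
  eval_point(fit$means[["e0"]], fit$means[["abs_delta"]])
}

coef_or_zero <- function(fit, term) {
  if (term %in% names(fit$coefficients)) unname(fit$coefficients[term]) else 0
}

#' Developmental-constraints marginal effect
#'
#' The partial derivative of the fitted outcome surface with respect to
#' the developmental environment,
#' `dy1/de0 = gamma_0 + 2 gamma_00 e0 + gamma_0d |delta e|`,
#' evaluated at `at`. The developmental-constraints (silver spoon)
#' hypothesis predicts this derivative is positive: better developmental
#' environments produce better adult outcomes. Not estimable under an
#' individual fixed effect, which absorbs e0 (each female has a single
#' developmental environment).
#'
#' @param fit A `quad_fit`.
#' @param at An [eval_point()]; default sample means.
#' @return The derivative estimate (probability per environment unit).
#' @export
dc_derivative <- function(fit, at = default_eval_point(fit)) {
  if (any(DEV_TERMS %in% fit$absorbed)) {
    stop("developmental-constraints derivative is not estimable under individual fixed effects (e0 is absorbed).",
         call. = FALSE)
  }
  coef_or_zero(fit, "e0") +
    2 * coef_or_zero(fit, "e0_sq") * at$e0 +
    coef_or_zero(fit, "e0_x_absdelta") * at$abs_delta
}

#' Adaptive-response marginal effect
#'
#' The partial derivative of the fitted outcome surface with respect to
#' the mismatch magnitude,
#' `dy1/d|delta e| = gamma_d + 2 gamma_dd |delta e| + gamma_0d e0`,
#' evaluated at `at`. Adaptive-response (mismatch) hypotheses predict
#' this derivative is negative: larger developmental/adult environment
#' differences produce worse adult outcomes. Estimable under both group
#' and individual fixed effects.
#'
#' @inheritParams dc_derivative
#' @return The derivative estimate (probability per environment unit).
#' @export
ar_derivative <- function(fit, at = default_eval_point(fit)) {
  coef_or_zero(fit, "abs_delta") +
    2 * coef_or_zero(fit, "abs_delta_sq") * at$abs_delta +
    coef_or_zero(fit, "e0_x_absdelta") * at$e0
}

derivative_gradient <- function(fit, at, hypothesis) {
  terms <- names(fit$coefficients)
  g <- stats::setNames(numeric(length(terms)), terms)
  if (hypothesis == "DC") {
    if (!"e0" %in% terms) {
      stop("DC gradient not constructible: e0 term is not estimable.", call. = FALSE)
    }
    g["e0"] <- 1
    if ("e0_sq" %in% terms) g["e0_sq"] <- 2 * at$e0
    if ("e0_x_absdelta" %in% terms) g["e0_x_absdelta"] <- at$abs_delta
  } else {
    if (!"abs_delta" %in% terms) {
      stop("AR gradient not constructible: abs_delta term is not estimable.", call. = FALSE)
    }
    g["abs_delta"] <- 1
    if ("abs_delta_sq" %in% terms) g["abs_delta_sq"] <- 2 * at$abs_delta
    if ("e0_x_absdelta" %in% terms) g["e0_x_absdelta"] <- at$e0
  }
  g
}

#' Derivative-based hypothesis test
#'
#' Delta-method test of a marginal effect of the fitted quadratic
#' surface: the estimate is the linear combination `c . gamma_hat` of
#' the fitted coefficients given by the derivative's gradient, its
#' standard error is `sqrt(c' V c)` with V the cluster-robust
#' covariance, and the two-sided p-value uses a t reference distribution
#' with G - 1 degrees of freedom (G = number of female clusters).
#'
#' @param fit A `quad_fit` with cluster-robust `vcov` (see
#'   [fit_quadratic()]); a bare [fit_lpm()] result gets its vcov
#'   computed on the fly.
#' @param hypothesis `"DC"` (predicts a positive derivative) or `"AR"`
#'   (predicts a negative derivative).
#' @param at An [eval_point()]; default sample means.
#' @param alpha Significance level used for the theory-consistency flag.
#' @return A list with class `derivative_test`: `hypothesis`,
#'   `estimate`, `se`, `statistic`, `p_value`, `df`,
#'   `predicted_direction`, `consistent_with_theory` (sign matches the
#'   theory's prediction AND `p_value < alpha`), `at`.
#' @export
test_derivative <- function(fit, hypothesis = c("DC", "AR"),
                            at = default_eval_point(fit), alpha = 0.05) {
  hypothesis <- match.arg(hypothesis)
  if (hypothesis == "DC" && any(DEV_TERMS %in% fit$absorbed)) {
    stop("developmental-constraints test is not estimable under individual fixed effects (e0 is absorbed).",
         call. = FALSE)
  }
  V <- fit$vcov %||% cluster_vcov(fit)
  g <- derivative_gradient(fit, at, hypothesis)
  estimate <- sum(g * fit$coefficients)
  se <- sqrt(drop(t(g) %*% V %*% g))
  if (se == 0 && estimate != 0) {
    stop("degenerate variance: zero standard error with non-zero estimate.",
         call. = FALSE)
  }
  statistic <- if (se == 0) 0 else estimate / se
  df <- fit$n_clusters - 1
  p_value <- 2 * stats::pt(-abs(statistic), df = df)
  direction <- if (hypothesis == "DC") "positive" else "negative"
  consistent <- (if (direction == "positive") estimate > 0 else estimate < 0) &&
    p_value < alpha
  structure(list(hypothesis = hypothesis, estimate = estimate, se = se,
                 statistic = statistic, p_value = p_value, df = df,
                 predicted_direction = direction,
                 consistent_with_theory = consistent,
                 alpha = alpha, at = at),
            class = "derivative_test")
}

#' @export
print.derivative_test <- function(x, ...) {
  cat(sprintf("%s test: marginal effect %.5f (se %.5f), t(%d) = %.3f, p = %.4f\n",
              x$hypothesis, x$estimate, x$se, x$df, x$statistic, x$p_value))
  cat(sprintf("theory predicts a %s derivative; consistent at alpha = %.2f: %s\n",
              x$predicted_direction, x$alpha, x$consistent_with_theory))
  invisible(x)
}

#' Translate a relative effect into an absolute one
#'
#' Converts a relative difference in an outcome's failure/success
#' probability into the corresponding absolute difference given the
#' baseline mean outcome, both in percent: `relative * baseline / 100`,
#' reported to two decimals. For example a 13.18% relative difference on
#' a 73.74% baseline is a 9.72 percentage-point difference.
#'
#' @param relative_pct Relative difference in percent.
#' @param baseline_mean_pct Baseline mean outcome in percent, in (0, 100].
#' @return The absolute difference in percentage points (2 dp).
#' @export
#' @examples
#' relative_to_absolute(13.18, 73.74) # 9.72
relative_to_absolute <- function(relative_pct, baseline_mean_pct) {
  if (baseline_mean_pct <= 0 || baseline_mean_pct > 100) {
    stop("baseline_mean_pct must lie in (0, 100].", call. = FALSE)
  }
  round(relative_pct * baseline_mean_pct / 100, 2)
}

# prediction at a covariate point, fixed effects held at their sample
# average: mean(fitted) + gamma' (x* - xbar)
predict_at <- function(fit, table, e0_at, absd_at) {
  df <- tibble::as_tibble(table)
  cols <- list(e0 = df$e0, abs_delta = df$abs_delta, e0_sq = df$e0^2,
               abs_delta_sq = df$abs_delta^2,
               e0_x_absdelta = df$e0 * df$abs_delta)
  point <- c(e0 = e0_at, abs_delta = absd_at, e0_sq = e0_at^2,
             abs_delta_sq = absd_at^2, e0_x_absdelta = e0_at * absd_at)
  pred <- mean(fit$fitted)
  for (term in intersect(names(cols), names(fit$coefficients))) {
    pred <- pred + fit$coefficients[[term]] * (point[[term]] - mean(cols[[term]]))
  }
  pred
}

#' Percentile contrast of predicted outcomes
#'
#' Predicted outcome probability at a low and a high empirical
#' percentile of one environment variable, all other model inputs held
#' at sample means, translated into the relative and absolute
#' differences used to report effect sizes. The adverse direction is the
#' low percentile for `e0` (worse developmental environment) and the
#' high percentile for `abs_delta` (bigger mismatch); the relative
#' difference compares failure probabilities (1 - outcome) between the
#' adverse and favourable points, as a percentage of the mean failure
#' probability.
#'
#' @param fit A `quad_fit` (the fitted table's model).
#' @param table The [analysis_table()] the model was fitted to.
#' @param variable `"e0"` or `"abs_delta"`.
#' @param lo,hi Percentiles in `[0, 1]` (defaults 0.10 and 0.90).
#' @return A list with class `contrast_result`: `low_percentile`,
#'   `high_percentile`, `value_lo`, `value_hi`, `pred_lo`, `pred_hi`,
#'   `relative_difference_pct`, `absolute_difference_pct`,
#'   `baseline_mean_pct`, `convention`.
#' @export
percentile_contrast <- function(fit, table, variable = c("e0", "abs_delta"),
                                lo = 0.10, hi = 0.90) {
  variable <- match.arg(variable)
  if (lo < 0 || hi > 1) stop("percentiles must lie in [0, 1].", call. = FALSE)
  if (variable == "e0" && any(DEV_TERMS %in% fit$absorbed)) {
    stop("e0 contrast is not estimable under individual fixed effects.",
         call. = FALSE)
  }
  df <- tibble::as_tibble(table)
  x <- df[[variable]]
  q <- stats::quantile(x, probs = c(lo, hi), names = FALSE)
  if (q[1] < min(x) || q[2] > max(x)) {
    stop("percentile outside the observed support.", call. = FALSE)
  }
  at <- function(v) {
    if (variable == "e0") predict_at(fit, df, v, mean(df$abs_delta))
    else predict_at(fit, df, mean(df$e0), v)
  }
  pred_lo <- at(q[1]); pred_hi <- at(q[2])
  # adverse = low e0 (poor developmental environment) or high |delta|
  pred_adverse <- if (variable == "e0") pred_lo else pred_hi
  pred_favourable <- if (variable == "e0") pred_hi else pred_lo
  fail_mean <- mean(1 - df$outcome)
  relative <- if (fail_mean == 0) 0 else
    100 * ((1 - pred_adverse) - (1 - pred_favourable)) / fail_mean
  baseline <- 100 * mean(df$outcome)
  absolute <- relative_to_absolute(relative, baseline)
  structure(list(low_percentile = lo, high_percentile = hi,
                 value_lo = q[1], value_hi = q[2],
                 pred_lo = pred_lo, pred_hi = pred_hi,
                 relative_difference_pct = relative,
                 absolute_difference_pct = absolute,
                 baseline_mean_pct = baseline,
                 convention = paste("relative = 100 * (failure at adverse percentile -",
                                    "failure at favourable percentile) / mean failure;",
                                    "adverse =", if (variable == "e0") "low e0" else "high |delta|")),
            class = "contrast_result")
}

#' Test for asymmetry between positive and negative deltas
#'
#' The quadratic model uses the mismatch magnitude `|delta e|`, which
#' forces rank/rainfall gains and losses of equal size to have equal
#' effects. This test relaxes that: the `|delta|` terms are replaced by
#' sign-split terms `delta+ = max(delta, 0)` and `delta- = max(-delta,
#' 0)`, each with its square (the `e0 * |delta|` interaction is kept as
#' is), and a joint cluster-robust Wald test asks whether the positive
#' and negative linear and quadratic coefficients are pairwise equal
#' (F with 2 and G - 1 degrees of freedom).
#'
#' @param table An [analysis_table()] containing signed deltas of both
#'   signs.
#' @param spec A [model_spec()].
#' @return A list with class `asymmetry_test`: `p_value`, `statistic`
#'   (F), `df1`, `df2`, `fit`, and a `form` string recording the
#'   construction.
#' @export
asymmetry_test <- function(table, spec = model_spec()) {
  df <- tibble::as_tibble(table)
  if (all(df$delta >= 0) || all(df$delta <= 0)) {
    stop("asymmetry is not testable: all deltas share one sign.", call. = FALSE)
  }
  dpos <- pmax(df$delta, 0)
  dneg <- pmax(-df$delta, 0)
  X <- cbind(delta_pos = dpos, delta_neg = dneg,
             delta_pos_sq = dpos^2, delta_neg_sq = dneg^2,
             e0 = df$e0, e0_sq = df$e0^2,
             e0_x_absdelta = df$e0 * df$abs_delta)
  if (spec$fixed_effect == "individual") {
    X <- X[, setdiff(colnames(X), DEV_TERMS), drop = FALSE]
  }
  X <- cbind(X, as.matrix(df[spec$covariates]))
  design <- structure(list(
    y = as.numeric(df$outcome), X = X,
    cluster = as.character(df$female_id),
    fe = switch(spec$fixed_effect,
                group = as.character(df$group_id),
                individual = as.character(df$female_id),
                none = NULL),
    fe_type = spec$fixed_effect,
    absorbed = if (spec$fixed_effect == "individual") DEV_TERMS else character(0),
    means = c(e0 = mean(df$e0), abs_delta = mean(df$abs_delta)),
    n_dropped = 0L, spec = spec), class = "design_matrix")
  fit <- fit_lpm(design)
  V <- cluster_vcov(fit)
  terms <- names(fit$coefficients)
  pairs <- list(c("delta_pos", "delta_neg"),
                c("delta_pos_sq", "delta_neg_sq"))
  R <- matrix(0, nrow = length(pairs), ncol = length(terms),
              dimnames = list(NULL, terms))
  for (j in seq_along(pairs)) {
    if (!all(pairs[[j]] %in% terms)) {
      stop("asymmetry test terms were dropped as collinear; not testable.",
           call. = FALSE)
    }
    R[j, pairs[[j]][1]] <- 1
    R[j, pairs[[j]][2]] <- -1
  }
  rb <- drop(R %*% fit$coefficients)
  RVR <- R %*% V %*% t(R)
  W <- if (all(abs(rb) < 1e-12)) 0 else drop(t(rb) %*% solve(RVR) %*% rb)
  df2 <- fit$n_clusters - 1
  Fstat <- W / nrow(R)
  p <- stats::pf(Fstat, nrow(R), df2, lower.tail = FALSE)
  structure(list(p_value = p, statistic = Fstat, df1 = nrow(R), df2 = df2,
                 fit = fit,
                 form = "sign-split linear and quadratic delta terms; joint Wald on pairwise equality"),
            class = "asymmetry_test")
}
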