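new_pooled_estimate <- function(mu, se, tau2, i2, i2_ci, k, method) {
  z <- qnorm(0.975)
  structure(list(
    mu = mu, se = se,
    ci_low = mu - z * se, ci_high = mu + z * se,
    tau2 = tau2, i2 = i2,
    i2_ci_low = i2_ci[[1]], i2_ci_high = i2_ci[[2]],
    k = k, p = 2 * pnorm(-abs(mu / se)), method = method
  ), class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("Pooled log OR (%s, k = %d)\n", x$method, x$k))
  cat(sprintf("  mu = %.4f [%.4f, %.4f], OR = %.2f [%.2f, %.2f], p = %.3g\n",
              x$mu, x$ci_low, x$ci_high,
              exp(x$mu), exp(x$ci_low), exp(x$ci_high), x$p))
  if (!is.na(x$i2)) {
    cat(sprintf("  tau^2 = %.4f, I^2 = %.2f%% [%.2f, %.2f]\n",
                x$tau2, x$i2, x$i2_ci_low, x$i2_ci_high))
  }
  invisible(x)
}

#' Random-effects pooling of attrition effect sizes
#'
#' Inverse-variance random-effects meta-analysis of per-study log odds
#' ratios: the pooled estimate weights each study by
#' \eqn{1/(v_i + \tau^2)}, with the between-study variance \eqn{\tau^2}
#' estimated by REML (default) or DerSimonian-Laird. Heterogeneity is
#' expressed as \eqn{I^2 = 100\,\tau^2/(\tau^2 + \tilde v)} (with
#' \eqn{\tilde v} the typical within-study variance) and its 95% CI
#' is obtained by the Q-profile method. The CI for the pooled estimate
#' and the two-sided p-value are Wald-type on the log-OR scale.
#'
#' With a single study the pooled estimate equals that study's effect
#' and \eqn{\tau^2 = 0}.
#'
#' @param effects An `attrition_effects` data frame (see
#'   [compute_log_or()]), or any data frame with `yi` and `vi` columns.
#' @param tau2_estimator `"REML"` (default) or `"DL"`.
#' @return A `pooled_estimate` object: `mu`, `se`, `ci_low`, `ci_high`
#'   (log scale), `tau2`, `i2` with `i2_ci_low`/`i2_ci_high`, `k`, `p`.
#' @examples
#' eff <- compute_log_or(attrition_fixture(), correct = TRUE)
#' pool_random_effects(eff)
#' @export
pool_random_effects <- function(effects, tau2_estimator = c("REML", "DL")) {
  tau2_estimator <- match.arg(tau2_estimator)
  yi <- effects$yi
  vi <- effects$vi
  keep <- is.finite(yi) & is.finite(vi) & vi > 0
  yi <- yi[keep]
  vi <- vi[keep]
  k <- length(yi)
  if (k == 0L) stop("no usable effect sizes", call. = FALSE)
  if (k == 1L) {
    return(new_pooled_estimate(yi, sqrt(vi), 0, 0, c(NA_real_, NA_real_),
                               1L, paste0("random-", tau2_estimator)))
  }
  res <- metafor::rma(yi = yi, vi = vi, method = tau2_estimator)
  i2_ci <- tryCatch({
    ci <- stats::confint(res)
    unname(ci$random["I^2(%)", c("ci.lb", "ci.ub")])
  }, error = function(e) c(NA_real_, NA_real_))
  new_pooled_estimate(as.numeric(res$beta), res$se, res$tau2, res$I2,
                      i2_ci, k, paste0("random-", tau2_estimator))
}

#' Classic fixed-effect Peto pool
#'
#' The traditional Peto meta-analysis: per-study observed-minus-expected
#' dropout counts and hypergeometric variances are summed directly,
#' \eqn{\hat\beta = \sum(O_i - E_i)/\sum V_i}, a fixed-effect estimator
#' that needs no continuity correction for zero cells.
#'
#' @param table A [as_study_table()] object.
#' @return A `pooled_estimate` (with `tau2 = 0`; `i2` reported from the
#'   Q statistic of the fixed-effect model).
#' @examples
#' pool_peto_fixed(attrition_fixture())
#' @export
pool_peto_fixed <- function(table) {
  table <- as_study_table(table)
  # studies with no dropouts (or nothing but dropouts) carry no
  # information: O - E = 0 with V = 0
  ev <- table$drop_active + table$drop_passive
  table <- table[ev > 0 & ev < table$n_itt_active + table$n_itt_passive, ,
                 drop = FALSE]
  res <- metafor::rma.peto(ai = table$drop_active, n1i = table$n_itt_active,
                           ci = table$drop_passive, n2i = table$n_itt_passive)
  new_pooled_estimate(as.numeric(res$beta), res$se, 0, res$I2,
                      c(NA_real_, NA_real_), res$k, "peto-fixed")
}

#' Leave-one-out influence analysis
#'
#' Re-pools the effect sizes k times, omitting one study each time.
#'
#' @inheritParams pool_random_effects
#' @return A data frame with one row per omitted study: `omitted`, `mu`,
#'   `se`, `ci_low`, `ci_high`, `or`, `tau2`, `p`.
#' @examples
#' eff <- compute_log_or(attrition_fixture(), correct = TRUE)
#' range(leave_one_out(eff)$or)
#' @export
leave_one_out <- function(effects, tau2_estimator = c("REML", "DL")) {
  tau2_estimator <- match.arg(tau2_estimator)
  k <- nrow(effects)
  if (k < 2L) stop("leave-one-out needs at least 2 studies", call. = FALSE)
  ids <- if ("study_id" %in% names(effects)) effects$study_id
  else as.character(seq_len(k))
  rows <- lapply(seq_len(k), function(i) {
    p <- pool_random_effects(effects[-i, , drop = FALSE], tau2_estimator)
    data.frame(omitted = ids[i], mu = p$mu, se = p$se,
               ci_low = p$ci_low, ci_high = p$ci_high,
               or = exp(p$mu), tau2 = p$tau2, p = p$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Outlier detection by CI non-overlap
#'
#' Flags studies whose individual 95% CI (\eqn{y_i \pm 1.96\sqrt{v_i}})
#' lies entirely above or entirely below the 95% CI of the pooled
#' estimate, and re-pools the remaining studies as a convenience.
#'
#' @inheritParams pool_random_effects
#' @param pooled A `pooled_estimate` computed from the same effects.
#' @return A list with `outliers` (character vector of study ids,
#'   possibly empty) and `repooled` (a `pooled_estimate` without the
#'   flagged studies, or `NULL` if none were flagged).
#' @examples
#' eff <- compute_log_or(attrition_fixture(), correct = TRUE)
#' detect_outliers(eff, pool_random_effects(eff))$outliers
#' @export
detect_outliers <- function(effects, pooled,
                            tau2_estimator = c("REML", "DL")) {
  tau2_estimator <- match.arg(tau2_estimator)
  z <- qnorm(0.975)
  lo <- effects$yi - z * sqrt(effects$vi)
  hi <- effects$yi + z * sqrt(effects$vi)
  flag <- lo > pooled$ci_high | hi < pooled$ci_low
  flag[is.na(flag)] <- FALSE
  ids <- if ("study_id" %in% names(effects)) effects$study_id
  else as.character(seq_len(nrow(effects)))
  repooled <- NULL
  if (any(flag)) {
    repooled <- pool_random_effects(effects[!flag, , drop = FALSE],
                                    tau2_estimator)
  }
  list(outliers = ids[flag], repooled = repooled)
}

#' Mixed-effects meta-regression
#'
#' Regresses per-study log ORs on a moderator with a random study
#' intercept (fixed moderator slope, residual heterogeneity estimated
#' with the same \eqn{\tau^2} estimator as [pool_random_effects()]).
#' The slope is in log-OR units per moderator unit. Studies with a
#' missing moderator value are dropped. With `moderator = NULL` the
#' intercept-only model is fitted, which is identical to
#' [pool_random_effects()].
#'
#' @inheritParams pool_random_effects
#' @param moderator Numeric vector, one value per effect (`NA` allowed),
#'   or `NULL` for the intercept-only model.
#' @param moderator_name Label stored in the result.
#' @return A `meta_regression_fit` list: `B`, `ci_low`, `ci_high`, `p`
#'   (for the slope; for the intercept when `moderator = NULL`),
#'   `moderator_name`, `intercept`, `k`.
#' @examples
#' eff <- compute_log_or(attrition_fixture(), correct = TRUE)
#' mods <- code_moderators(attrition_fixture())
#' meta_regress(eff, mods$total_n, "total_n")
#' @export
meta_regress <- function(effects, moderator, moderator_name = "moderator",
                         tau2_estimator = c("REML", "DL")) {
  tau2_estimator <- match.arg(tau2_estimator)
  if (is.null(moderator)) {
    p <- pool_random_effects(effects, tau2_estimator)
    return(structure(list(B = p$mu, ci_low = p$ci_low, ci_high = p$ci_high,
                          p = p$p, moderator_name = "(intercept)",
                          intercept = p$mu, k = p$k),
                     class = "meta_regression_fit"))
  }
  if (length(moderator) != nrow(effects)) {
    stop("moderator must have one value per study", call. = FALSE)
  }
  keep <- !is.na(moderator) & is.finite(effects$yi) & effects$vi > 0
  yi <- effects$yi[keep]
  vi <- effects$vi[keep]
  x <- moderator[keep]
  if (length(unique(x)) < 2L) {
    stop("no moderator variance", call. = FALSE)
  }
  res <- metafor::rma(yi = yi, vi = vi, mods = ~x, method = tau2_estimator)
  structure(list(B = as.numeric(res$beta[2]), ci_low = res$ci.lb[2],
                 ci_high = res$ci.ub[2], p = res$pval[2],
                 moderator_name = moderator_name,
                 intercept = as.numeric(res$beta[1]), k = res$k),
            class = "meta_regression_fit")
}

#' @export
print.meta_regression_fit <- function(x, ...) {
  cat(sprintf("Meta-regression on %s (k = %d)\n", x$moderator_name, x$k))
  cat(sprintf("  B = %.4f [%.4f, %.4f], p = %.3g\n",
              x$B, x$ci_low, x$ci_high, x$p))
  invisible(x)
}

#' Descriptive review summary of a study table
#'
#' Per-arm attrition percentages are computed study-wise
#' (100 x dropouts / ITT) and averaged across studies unweighted.
#' Feature counts are tallied from the coded moderator columns when
#' present.
#'
#' @param table A [as_study_table()] object.
#' @return A list of class `review_summary`: `n_studies`,
#'   `n_with_attrition`, `mean_total_n`, `sd_total_n`,
#'   `mean_attrition_active`, `sd_attrition_active`,
#'   `mean_attrition_passive`, `sd_attrition_passive` (percent),
#'   `n_tested_diff`, `n_detected_diff`, `n_ml_mi` (`NA` when the
#'   moderator columns are absent).
#' @examples
#' summarize_review(attrition_fixture())
#' @export
summarize_review <- function(table) {
  table <- as_study_table(table)
  total_n <- table$n_itt_active + table$n_itt_passive
  pct_a <- 100 * table$drop_active / table$n_itt_active
  pct_p <- 100 * table$drop_passive / table$n_itt_passive
  mods <- code_moderators(table)
  structure(list(
    n_studies = nrow(table),
    n_with_attrition = sum(table$drop_active + table$drop_passive > 0),
    mean_total_n = mean(total_n), sd_total_n = sd(total_n),
    mean_attrition_active = mean(pct_a), sd_attrition_active = sd(pct_a),
    mean_attrition_passive = mean(pct_p), sd_attrition_passive = sd(pct_p),
    n_tested_diff = if ("tested_diff" %in% names(mods))
      sum(mods$tested_diff) else NA_integer_,
    n_detected_diff = if ("detected_diff" %in% names(mods))
      sum(mods$detected_diff, na.rm = TRUE) else NA_integer_,
    n_ml_mi = if ("used_ml_or_mi" %in% names(mods))
      sum(mods$used_ml_or_mi) else NA_integer_
  ), class = "review_summary")
}

#' @export
print.review_summary <- function(x, ...) {
  cat(sprintf("Review of %d studies (%d with attrition)\n",
              x$n_studies, x$n_with_attrition))
  cat(sprintf("  total N: mean %.2f (SD %.2f)\n",
              x$mean_total_n, x$sd_total_n))
  cat(sprintf("  attrition: active %.2f%% (SD %.2f), passive %.2f%% (SD %.2f)\n",
              x$mean_attrition_active, x$sd_attrition_active,
              x$mean_attrition_passive, x$sd_attrition_passive))
  if (!is.na(x$n_ml_mi)) {
    cat(sprintf("  tested diff: %d, detected: %d, used ML/MI: %d\n",
                x$n_tested_diff, x$n_detected_diff, x$n_ml_mi))
  }
  invisible(x)
}

#' Forest-plot data table
#'
#' The per-study effects with their 95% CIs and random-effects weights
#' (percent of total \eqn{1/(v_i + \tau^2)}), ready for plotting or
#' export.
#'
#' @inheritParams detect_outliers
#' @return A data frame: `study_id`, `yi`, `ci_low`, `ci_high`, `or`,
#'   `weight_pct`.
#' @export
forest_data <- function(effects, pooled) {
  z <- qnorm(0.975)
  w <- 1 / (effects$vi + pooled$tau2)
  data.frame(
    study_id = if ("study_id" %in% names(effects)) effects$study_id
    else as.character(seq_len(nrow(effects))),
    yi = effects$yi,
    ci_low = effects$yi - z * sqrt(effects$vi),
    ci_high = effects$yi + z * sqrt(effects$vi),
    or = exp(effects$yi),
    weight_pct = 100 * w / sum(w),
    stringsAsFactors = FALSE
  )
}
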