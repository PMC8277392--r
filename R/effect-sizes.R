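#' Continuity correction for zero cells
#'
#' Adds 0.5 to all four cells (dropouts and completers in both arms) of
#' every study whose 2x2 attrition table contains an empty cell. Studies
#' without a zero cell are returned unchanged. A logical `corrected`
#' column records which studies were modified.
#'
#' @param table A [as_study_table()] object.
#' @return The study table with corrected counts (no longer integers for
#'   corrected studies) and a `corrected` column.
#' @examples
#' tab <- attrition_fixture()
#' sum(continuity_correct(tab)$corrected)
#' @export
continuity_correct <- function(table) {
  table <- as_study_table(table)
  comp_a <- table$n_itt_active - table$drop_active
  comp_p <- table$n_itt_passive - table$drop_passive
  zero <- table$drop_active == 0 | comp_a == 0 |
    table$drop_passive == 0 | comp_p == 0
  table$drop_active[zero] <- table$drop_active[zero] + 0.5
  table$drop_passive[zero] <- table$drop_passive[zero] + 0.5
  # adding 0.5 to completers too means ITT grows by 1 per arm
  table$n_itt_active[zero] <- table$n_itt_active[zero] + 1
  table$n_itt_passive[zero] <- table$n_itt_passive[zero] + 1
  table$corrected <- zero
  table
}

new_effect_sizes <- function(study_id, yi, vi, method_tag, corrected) {
  out <- data.frame(study_id = study_id, yi = yi, vi = vi,
                    method_tag = method_tag, corrected = corrected,
                    stringsAsFactors = FALSE)
  class(out) <- c("attrition_effects", "data.frame")
  out
}

#' Per-study differential-attrition effect sizes
#'
#' `compute_log_or()` computes the standard log odds ratio of dropping
#' out in the active versus the passive arm,
#' \eqn{y_i = \log\{(d_a/c_a)/(d_p/c_p)\}} with sampling variance
#' \eqn{v_i = 1/d_a + 1/c_a + 1/d_p + 1/c_p}, where \eqn{d} counts
#' dropouts and \eqn{c} completers. Positive values mean higher attrition
#' in the active arm. A zero cell makes the log OR undefined; apply
#' [continuity_correct()] first (pass `correct = TRUE`) or use the Peto
#' estimator.
#'
#' `compute_peto_log_or()` computes the Peto approximate log odds ratio
#' \eqn{y_i = (O - E)/V}, with \eqn{O} the active-arm dropouts, \eqn{E}
#' the dropouts expected in the active arm under no arm effect, and
#' \eqn{V} the hypergeometric variance
#' \eqn{n_a n_p m (N - m) / \{N^2 (N-1)\}} (with \eqn{m} total dropouts
#' out of \eqn{N}); its sampling variance is \eqn{1/V}. The Peto
#' estimator tolerates a zero cell without correction but is undefined
#' when a study has no dropouts at all or nothing but dropouts.
#'
#' @param table A [as_study_table()] object.
#' @param correct If `TRUE`, apply [continuity_correct()] before
#'   computing standard log ORs.
#' @param na_undefined If `TRUE`, studies with an undefined effect get
#'   `NA` for `yi`/`vi` (they are then dropped by the pooling
#'   functions) instead of raising an error.
#' @return A data frame of class `attrition_effects` with columns
#'   `study_id`, `yi`, `vi`, `method_tag`, `corrected`.
#' @examples
#' eff <- compute_log_or(continuity_correct(attrition_fixture()))
#' peto <- compute_peto_log_or(attrition_fixture(), na_undefined = TRUE)
#' @export
compute_log_or <- function(table, correct = FALSE, na_undefined = FALSE) {
  table <- as_study_table(table)
  if (correct) table <- continuity_correct(table)
  corrected <- if ("corrected" %in% names(table)) table$corrected
  else rep(FALSE, nrow(table))
  da <- table$drop_active
  ca <- table$n_itt_active - table$drop_active
  dp <- table$drop_passive
  cp <- table$n_itt_passive - table$drop_passive
  zero <- da <= 0 | ca <= 0 | dp <= 0 | cp <= 0
  if (any(zero) && !na_undefined) {
    stop("undefined effect (zero cell, no continuity correction) for: ",
         paste(table$study_id[zero], collapse = ", "), call. = FALSE)
  }
  yi <- ifelse(zero, NA_real_, log((da / ca) / (dp / cp)))
  vi <- ifelse(zero, NA_real_, 1 / da + 1 / ca + 1 / dp + 1 / cp)
  new_effect_sizes(table$study_id, yi, vi, "standard", corrected)
}

#' @rdname compute_log_or
#' @export
compute_peto_log_or <- function(table, na_undefined = FALSE) {
  table <- as_study_table(table)
  n1 <- as.numeric(table$n_itt_active)
  n2 <- as.numeric(table$n_itt_passive)
  N <- n1 + n2
  O <- table$drop_active
  m <- table$drop_active + table$drop_passive
  undef <- m <= 0 | m >= N
  if (any(undef) && !na_undefined) {
    stop("undefined effect (no dropouts, or dropouts only) for: ",
         paste(table$study_id[undef], collapse = ", "), call. = FALSE)
  }
  E <- n1 * m / N
  V <- n1 * n2 * m * (N - m) / (N^2 * (N - 1))
  yi <- ifelse(undef, NA_real_, (O - E) / V)
  vi <- ifelse(undef, NA_real_, 1 / V)
  new_effect_sizes(table$study_id, yi, vi, "peto",
                   rep(FALSE, nrow(table)))
}

#' Odds ratio of dropout for a single trial
#'
#' Convenience wrapper for one 2x2 attrition table: the odds ratio of
#' dropping out in the active versus the passive arm, with a 95% CI
#' either on the Wald log-OR scale (the meta-analytic convention) or by
#' profile likelihood from a binomial logistic regression.
#'
#' @param n_itt_active,drop_active,n_itt_passive,drop_passive Counts.
#' @param ci_method `"wald"` or `"profile"`.
#' @return A list with `or`, `ci_low`, `ci_high`, `p` (two-sided Wald).
#' @examples
#' dropout_or(228, 137, 115, 48)
#' @export
dropout_or <- function(n_itt_active, drop_active, n_itt_passive,
                       drop_passive, ci_method = c("wald", "profile")) {
  ci_method <- match.arg(ci_method)
  tab <- as_study_table(data.frame(
    study_id = "trial", n_itt_active = n_itt_active,
    drop_active = drop_active, n_itt_passive = n_itt_passive,
    drop_passive = drop_passive))
  eff <- compute_log_or(tab)
  se <- sqrt(eff$vi)
  if (ci_method == "wald") {
    ci <- eff$yi + c(-1, 1) * qnorm(0.975) * se
  } else {
    fit <- glm(cbind(c(drop_active, drop_passive),
                     c(n_itt_active - drop_active,
                       n_itt_passive - drop_passive)) ~ c(1, 0),
               family = binomial())
    ci <- suppressMessages(confint(fit))[2, ]
  }
  list(or = exp(eff$yi), ci_low = exp(ci[[1]]), ci_high = exp(ci[[2]]),
       p = 2 * pnorm(-abs(eff$yi / se)))
}
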