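#' Residualized change scores
#'
#' Residualized change is the observed posttest minus the posttest
#' predicted from the pretest by OLS among completers, pooled across
#' arms — the prediction model deliberately has NO group term, in
#' contrast with the pattern-mixture [fit_outcome_model()] scale (which
#' includes it and is therefore smaller). A larger residual means a
#' smaller decline (or an increase) for a lower-is-better outcome.
#' Simple change scores (posttest minus pretest) are available as an
#' alternative.
#'
#' @param data A [as_trial_data()] object.
#' @param change `"residualized"` (default) or `"simple"`.
#' @return A list of class `residual_change_set`: `residuals` (named by
#'   subject id, completers only), `mean_residual`, `sd_residual`,
#'   `max_residual`, `min_residual`, `missing_ids`, `completer_ids`,
#'   and the `data`.
#' @examples
#' d <- simulate_trial(n_active = 60, n_passive = 30,
#'                     miss_prob_active = 0.3, seed = 1)
#' rcs <- compute_residualized_change(d)
#' c(rcs$mean_residual, rcs$sd_residual)
#' @export
compute_residualized_change <- function(data,
                                        change = c("residualized",
                                                   "simple")) {
  change <- match.arg(change)
  obs <- !is.na(data$posttest)
  if (sum(obs) < 3L) stop("need at least 3 completers", call. = FALSE)
  if (change == "residualized") {
    fit <- lm(posttest ~ pretest, data = as.data.frame(data)[obs, ])
    res <- residuals(fit)
  } else {
    res <- data$posttest[obs] - data$pretest[obs]
  }
  names(res) <- data$subject_id[obs]
  structure(list(
    residuals = res,
    mean_residual = mean(res),
    sd_residual = sd(res),
    max_residual = max(res),
    min_residual = min(res),
    completer_ids = data$subject_id[obs],
    missing_ids = data$subject_id[!obs],
    change = change,
    data = data
  ), class = "residual_change_set")
}

#' Resolve the replacement value of a named scenario
#'
#' `complete_case` excludes the missing subjects. `worst_case` replaces
#' every missing value with the worst observed residual (the maximum for
#' lower-is-better outcomes, the minimum otherwise). `small`, `medium`
#' and `large` replace them with the mean residual plus 0.20, 0.50 or
#' 0.80 observed SDs (minus, for higher-is-better outcomes). `custom`
#' uses a caller-supplied multiplier the same way.
#'
#' @param rcs A [compute_residualized_change()] result.
#' @param scenario One of `"complete_case"`, `"worst_case"`, `"small"`,
#'   `"medium"`, `"large"`, `"custom"`.
#' @param multiplier SD multiplier for `scenario = "custom"`.
#' @return `scenario_replacement()` returns the numeric replacement
#'   value (`NA` for `complete_case`). `replace_missing()` returns the
#'   full residual vector: completer residuals untouched, missing
#'   entries set to the replacement value (dropped entirely for
#'   `complete_case`), named by subject id.
#' @examples
#' d <- simulate_trial(n_active = 60, n_passive = 30,
#'                     miss_prob_active = 0.3, seed = 1)
#' rcs <- compute_residualized_change(d)
#' scenario_replacement(rcs, "small")  # mean + 0.2 * SD
#' @export
scenario_replacement <- function(rcs, scenario, multiplier = NULL) {
  lower_better <- trial_direction(rcs$data) == "lower_is_better"
  mult <- switch(scenario,
                 complete_case = return(NA_real_),
                 worst_case = return(if (lower_better) rcs$max_residual
                                     else rcs$min_residual),
                 small = 0.20, medium = 0.50, large = 0.80,
                 custom = multiplier,
                 stop("unknown scenario: ", scenario, call. = FALSE))
  if (is.null(mult)) {
    stop("scenario 'custom' needs a multiplier", call. = FALSE)
  }
  sign <- if (lower_better) 1 else -1
  rcs$mean_residual + sign * mult * rcs$sd_residual
}

#' @rdname scenario_replacement
#' @export
replace_missing <- function(rcs, scenario, multiplier = NULL) {
  if (scenario == "complete_case") return(rcs$residuals)
  value <- scenario_replacement(rcs, scenario, multiplier)
  filled <- setNames(rep(value, length(rcs$missing_ids)),
                     rcs$missing_ids)
  out <- c(rcs$residuals, filled)
  out[as.character(rcs$data$subject_id)]
}

#' Two-sample rank-sum test with mean-rank summaries
#'
#' Ranks the pooled values (midranks for ties) and compares the active
#' and passive groups. The p-value uses the exact Wilcoxon rank-sum
#' distribution when there are no ties and both groups have at most 50
#' observations, and the tie-corrected normal approximation otherwise.
#' Reported per group: mean rank, SD of ranks, and SE = SD / sqrt(n).
#' For a lower-is-better outcome a lower mean rank indicates a larger
#' decline.
#'
#' @param active_values,passive_values Numeric vectors.
#' @return A list of class `rank_test_result`: `mean_rank_active`,
#'   `mean_rank_passive`, `sd_rank_active`, `sd_rank_passive`,
#'   `se_rank_active`, `se_rank_passive`, `n_active`, `n_passive`, `p`,
#'   `method`.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p  # exact: 0.1
#' @export
rank_sum_test <- function(active_values, passive_values) {
  n_a <- length(active_values)
  n_p <- length(passive_values)
  if (n_a == 0L || n_p == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  pooled <- c(active_values, passive_values)
  r <- rank(pooled)
  ra <- r[seq_len(n_a)]
  rp <- r[n_a + seq_len(n_p)]
  U <- sum(ra) - n_a * (n_a + 1) / 2
  ties <- table(pooled)
  has_ties <- any(ties > 1L)
  if (!has_ties && max(n_a, n_p) <= 50L) {
    method <- "exact"
    p <- if (U > n_a * n_p / 2) {
      2 * pwilcox(U - 1, n_a, n_p, lower.tail = FALSE)
    } else {
      2 * pwilcox(U, n_a, n_p)
    }
    p <- min(1, p)
  } else {
    method <- "normal_approx"
    N <- n_a + n_p
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n_a * n_p / 12 * ((N + 1) - tie_term)
    z <- (U - n_a * n_p / 2) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(
    mean_rank_active = mean(ra), mean_rank_passive = mean(rp),
    sd_rank_active = sd(ra), sd_rank_passive = sd(rp),
    se_rank_active = sd(ra) / sqrt(n_a),
    se_rank_passive = sd(rp) / sqrt(n_p),
    n_active = n_a, n_passive = n_p, p = p, method = method
  ), class = "rank_test_result")
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("Rank-sum test (%s): p = %.3g\n", x$method, x$p))
  cat(sprintf("  active  n = %d, mean rank %.2f (SD %.2f, SE %.2f)\n",
              x$n_active, x$mean_rank_active, x$sd_rank_active,
              x$se_rank_active))
  cat(sprintf("  passive n = %d, mean rank %.2f (SD %.2f, SE %.2f)\n",
              x$n_passive, x$mean_rank_passive, x$sd_rank_passive,
              x$se_rank_passive))
  invisible(x)
}

#' Fixed-value replacement sensitivity analysis across scenarios
#'
#' For each scenario, builds the residual vector (completers only for
#' `complete_case`; all randomized subjects otherwise, with the missing
#' entries set to the scenario's fixed value) and runs the rank-sum
#' test. The replacement value is the same for missing subjects in both
#' arms, so with more missingness in the active arm the harsher
#' scenarios move the comparison against the active arm.
#'
#' @param data A [as_trial_data()] object.
#' @param scenarios Character vector of scenario names (see
#'   [scenario_replacement()]); default all five named scenarios.
#' @param multipliers Named numeric vector of multipliers for any
#'   `custom` scenarios (ignored otherwise).
#' @param change Passed to [compute_residualized_change()].
#' @return A data frame of class `scenario_table`, two rows (active,
#'   passive) per scenario: `scenario`, `group`, `n`, `pct` (of the
#'   arm's randomized sample), `mean_rank`, `sd_rank`, `se_rank`, `p`
#'   (on the active row, as in the usual presentation). Attribute
#'   `replacements` maps scenarios to their replacement values;
#'   attribute `trajectories` holds per-scenario, per-group means of
#'   the pretest and of the z-scored residual values, the data behind
#'   between-group trajectory plots.
#' @examples
#' d <- simulate_trial(n_active = 120, n_passive = 60,
#'                     miss_prob_active = 0.4, miss_prob_passive = 0.2,
#'                     seed = 7)
#' run_scenarios(d)
#' @export
run_scenarios <- function(data,
                          scenarios = c("complete_case", "worst_case",
                                        "small", "medium", "large"),
                          multipliers = NULL,
                          change = c("residualized", "simple")) {
  if (length(scenarios) == 0L) stop("no scenarios given", call. = FALSE)
  rcs <- compute_residualized_change(data, change = match.arg(change))
  arm_of <- setNames(as.character(data$arm), data$subject_id)
  n_itt <- table(data$arm)
  rows <- list()
  traj <- list()
  repl <- setNames(numeric(length(scenarios)), scenarios)
  for (sc in scenarios) {
    mult <- if (!is.null(multipliers) && sc %in% names(multipliers))
      multipliers[[sc]] else NULL
    values <- replace_missing(rcs, sc, mult)
    repl[sc] <- scenario_replacement(rcs, sc, mult)
    grp <- arm_of[names(values)]
    z <- as.numeric(scale(values))
    for (a in c("active", "passive")) {
      sel_ids <- names(values)[grp == a]
      traj[[length(traj) + 1L]] <- data.frame(
        scenario = sc, group = a, n = length(sel_ids),
        mean_pretest = mean(data$pretest[data$subject_id %in% sel_ids]),
        mean_residual_z = mean(z[grp == a]), stringsAsFactors = FALSE)
    }
    rt <- rank_sum_test(values[grp == "active"], values[grp == "passive"])
    rows[[length(rows) + 1L]] <- data.frame(
      scenario = sc, group = c("active", "passive"),
      n = c(rt$n_active, rt$n_passive),
      pct = 100 * c(rt$n_active / n_itt[["active"]],
                    rt$n_passive / n_itt[["passive"]]),
      mean_rank = c(rt$mean_rank_active, rt$mean_rank_passive),
      sd_rank = c(rt$sd_rank_active, rt$sd_rank_passive),
      se_rank = c(rt$se_rank_active, rt$se_rank_passive),
      p = c(rt$p, NA_real_), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "replacements") <- repl
  attr(out, "trajectories") <- do.call(rbind, traj)
  class(out) <- c("scenario_table", "data.frame")
  out
}
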