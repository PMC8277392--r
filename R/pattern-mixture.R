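# Design matrix for the imputation / outcome model: intercept, pretest,
# active-arm indicator, then any covariates.
outcome_design <- function(data, covariates = attr(data, "covariates")) {
  X <- cbind(1, data$pretest, as.integer(data$arm == "active"))
  colnames(X) <- c("(Intercept)", "pretest", "armactive")
  if (length(covariates) > 0L) {
    Xc <- as.matrix(data[, covariates, drop = FALSE])
    storage.mode(Xc) <- "double"
    X <- cbind(X, Xc)
  }
  X
}

#' Outcome model on completers
#'
#' Ordinary least squares of the posttest on the pretest and group
#' status (plus any covariates), fitted to completers. Its residual SD
#' (`sd_model`, computed as sqrt(RSS / (n - p))) is the scale that the
#' pattern-mixture offset multiplies. Including the group term makes the
#' residual SD smaller, hence the resulting offsets more conservative,
#' than a model without it.
#'
#' @param data A [as_trial_data()] object.
#' @param include_group Keep the arm indicator in the model (default).
#' @return A list of class `outcome_model_fit`: `coefficients`,
#'   `sd_model`, `n_complete`, `df_residual`.
#' @examples
#' d <- simulate_trial(n_active = 60, n_passive = 30, seed = 1)
#' fit_outcome_model(d)$sd_model
#' @export
fit_outcome_model <- function(data, include_group = TRUE) {
  obs <- !is.na(data$posttest)
  X <- outcome_design(data)
  if (!include_group) X <- X[, colnames(X) != "armactive", drop = FALSE]
  n <- sum(obs)
  p <- ncol(X)
  if (n < p || !all(table(data$arm[obs]) >= 1L)) {
    stop("too few completers to fit the outcome model", call. = FALSE)
  }
  fit <- lm.fit(X[obs, , drop = FALSE], data$posttest[obs])
  rss <- sum(fit$residuals^2)
  structure(list(
    coefficients = fit$coefficients,
    sd_model = sqrt(rss / (n - p)),
    n_complete = n,
    df_residual = n - p
  ), class = "outcome_model_fit")
}

#' Proper multiple imputation of missing posttests
#'
#' Bayesian normal linear-regression imputation with the pretest, group
#' status and any covariates as predictors. For each of the `m`
#' completed datasets the residual variance is drawn from its scaled
#' inverse-chi-squared posterior, the coefficients from their normal
#' posterior given that draw, and each missing posttest from the
#' predictive normal — so between-imputation variability reflects full
#' posterior uncertainty (no Markov chain is needed with a single
#' incomplete variable). Observed posttests are carried into every
#' completed copy untouched.
#'
#' @param data A [as_trial_data()] object.
#' @param m Number of completed datasets (default 100).
#' @param seed Integer seed; identical inputs give identical draws.
#' @return A list of class `imputation_draws`: `completed` (numeric
#'   matrix, one column per imputation), `missing_mask`, `m`, `seed`,
#'   `delta` (offset already applied, 0 here), and the `data`.
#' @examples
#' d <- simulate_trial(n_active = 60, n_passive = 30,
#'                     miss_prob_active = 0.3, seed = 1)
#' draws <- multiple_impute(d, m = 5, seed = 42)
#' @export
multiple_impute <- function(data, m = 100, seed = 1) {
  if (m < 2L) stop("m must be at least 2 for pooled inference",
                   call. = FALSE)
  miss <- is.na(data$posttest)
  if (all(miss)) stop("all posttests are missing", call. = FALSE)
  X <- outcome_design(data)
  Xobs <- X[!miss, , drop = FALSE]
  yobs <- data$posttest[!miss]
  n <- nrow(Xobs)
  p <- ncol(X)
  if (n <= p) stop("too few completers to fit the imputation model",
                   call. = FALSE)
  qr_fit <- lm.fit(Xobs, yobs)
  bhat <- qr_fit$coefficients
  rss <- sum(qr_fit$residuals^2)
  df <- n - p
  R <- chol(crossprod(Xobs))
  Xmis <- X[miss, , drop = FALSE]
  completed <- matrix(data$posttest, nrow = length(miss), ncol = m)
  set.seed(seed)
  for (j in seq_len(m)) {
    sigma2 <- rss / rchisq(1L, df)
    beta <- bhat + sqrt(sigma2) * backsolve(R, rnorm(p))
    if (any(miss)) {
      completed[miss, j] <- as.numeric(Xmis %*% beta) +
        rnorm(sum(miss), sd = sqrt(sigma2))
    }
  }
  structure(list(completed = completed, missing_mask = miss, m = m,
                 seed = seed, delta = 0, data = data),
            class = "imputation_draws")
}

#' Shift imputed values by a pattern-mixture offset
#'
#' Adds `delta * sd_model` to the imputed (previously missing) posttest
#' entries of every completed dataset, leaving observed entries
#' untouched. The sign is set by the outcome direction: the shift always
#' makes the assumed outcome of dropouts worse, so it is added for
#' lower-is-better outcomes (e.g. distress) and subtracted for
#' higher-is-better outcomes. The offset is applied to the imputed
#' values of both arms.
#'
#' @param draws An [multiple_impute()] result.
#' @param delta Nonnegative multiplier of the residual SD.
#' @param sd_model Scale of the offset; defaults to the residual SD of
#'   the completers outcome model with the group term
#'   ([fit_outcome_model()]).
#' @return An `imputation_draws` object with shifted imputed entries and
#'   the `delta` field updated.
#' @export
apply_offset <- function(draws, delta, sd_model = NULL) {
  stopifnot(delta >= 0)
  if (is.null(sd_model)) sd_model <- fit_outcome_model(draws$data)$sd_model
  sign <- if (trial_direction(draws$data) == "lower_is_better") 1 else -1
  shift <- sign * delta * sd_model
  out <- draws
  out$completed[draws$missing_mask, ] <-
    draws$completed[draws$missing_mask, , drop = FALSE] + shift
  out$delta <- delta
  out
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Point estimate = mean of the per-imputation estimates; total variance
#' = mean within-imputation variance + (1 + 1/m) x between-imputation
#' variance; degrees of freedom by the Barnard-Rubin small-sample
#' adjustment when the complete-data degrees of freedom `dfcom` are
#' supplied (otherwise the classical large-sample df); two-sided t-test
#' p-value.
#'
#' @param estimates Numeric vector of per-imputation point estimates.
#' @param variances Their squared standard errors.
#' @param dfcom Complete-data residual degrees of freedom (`Inf` for the
#'   large-sample df).
#' @return A list of class `pooled_fit`: `estimate`, `se`, `df`, `p`,
#'   `m`, `within`, `between`, `delta` (filled by [run_sensitivity()]).
#' @examples
#' pool_rubin(c(1, 3), c(1, 1))  # estimate 2, total variance 4
#' @export
pool_rubin <- function(estimates, variances, dfcom = Inf) {
  m <- length(estimates)
  if (m < 2L) stop("need at least 2 imputations to pool", call. = FALSE)
  stopifnot(length(variances) == m)
  qbar <- mean(estimates)
  ubar <- mean(variances)
  b <- var(estimates)
  total <- ubar + (1 + 1 / m) * b
  lambda <- (1 + 1 / m) * b / total
  df_old <- if (lambda > 0) (m - 1) / lambda^2 else Inf
  if (is.finite(dfcom)) {
    df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
    df <- 1 / (1 / df_old + 1 / df_obs)
  } else {
    df <- df_old
  }
  se <- sqrt(total)
  stat <- qbar / se
  p <- if (is.finite(df)) 2 * pt(-abs(stat), df) else 2 * pnorm(-abs(stat))
  structure(list(estimate = qbar, se = se, df = df, p = p, m = m,
                 within = ubar, between = b, delta = NA_real_),
            class = "pooled_fit")
}

# ANCOVA (posttest ~ pretest + arm) on one completed dataset; returns
# the active-arm coefficient and its squared SE.
analyze_completed <- function(data, posttest) {
  X <- outcome_design(data, covariates = character())
  fit <- lm.fit(X, posttest)
  rss <- sum(fit$residuals^2)
  dfres <- nrow(X) - ncol(X)
  XtXinv <- chol2inv(chol(crossprod(X)))
  idx <- which(colnames(X) == "armactive")
  c(estimate = fit$coefficients[[idx]],
    variance = rss / dfres * XtXinv[idx, idx])
}

#' Pattern-mixture sensitivity analysis over a grid of offsets
#'
#' Imputes the missing posttests once ([multiple_impute()]), then for
#' each `delta` shifts the imputed values by `delta * sd_model`
#' ([apply_offset()]), fits the ANCOVA `posttest ~ pretest + arm` to
#' every completed dataset and pools by Rubin's rules
#' ([pool_rubin()]). `delta = 0` is ordinary multiple imputation under
#' MAR; growing `delta` assumes progressively worse outcomes for the
#' dropouts. The same imputation draws are reused across offsets by
#' default (less Monte-Carlo noise between rows); set
#' `reuse_draws = FALSE` to re-impute per delta.
#'
#' @param data A [as_trial_data()] object.
#' @param deltas Offset grid; must contain 0, the MAR anchor. Default
#'   `c(0, 0.2, 0.5, 0.8, 1.1, 1.4)`.
#' @param m Number of imputations (default 100).
#' @param seed Integer seed.
#' @param reuse_draws Reuse one set of imputation draws for all deltas.
#' @return A data frame of class `sensitivity_table` with one row per
#'   delta: `delta`, `estimate` (active vs passive coefficient on the
#'   posttest controlling for pretest), `se`, `df`, `p`. Attributes:
#'   `sd_model`, `m`, `seed`, and `trajectories` (per delta and arm, the
#'   mean pretest and mean posttest of observed and imputed subjects —
#'   the data behind trajectory plots).
#' @examples
#' d <- simulate_trial(n_active = 120, n_passive = 60,
#'                     miss_prob_active = 0.4, miss_prob_passive = 0.2,
#'                     seed = 7)
#' run_sensitivity(d, m = 10, seed = 7)
#' @export
run_sensitivity <- function(data, deltas = c(0, 0.2, 0.5, 0.8, 1.1, 1.4),
                            m = 100, seed = 1, reuse_draws = TRUE) {
  if (!any(deltas == 0)) {
    stop("deltas must include 0 (the MAR anchor)", call. = FALSE)
  }
  sd_model <- fit_outcome_model(data)$sd_model
  base <- multiple_impute(data, m = m, seed = seed)
  dfcom <- nrow(data) - 3
  rows <- vector("list", length(deltas))
  traj <- vector("list", length(deltas))
  for (i in seq_along(deltas)) {
    dr <- if (reuse_draws) base
    else multiple_impute(data, m = m, seed = seed + i - 1L)
    dr <- apply_offset(dr, deltas[i], sd_model = sd_model)
    est <- apply(dr$completed, 2, function(y) analyze_completed(data, y))
    fit <- pool_rubin(est["estimate", ], est["variance", ], dfcom = dfcom)
    rows[[i]] <- data.frame(delta = deltas[i], estimate = fit$estimate,
                            se = fit$se, df = fit$df, p = fit$p)
    traj[[i]] <- imputation_trajectories(dr)
  }
  out <- do.call(rbind, rows)
  attr(out, "sd_model") <- sd_model
  attr(out, "m") <- m
  attr(out, "seed") <- seed
  attr(out, "trajectories") <- do.call(rbind, traj)
  class(out) <- c("sensitivity_table", "data.frame")
  out
}

# Group means of observed vs imputed pre/post values for one offset.
imputation_trajectories <- function(draws) {
  data <- draws$data
  miss <- draws$missing_mask
  post_imp <- rowMeans(draws$completed)
  rows <- list()
  for (a in levels(data$arm)) {
    for (st in c("observed", "imputed")) {
      sel <- data$arm == a & (if (st == "observed") !miss else miss)
      if (!any(sel)) next
      rows[[length(rows) + 1L]] <- data.frame(
        delta = draws$delta, arm = a, status = st, n = sum(sel),
        mean_pretest = mean(data$pretest[sel]),
        mean_posttest = mean(post_imp[sel]))
    }
  }
  do.call(rbind, rows)
}
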