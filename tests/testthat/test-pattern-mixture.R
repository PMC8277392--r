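test_that("outcome model residual SD behaves like an OLS sigma", {
  # perfectly linear outcome -> zero residual SD
  pre <- rnorm(40)
  arm <- rep(c("active", "passive"), 20)
  post <- 1 + 0.5 * pre - 0.3 * (arm == "active")
  d <- make_trial(pre, post, arm)
  expect_equal(fit_outcome_model(d)$sd_model, 0, tolerance = 1e-8)

  # recovers the generating residual SD at large n
  d2 <- simulate_trial(n_active = 3000, n_passive = 2000,
                       residual_sd = 0.65, miss_prob_active = 0,
                       miss_prob_passive = 0, seed = 11)
  expect_lt(abs(fit_outcome_model(d2)$sd_model - 0.65), 0.02)

  # dropping the group term cannot reduce the residual SD much below
  # the full model (nested RSS monotonicity, up to the df adjustment)
  d3 <- simulate_trial(n_active = 400, n_passive = 200,
                       treatment_effect = -0.5, miss_prob_active = 0,
                       miss_prob_passive = 0, seed = 12)
  full <- fit_outcome_model(d3)
  reduced <- fit_outcome_model(d3, include_group = FALSE)
  rss_full <- full$sd_model^2 * full$df_residual
  rss_reduced <- reduced$sd_model^2 * reduced$df_residual
  expect_gte(rss_reduced, rss_full)

  expect_error(fit_outcome_model(
    make_trial(c(1, 2, 3, 4), c(1, NA, NA, NA),
               c("active", "active", "passive", "passive"))),
    "too few")
})

test_that("imputation is proper, deterministic, and leaves observed data alone", {
  d <- simulate_trial(n_active = 150, n_passive = 80,
                      miss_prob_active = 0.4, miss_prob_passive = 0.2,
                      seed = 21)
  draws <- multiple_impute(d, m = 10, seed = 5)
  obs <- !draws$missing_mask
  # observed entries identical across all copies and to the input
  expect_true(all(draws$completed[obs, ] == d$posttest[obs]))
  # imputed entries differ across imputations
  expect_gt(min(apply(draws$completed[draws$missing_mask, ], 1, sd)), 0)
  # same seed, same draws; different seed, different draws
  again <- multiple_impute(d, m = 10, seed = 5)
  expect_identical(draws$completed, again$completed)
  other <- multiple_impute(d, m = 10, seed = 6)
  expect_false(identical(draws$completed, other$completed))

  # no missing data: all copies equal the input
  d0 <- simulate_trial(n_active = 50, n_passive = 30,
                       miss_prob_active = 0, miss_prob_passive = 0,
                       seed = 3)
  dr0 <- multiple_impute(d0, m = 4, seed = 1)
  expect_true(all(dr0$completed == d0$posttest))

  expect_error(multiple_impute(d, m = 1, seed = 1), "at least 2")
  d_allmiss <- make_trial(rnorm(6), rep(NA_real_, 6),
                          rep(c("active", "passive"), 3))
  expect_error(multiple_impute(d_allmiss, m = 5, seed = 1),
               "all posttests")
})

test_that("MI under MCAR tracks the full-data ANCOVA estimate", {
  d_full <- simulate_trial(n_active = 700, n_passive = 300,
                           treatment_effect = -0.4, miss_prob_active = 0,
                           miss_prob_passive = 0, seed = 31)
  full_fit <- lm(posttest ~ pretest + arm, data = as.data.frame(d_full))
  full_est <- coef(full_fit)[["armactive"]]
  # mask 30% completely at random
  set.seed(32)
  masked <- as.data.frame(d_full)
  masked$posttest[runif(nrow(masked)) < 0.3] <- NA
  dm <- as_trial_data(masked)
  st <- run_sensitivity(dm, deltas = 0, m = 100, seed = 33)
  expect_lt(abs(st$estimate[1] - full_est), 2.5 * st$se[1])
})

test_that("offsets shift imputed values only, with the direction convention", {
  d <- simulate_trial(n_active = 80, n_passive = 40,
                      miss_prob_active = 0.3, miss_prob_passive = 0.2,
                      seed = 41)
  draws <- multiple_impute(d, m = 5, seed = 2)
  # delta = 0 leaves everything alone
  expect_identical(apply_offset(draws, 0, sd_model = 1)$completed,
                   draws$completed)
  # lower-is-better adds delta * sd to imputed entries only
  sh <- apply_offset(draws, 0.2, sd_model = 1)
  miss <- draws$missing_mask
  expect_equal(sh$completed[miss, ], draws$completed[miss, ] + 0.2)
  expect_equal(sh$completed[!miss, ], draws$completed[!miss, ])

  # higher-is-better subtracts
  d_hib <- simulate_trial(n_active = 80, n_passive = 40,
                          miss_prob_active = 0.3, miss_prob_passive = 0.2,
                          direction = "higher_is_better", seed = 41)
  dr2 <- multiple_impute(d_hib, m = 3, seed = 2)
  sh2 <- apply_offset(dr2, 0.5, sd_model = 2)
  miss2 <- dr2$missing_mask
  expect_equal(sh2$completed[miss2, ], dr2$completed[miss2, ] - 1.0)
})

test_that("Rubin pooling matches the direct formulas", {
  # {1, 3} with unit within-variances: pooled 2, total variance 4
  p <- pool_rubin(c(1, 3), c(1, 1))
  expect_equal(p$estimate, 2)
  expect_equal(p$se^2, 4)

  # identical estimates: between-variance zero, se = sqrt(mean within)
  p0 <- pool_rubin(rep(1.5, 10), rep(0.04, 10))
  expect_equal(p0$between, 0)
  expect_equal(p0$se, 0.2)
  expect_equal(p0$df, Inf)

  # oracle equivalence on arbitrary inputs
  set.seed(7)
  q <- rnorm(20)
  u <- runif(20, 0.5, 2)
  ora <- rubin_oracle(q, u)
  pp <- pool_rubin(q, u)
  expect_equal(pp$estimate, ora$estimate, tolerance = 1e-12)
  expect_equal(pp$se^2, ora$total_variance, tolerance = 1e-12)

  # Barnard-Rubin df never exceeds the complete-data df
  pbr <- pool_rubin(q, u, dfcom = 50)
  expect_lt(pbr$df, 50)
  expect_error(pool_rubin(1, 1), "at least 2")
})

test_that("sensitivity table attenuates monotonically under MNAR-style offsets", {
  d <- simulate_trial(n_active = 1340, n_passive = 660,
                      treatment_effect = -0.4, miss_prob_active = 0.6,
                      miss_prob_passive = 0.42, seed = 51)
  st <- run_sensitivity(d, m = 50, seed = 52)
  # same draws across deltas -> strictly monotone attenuation of the
  # (negative) active-arm benefit
  expect_true(all(diff(st$estimate) > 0))
  expect_lt(st$estimate[1], 0)
  # delta grid echoes the default
  expect_equal(st$delta, c(0, 0.2, 0.5, 0.8, 1.1, 1.4))

  # identical inputs give identical output, to the last bit
  st2 <- run_sensitivity(d, m = 50, seed = 52)
  expect_identical(st, st2)

  # no missing data: the estimate ignores delta
  d0 <- simulate_trial(n_active = 60, n_passive = 40,
                       miss_prob_active = 0, miss_prob_passive = 0,
                       seed = 53)
  st0 <- run_sensitivity(d0, m = 5, seed = 1)
  expect_equal(var(st0$estimate), 0)

  expect_error(run_sensitivity(d, deltas = c(0.2, 0.5)), "include 0")
})
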