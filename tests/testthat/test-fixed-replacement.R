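test_that("residualized change is centred and shift-invariant", {
  d <- simulate_trial(n_active = 200, n_passive = 100,
                      miss_prob_active = 0.3, miss_prob_passive = 0.2,
                      seed = 61)
  rcs <- compute_residualized_change(d)
  expect_lt(abs(rcs$mean_residual), 1e-10)
  expect_lte(rcs$min_residual, rcs$max_residual)
  expect_equal(sort(c(rcs$completer_ids, rcs$missing_ids)),
               sort(d$subject_id))

  # posttest identical to pretest: all residuals zero
  pre <- rnorm(30)
  d2 <- make_trial(pre, pre, rep(c("active", "passive"), 15))
  expect_equal(max(abs(compute_residualized_change(d2)$residuals)), 0,
               tolerance = 1e-12)

  # adding a constant to every posttest is absorbed by the intercept
  d3 <- as.data.frame(d)
  d3$posttest <- d3$posttest + 5
  rcs3 <- compute_residualized_change(as_trial_data(d3))
  expect_equal(rcs3$residuals, rcs$residuals)

  expect_error(compute_residualized_change(
    make_trial(c(1, 2, 3, 4), c(1, 2, NA, NA),
               c("active", "passive", "active", "passive"))),
    "3 completers")
})

test_that("scenario replacements implement the fixed-value arithmetic", {
  # printed worked example: mean 0, SD 0.65
  d <- simulate_trial(n_active = 40, n_passive = 20,
                      miss_prob_active = 0.3, miss_prob_passive = 0.2,
                      seed = 62)
  rcs <- compute_residualized_change(d)
  rcs$mean_residual <- 0
  rcs$sd_residual <- 0.65
  expect_equal(scenario_replacement(rcs, "small"), 0.13)
  expect_equal(scenario_replacement(rcs, "medium"), 0.325)
  expect_equal(scenario_replacement(rcs, "large"), 0.52)
  expect_equal(scenario_replacement(rcs, "worst_case"), rcs$max_residual)
  expect_equal(scenario_replacement(rcs, "custom", multiplier = 1.1),
               0.715)
  expect_error(scenario_replacement(rcs, "bogus"), "unknown scenario")

  # higher-is-better flips the sign and the worst case
  d_hib <- simulate_trial(n_active = 40, n_passive = 20,
                          miss_prob_active = 0.3, miss_prob_passive = 0.2,
                          direction = "higher_is_better", seed = 62)
  rcs2 <- compute_residualized_change(d_hib)
  expect_equal(scenario_replacement(rcs2, "worst_case"),
               rcs2$min_residual)
  expect_equal(scenario_replacement(rcs2, "small"),
               rcs2$mean_residual - 0.2 * rcs2$sd_residual)

  # replacement never alters completer residuals
  filled <- replace_missing(rcs, "large")
  expect_equal(filled[rcs$completer_ids], rcs$residuals[rcs$completer_ids])
  expect_true(all(filled[rcs$missing_ids] ==
                    scenario_replacement(rcs, "large")))
})

test_that("rank-sum test matches exact enumeration and wilcox.test", {
  # smallest possible rank sum: exact two-sided p = 2/20
  rt <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rt$p, 0.1)
  expect_equal(rt$method, "exact")

  # identical groups: equal mean ranks, p near 1
  rt2 <- rank_sum_test(1:6 + 0.5, 1:6)
  expect_equal(rt2$mean_rank_active, rt2$mean_rank_passive,
               tolerance = 0.2)
  expect_gt(rt2$p, 0.5)

  # exact p equals brute-force enumeration for small tie-free groups
  set.seed(70)
  for (r in 1:8) {
    a <- rnorm(sample(3:8, 1))
    b <- rnorm(sample(3:8, 1))
    rt <- rank_sum_test(a, b)
    expect_equal(rt$p, enumeration_rank_p(a, b), tolerance = 1e-12)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(rt$p, ref$p.value, tolerance = 1e-12)
  }

  # tie-corrected normal approximation agrees with wilcox.test
  set.seed(71)
  a <- round(rnorm(60), 1)
  b <- round(rnorm(80, 0.3), 1)
  rt3 <- rank_sum_test(a, b)
  expect_equal(rt3$method, "normal_approx")
  ref3 <- wilcox.test(a, b, correct = FALSE)
  expect_equal(rt3$p, ref3$p.value, tolerance = 1e-10)

  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("midranks preserve the rank sum", {
  set.seed(72)
  for (r in 1:5) {
    a <- sample(1:5, 20, replace = TRUE)
    b <- sample(1:5, 15, replace = TRUE)
    rt <- rank_sum_test(a, b)
    N <- rt$n_active + rt$n_passive
    expect_equal(rt$mean_rank_active * rt$n_active +
                   rt$mean_rank_passive * rt$n_passive,
                 N * (N + 1) / 2)
  }
})

test_that("direction reversal is equivalent to negating the scores", {
  d <- simulate_trial(n_active = 120, n_passive = 60,
                      treatment_effect = -0.4, miss_prob_active = 0.4,
                      miss_prob_passive = 0.2, seed = 73)
  neg <- as.data.frame(d)
  neg$pretest <- -neg$pretest
  neg$posttest <- -neg$posttest
  d_neg <- as_trial_data(neg, direction = "higher_is_better")
  t1 <- run_scenarios(d)
  t2 <- run_scenarios(d_neg)
  expect_equal(t1$p, t2$p, tolerance = 1e-10)
  # ranks mirror: mean rank of one is N + 1 minus the other's
  for (i in seq_len(nrow(t1))) {
    N <- sum(t1$n[t1$scenario == t1$scenario[i] &
                    t1$group %in% c("active", "passive")])
    expect_equal(t1$mean_rank[i] + t2$mean_rank[i], N + 1,
                 tolerance = 1e-10)
  }
})

test_that("scenario severity narrows the active advantage monotonically", {
  d <- simulate_trial(n_active = 1340, n_passive = 660,
                      treatment_effect = -0.4, miss_prob_active = 0.6,
                      miss_prob_passive = 0.42, seed = 74)
  tab <- run_scenarios(d, scenarios = c("small", "medium", "large"))
  gaps <- with(as.data.frame(tab), {
    a <- mean_rank[group == "active"]
    p <- mean_rank[group == "passive"]
    p - a  # positive gap favours the active arm (lower rank = decline)
  })
  expect_true(all(diff(gaps) < 0))

  # no missing data: every scenario yields the same rows
  d0 <- simulate_trial(n_active = 50, n_passive = 30,
                       miss_prob_active = 0, miss_prob_passive = 0,
                       seed = 75)
  t0 <- run_scenarios(d0)
  base <- t0[t0$scenario == "complete_case", -1]
  for (sc in unique(t0$scenario)) {
    expect_equal(t0[t0$scenario == sc, -1], base, ignore_attr = TRUE)
  }
})
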