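# Builders and independent oracles shared across the test files.

make_study_table <- function(n_itt_active, drop_active, n_itt_passive,
                             drop_passive, ids = NULL) {
  k <- length(n_itt_active)
  as_study_table(data.frame(
    study_id = ids %||% paste0("study", seq_len(k)),
    n_itt_active = n_itt_active, drop_active = drop_active,
    n_itt_passive = n_itt_passive, drop_passive = drop_passive,
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_trial <- function(pretest, posttest, arm,
                       direction = "lower_is_better") {
  as_trial_data(data.frame(
    subject_id = seq_along(pretest), arm = arm,
    pretest = pretest, posttest = posttest,
    stringsAsFactors = FALSE), direction = direction)
}

# Closed-form DerSimonian-Laird pool, written independently of the
# package (and of metafor): fixed-effect weights for Q, moment tau2,
# then inverse-variance pooling.
dl_pool_oracle <- function(yi, vi) {
  w <- 1 / vi
  mu_fe <- sum(w * yi) / sum(w)
  Q <- sum(w * (yi - mu_fe)^2)
  k <- length(yi)
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - (k - 1)) / C)
  wr <- 1 / (vi + tau2)
  mu <- sum(wr * yi) / sum(wr)
  se <- sqrt(1 / sum(wr))
  list(mu = mu, se = se, tau2 = tau2)
}

# Rubin's rules by direct formula evaluation.
rubin_oracle <- function(q, u) {
  m <- length(q)
  qbar <- sum(q) / m
  ubar <- sum(u) / m
  b <- sum((q - qbar)^2) / (m - 1)
  total <- ubar + (1 + 1 / m) * b
  list(estimate = qbar, total_variance = total)
}

# Exact two-sided rank-sum p-value by brute-force enumeration of all
# choose(n, n_a) group assignments of the pooled sample.
enumeration_rank_p <- function(active, passive) {
  pooled <- c(active, passive)
  r <- rank(pooled)
  n_a <- length(active)
  obs <- sum(r[seq_len(n_a)])
  idx <- utils::combn(length(pooled), n_a)
  sums <- apply(idx, 2, function(i) sum(r[i]))
  mu <- mean(sums)
  # two-sided: assignments at least as extreme (in distance from the
  # mean rank sum) as observed
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}
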