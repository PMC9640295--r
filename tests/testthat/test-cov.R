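test_that("pooled log-scale within-subject variance matches hand evaluation", {
  res <- cov_within(c(100, 110, 90, 110), c("A", "A", "B", "B"))
  # hand arithmetic: (log(110/100)^2 + log(110/90)^2) / 2 / 2
  expect_equal(res$s_w^2, 0.01233820, tolerance = 1e-6)
  expect_equal(res$cov_pct, 11.142, tolerance = 1e-3)
  expect_equal(res$df, 2L)
  expect_equal(res$n_individuals, 2L)
})

test_that("zero within-individual variance gives CoV 0 with degenerate CI", {
  res <- cov_within(c(100, 100, 120, 120), c("A", "A", "B", "B"))
  expect_equal(res$s_w, 0)
  expect_equal(res$cov_pct, 0)
  expect_equal(c(res$ci_lo, res$ci_hi), c(0, 0))
})

test_that("estimator is invariant to rescaling all measurements", {
  s <- sim_repeated(40, 3, 6, seed = 41)
  a <- cov_within(s$values, s$id)
  b <- cov_within(s$values * 10, s$id)
  expect_equal(a$cov_pct, b$cov_pct, tolerance = 1e-12)
  expect_equal(a$ci_lo, b$ci_lo, tolerance = 1e-12)
})

test_that("single-session individuals are excluded without changing the estimate", {
  s <- sim_repeated(25, 3, 7, seed = 42)
  with_extra <- cov_within(c(s$values, 140), c(s$id, 999L))
  without <- cov_within(s$values, s$id)
  expect_equal(with_extra$cov_pct, without$cov_pct)
  expect_equal(with_extra$n_excluded, 1L)
  expect_equal(with_extra$df, without$df)
})

test_that("s_w^2 agrees with brute-force decomposition and one-way aov", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    m <- sample(3:5, 1)
    s <- sim_repeated(n, m, runif(1, 3, 12))
    res <- cov_within(s$values, s$id)
    expect_equal(res$s_w^2, brute_pooled_within_var(s$values, s$id),
                 tolerance = 1e-10)
    # independent route: residual mean square of one-way ANOVA on log values
    fit <- stats::aov(log(s$values) ~ factor(s$id))
    ms_within <- sum(fit$residuals^2) / fit$df.residual
    expect_equal(res$s_w^2, ms_within, tolerance = 1e-10)
  }
})

test_that("unbalanced designs pool degrees of freedom correctly", {
  values <- c(100, 104, 98, 120, 126, 90, 92)
  id <- c("a", "a", "a", "b", "b", "c", "c")
  res <- cov_within(values, id)
  expect_equal(res$df, 4L)
  expect_equal(res$s_w^2, brute_pooled_within_var(values, id),
               tolerance = 1e-12)
})

test_that("CoV approximates s_w to first order at moderate magnitudes", {
  # leading error term is cv^2/4 relative, ~0.5% around CoV 14%
  for (cv in c(2, 5, 10, 14)) {
    sw <- sigma_w_from_cov(cv)
    expect_lt(abs(cv / 100 - sw) / sw, 0.005)
    expect_lt(abs(cv / 100 - sw) / sw, 1.01 * (cv / 100)^2 / 4)
  }
})

test_that("non-positive values and all-singleton input raise errors", {
  expect_error(cov_within(c(1, -1), c("a", "a")), "positive")
  expect_error(cov_within(c(100, 120), c("a", "b")), "insufficient")
})

test_that("chi-square interval is a valid alternative and brackets the estimate", {
  s <- sim_repeated(50, 3, 6, seed = 9)
  d <- cov_within(s$values, s$id, ci_method = "delta")
  x <- cov_within(s$values, s$id, ci_method = "chisq")
  expect_equal(d$cov_pct, x$cov_pct)
  expect_lt(x$ci_lo, x$cov_pct)
  expect_gt(x$ci_hi, x$cov_pct)
  # the two intervals agree closely at this df
  expect_equal(x$ci_lo, d$ci_lo, tolerance = 0.02)
})

test_that("comparison of identical estimates gives z = 0, p = 1 and overlap", {
  s <- sim_repeated(30, 3, 6, seed = 5)
  a <- cov_within(s$values, s$id)
  cmp <- compare_cov(a, a)
  expect_true(cmp$ci_overlap)
  expect_equal(cmp$z, 0)
  expect_equal(cmp$p, 1)
})

test_that("clearly different variability yields non-overlapping intervals", {
  lo <- sim_repeated(200, 4, 3, seed = 6)
  hi <- sim_repeated(200, 4, 12, seed = 7)
  cmp <- compare_cov(cov_within(lo$values, lo$id), cov_within(hi$values, hi$id))
  expect_false(cmp$ci_overlap)
  expect_lt(cmp$p, 0.001)
})

test_that("zero-variance group disables the z-test but keeps the CI verdict", {
  a <- cov_within(c(100, 100, 90, 90), c("a", "a", "b", "b"))
  b <- cov_within(sim_repeated(20, 3, 6, seed = 8)$values,
                  sim_repeated(20, 3, 6, seed = 8)$id)
  cmp <- compare_cov(a, b)
  expect_true(is.na(cmp$z))
  expect_false(cmp$ci_overlap)
})

test_that("per-individual BPV records match hand arithmetic", {
  s <- data.frame(individual_id = c("A", "A", "B", "B", "B"),
                  sbp_day = c(120, 130, 110, 110, 110))
  bpv <- individual_bpv(s, "sbp_day")
  a <- bpv[bpv$individual_id == "A", ]
  expect_equal(a$mean, 125)
  expect_equal(a$sd, 7.0710678, tolerance = 1e-6)
  expect_equal(a$individual_cov, 7.0710678 / 125, tolerance = 1e-6)
  b <- bpv[bpv$individual_id == "B", ]
  expect_equal(b$sd, 0)
  expect_equal(b$individual_cov, 0)
})

test_that("single-session individuals are dropped from BPV with a count", {
  s <- data.frame(individual_id = c("A", "A", "C"),
                  sbp_day = c(120, 130, 140))
  bpv <- individual_bpv(s, "sbp_day")
  expect_equal(nrow(bpv), 1L)
  expect_equal(attr(bpv, "n_excluded"), 1L)
})

test_that("cohort mean of individual SDs tracks sigma_w times the mean level", {
  # E[sample SD of m lognormal draws] ~ c4(m) * sigma * mean for small CoV
  set.seed(123)
  n <- 800; m <- 3
  cov_target <- 5.4
  sw <- sigma_w_from_cov(cov_target)
  mu <- log(130) + rnorm(n, 0, 0.08)
  sess <- data.frame(
    individual_id = rep(seq_len(n), each = m),
    sbp_day = exp(rep(mu, each = m) + sw * rnorm(n * m)))
  bpv <- individual_bpv(sess, "sbp_day")
  c4 <- sqrt(2 / (m - 1)) * gamma(m / 2) / gamma((m - 1) / 2)
  expected <- mean(exp(mu)) * (cov_target / 100) * c4
  expect_equal(mean(bpv$sd), expected, tolerance = 0.08)
})

test_that("reference range reproduces the worked clinical examples", {
  rr <- reference_range(140, 5.4)
  expect_equal(rr$lo, 140 * (1 - qnorm(0.975) * 0.054), tolerance = 1e-10)
  expect_equal(round(rr$lo, 1), 125.2)
  expect_equal(round(rr$hi, 1), 154.8)
  expect_equal(rr$presented, "125–155")
  # diastolic example: the formula gives 79-101
  rr2 <- reference_range(90, 6.1)
  expect_equal(round(rr2$lo, 1), 79.2)
  expect_equal(round(rr2$hi, 1), 100.8)
  expect_equal(rr2$presented, "79–101")
})

test_that("reference range degenerates to the mean at CoV 0 and rejects huge CoV", {
  rr <- reference_range(117, 0)
  expect_equal(c(rr$lo, rr$hi), c(117, 117))
  expect_error(reference_range(120, 60), "not positive")
})
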