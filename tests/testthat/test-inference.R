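test_that("repeated-measures ANOVA matches brute-force sums of squares", {
  set.seed(55)
  for (rep in 1:20) {
    n <- sample(4:8, 1); t <- sample(3:5, 1)
    mat <- matrix(rnorm(n * t, 120, 8), n, t) +
      outer(rnorm(n, 0, 6), rnorm(t, 0, 2), `+`)
    a <- rm_anova(mat)
    b <- brute_rm_anova(mat)
    expect_equal(a$F, b$F, tolerance = 1e-10)
    expect_equal(unname(a$ss["time"]), b$ss_time, tolerance = 1e-10)
  }
})

test_that("F equals the squared paired-t statistic at two timepoints", {
  set.seed(56)
  mat <- matrix(rnorm(24, 120, 10), 12, 2)
  a <- rm_anova(mat)
  pt <- paired_t(mat[, 2], mat[, 1])
  expect_equal(a$F, pt$t^2, tolerance = 1e-10)
  expect_equal(a$p, pt$p, tolerance = 1e-12)
})

test_that("identical columns give F = 0 and p = 1", {
  mat <- matrix(rnorm(5, 120, 8), 5, 1)[, c(1, 1, 1)]
  a <- rm_anova(mat)
  expect_equal(a$F, 0)
  expect_equal(a$p, 1)
})

test_that("incomplete rows are dropped and tiny designs rejected", {
  mat <- matrix(rnorm(20), 5, 4)
  mat[2, 3] <- NA
  expect_equal(rm_anova(mat)$n_dropped, 1L)
  expect_error(rm_anova(matrix(rnorm(4), 2, 2)), "insufficient")
})

test_that("an arm with identical sessions is eligible with p = 1", {
  mat <- matrix(rnorm(3, 120, 5), 3, 1)[, c(1, 1)]
  dec <- screen_arm_eligibility(mat)
  expect_equal(dec$anova_p, 1)
  expect_true(dec$eligible)
  expect_true(is.na(dec$posthoc_p))
})

test_that("a step change at the final session makes the arm ineligible", {
  set.seed(57)
  hits <- 0L
  for (r in 1:40) {
    mat <- matrix(130 + rnorm(250, 0, 7), 50, 5)
    mat[, 5] <- mat[, 5] + 8
    dec <- screen_arm_eligibility(mat)
    hits <- hits + !dec$eligible
  }
  expect_gt(hits / 40, 0.9)
})

test_that("the Bonferroni family switch changes only the adjusted p", {
  set.seed(58)
  mat <- matrix(130 + rnorm(150, 0, 6), 30, 5)
  mat[, 5] <- mat[, 5] + 6
  pw <- screen_arm_eligibility(mat, "pairwise")
  sg <- screen_arm_eligibility(mat, "single")
  expect_equal(pw$anova_p, sg$anova_p)
  if (!is.na(pw$posthoc_p) && pw$posthoc_p < 1) {
    expect_equal(pw$posthoc_p, min(1, sg$posthoc_p * 10), tolerance = 1e-12)
  }
})

test_that("paired t-test matches its closed form and degenerate conventions", {
  pt <- paired_t(c(2, 3, 4), c(1, 1, 1))
  expect_equal(pt$t, 3.4641, tolerance = 1e-4)
  expect_equal(pt$df, 2)
  expect_equal(pt$p, 0.0742, tolerance = 1e-3)
  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(same$t, same$p), c(0, 1))
  const <- paired_t(c(2, 3, 4), c(1, 2, 3))
  expect_equal(const$p, 0)
})

test_that("pearson correlation handles exact linear relations and brute force", {
  x <- c(1, 2, 4, 6, 9)
  expect_equal(pearson_r(x, x)$r, 1)
  expect_equal(pearson_r(x, -2 * x + 7)$r, -1)
  set.seed(59)
  a <- rnorm(10); b <- rnorm(10)
  r_brute <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_r(a, b)$r, r_brute, tolerance = 1e-12)
  expect_error(pearson_r(c(1, 1, 1), a[1:3]), "zero variance")
})

test_that("standardized OLS matches the normal equations oracle", {
  set.seed(60)
  d <- data.frame(x1 = rnorm(12), x2 = rnorm(12), x3 = rbinom(12, 1, 0.5))
  d$y <- 1 + 0.5 * d$x1 - 0.3 * d$x2 + 0.8 * d$x3 + rnorm(12, 0, 0.4)
  fit <- ols_std(y ~ x1 + x2 + x3, d)
  b_oracle <- brute_ols_coef(d$y, as.matrix(d[c("x1", "x2", "x3")]))
  expect_equal(fit$coefficients$b, unname(b_oracle), tolerance = 1e-10)
})

test_that("with a single predictor the standardized beta equals Pearson r", {
  set.seed(61)
  d <- data.frame(x = rnorm(30))
  d$y <- 0.6 * d$x + rnorm(30)
  fit <- ols_std(y ~ x, d)
  expect_equal(fit$coefficients$beta, pearson_r(d$x, d$y)$r,
               tolerance = 1e-10)
})

test_that("standardized betas are invariant to affine predictor rescaling", {
  set.seed(62)
  d <- data.frame(x1 = rnorm(40), x2 = rnorm(40))
  d$y <- d$x1 - d$x2 + rnorm(40)
  a <- ols_std(y ~ x1 + x2, d)
  d$x1 <- 1000 * d$x1 + 77
  b <- ols_std(y ~ x1 + x2, d)
  expect_equal(a$coefficients$beta, b$coefficients$beta, tolerance = 1e-10)
})

test_that("a noiseless linear combination gives R^2 = 1 and a singular design errors", {
  d <- data.frame(x1 = rnorm(15), x2 = rnorm(15))
  d$y <- 2 * d$x1 + 3 * d$x2
  fit <- suppressWarnings(ols_std(y ~ x1 + x2, d))  # lm warns on perfect fit
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  d$x3 <- d$x1 + d$x2
  expect_error(ols_std(y ~ x1 + x2 + x3, d), "collinear")
})

test_that("Fleiss kappa is 1 on perfect agreement and matches brute force", {
  perfect <- rbind(c("A", "A", "A"), c("B", "B", "B"), c("A", "A", "A"))
  expect_equal(fleiss_kappa(perfect)$kappa, 1)
  mixed <- rbind(c("A", "A"), c("A", "B"), c("B", "B"))
  k <- fleiss_kappa(mixed)
  expect_equal(k$kappa, brute_fleiss_kappa(mixed), tolerance = 1e-12)
  expect_equal(k$kappa, 1 / 3, tolerance = 1e-12)
  set.seed(63)
  r <- matrix(sample(letters[1:4], 60, TRUE), 15, 4)
  expect_equal(fleiss_kappa(r)$kappa, brute_fleiss_kappa(r), tolerance = 1e-12)
})

test_that("kappa is invariant to relabeling categories and permuting rows/columns", {
  set.seed(64)
  r <- matrix(sample(c("x", "y", "z"), 100, TRUE), 20, 5)
  k0 <- fleiss_kappa(r)$kappa
  relabel <- matrix(c(x = "P", y = "Q", z = "R")[r], 20, 5)
  expect_equal(fleiss_kappa(relabel)$kappa, k0, tolerance = 1e-12)
  expect_equal(fleiss_kappa(r[sample(20), ])$kappa, k0, tolerance = 1e-12)
  expect_equal(fleiss_kappa(r[, sample(5)])$kappa, k0, tolerance = 1e-12)
})

test_that("kappa errors on degenerate tables and excludes incomplete subjects", {
  expect_error(fleiss_kappa(rbind(c("A", "A"), c("A", "A"))), "single category")
  r <- rbind(c("A", "B"), c("B", "B"), c("A", NA))
  k <- fleiss_kappa(r)
  expect_equal(k$n_subjects, 2L)
  expect_equal(k$n_excluded, 1L)
})

test_that("adaptation test recovers an injected night-time diastolic pattern", {
  spec <- cohort_spec(n_per_study = c(CRESSIDA = 120L),
                      adaptation = list(enabled = TRUE,
                                        offsets = c(-3, 3, 1.5, 0, -1.5)))
  co <- simulate_cohort(spec, seed = 21)
  a <- adaptation_test(co$sessions, "dbp_night")
  expect_equal(order(a$means), order(65 + c(-3, 3, 1.5, 0, -1.5)))
  expect_lt(a$p, 0.05)
  const <- data.frame(individual_id = rep(1:3, each = 3),
                      session_index = rep(1:3, 3),
                      dbp_night = rep(c(60, 70, 65), each = 3))
  expect_equal(adaptation_test(const, "dbp_night")$F, 0)
})
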