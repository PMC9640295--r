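small_spec <- function(...) cohort_spec(n_per_study = c(CRESSIDA = 15L,
                                                        MARINA = 10L), ...)

test_that("the generator is deterministic under a fixed seed", {
  a <- simulate_cohort(small_spec(), seed = 101, readings = TRUE)
  b <- simulate_cohort(small_spec(), seed = 101, readings = TRUE)
  expect_identical(a$individuals, b$individuals)
  expect_identical(a$sessions, b$sessions)
  expect_identical(a$readings, b$readings)
  c <- simulate_cohort(small_spec(), seed = 102)
  expect_false(identical(a$sessions$sbp_day, c$sessions$sbp_day))
})

test_that("session draws are unchanged when readings are also requested", {
  a <- simulate_cohort(small_spec(), seed = 103, readings = FALSE)
  b <- simulate_cohort(small_spec(), seed = 103, readings = TRUE)
  expect_identical(a$sessions, b$sessions)
})

test_that("visit counts and spacing follow the study templates", {
  co <- simulate_cohort(seed = 104)
  counts <- table(co$sessions$individual_id)
  ind <- co$individuals
  expect_true(all(counts[ind$individual_id[ind$study == "CRESSIDA"]] == 5))
  expect_true(all(counts[ind$individual_id[ind$study == "FruitVeg"]] == 5))
  expect_true(all(counts[ind$individual_id[ind$study == "MARINA"]] == 3))
  expect_equal(nrow(ind), 501L)
  expect_equal(nrow(co$sessions), 159L * 5 + 48L * 5 + 294L * 3)
  # PWV measured once per visit, blank beyond the study's schedule
  expect_true(all(!is.na(ind$pwv_v5[ind$study == "CRESSIDA"])))
  expect_true(all(is.na(ind$pwv_v4[ind$study == "MARINA"])))
})

test_that("zero within-individual noise reproduces the true means exactly", {
  m <- get("AMBULATORY_MARGINALS", envir = asNamespace("abpmvar"))
  m$cov <- rep(0, nrow(m))
  spec <- cohort_spec(n_per_study = c(MARINA = 8L), marginals = m)
  co <- simulate_cohort(spec, seed = 105)
  truth <- co$truth[match(co$sessions$individual_id, co$truth$individual_id), ]
  for (p in c("sbp_day", "sbp_night", "dbp_night", "hr_day")) {
    expect_equal(co$sessions[[p]], truth[[p]], tolerance = 1e-12)
  }
})

test_that("session values follow exp(mu + sigma_w eps) against replayed draws", {
  spec <- cohort_spec(n_per_study = c(MARINA = 2L))
  gi <- generate_individuals(spec, seed = 106)
  sessions <- generate_sessions(gi, spec, seed = 106)
  # replay: same substream, same draw order as the generator
  set.seed(abpmvar:::substream_seed(106, "sessions"))
  comp <- abpmvar:::log_scale_components(spec)
  n_sess <- nrow(sessions)
  replay <- exp(log(rep(gi$truth$sbp_day, each = 3)) +
                  comp["sbp_day", "sigma_w"] * rnorm(n_sess))
  expect_equal(sessions$sbp_day, replay, tolerance = 1e-12)
})

test_that("scaling every true mean leaves the estimated CoV unchanged", {
  m <- get("AMBULATORY_MARGINALS", envir = asNamespace("abpmvar"))
  m2 <- m; m2$mean <- m$mean * 3; m2$sd <- m$sd * 3
  co1 <- simulate_cohort(cohort_spec(n_per_study = c(MARINA = 150L),
                                     marginals = m), seed = 107)
  co2 <- simulate_cohort(cohort_spec(n_per_study = c(MARINA = 150L),
                                     marginals = m2), seed = 107)
  c1 <- cov_within(co1$sessions$sbp_day, co1$sessions$individual_id)
  c2 <- cov_within(co2$sessions$sbp_day, co2$sessions$individual_id)
  expect_equal(c1$cov_pct, c2$cov_pct, tolerance = 1e-10)
})

test_that("zeroed correlation targets produce uncorrelated latents", {
  spec <- cohort_spec(n_per_study = c(MARINA = 5000L), corr = diag(9))
  gi <- generate_individuals(spec, seed = 108)
  tr <- gi$truth
  pairs <- list(c("pwv", "sbp_day"), c("pwv", "dbp_night"),
                c("sbp_day", "dbp_day"), c("sbp_day", "sbp_night"))
  for (pr in pairs) {
    expect_lt(abs(cor(tr[[pr[1]]], tr[[pr[2]]])), 0.04)
  }
  expect_lt(abs(cor(gi$individuals$age, tr$sbp_day)), 0.04)
  expect_lt(abs(cor(gi$individuals$bmi, tr$sbp_night)), 0.04)
})

test_that("a non-positive-definite correlation target names the offending pair", {
  R <- default_correlations()
  R["age", "pwv"] <- R["pwv", "age"] <- 0.99
  R["age", "bmi"] <- R["bmi", "age"] <- -0.99
  R["bmi", "pwv"] <- R["pwv", "bmi"] <- 0.99
  expect_error(cohort_spec(corr = R), "positive definite")
})

test_that("recovered within-individual CoV hits the generating target", {
  spec <- cohort_spec()
  co <- simulate_cohort(spec, seed = 109)
  cw <- cov_within(co$sessions$sbp_night, co$sessions$individual_id)
  expect_gt(cw$cov_pct, 6.5)
  expect_lt(cw$cov_pct, 7.5)
})

test_that("noise-free readings recover the latent day mean almost exactly", {
  spec <- cohort_spec(n_per_study = c(MARINA = 3L),
                      reading_noise = c(sbp = 0, dbp = 0, hr = 0),
                      p_missing = 0)
  co <- simulate_cohort(spec, seed = 110, readings = TRUE)
  sm <- summarize_sessions(co$readings, co$diary,
                           validity_rules(min_day = 1, min_night = 1))
  m <- merge(co$sessions, sm, by = c("individual_id", "session_id"))
  expect_lt(max(abs(m$sbp_day.x - m$sbp_day.y)), 0.01)
  expect_lt(max(abs(m$sbp_night.x - m$sbp_night.y)), 0.01)
})

test_that("the device schedule yields about 30 day-cadence slots per session", {
  spec <- cohort_spec(n_per_study = c(MARINA = 10L), p_missing = 0)
  co <- simulate_cohort(spec, seed = 111, readings = TRUE)
  per_session <- table(co$readings$session_id)
  expect_true(all(per_session == 39))  # 30 half-hourly day + 9 hourly night
  spec2 <- cohort_spec(n_per_study = c(MARINA = 30L))  # default 8% missing
  co2 <- simulate_cohort(spec2, seed = 112, readings = TRUE)
  mean_n <- mean(table(co2$readings$session_id))
  expect_equal(mean_n, 39 * 0.92, tolerance = 0.05)
})

test_that("recovered day means track latents within reading noise at scale", {
  spec <- cohort_spec(n_per_study = c(CRESSIDA = 40L))  # 200 sessions
  co <- simulate_cohort(spec, seed = 113, readings = TRUE)
  sm <- summarize_sessions(co$readings, co$diary, validity_rules(min_day = 5,
                                                                 min_night = 3))
  m <- merge(co$sessions, sm, by = c("individual_id", "session_id"))
  expect_lt(mean(abs(m$sbp_day.x - m$sbp_day.y)), 2)
})

test_that("an invalid cadence is rejected", {
  expect_error(cohort_spec(night_step_min = 0.5), "night_step_min")
})
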