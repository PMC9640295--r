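# Independent brute-force oracles, written as plain loops so they share no
# code path with the implementations they check.

brute_pooled_within_var <- function(values, id) {
  x <- log(values)
  total_ss <- 0
  total_df <- 0
  for (i in unique(id)) {
    xi <- x[id == i]
    if (length(xi) < 2) next
    m <- mean(xi)
    for (v in xi) total_ss <- total_ss + (v - m)^2
    total_df <- total_df + length(xi) - 1
  }
  total_ss / total_df
}

brute_rm_anova <- function(mat) {
  n <- nrow(mat); t <- ncol(mat)
  grand <- mean(mat)
  ss_subj <- 0; ss_time <- 0; ss_total <- 0
  for (i in seq_len(n)) ss_subj <- ss_subj + t * (mean(mat[i, ]) - grand)^2
  for (j in seq_len(t)) ss_time <- ss_time + n * (mean(mat[, j]) - grand)^2
  for (i in seq_len(n)) for (j in seq_len(t)) {
    ss_total <- ss_total + (mat[i, j] - grand)^2
  }
  ss_res <- ss_total - ss_subj - ss_time
  f <- (ss_time / (t - 1)) / (ss_res / ((t - 1) * (n - 1)))
  list(F = f, ss_time = ss_time, ss_res = ss_res)
}

brute_fleiss_kappa <- function(ratings) {
  cats <- sort(unique(as.vector(ratings)))
  N <- nrow(ratings); n <- ncol(ratings)
  counts <- matrix(0, N, length(cats))
  for (i in seq_len(N)) for (j in seq_len(n)) {
    k <- match(ratings[i, j], cats)
    counts[i, k] <- counts[i, k] + 1
  }
  p_j <- colSums(counts) / (N * n)
  P_i <- numeric(N)
  for (i in seq_len(N)) P_i[i] <- (sum(counts[i, ]^2) - n) / (n * (n - 1))
  (mean(P_i) - sum(p_j^2)) / (1 - sum(p_j^2))
}

brute_ols_coef <- function(y, X) {
  X1 <- cbind(1, X)
  solve(t(X1) %*% X1, t(X1) %*% y)[-1, 1]
}

# Small lognormal repeated-measures sample: n individuals, m sessions each,
# generating within-individual CoV in percent.
sim_repeated <- function(n, m, cov_pct, mean_level = 130, between_sd = 12,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sw <- sqrt(log(1 + (cov_pct / 100)^2))
  mu <- log(mean_level) + stats::rnorm(n, 0, between_sd / mean_level)
  values <- exp(rep(mu, each = m) + sw * stats::rnorm(n * m))
  list(values = values, id = rep(seq_len(n), each = m))
}

# Readings fixture: a session of explicit timestamps and values. Times given
# as "HH:MM" on `date` or, prefixed "+", on the following day.
make_readings <- function(times, sbp, dbp = NULL, hr = NULL,
                          date = "2020-03-02") {
  nextday <- startsWith(times, "+")
  times <- sub("^\\+", "", times)
  ts <- as.POSIXct(paste(date, times), tz = "UTC") + nextday * 86400
  data.frame(
    individual_id = "X1", session_id = "X1-S1",
    timestamp = ts,
    sbp = sbp,
    dbp = dbp %||% (sbp - 50),
    hr = hr %||% rep(70, length(ts))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
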