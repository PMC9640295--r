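# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a percent coefficient of variation to a log-scale SD
#'
#' Under a multiplicative (lognormal) error model a within-individual
#' coefficient of variation CoV (as a fraction) corresponds to a standard
#' deviation on the natural-log scale of `sqrt(log(1 + CoV^2))`. These two
#' helpers move between the percent CoV used in reports and the log-scale
#' sigma used by the simulator and estimator.
#'
#' @param cov_pct coefficient of variation in percent (e.g. 5.4).
#' @return `sigma_w_from_cov()`: SD on the natural-log scale.
#' @examples
#' sigma_w_from_cov(5.4)
#' cov_from_sigma_w(sigma_w_from_cov(5.4))
#' @export
sigma_w_from_cov <- function(cov_pct) {
  stopifnot(is.numeric(cov_pct), all(cov_pct >= 0))
  sqrt(log(1 + (cov_pct / 100)^2))
}

#' @rdname sigma_w_from_cov
#' @param sigma_w SD on the natural-log scale.
#' @return `cov_from_sigma_w()`: coefficient of variation in percent.
#' @export
cov_from_sigma_w <- function(sigma_w) {
  stopifnot(is.numeric(sigma_w), all(sigma_w >= 0))
  100 * sqrt(exp(sigma_w^2) - 1)
}

# Deterministic per-stage sub-seed derived from a root seed and a stage name,
# so adding a stage never perturbs the draws of earlier stages. Kept below
# 2^31 - 1 (R integers are 32-bit).
substream_seed <- function(seed, name) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 2654435761) %% 1e9
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483629L)
}

# "5.4 (5.2-5.6)" with an en dash, the house style of CoV tables.
fmt_cov_ci <- function(cov, lo, hi, digits = 1L) {
  sprintf("%.*f (%.*f–%.*f)", digits, cov, digits, lo, digits, hi)
}

# "125-155" with an en dash, integer mmHg.
fmt_range <- function(lo, hi) {
  sprintf("%d–%d", as.integer(round(lo)), as.integer(round(hi)))
}

# Draws from a multivariate normal via the Cholesky factor; deterministic
# given the RNG state. mu: length-p, sd: length-p, R: p x p correlation.
rmvn_corr <- function(n, mu, sd, R) {
  p <- length(mu)
  stopifnot(nrow(R) == p, ncol(R) == p, length(sd) == p)
  L <- tryCatch(chol(R), error = function(e) {
    stop("correlation target matrix is not positive definite", call. = FALSE)
  })
  z <- matrix(stats::rnorm(n * p), n, p) %*% L
  sweep(sweep(z, 2L, sd, `*`), 2L, mu, `+`)
}
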