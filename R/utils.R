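# Internal numerical helpers shared across modules.

logit <- function(p) log(p / (1 - p))

inv_logit <- function(x) 1 / (1 + exp(-x))

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_pd <- function(m, tol = 1e-10) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  all(ev > tol * max(abs(ev), 1))
}

is_psd <- function(m, tol = 1e-8) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  all(ev > -tol * max(abs(ev), 1))
}

symmetrize <- function(m) (m + t(m)) / 2

# Draw n MVN deviates; thin wrapper so all modules share one code path.
rmvn <- function(n, mu, sigma) {
  MASS::mvrnorm(n = n, mu = mu, Sigma = sigma)
}

# Effective sample size from the initial positive sequence of autocorrelations
# (Geyer-style truncation on a single chain).
ess <- function(x) {
  n <- length(x)
  if (n < 4 || stats::var(x) == 0) return(n)
  acf_x <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  k <- 1
  while (k <= length(acf_x) - 1) {
    pair <- acf_x[k] + acf_x[k + 1]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2
  }
  max(1, n / (1 + 2 * s))
}

# Split-chain potential scale reduction factor on one chain (split in halves).
split_rhat <- function(x) {
  n <- length(x)
  if (n < 8) return(NA_real_)
  half <- floor(n / 2)
  chains <- cbind(x[seq_len(half)], x[(n - half + 1):n])
  m <- ncol(chains)
  w <- mean(apply(chains, 2, stats::var))
  if (w == 0) return(1)
  b <- half * stats::var(colMeans(chains))
  v <- (half - 1) / half * w + b / half
  sqrt(v / w)
}

# Stable log(1 - (1 - m)^dt) for interval death probabilities.
log_interval_death <- function(log_surv_annual, interval) {
  log1p(-exp(interval * log_surv_annual))
}
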