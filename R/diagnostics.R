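# Native MCMC diagnostics: autocorrelation, ESS (Geyer initial positive
# sequence), split-chain Gelman-Rubin R-hat, Geweke z.

#' Lag-k autocorrelation of a chain
#' @param x numeric vector of draws.
#' @param lag non-negative integer lag.
#' @export
autocorr <- function(x, lag = 1) {
  n <- length(x)
  if (lag == 0) return(1)
  if (lag >= n) return(0)
  x <- x - mean(x)
  v <- sum(x^2) / n
  if (v == 0) return(0)
  sum(x[1:(n - lag)] * x[(lag + 1):n]) / n / v
}

#' Effective sample size
#'
#' Geyer's initial positive-sequence estimator: sums of adjacent
#' autocorrelation pairs are accumulated while positive;
#' `ESS = n / (1 + 2 sum rho_k)`.
#'
#' @param x numeric vector of draws.
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 4 || stats::var(x) == 0) return(n)
  rho <- vapply(seq_len(min(n - 2, 2000)), function(k) autocorr(x, k), 0)
  s <- 0
  for (k in seq(1, length(rho) - 1, by = 2)) {
    pair <- rho[k] + rho[k + 1]
    if (pair <= 0) break
    s <- s + pair
  }
  max(1, min(n, n / (1 + 2 * s)))
}

#' Split-chain Gelman-Rubin statistic
#'
#' Each chain is split in half; R-hat is the classic ratio of pooled to
#' within-chain variance estimates.
#'
#' @param chains list of numeric vectors (>= 1 chain; each split in two).
#' @export
rhat <- function(chains) {
  if (!is.list(chains)) chains <- list(chains)
  halves <- unlist(lapply(chains, function(x) {
    m <- length(x) %/% 2
    list(x[1:m], x[(m + 1):(2 * m)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Geweke convergence z-score
#'
#' Compares the means of the first `frac1` and last `frac2` fractions of a
#' chain, with spectral-density-at-zero variances estimated by batch means.
#'
#' @param x numeric vector of draws.
#' @param frac1,frac2 fractions of the chain compared (defaults 0.1, 0.5).
#' @export
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  a <- x[seq_len(max(2, floor(frac1 * n)))]
  b <- x[seq(n - max(2, floor(frac2 * n)) + 1, n)]
  bm_var <- function(z) {
    nb <- max(2, floor(sqrt(length(z))))
    bs <- length(z) %/% nb
    if (bs < 1) return(stats::var(z) / length(z))
    means <- vapply(seq_len(nb), function(i) mean(z[((i - 1) * bs + 1):(i * bs)]), 0)
    stats::var(means) / nb
  }
  den <- bm_var(a) + bm_var(b)
  if (den == 0) return(0)
  (mean(a) - mean(b)) / sqrt(den)
}
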