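# Log-density building blocks shared by log_posterior() and the sampler.

# Multivariate normal log-density via the Cholesky factor.
ldmvnorm <- function(x, mean, Sigma) {
  L <- chol(Sigma)
  z <- backsolve(L, x - mean, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z^2)
}

# Log multivariate gamma function.
lmvgamma <- function(p, a) {
  0.25 * p * (p - 1) * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

# Inverse-Wishart log-density with scale matrix S0 and degrees of freedom nu.
ldinvwish <- function(Sigma, S0, nu) {
  p <- nrow(Sigma)
  L <- chol(Sigma)
  ldetS <- 2 * sum(log(diag(L)))
  ldetS0 <- 2 * sum(log(diag(chol(S0))))
  Sinv <- chol2inv(L)
  0.5 * nu * ldetS0 - 0.5 * nu * p * log(2) - lmvgamma(p, nu / 2) -
    0.5 * (nu + p + 1) * ldetS - 0.5 * sum(diag(S0 %*% Sinv))
}

# Truncated-normal log-density on (lo, hi), including the normalizer.
ldtnorm <- function(x, mean, sd, lo = -1, hi = 1) {
  if (x <= lo || x >= hi) return(-Inf)
  dnorm(x, mean, sd, log = TRUE) -
    log(pnorm(hi, mean, sd) - pnorm(lo, mean, sd))
}

#' Joint log-posterior density of the stream-temperature model
#'
#' Sum of (a) the normal log-likelihood of every observed water temperature
#' at its conditional mean with residual sd; (b) the truncated-normal
#' log-density (including the truncation normalizer) of each site AR(1)
#' coefficient; (c) the multivariate-normal log-density of each year's
#' coefficient row at the hyper-mean and covariance; and (d) the hyperprior
#' log-densities: `N(0, 100)` for the intercept, the fixed effects and the
#' free elements of the hyper-mean, `U(-1, 1)` for `mu_delta`, `U(0, 2)` for
#' `sd_delta`, `U(0, 10)` for `sd`, and inverse-Wishart(identity, l + 1) for
#' `Sigma`.  Parameters outside the prior support give `-Inf`.
#'
#' This is the stationary density targeted by [fit_stream_model()].
#'
#' @inheritParams linear_predictor
#' @return A single log-density value (up to no additional constant).
#' @export
log_posterior <- function(params, design) {
  p <- params
  l <- design$meta$l
  n_site <- length(design$meta$site_levels)
  if (length(p$delta) < n_site) stop("need one delta per site")
  if (any(abs(p$delta) >= 1) || p$sd <= 0 || p$sd >= 10 ||
      p$sd_delta <= 0 || p$sd_delta >= 2 || abs(p$mu_delta) >= 1)
    return(-Inf)
  if (l > 0) {
    ev <- eigen(p$Sigma, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) return(-Inf)
  }
  mu <- conditional_mean(p, design)
  ll <- sum(dnorm(design$y, mu, p$sd, log = TRUE))
  ld <- sum(vapply(seq_len(n_site), function(s)
    ldtnorm(p$delta[s], p$mu_delta, p$sd_delta), numeric(1)))
  lB <- 0
  if (l > 0) {
    for (y in seq_along(design$meta$year_levels))
      lB <- lB + ldmvnorm(p$B[y, seq_len(l)], p$M[seq_len(l)],
                          p$Sigma[seq_len(l), seq_len(l), drop = FALSE])
    lB <- lB + ldinvwish(p$Sigma, diag(l), l + 1)
    if (l > 1)
      lB <- lB + sum(dnorm(p$M[2:l], 0, 10, log = TRUE))
  }
  lprior <- dnorm(p$alpha, 0, 10, log = TRUE) +
    sum(dnorm(p$beta, 0, 10, log = TRUE)) +
    log(1 / 2) +        # mu_delta ~ U(-1, 1)
    log(1 / 2) +        # sd_delta ~ U(0, 2)
    log(1 / 10)         # sd ~ U(0, 10)
  ll + ld + lB + lprior
}
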