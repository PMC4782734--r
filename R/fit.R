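#' MCMC settings
#'
#' Defaults mirror the full analysis (3 chains, 1,000 burn-in, 2,500
#' evaluation iterations thinned to every 5th); [mcmc_control_small()] is the
#' scaled-down configuration used by the refit-heavy experiment batteries
#' (2 chains, 500 retained draws each).
#'
#' @param chains Number of chains.
#' @param burnin Burn-in iterations per chain (discarded).
#' @param iter Evaluation iterations per chain.
#' @param thin Keep every `thin`-th evaluation iteration.
#' @return A list of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 3, burnin = 1000, iter = 2500, thin = 5) {
  stopifnot(chains >= 1, burnin >= 0, iter >= thin, thin >= 1)
  structure(list(chains = chains, burnin = burnin, iter = iter, thin = thin),
            class = "mcmc_control")
}

#' @rdname mcmc_control
#' @export
mcmc_control_small <- function(chains = 2, burnin = 300, iter = 1000, thin = 2) {
  mcmc_control(chains, burnin, iter, thin)
}

# Draw from N(mean, sd) truncated to (lo, hi) by inverse-CDF.
rtnorm1 <- function(mean, sd, lo = -1, hi = 1) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  if (phi - plo < 1e-12) return(min(max(mean, lo + 1e-9), hi - 1e-9))
  qnorm(runif(1, plo, phi), mean, sd)
}

#' Fit the hierarchical stream-temperature model by blocked Gibbs sampling
#'
#' Samples the posterior defined by [log_posterior()] with a blocked
#' Metropolis-within-Gibbs scheme chosen for this model's structure:
#'
#' * all regression coefficients (intercept, fixed effects and every year's
#'   cubic coefficients) are drawn jointly from their exact multivariate
#'   normal full conditional, after absorbing the AR(1) term into a
#'   generalized-least-squares transform of each row (`x_i - delta_s
#'   x_{i-1}`, `t_i - delta_s t_{i-1}`); per-site cross-products are
#'   precomputed once so each iteration is quadratic in the parameter count,
#'   not the row count;
#' * each site's `delta_s` has a conjugate truncated-normal full conditional;
#' * the residual precision has a truncated-Gamma full conditional implied by
#'   the uniform prior on `sd`;
#' * the year-level hyper-mean and covariance have conjugate normal and
#'   inverse-Wishart full conditionals;
#' * `mu_delta` and `sd_delta`, whose truncation normalizers break
#'   conjugacy, use random-walk Metropolis steps.
#'
#' Identical seed and settings give bit-identical samples.
#'
#' @param design A [build_design()] result (observed responses only).
#' @param mcmc An [mcmc_control()] list.
#' @param seed Integer seed; chains use deterministic child seeds.
#' @param control Optional list: `fix_delta` (fix all AR coefficients at a
#'   value, skipping their updates), `fix_sd` (fix the residual sd),
#'   `prop_mu_delta` (random-walk proposal sd for the AR hyper-mean,
#'   default 0.1), `prop_sd_delta` (log-scale proposal sd for the AR
#'   hyper-sd, default 0.5).
#' @return An object of class `stream_fit`: retained samples per chain
#'   (matrices with named columns), split of the parameter vector, R-hat per
#'   parameter, the design (without its response being modified) and the
#'   settings.
#' @seealso [posterior_summary()], [predict.stream_fit()], [cubic_curves()]
#' @export
fit_stream_model <- function(design, mcmc = mcmc_control(), seed = 1,
                             control = list()) {
  stopifnot(inherits(design, "stream_design"))
  if (anyNA(design$y))
    stop("the fitting design must not contain missing responses")
  y <- design$y
  n <- length(y)
  kf <- design$meta$kf
  l <- design$meta$l
  Y <- length(design$meta$year_levels)
  n_site <- length(design$meta$site_levels)
  pg <- 1L + kf
  p <- pg + Y * l

  W <- matrix(0, n, p)
  W[, 1] <- 1
  W[, 1 + seq_len(kf)] <- design$Xf
  if (l > 0) {
    for (j in seq_len(l))
      W[cbind(seq_len(n), pg + (design$year_idx - 1L) * l + j)] <- design$Z[, j]
  }

  Nset <- which(!design$prev_avail)
  XtX_N <- crossprod(W[Nset, , drop = FALSE])
  Xty_N <- crossprod(W[Nset, , drop = FALSE], y[Nset])
  site_pre <- lapply(seq_len(n_site), function(s) {
    R <- which(design$prev_avail & design$site_idx == s)
    P <- design$prev_idx[R]
    WR <- W[R, , drop = FALSE]; WP <- W[P, , drop = FALSE]
    list(R = R, P = P,
         A = crossprod(WR), Bm = crossprod(WR, WP), C = crossprod(WP),
         va = crossprod(WR, y[R]), vb = crossprod(WR, y[P]),
         vc = crossprod(WP, y[R]), vd = crossprod(WP, y[P]))
  })

  fix_delta <- control$fix_delta
  fix_sd <- control$fix_sd
  prop_mu <- control$prop_mu_delta %||% 0.1
  prop_sd <- control$prop_sd_delta %||% 0.5
  prior_prec_fixef <- 1 / 100   # N(0, 100) on intercept and fixed effects

  n_keep <- floor(mcmc$iter / mcmc$thin)
  par_names <- c("alpha",
                 if (kf > 0) paste0("beta[", seq_len(kf), "]"),
                 if (l > 0) as.vector(t(outer(design$meta$year_levels,
                                              seq_len(l),
                                              function(a, b) paste0("B[", a, ",", b, "]")))),
                 if (l > 1) paste0("M[", 2:l, "]"),
                 if (l > 0) {
                   ut <- which(upper.tri(diag(l), diag = TRUE), arr.ind = TRUE)
                   paste0("Sigma[", ut[, 1], ",", ut[, 2], "]")
                 },
                 paste0("delta[", seq_len(n_site), "]"),
                 "mu_delta", "sd_delta", "sd")

  run_chain <- function(chain) {
    set.seed(child_seed(seed, "chain", chain))
    # overdispersed starts inside the prior support
    theta <- c(mean(y) + rnorm(1, 0, 1), rnorm(kf, 0, 0.3),
               if (l > 0) rnorm(Y * l, 0, 0.3))
    delta <- if (is.null(fix_delta)) rep(runif(1, -0.3, 0.9), n_site)
             else rep_len(fix_delta, n_site)
    sdres <- if (is.null(fix_sd)) runif(1, 0.4, 2) else fix_sd
    mu_delta <- if (is.null(fix_delta)) runif(1, -0.3, 0.9) else 0
    sd_delta <- if (is.null(fix_delta)) runif(1, 0.05, 0.5) else 0.1
    M <- if (l > 0) c(0, rnorm(l - 1, 0, 0.3)) else numeric(0)
    Sigma <- if (l > 0) diag(l) * runif(1, 0.3, 1.5) else NULL

    out <- matrix(NA_real_, n_keep, length(par_names),
                  dimnames = list(NULL, par_names))
    keep_i <- 0L
    total <- mcmc$burnin + mcmc$iter
    for (it in seq_len(total)) {
      ## -- joint draw of all regression coefficients -------------------
      XtX <- XtX_N
      Xty <- Xty_N
      for (s in seq_len(n_site)) {
        sp <- site_pre[[s]]
        if (length(sp$R) == 0) next
        ds <- delta[s]
        XtX <- XtX + sp$A - ds * (sp$Bm + t(sp$Bm)) + ds^2 * sp$C
        Xty <- Xty + sp$va - ds * (sp$vb + sp$vc) + ds^2 * sp$vd
      }
      prec <- XtX / sdres^2
      b <- Xty / sdres^2
      diag(prec)[seq_len(pg)] <- diag(prec)[seq_len(pg)] + prior_prec_fixef
      if (l > 0) {
        Om <- chol2inv(chol(Sigma))
        OmM <- Om %*% M
        for (yy in seq_len(Y)) {
          idx <- pg + (yy - 1L) * l + seq_len(l)
          prec[idx, idx] <- prec[idx, idx] + Om
          b[idx] <- b[idx] + OmM
        }
      }
      Lq <- chol(prec)
      mu_t <- backsolve(Lq, backsolve(Lq, b, transpose = TRUE))
      theta <- as.numeric(mu_t + backsolve(Lq, rnorm(p)))

      omega <- as.numeric(W %*% theta)
      e <- y - omega

      ## -- AR coefficients ---------------------------------------------
      if (is.null(fix_delta)) {
        for (s in seq_len(n_site)) {
          sp <- site_pre[[s]]
          if (length(sp$R) == 0) {
            delta[s] <- rtnorm1(mu_delta, sd_delta)
            next
          }
          ep <- e[sp$P]; ei <- e[sp$R]
          prec_d <- sum(ep^2) / sdres^2 + 1 / sd_delta^2
          mean_d <- (sum(ei * ep) / sdres^2 + mu_delta / sd_delta^2) / prec_d
          delta[s] <- rtnorm1(mean_d, sqrt(1 / prec_d))
        }
      }

      ## -- residual sd --------------------------------------------------
      SS <- sum(e[Nset]^2)
      for (s in seq_len(n_site)) {
        sp <- site_pre[[s]]
        if (length(sp$R))
          SS <- SS + sum((e[sp$R] - delta[s] * e[sp$P])^2)
      }
      if (is.null(fix_sd)) {
        shape <- (n - 1) / 2
        lo <- pgamma(1 / 100, shape, rate = SS / 2)
        phi <- qgamma(runif(1, lo, 1), shape, rate = SS / 2)
        sdres <- 1 / sqrt(phi)
      }

      ## -- AR hyperparameters -------------------------------------------
      # Their 2-D conditional is cheap (a handful of density evaluations),
      # so several Metropolis sweeps per Gibbs iteration keep this block
      # from throttling the chain; sd_delta walks on the log scale, which
      # handles the funnel at small hyper-sd.
      if (is.null(fix_delta)) {
        ltarget <- function(m, s2) {
          if (abs(m) >= 1 || s2 <= 0 || s2 >= 2) return(-Inf)
          sum(vapply(delta, function(d) ldtnorm(d, m, s2), numeric(1)))
        }
        cur <- ltarget(mu_delta, sd_delta)
        for (sweep in 1:10) {
          profm <- mu_delta + rnorm(1, 0, prop_mu)
          lp <- ltarget(profm, sd_delta)
          if (log(runif(1)) < lp - cur) { mu_delta <- profm; cur <- lp }
          profs <- sd_delta * exp(rnorm(1, 0, prop_sd))
          lp <- ltarget(mu_delta, profs)
          if (log(runif(1)) < lp - cur + log(profs / sd_delta)) {
            sd_delta <- profs; cur <- lp
          }
        }
      }

      ## -- year-level hyper-mean and covariance -------------------------
      if (l > 0) {
        Bmat <- matrix(theta[pg + seq_len(Y * l)], Y, l, byrow = TRUE)
        Om <- chol2inv(chol(Sigma))
        if (l > 1) {
          f <- 2:l
          precM <- Y * Om[f, f, drop = FALSE] + diag(1 / 100, l - 1)
          bM <- rowSums(Om %*% t(Bmat))[f]
          Lm <- chol(precM)
          mM <- backsolve(Lm, backsolve(Lm, bM, transpose = TRUE))
          M <- c(0, as.numeric(mM + backsolve(Lm, rnorm(l - 1))))
        }
        SSB <- crossprod(sweep(Bmat, 2, M))
        OmD <- rWishart(1, l + 1 + Y, chol2inv(chol(diag(l) + SSB)))[, , 1]
        Sigma <- chol2inv(chol(OmD))
      }

      ## -- store --------------------------------------------------------
      if (it > mcmc$burnin && (it - mcmc$burnin) %% mcmc$thin == 0) {
        keep_i <- keep_i + 1L
        row <- c(theta[seq_len(pg)],
                 if (l > 0) theta[pg + seq_len(Y * l)],
                 if (l > 1) M[2:l],
                 if (l > 0) Sigma[upper.tri(Sigma, diag = TRUE)],
                 delta, mu_delta, sd_delta, sdres)
        out[keep_i, ] <- row
      }
    }
    out
  }

  samples <- lapply(seq_len(mcmc$chains), run_chain)
  rh <- rhat_chains(samples)
  structure(list(samples = samples, par_names = par_names,
                 design = design, mcmc = mcmc, seed = seed,
                 control = control, rhat = rh),
            class = "stream_fit")
}

# Gelman-Rubin potential scale reduction from a list of chain matrices.
rhat_chains <- function(chains) {
  m <- length(chains)
  n <- nrow(chains[[1]])
  cols <- colnames(chains[[1]])
  vapply(seq_along(cols), function(j) {
    x <- vapply(chains, function(ch) ch[, j], numeric(n))
    if (m < 2 || n < 2) return(NA_real_)
    means <- colMeans(x)
    vars <- apply(x, 2, var)
    Wv <- mean(vars)
    if (Wv == 0) return(NA_real_)
    Bv <- n * var(means)
    sqrt(((n - 1) / n * Wv + Bv / n) / Wv)
  }, numeric(1), USE.NAMES = FALSE) -> out
  names(out) <- cols
  out
}

#' Potential scale reduction factor (Gelman-Rubin R-hat)
#'
#' Between/within-chain variance ratio for each retained scalar:
#' `sqrt(((n-1)/n * W + B/n) / W)` over `m` chains of `n` retained draws.
#' Values near 1 indicate convergence; the full analysis requires all
#' values < 1.01.  Parameters with zero within-chain variance (e.g. fixed by
#' `control`) are `NA`.
#'
#' @param fit A `stream_fit` object (or a list of chain matrices).
#' @param parameter Optional parameter name(s).
#' @return Named numeric vector of R-hat values.
#' @export
rhat <- function(fit, parameter = NULL) {
  rh <- if (inherits(fit, "stream_fit")) fit$rhat else rhat_chains(fit)
  if (is.null(parameter)) rh else rh[parameter]
}

#' @export
as.matrix.stream_fit <- function(x, ...) do.call(rbind, x$samples)

#' Posterior summary table
#'
#' Mean, sd, central quantiles and R-hat for every retained scalar.
#'
#' @param fit A `stream_fit`.
#' @param probs Quantiles to report.
#' @return Data frame with one row per parameter.
#' @export
posterior_summary <- function(fit, probs = c(0.025, 0.5, 0.975)) {
  sm <- as.matrix(fit)
  qs <- t(apply(sm, 2, quantile, probs = probs))
  colnames(qs) <- paste0("q", probs * 100)
  data.frame(parameter = colnames(sm), mean = colMeans(sm),
             sd = apply(sm, 2, sd), qs, rhat = fit$rhat[colnames(sm)],
             row.names = NULL)
}

#' @export
print.stream_fit <- function(x, ...) {
  cat("Hierarchical stream-temperature model fit\n")
  cat("  rows:", length(x$design$y),
      " sites:", length(x$design$meta$site_levels),
      " years:", length(x$design$meta$year_levels), "\n")
  cat("  chains:", x$mcmc$chains, " burn-in:", x$mcmc$burnin,
      " iterations:", x$mcmc$iter, " thin:", x$mcmc$thin, "\n")
  rh <- x$rhat[!is.na(x$rhat)]
  cat("  max R-hat:", format(max(rh), digits = 4),
      if (max(rh) < 1.01) "(converged at the < 1.01 criterion)" else "", "\n")
  invisible(x)
}

#' @export
summary.stream_fit <- function(object, ...) {
  s <- posterior_summary(object)
  key <- c("alpha", paste0("beta[", seq_len(min(5, object$design$meta$kf)), "]"),
           "mu_delta", "sd")
  print(object)
  cat("\nKey parameters:\n")
  print(s[s$parameter %in% key, ], digits = 3, row.names = FALSE)
  invisible(s)
}

#' Posterior means as a parameter object
#'
#' @param object A `stream_fit`.
#' @param ... Unused.
#' @return A [stream_params] object at the posterior means.
#' @export
coef.stream_fit <- function(object, ...) {
  sm <- colMeans(as.matrix(object))
  meta <- object$design$meta
  kf <- meta$kf; l <- meta$l
  Yl <- meta$year_levels
  B <- matrix(0, length(Yl), max(l, 1))
  if (l > 0)
    for (y in seq_along(Yl)) for (j in seq_len(l))
      B[y, j] <- sm[paste0("B[", Yl[y], ",", j, "]")]
  Sigma <- diag(max(l, 1))
  if (l > 0) {
    ut <- which(upper.tri(diag(l), diag = TRUE), arr.ind = TRUE)
    for (k in seq_len(nrow(ut))) {
      v <- sm[paste0("Sigma[", ut[k, 1], ",", ut[k, 2], "]")]
      Sigma[ut[k, 1], ut[k, 2]] <- v
      Sigma[ut[k, 2], ut[k, 1]] <- v
    }
  }
  M <- numeric(max(l, 1))
  if (l > 1) for (j in 2:l) M[j] <- sm[paste0("M[", j, "]")]
  stream_params(alpha = sm["alpha"],
                beta = if (kf > 0) sm[paste0("beta[", seq_len(kf), "]")] else numeric(0),
                B = B, M = M, Sigma = Sigma,
                delta = sm[paste0("delta[", seq_along(meta$site_levels), "]")],
                mu_delta = min(max(sm["mu_delta"], -0.999), 0.999),
                sd_delta = min(max(sm["sd_delta"], 1e-6), 1.999),
                sd = sm["sd"])
}
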