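test_that("design rows, lags and AR availability follow the contiguity rules", {
  d <- toy_canonical(100:102)
  w <- data.frame(site = "s1", year = 2005, spring_day = 100, fall_day = 102)
  des <- build_design(d, w)
  expect_equal(length(des$y), 3)
  expect_equal(des$prev_avail, c(FALSE, TRUE, TRUE))
  expect_equal(des$t_prev[2:3], des$y[1:2])

  d2 <- d; d2$waterT[d2$doy == 101] <- NA
  des2 <- build_design(d2, w)
  expect_equal(length(des2$y), 2)
  expect_equal(des2$prev_avail, c(FALSE, FALSE))

  # air lags come from the year-round series even before the window
  std <- des$meta$standardization
  expect_equal(unname(des$Xf[1, "air_lag1"]) * std$air_scale + std$air_center,
               d$airT[99], tolerance = 1e-6)

  # raw covariates under the "none" standardization
  des3 <- build_design(d, w, standardization = "none", log_flow = FALSE)
  expect_equal(unname(des3$Xf[, "air"]), d$airT[100:102])
  expect_equal(unname(des3$Xf[, "flow"]), d$flow[100:102])
  expect_equal(unname(des3$Z[, "u"]), 100:102)
})

test_that("linear predictor and conditional mean follow the model equations", {
  d <- toy_canonical(100:110, airT = 2, flow = 1)
  w <- data.frame(site = "s1", year = 2005, spring_day = 100, fall_day = 110)
  des <- build_design(d, w, standardization = "none", log_flow = FALSE)
  mk <- function(alpha, beta1 = 0, delta = 0)
    stream_params(alpha = alpha, beta = c(beta1, 0, 0, 0, 0),
                  B = matrix(0, 1, 4), M = rep(0, 4), Sigma = diag(4),
                  delta = delta, mu_delta = 0, sd_delta = 0.1, sd = 1)

  expect_equal(linear_predictor(mk(15), des), rep(15, 11))
  # beta1 = 1.52 on a standardized air value of 2
  expect_equal(linear_predictor(mk(15, 1.52), des), rep(15 + 1.52 * 2, 11))

  # delta = 0: mu == omega regardless of history
  expect_equal(conditional_mean(mk(15), des), linear_predictor(mk(15), des))
  # delta = 1 (boundary): full carryover of the previous residual
  p1 <- mk(15, delta = 1)
  om <- linear_predictor(p1, des)
  mu <- conditional_mean(p1, des)
  expect_equal(mu[2], om[2] + (des$y[1] - om[1]))
  # no previous day: mu == omega even with a large delta
  p9 <- mk(15, delta = 0.9)
  expect_equal(conditional_mean(p9, des)[1], om[1])

  set.seed(7)
  sim <- small_sim()
  des <- design_from_sim(sim)
  for (r in 1:5) {
    pars <- random_params(des)
    lp <- linear_predictor(pars, des)
    lp_o <- vapply(seq_along(des$y), function(i)
      pars$alpha + sum(des$Xf[i, ] * pars$beta) +
        sum(des$Z[i, ] * pars$B[des$year_idx[i], ]), numeric(1))
    expect_lt(max(abs(lp - lp_o)), 1e-12)
  }
})

test_that("log-posterior matches the independent density-by-density oracle", {
  set.seed(11)
  sim <- small_sim(n_sites = 2, years = 2001:2002, seed = 3)
  keep <- sort(sample(nrow(sim$data), nrow(sim$data)))
  des <- design_from_sim(sim)
  # a 20-row toy subset via narrow windows
  w20 <- data.frame(site = "mainstem", year = 2001,
                    spring_day = 150, fall_day = 169)
  des20 <- build_design(sim$data, w20,
                        standardization = sim$truth$standardization)
  expect_equal(length(des20$y), 20)
  for (r in 1:5) {
    pars <- random_params(des20)
    expect_equal(log_posterior(pars, des20),
                 oracle_log_posterior(pars, des20), tolerance = 1e-8)
  }
  # outside the truncation support
  pars <- random_params(des20)
  pars$delta[1] <- 1
  expect_identical(log_posterior(pars, des20), -Inf)
  pars <- random_params(des20)
  pars$sd <- 11
  expect_error(validate_stream_params(pars))
})

test_that("normal likelihood term is exact at its mean", {
  d <- toy_canonical(150, airT = 10, flow = 1)
  w <- data.frame(site = "s1", year = 2005, spring_day = 150, fall_day = 150)
  des <- build_design(d, w, standardization = "none", log_flow = FALSE)
  pars <- stream_params(alpha = des$y[1], beta = rep(0, 5),
                        B = matrix(0, 1, 4), M = rep(0, 4), Sigma = diag(4),
                        delta = 0, mu_delta = 0, sd_delta = 0.1, sd = 1)
  base <- log_posterior(pars, des)
  pars2 <- pars; pars2$alpha <- pars$alpha + 2   # shift the mean 2 deg away
  # likelihood drops by 2^2/2; the flat-ish N(0,100) prior shifts negligibly
  expect_equal(log_posterior(pars2, des) - base,
               -2 + dnorm(pars2$alpha, 0, 10, TRUE) - dnorm(pars$alpha, 0, 10, TRUE),
               tolerance = 1e-12)
})

test_that("R-hat reproduces the between/within variance formula", {
  set.seed(5)
  a <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("x", "y")))
  # two identical chains: R-hat = sqrt((n-1)/n)
  rh <- rhat(list(a, a))
  expect_equal(unname(rh), rep(sqrt(99 / 100), 2), tolerance = 1e-12)

  # hand-coded formula on distinct chains
  b <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("x", "y")))
  rh <- rhat(list(a, b))
  for (j in 1:2) {
    Wv <- mean(c(var(a[, j]), var(b[, j])))
    Bv <- 100 * var(c(mean(a[, j]), mean(b[, j])))
    expect_equal(unname(rh[j]), sqrt((99 / 100 * Wv + Bv / 100) / Wv))
  }

  # long same-distribution chains converge; disjoint chains do not
  set.seed(6)
  c1 <- matrix(rnorm(10000), ncol = 1, dimnames = list(NULL, "x"))
  c2 <- matrix(rnorm(10000), ncol = 1, dimnames = list(NULL, "x"))
  expect_lt(rhat(list(c1, c2)), 1.01)
  expect_gt(rhat(list(c1, c2 + 10)), 1.1)

  # zero within-chain variance is flagged undefined
  z <- matrix(1, 50, 1, dimnames = list(NULL, "x"))
  expect_true(is.na(rhat(list(z, z))))
})

test_that("sampler is seed-deterministic and respects truncation supports", {
  sim <- small_sim(n_sites = 2, years = 2001:2002, seed = 13)
  des <- design_from_sim(sim)
  mc <- mcmc_control(chains = 2, burnin = 50, iter = 100, thin = 2)
  f1 <- fit_stream_model(des, mcmc = mc, seed = 42)
  f2 <- fit_stream_model(des, mcmc = mc, seed = 42)
  expect_identical(f1$samples, f2$samples)
  f3 <- fit_stream_model(des, mcmc = mc, seed = 43)
  expect_false(identical(f1$samples, f3$samples))

  sm <- as.matrix(f1)
  expect_equal(nrow(sm), 2 * 50)   # floor(iter / thin) per chain
  dcols <- grep("^delta\\[", colnames(sm))
  expect_true(all(abs(sm[, dcols]) < 1))
  expect_true(all(sm[, "sd"] > 0 & sm[, "sd"] < 10))
  expect_true(all(sm[, "sd_delta"] > 0 & sm[, "sd_delta"] < 2))
  expect_true(all(abs(sm[, "mu_delta"]) < 1))
})

test_that("the Gibbs sampler agrees with an independent JAGS fit of the same model", {
  sim <- small_sim(n_sites = 1, years = 2001:2002, seed = 17)
  des <- design_from_sim(sim)
  fit <- fit_stream_model(des, mcmc = mcmc_control(2, 500, 2000, 2), seed = 1)
  ps <- posterior_summary(fit)
  rownames(ps) <- ps$parameter

  library(rjags)
  mod <- "model {
    for (i in 1:n) {
      omega[i] <- alpha + inprod(beta[], Xf[i,]) + inprod(B[year[i],], Z[i,])
      mu[i] <- omega[i] + prevAvail[i] * delta[1] * (tprev[i] - omega[pidx[i]])
      t[i] ~ dnorm(mu[i], tau)
    }
    tau <- pow(sd, -2)
    sd ~ dunif(0, 10)
    alpha ~ dnorm(0, 0.01)
    for (j in 1:kf) { beta[j] ~ dnorm(0, 0.01) }
    delta[1] ~ dnorm(mu_delta, pow(sd_delta, -2)) T(-1, 1)
    mu_delta ~ dunif(-1, 1)
    sd_delta ~ dunif(0, 2)
    M[1] <- 0
    for (j in 2:4) { M[j] ~ dnorm(0, 0.01) }
    for (y in 1:nyear) { B[y, 1:4] ~ dmnorm(M[], Omega[,]) }
    Omega ~ dwish(I4[,], 5)
  }"
  n <- length(des$y)
  pidx <- ifelse(is.na(des$prev_idx), 1L, des$prev_idx)
  tprev <- ifelse(is.na(des$t_prev), 0, des$t_prev)
  dat <- list(n = n, t = des$y, Xf = des$Xf, Z = des$Z,
              year = des$year_idx, prevAvail = as.numeric(des$prev_avail),
              pidx = pidx, tprev = tprev, kf = ncol(des$Xf),
              nyear = length(des$meta$year_levels), I4 = diag(4))
  jm <- jags.model(textConnection(mod), data = dat, n.chains = 2,
                   n.adapt = 300, quiet = TRUE,
                   inits = list(list(.RNG.name = "base::Mersenne-Twister",
                                     .RNG.seed = 101),
                                list(.RNG.name = "base::Mersenne-Twister",
                                     .RNG.seed = 102)))
  update(jm, 500)
  js <- as.matrix(coda.samples(jm, c("alpha", "beta", "delta", "sd",
                                     "mu_delta"), 2000, thin = 2))
  # (the delta hyper-mean is excluded: with a single site it is essentially
  # unidentified and both samplers wander its flat ridge)
  for (pair in list(c("beta[1]", "beta[1]"), c("beta[4]", "beta[4]"),
                    c("delta[1]", "delta"), c("sd", "sd"),
                    c("alpha", "alpha"))) {
    expect_lt(abs(ps[pair[1], "mean"] - mean(js[, pair[2]])), 0.06)
  }
})

test_that("two standardization specs span the same prediction space", {
  sim <- small_sim(n_sites = 2, years = 2001:2002, seed = 23)
  desA <- build_design(sim$data, sim$truth$windows, standardization = "none",
                       log_flow = FALSE)
  desB <- build_design(sim$data, sim$truth$windows, log_flow = FALSE)
  full <- function(des) {
    n <- length(des$y); l <- des$meta$l
    Yn <- length(des$meta$year_levels)
    Wm <- matrix(0, n, 1 + des$meta$kf + Yn * l)
    Wm[, 1] <- 1
    Wm[, 1 + seq_len(des$meta$kf)] <- des$Xf
    for (j in seq_len(l))
      Wm[cbind(seq_len(n), 1 + des$meta$kf + (des$year_idx - 1) * l + j)] <- des$Z[, j]
    Wm
  }
  WA <- full(desA); WB <- full(desB)
  set.seed(2)
  for (r in 1:3) {
    lpA <- linear_predictor(random_params(desA), desA)
    # the raw-scale predictor must be exactly representable on the
    # standardized design (pure reparameterization)
    co <- qr.coef(qr(WB), lpA)
    co[is.na(co)] <- 0
    expect_lt(max(abs(WB %*% co - lpA)), 1e-8)
  }
})

test_that("held-out predictions are calibrated and pool unseen years", {
  sim <- small_sim(n_sites = 3, years = 2001:2004, seed = 29)
  elig <- which(!is.na(sim$data$waterT))
  tw <- sim$truth$windows
  k <- paste(sim$data$site, sim$data$year)
  ix <- match(k, paste(tw$site, tw$year))
  inw <- sim$data$doy >= tw$spring_day[ix] & sim$data$doy <= tw$fall_day[ix]
  set.seed(101)
  hold <- sample(which(inw), 1000)
  masked <- sim$data
  masked$waterT[hold] <- NA
  des <- build_design(masked, tw)
  fit <- fit_stream_model(des, mcmc = mcmc_control_small(), seed = 3)
  pr <- predict(fit, newdata = masked, windows = tw, seed = 4)
  pk <- paste(pr$site, pr$date)
  hk <- paste(sim$data$site, sim$data$date)[hold]
  sel <- match(hk, pk)
  truth <- sim$data$waterT[hold]
  cover <- mean(truth >= pr$lwr[sel] & truth <= pr$upr[sel])
  expect_gt(cover, 0.92)
  expect_lt(cover, 0.98)

  # a year entirely absent from training is predicted from the
  # hyper-distribution with wider uncertainty
  m2 <- sim$data
  m2$waterT[m2$year == 2004] <- NA
  des2 <- suppressWarnings(build_design(m2, tw))
  fit2 <- fit_stream_model(des2, mcmc = mcmc_control_small(), seed = 5)
  pr2 <- predict(fit2, newdata = m2, windows = tw, seed = 6)
  w_new <- mean(pr2$upr[pr2$year == 2004] - pr2$lwr[pr2$year == 2004])
  w_old <- mean(pr2$upr[pr2$year == 2002] - pr2$lwr[pr2$year == 2002])
  expect_gt(w_new, w_old)
  expect_lt(rmse(sim$data$waterT[match(paste(pr2$site, pr2$date), hk0 <- paste(sim$data$site, sim$data$date))][pr2$year == 2004],
                 pr2$fit[pr2$year == 2004]), 3)
})

test_that("analytic cubic peaks match calculus and a dense grid", {
  pk <- peak_cubic(matrix(c(0, 0, -1, 0), 1))
  expect_equal(pk$max, 0)
  expect_equal(pk$argmax, 0)
  expect_false(pk$at_edge)

  co <- c(1, 0.8, -2.2, 0.4)
  pk <- peak_cubic(matrix(co, 1))
  roots <- polyroot(c(co[2], 2 * co[3], 3 * co[4]))
  roots <- Re(roots[abs(Im(roots)) < 1e-10])
  f <- function(u) co[1] + co[2] * u + co[3] * u^2 + co[4] * u^3
  expect_equal(pk$argmax, roots[which.max(f(roots))], tolerance = 1e-10)

  # monotone cubic: maximum at the window edge, flagged
  pk <- peak_cubic(matrix(c(0, 1, 0, 0.1), 1))
  expect_true(pk$at_edge)
  expect_equal(pk$argmax, 1)

  set.seed(12)
  grid <- seq(-1, 1, by = 0.01)
  co <- cbind(rnorm(200), rnorm(200, 0, 2), rnorm(200, 0, 2), rnorm(200, 0, 2))
  pk <- peak_cubic(co)
  gv <- co[, 1] + outer(co[, 2], grid) + outer(co[, 3], grid^2) +
    outer(co[, 4], grid^3)
  gmax <- apply(gv, 1, max)
  garg <- grid[apply(gv, 1, which.max)]
  expect_true(all(pk$max >= gmax - 1e-10))
  expect_true(all(abs(pk$argmax - garg) <= 0.01 + 1e-10))
})

test_that("yearly-maximum trends recover exact and noisy slopes", {
  yrs <- 2000:2014
  tr <- suppressWarnings(max_temp_trend(18 + 0.063 * (yrs - 2000), yrs))
  expect_equal(tr$decadal, 0.63, tolerance = 1e-10)

  tr <- max_temp_trend(rep(17.5, 15), yrs)
  expect_equal(tr$slope, 0)
  expect_equal(tr$F, 0)

  set.seed(33)
  sl <- replicate(500, max_temp_trend(18 + 0.063 * (yrs - 2000) +
                                        rnorm(15, 0, 0.3), yrs)$slope)
  expect_lt(abs(mean(sl) - 0.063), 0.01)

  expect_error(max_temp_trend(1:2, 2001:2002), "at least 3")
})

test_that("observed-versus-predicted regression matches the normal equations", {
  x <- rnorm(50, 15, 3)
  o <- suppressWarnings(observed_vs_predicted(x, x))
  expect_equal(o$slope, 1)
  expect_equal(o$intercept, 0, tolerance = 1e-12)
  expect_equal(o$r_squared, 1)

  o <- suppressWarnings(observed_vs_predicted(x + 2, x))
  expect_equal(o$slope, 1)
  expect_equal(o$intercept, 2, tolerance = 1e-10)

  set.seed(14)
  obs <- rnorm(200, 15, 3); prd <- obs + rnorm(200, 0, 1)
  o <- observed_vs_predicted(obs, prd)
  X <- cbind(1, prd)
  bhat <- solve(t(X) %*% X, t(X) %*% obs)
  expect_equal(o$intercept, bhat[1], tolerance = 1e-10)
  expect_equal(o$slope, bhat[2], tolerance = 1e-10)

  expect_error(observed_vs_predicted(obs, rep(1, 200)), "degenerate")
})
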