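test_that("degenerate air configurations reproduce the closed-form sinusoid", {
  cfg <- synth_config(sites = "s1", years = 2001, air_mean = 10, air_amp = 0,
                      air_noise_sd = 0, seed = 1)
  air <- simulate_air(cfg)
  expect_equal(air$airT, rep(10, 365))

  cfg <- synth_config(sites = "s1", years = 2001:2002, air_mean = 7,
                      air_amp = 9, air_peak_doy = 200, air_noise_sd = 0,
                      seed = 1)
  air <- simulate_air(cfg)
  expect_equal(air$airT,
               7 + 9 * cos(2 * pi * (air$doy - 200) / 365.25))
})

test_that("air noise reproduces its configured AR(1) autocorrelation", {
  # ~10,000 days, lag-1 autocorrelation of the anomaly within +-0.05 of 0.6
  cfg <- synth_config(sites = "s1", years = 1981:2008, air_noise_sd = 2,
                      air_noise_ar = 0.6, seed = 3)
  air <- simulate_air(cfg)
  anom <- air$airT - (cfg$air_mean +
    cfg$air_amp * cos(2 * pi * (air$doy - cfg$air_peak_doy) / 365.25))
  n <- length(anom)
  expect_gt(n, 10000)
  expect_lt(abs(cor(anom[-1], anom[-n]) - 0.6), 0.05)
})

test_that("flow follows its seasonal log-mean with the configured spread", {
  cfg <- synth_config(sites = "s1", years = 2001, flow_log_sd = 0, seed = 1)
  fl <- simulate_flow(cfg)
  expect_equal(fl$flow,
               exp(cfg$flow_log_mean +
                     cfg$flow_log_amp * cos(2 * pi * (fl$doy - cfg$flow_peak_doy) / 365.25)))

  cfg <- synth_config(sites = "s1", years = 2001, flow_log_sd = 0,
                      flow_log_amp = 0, flow_log_mean = 0, seed = 1)
  expect_equal(simulate_flow(cfg)$flow, rep(1, 365))

  cfg <- synth_config(sites = "s1", years = 1981:2008, flow_log_sd = 0.5,
                      flow_log_amp = 0.4, seed = 8)
  fl <- simulate_flow(cfg)
  lf <- log(fl$flow) -
    (cfg$flow_log_mean +
       cfg$flow_log_amp * cos(2 * pi * (fl$doy - cfg$flow_peak_doy) / 365.25))
  expect_lt(abs(sd(lf) - 0.5), 0.02)

  expect_error(synth_config(flow_log_sd = -1), "non-negative")
  expect_error(synth_config(years = integer(0)), "empty year list")
})

test_that("degenerate water generation collapses to the linear predictor", {
  # all beta = 0, alpha = 15, sd = 0, delta = 0 -> water == 15 in the window
  yrs <- 2001:2002
  p0 <- stream_params(alpha = 15, beta = rep(0, 5),
                      B = matrix(0, length(yrs), 4), M = rep(0, 4),
                      Sigma = diag(4) * 0.01, delta = 0, mu_delta = 0,
                      sd_delta = 0.1, sd = 0)
  cfg <- synth_config(sites = "s1", years = yrs, true_params = p0, seed = 2)
  sim <- simulate_stream_data(cfg)
  tw <- sim$truth$windows
  d <- sim$data
  ix <- match(paste(d$site, d$year), paste(tw$site, tw$year))
  inw <- d$doy >= tw$spring_day[ix] & d$doy <= tw$fall_day[ix]
  expect_equal(d$waterT[inw], rep(15, sum(inw)))

  # delta = 0, sd = 0 with arbitrary coefficients -> water == omega day by day
  p1 <- default_true_params(1, yrs)
  p1$delta <- 0; p1$mu_delta <- 0; p1$sd <- 0
  cfg <- synth_config(sites = "s1", years = yrs, true_params = p1, seed = 2)
  sim <- simulate_stream_data(cfg)
  lat <- sim$truth$latent
  w <- sim$data$waterT[match(paste(lat$site, lat$date),
                             paste(sim$data$site, sim$data$date))]
  expect_lt(max(abs(w - lat$omega)), 1e-10)
})

test_that("round trip: noise-free water equals the design-matrix linear predictor", {
  yrs <- 2002:2003
  p1 <- default_true_params(2, yrs)
  p1$delta <- rep(0, 2); p1$sd <- 0
  cfg <- synth_config(sites = c("mainstem", "trib1"), years = yrs,
                      true_params = p1, seed = 9)
  sim <- simulate_stream_data(cfg)
  des <- design_from_sim(sim)
  pars <- sim$truth$params
  expect_lt(max(abs(linear_predictor(pars, des) - des$y)), 1e-10)
})

test_that("in-window residuals carry the configured AR(1) autocorrelation", {
  # long single-site run: lag-1 autocorrelation of (water - omega) near 0.8
  p <- default_true_params(1, 1901:2040)
  p$delta <- 0.8; p$mu_delta <- 0.8; p$sd_delta <- 0.01
  cfg <- synth_config(sites = "s1", years = 1901:2040, true_params = p,
                      windows = make_true_windows("s1", 1901:2040,
                                                  jitter_sd = 0, seed = 1),
                      seed = 4)
  sim <- simulate_stream_data(cfg)
  lat <- sim$truth$latent
  e <- lat$resid
  same_run <- diff(as.numeric(lat$date)) == 1
  x <- e[-length(e)][same_run]
  y <- e[-1][same_run]
  expect_gt(length(x), 20000)
  expect_lt(abs(cor(x, y) - 0.8), 0.02)
})

test_that("missingness masks are exact, scoped and invertible", {
  sim <- small_sim()
  d <- sim$data

  out <- apply_missingness(d, list(), seed = 1)
  expect_identical(out$data, d)
  expect_false(any(out$mask))

  out <- apply_missingness(d, list(list(type = "site_year", site = "trib1",
                                        year = 2002)), seed = 1)
  sel <- out$data$site == "trib1" & out$data$year == 2002
  expect_true(all(is.na(out$data$waterT[sel])))
  expect_identical(out$data$waterT[!sel], d$waterT[!sel])
  expect_identical(out$data$airT, d$airT)

  # random fraction: exactly round(0.3 * n) days, reproducible
  out1 <- apply_missingness(d, list(list(type = "random", fraction = 0.3,
                                         site = "mainstem", year = 2001)),
                            seed = 7)
  n_elig <- sum(d$site == "mainstem" & d$year == 2001 & !is.na(d$waterT))
  expect_identical(sum(out1$mask), as.integer(round(0.3 * n_elig)))
  out2 <- apply_missingness(d, list(list(type = "random", fraction = 0.3,
                                         site = "mainstem", year = 2001)),
                            seed = 7)
  expect_identical(out1$mask, out2$mask)
  # inversion: masked values recoverable from the truth record
  expect_identical(sim$truth$full_water[!sim$truth$mask],
                   sim$data$waterT[!sim$truth$mask])

  expect_error(apply_missingness(d, list(list(type = "site_year",
                                              site = "nowhere", year = 2001))),
               "unknown site")
  expect_error(apply_missingness(d, list(list(type = "range", site = "trib1",
                                              year = 2002, doy = c(0, 50)))),
               "doy range")
})

test_that("air and water visibly decouple outside the true windows", {
  sim <- small_sim(n_sites = 2, years = 2001:2003, seed = 12)
  d <- sim$data
  tw <- sim$truth$windows
  ix <- match(paste(d$site, d$year), paste(tw$site, tw$year))
  inw <- d$doy >= tw$spring_day[ix] & d$doy <= tw$fall_day[ix]
  gap <- abs(d$waterT - d$airT)
  for (k in unique(paste(d$site, d$year))) {
    sel <- paste(d$site, d$year) == k
    expect_gt(mean(gap[sel & !inw]), mean(gap[sel & inw]))
  }
})

test_that("simulation is bit-reproducible from config and seed", {
  cfg <- synth_config(sites = c("mainstem", "trib1"), years = 2001:2002,
                      missingness = list(list(type = "random", fraction = 0.2)),
                      seed = 31)
  s1 <- simulate_stream_data(cfg)
  s2 <- simulate_stream_data(cfg)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$truth, s2$truth)
})
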