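#' Configuration of the synthetic daily-series generator
#'
#' Describes a multi-site, multi-year daily dataset: a shared regional air
#' temperature (annual sinusoid plus AR(1) noise), per-site relative stream
#' flow (seasonal log-mean plus AR(1) noise), and water temperature generated
#' from the hierarchical stream-temperature model itself inside a known
#' ("true") synchronized window for every site-year, with winter decoupling
#' outside it.  Everything is reproducible from `seed`.
#'
#' @param sites Character vector of site ids; the first is the reference
#'   (mainstem) site.
#' @param years Integer vector of calendar years.
#' @param air_mean,air_amp Annual mean and semi-amplitude of regional air
#'   temperature (deg C).
#' @param air_peak_doy Day of year of the air-temperature maximum.
#' @param air_noise_sd Marginal standard deviation of the AR(1) air noise
#'   (deg C).
#' @param air_noise_ar Lag-1 autocorrelation of the air noise, in (-1, 1).
#' @param site_air_offset Per-site additive air offsets (deg C); recycled.
#' @param flow_log_mean,flow_log_amp Mean and semi-amplitude of the seasonal
#'   log relative discharge (peak in early spring).
#' @param flow_peak_doy Day of year of the flow maximum.
#' @param flow_log_sd Marginal standard deviation of the AR(1) noise on log
#'   flow (must be >= 0).
#' @param flow_log_ar Lag-1 autocorrelation of the log-flow noise.
#' @param true_params A [stream_params] ground truth; its `B` rows, when
#'   absent, are drawn from `MVN(M, Sigma)` at simulation time.
#' @param windows Data frame of true synchronized windows with columns
#'   `site`, `year`, `spring_day`, `fall_day` (see [make_true_windows()]).
#'   Every `spring_day < fall_day` and both lie in `[1, 366]`.
#' @param winter_floor Lower bound (deg C, >= 0) water relaxes to outside the
#'   synchronized window.
#' @param winter_relax_rate Fraction of the gap to the winter target closed
#'   per day outside the window, in (0, 1].
#' @param winter_noise_sd Sd of the small daily noise outside the window.
#' @param missingness List of masks applied to the water series (see
#'   [apply_missingness()]); air and flow are never masked.
#' @param seed Master integer seed; split internally per site and operation.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(sites = c("mainstem", "trib1", "trib2", "trib3"),
                         years = 1999:2013,
                         air_mean = 9, air_amp = 12, air_peak_doy = 200,
                         air_noise_sd = 2.2, air_noise_ar = 0.4,
                         site_air_offset = 0,
                         flow_log_mean = 0, flow_log_amp = 0.6,
                         flow_peak_doy = 105,
                         flow_log_sd = 0.5, flow_log_ar = 0.6,
                         true_params = default_true_params(length(sites), years),
                         windows = make_true_windows(sites, years, seed = seed),
                         winter_floor = 0.3,
                         winter_relax_rate = 0.3,
                         winter_noise_sd = 0.15,
                         missingness = list(),
                         seed = 1L) {
  if (length(years) < 1) stop("configuration error: empty year list")
  if (flow_log_sd < 0) stop("flow_log_sd must be non-negative")
  if (abs(air_noise_ar) >= 1 || abs(flow_log_ar) >= 1)
    stop("noise autocorrelations must lie strictly in (-1, 1)")
  if (winter_floor < 0) stop("winter_floor must be >= 0")
  validate_stream_params(true_params)
  stopifnot(all(c("site", "year", "spring_day", "fall_day") %in% names(windows)))
  if (any(windows$spring_day >= windows$fall_day))
    stop("every true window must satisfy spring_day < fall_day")
  if (any(windows$spring_day < 1 | windows$fall_day > 366))
    stop("true window days must lie in [1, 366]")
  structure(list(sites = sites, years = as.integer(years),
                 air_mean = air_mean, air_amp = air_amp,
                 air_peak_doy = air_peak_doy, air_noise_sd = air_noise_sd,
                 air_noise_ar = air_noise_ar,
                 site_air_offset = rep_len(site_air_offset, length(sites)),
                 flow_log_mean = flow_log_mean, flow_log_amp = flow_log_amp,
                 flow_peak_doy = flow_peak_doy, flow_log_sd = flow_log_sd,
                 flow_log_ar = flow_log_ar,
                 true_params = true_params, windows = windows,
                 winter_floor = winter_floor,
                 winter_relax_rate = winter_relax_rate,
                 winter_noise_sd = winter_noise_sd,
                 missingness = missingness, seed = as.integer(seed)),
            class = "synth_config")
}

#' True synchronized windows for the synthetic generator
#'
#' Spring and fall decoupling days per site-year, optionally with a linear
#' trend across years (days per year, used for breakpoint-trend recovery
#' experiments) and seeded jitter.
#'
#' @param sites,years Site ids and calendar years.
#' @param spring_mean,fall_mean Mean spring and fall days of year.
#' @param spring_trend,fall_trend Linear change of each breakpoint in days
#'   per year (applied around the middle year).
#' @param jitter_sd Sd of independent normal jitter added per site-year.
#' @param seed Integer seed for the jitter.
#' @return Data frame with columns `site`, `year`, `spring_day`, `fall_day`.
#' @export
make_true_windows <- function(sites, years, spring_mean = 115, fall_mean = 295,
                              spring_trend = 0, fall_trend = 0,
                              jitter_sd = 4, seed = 1L) {
  g <- expand.grid(site = sites, year = as.integer(years),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  yc <- g$year - mean(range(years))
  with_seed(child_seed(seed, "windows"), {
    g$spring_day <- round(spring_mean + spring_trend * yc +
                            rnorm(nrow(g), 0, jitter_sd))
    g$fall_day <- round(fall_mean + fall_trend * yc +
                          rnorm(nrow(g), 0, jitter_sd))
  })
  g$spring_day <- pmax(2L, as.integer(g$spring_day))
  g$fall_day <- pmin(364L, as.integer(g$fall_day))
  g
}

# Calendar scaffold for one site: one row per day over the configured years.
site_calendar <- function(years) {
  dates <- seq(as.Date(paste0(min(years), "-01-01")),
               as.Date(paste0(max(years), "-12-31")), by = "day")
  dates <- dates[as.integer(format(dates, "%Y")) %in% years]
  data.frame(date = dates,
             year = as.integer(format(dates, "%Y")),
             doy = day_of_year(dates))
}

# Stationary AR(1) noise with a given marginal sd (innovations are scaled by
# sqrt(1 - ar^2) so the long-run sd equals `sd_marginal`).
ar1_noise <- function(n, sd_marginal, ar) {
  if (sd_marginal == 0) return(numeric(n))
  innov <- rnorm(n, 0, sd_marginal * sqrt(1 - ar^2))
  as.numeric(filter(innov, ar, method = "recursive",
                    init = rnorm(1, 0, sd_marginal)))
}

#' Generate the daily air-temperature series
#'
#' One shared regional series (annual sinusoid plus stationary AR(1) noise)
#' replicated across sites with optional per-site offsets.
#'
#' @param config A [synth_config] object.
#' @return Data frame with columns `site`, `date`, `year`, `doy`, `airT`.
#' @export
simulate_air <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cal <- site_calendar(config$years)
  seasonal <- config$air_mean +
    config$air_amp * cos(2 * pi * (cal$doy - config$air_peak_doy) / 365.25)
  noise <- with_seed(child_seed(config$seed, "air"),
                     ar1_noise(nrow(cal), config$air_noise_sd,
                               config$air_noise_ar))
  regional <- seasonal + noise
  out <- do.call(rbind, lapply(seq_along(config$sites), function(i) {
    data.frame(site = config$sites[i], cal,
               airT = regional + config$site_air_offset[i])
  }))
  rownames(out) <- NULL
  out
}

#' Generate the daily relative stream-flow series
#'
#' Per site, flow is `exp(seasonal log-mean + AR(1) noise)`: positive,
#' right-skewed, peaking in early spring.
#'
#' @param config A [synth_config] object.
#' @return Data frame with columns `site`, `date`, `year`, `doy`, `flow`.
#' @export
simulate_flow <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cal <- site_calendar(config$years)
  log_seasonal <- config$flow_log_mean +
    config$flow_log_amp * cos(2 * pi * (cal$doy - config$flow_peak_doy) / 365.25)
  out <- do.call(rbind, lapply(config$sites, function(s) {
    noise <- with_seed(child_seed(config$seed, "flow", s),
                       ar1_noise(nrow(cal), config$flow_log_sd,
                                 config$flow_log_ar))
    data.frame(site = s, cal, flow = exp(log_seasonal + noise))
  }))
  rownames(out) <- NULL
  out
}

# Standardization constants used by the generator (and stored in the truth so
# model fits can reproduce the exact covariate scale): air and log-flow are
# centered and scaled over in-window days, day of year is mapped linearly to
# [-1, 1] over the union of the true windows.
synthetic_standardization <- function(air, flow, windows, log_flow = TRUE) {
  key <- paste(air$site, air$year)
  wkey <- paste(windows$site, windows$year)
  idx <- match(key, wkey)
  inw <- !is.na(idx) & air$doy >= windows$spring_day[idx] &
    air$doy <= windows$fall_day[idx]
  a <- air$airT[inw]
  f <- flow$flow[match(paste(air$site, air$date), paste(flow$site, flow$date))][inw]
  f <- if (log_flow) log(f) else f
  d0 <- (min(windows$spring_day) + max(windows$fall_day)) / 2
  dh <- (max(windows$fall_day) - min(windows$spring_day)) / 2
  list(air_center = mean(a), air_scale = sd(a),
       flow_center = mean(f), flow_scale = sd(f),
       day_center = d0, day_halfrange = dh, log_flow = log_flow)
}

#' Generate water temperature from the model's own generative process
#'
#' Inside each site-year's true synchronized window, water temperature is the
#' model's linear predictor (air lags, flow, air-by-flow, site terms, the
#' year's cubic day effect) plus an AR(1) residual: the first day of each
#' window starts a fresh residual series and subsequent days carry over
#' `delta_s` times the previous day's residual.  Air-temperature lags are
#' taken from the year-round air series, which always exists.  Outside the
#' window, water relaxes exponentially toward
#' `max(winter_floor, 0.2 * airT)` with small noise, so air and water
#' visibly decouple in winter.
#'
#' @param air,flow Outputs of [simulate_air()] and [simulate_flow()] on
#'   identical site/day grids.
#' @param config A [synth_config] object.
#' @return List with `data` (columns `site`, `date`, `year`, `doy`, `airT`,
#'   `waterT`, `flow`), `latent` (per in-window day: `omega`, `resid`),
#'   `B` (the year coefficients actually used) and `standardization`.
#' @export
simulate_water <- function(air, flow, config) {
  stopifnot(inherits(config, "synth_config"))
  if (nrow(air) != nrow(flow) ||
      any(air$site != flow$site) || any(air$date != flow$date))
    stop("air and flow must cover identical site/day grids")
  p <- config$true_params
  windows <- config$windows
  std <- synthetic_standardization(air, flow, windows, log_flow = TRUE)
  years <- sort(unique(windows$year))
  B <- p$B
  if (nrow(B) == 0) {
    B <- with_seed(child_seed(config$seed, "B"),
                   rmvnorm_mat(length(years), p$M, p$Sigma))
  }
  if (nrow(B) != length(years))
    stop("true_params$B must have one row per year")
  rownames(B) <- years

  n_sites <- length(config$sites)
  dat <- air
  dat$flow <- flow$flow
  dat$waterT <- NA_real_
  latent <- vector("list", length(config$sites))

  for (si in seq_along(config$sites)) {
    s <- config$sites[si]
    rows <- which(dat$site == s)
    d <- dat[rows, ]
    nd <- nrow(d)
    w <- windows[windows$site == s, ]
    widx <- match(d$year, w$year)
    if (anyNA(widx)) stop("generation error: a year lacks a true window")
    in_win <- d$doy >= w$spring_day[widx] & d$doy <= w$fall_day[widx]
    if (anyNA(d$airT[in_win]) || anyNA(d$flow[in_win]))
      stop("generation error: missing air or flow inside a sync window")

    a0 <- (d$airT - std$air_center) / std$air_scale
    a1 <- c(a0[1], a0[-nd])
    a2 <- c(a0[1:2], a0[-c(nd - 1, nd)])
    f <- (log(d$flow) - std$flow_center) / std$flow_scale
    u <- (d$doy - std$day_center) / std$day_halfrange
    site_dum <- as.numeric(seq_len(n_sites)[-1] == si)  # length n_sites - 1
    xf_site <- if (n_sites > 1) c(site_dum) else numeric(0)
    omega <- p$alpha +
      p$beta[1] * a0 + p$beta[2] * a1 + p$beta[3] * a2 +
      p$beta[4] * f + p$beta[5] * a0 * f +
      B[as.character(d$year), 1] + B[as.character(d$year), 2] * u +
      B[as.character(d$year), 3] * u^2 + B[as.character(d$year), 4] * u^3
    if (n_sites > 1) {
      omega <- omega + sum(p$beta[5 + seq_len(n_sites - 1)] * xf_site) +
        sum(p$beta[5 + (n_sites - 1) + seq_len(n_sites - 1)] * xf_site) * a0
    }

    resid <- rep(NA_real_, nd)
    water <- numeric(nd)
    with_seed(child_seed(config$seed, "water", s), {
      run_id <- cumsum(in_win & !c(FALSE, in_win[-nd]))
      for (r in unique(run_id[in_win])) {
        ridx <- which(in_win & run_id == r)
        eps <- rnorm(length(ridx), 0, p$sd)
        e <- as.numeric(filter(eps, p$delta[si], method = "recursive"))
        resid[ridx] <- e
        water[ridx] <- omega[ridx] + e
      }
      wn <- rnorm(nd, 0, config$winter_noise_sd)
      target <- pmax(config$winter_floor, 0.2 * d$airT)
      prev <- target[1]
      for (i in seq_len(nd)) {
        if (in_win[i]) {
          prev <- water[i]
        } else {
          prev <- prev + config$winter_relax_rate * (target[i] - prev) + wn[i]
          if (prev < 0) prev <- 0
          water[i] <- prev
        }
      }
    })
    dat$waterT[rows] <- water
    latent[[si]] <- data.frame(site = s, date = d$date[in_win],
                               omega = omega[in_win], resid = resid[in_win])
  }
  list(data = dat[, c("site", "date", "year", "doy", "airT", "waterT", "flow")],
       latent = do.call(rbind, latent), B = B, standardization = std)
}

#' Mask water observations
#'
#' Applies a list of masks to the water-temperature column; air and flow are
#' never masked.  Mask types: `site_year` (a whole site-year), `range` (a day
#' range within a site-year) and `random` (an exact `round(fraction * n)`
#' sample of currently observed water days, optionally scoped to a site
#' and/or year).
#'
#' @param data Canonical daily data frame.
#' @param missingness List of masks, each a list with `type` and the fields
#'   above (`site`, `year`, `doy = c(lo, hi)`, `fraction`).
#' @param seed Integer seed for `random` masks.
#' @return List with `data` (masked copy) and `mask` (logical vector marking
#'   masked rows, for exact inversion in tests).
#' @export
apply_missingness <- function(data, missingness, seed = 1L) {
  mask <- rep(FALSE, nrow(data))
  k <- 0
  for (m in missingness) {
    k <- k + 1
    type <- m$type %||% stop("each mask needs a type")
    if (!is.null(m$site) && !all(m$site %in% data$site))
      stop("mask outside data range: unknown site ", m$site)
    if (!is.null(m$year) && !all(m$year %in% data$year))
      stop("mask outside data range: year ", m$year)
    scope <- rep(TRUE, nrow(data))
    if (!is.null(m$site)) scope <- scope & data$site %in% m$site
    if (!is.null(m$year)) scope <- scope & data$year %in% m$year
    if (type == "site_year") {
      if (is.null(m$site) || is.null(m$year))
        stop("site_year mask needs site and year")
      mask <- mask | scope
    } else if (type == "range") {
      if (is.null(m$doy) || length(m$doy) != 2)
        stop("range mask needs doy = c(lo, hi)")
      if (m$doy[1] < 1 || m$doy[2] > 366 || m$doy[1] > m$doy[2])
        stop("mask outside data range: bad doy range")
      mask <- mask | (scope & data$doy >= m$doy[1] & data$doy <= m$doy[2])
    } else if (type == "random") {
      frac <- m$fraction %||% stop("random mask needs a fraction")
      eligible <- which(scope & !is.na(data$waterT) & !mask)
      n_mask <- round(frac * length(eligible))
      sel <- with_seed(child_seed(seed, "mask", k),
                       sample(eligible, n_mask))
      mask[sel] <- TRUE
    } else stop("unknown mask type: ", type)
  }
  out <- data
  out$waterT[mask] <- NA_real_
  list(data = out, mask = mask)
}

#' Simulate a complete multi-site daily dataset with known truth
#'
#' Runs [simulate_air()], [simulate_flow()] and [simulate_water()] and applies
#' the configured missingness, returning both the (masked) canonical data and
#' a truth record sufficient to score every downstream stage: the true
#' parameters (with the year coefficients actually used), the true
#' synchronized windows, the generator's standardization constants, the
#' latent linear predictors and residuals, and the missingness mask.
#'
#' @param config A [synth_config] object.
#' @return An object of class `stream_sim`: list with `data` (canonical data
#'   frame) and `truth`.
#' @examples
#' sim <- simulate_stream_data(synth_config(sites = c("mainstem", "trib1"),
#'                                          years = 2001:2003, seed = 42))
#' head(sim$data)
#' @export
simulate_stream_data <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  air <- simulate_air(config)
  flow <- simulate_flow(config)
  gen <- simulate_water(air, flow, config)
  masked <- apply_missingness(gen$data, config$missingness,
                              seed = child_seed(config$seed, "missing"))
  params <- config$true_params
  params$B <- gen$B
  structure(list(data = masked$data,
                 truth = list(params = params, windows = config$windows,
                              standardization = gen$standardization,
                              latent = gen$latent, mask = masked$mask,
                              full_water = gen$data$waterT),
                 config = config),
            class = "stream_sim")
}

#' @export
print.stream_sim <- function(x, ...) {
  cat("Synthetic stream-temperature dataset\n")
  cat("  sites:", paste(x$config$sites, collapse = ", "), "\n")
  cat("  years:", min(x$config$years), "-", max(x$config$years), "\n")
  cat("  days :", nrow(x$data), "rows;",
      sum(is.na(x$data$waterT)), "masked water days\n")
  invisible(x)
}

# Draw n rows from MVN(mean, Sigma) via the Cholesky factor.
rmvnorm_mat <- function(n, mean, Sigma) {
  L <- chol(Sigma)
  z <- matrix(rnorm(n * length(mean)), n)
  sweep(z %*% L, 2, mean, `+`)
}

#' Default Table-2-like missingness
#'
#' A missingness pattern emulating a real deployment history: tributary sites
#' absent for the first years, a couple of whole mainstem site-years missing,
#' and a few long within-year gaps.
#'
#' @param sites,years Site ids and years of the configuration.
#' @return A list of masks for [apply_missingness()].
#' @export
default_missingness <- function(sites, years) {
  masks <- list()
  if (length(years) >= 6 && length(sites) > 1) {
    early <- years[seq_len(min(4, length(years) %/% 3))]
    for (s in sites[-1])
      masks[[length(masks) + 1]] <- list(type = "site_year", site = s, year = early)
    mid <- years[ceiling(length(years) / 2)]
    masks[[length(masks) + 1]] <- list(type = "site_year", site = sites[1],
                                       year = mid)
    masks[[length(masks) + 1]] <- list(type = "range", site = sites[1],
                                       year = years[length(years) - 1],
                                       doy = c(100, 190))
    masks[[length(masks) + 1]] <- list(type = "range",
                                       site = sites[min(2, length(sites))],
                                       year = years[length(years) - 2],
                                       doy = c(200, 280))
  }
  masks
}
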