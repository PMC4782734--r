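# Independent, deliberately naive oracles used to check the implementation.
# These re-derive every quantity from first principles (loops, direct
# formulas, brute-force scans) and share no code with the package internals.

oracle_moving_average <- function(x, window = 10, min_valid = 5,
                                  align = "left") {
  n <- length(x)
  before <- if (align == "left") window %/% 2 else window - window %/% 2 - 1
  after <- window - before - 1
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    idx <- max(1, i - before):min(n, i + after)
    v <- x[idx][!is.na(x[idx])]
    if (length(v) >= min_valid) out[i] <- sum(v) / length(v)
  }
  out
}

# O(days x run_len) scan for the first spring run and last fall run.
oracle_detect <- function(smoothed, doy, ci, run_len = 10, mid = 150) {
  n <- length(smoothed)
  inside <- function(i) !is.na(smoothed[i]) &&
    smoothed[i] >= ci$lo && smoothed[i] <= ci$hi
  spring <- NA_integer_
  for (d in which(doy <= mid)) {
    if (d + run_len - 1 > n) next
    ok <- TRUE
    for (j in d:(d + run_len - 1)) if (!inside(j)) { ok <- FALSE; break }
    if (ok) { spring <- doy[d]; break }
  }
  fall <- NA_integer_
  for (d in rev(which(doy >= mid))) {
    if (d - run_len + 1 < 1) next
    ok <- TRUE
    for (j in (d - run_len + 1):d) if (!inside(j)) { ok <- FALSE; break }
    if (ok) { fall <- doy[d]; break }
  }
  list(spring_day = spring, fall_day = fall)
}

# Sort-based empirical quantile (type-7 interpolation written longhand).
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Term-by-term log-posterior written independently of the package: explicit
# row loop for the likelihood, textbook densities via solve()/det(), and the
# inverse-Wishart density derived through the Wishart density of the inverse
# plus the change-of-variables Jacobian.
oracle_log_posterior <- function(params, design) {
  p <- params
  l <- design$meta$l
  n_site <- length(design$meta$site_levels)
  if (any(abs(p$delta) >= 1) || p$sd <= 0 || p$sd >= 10 ||
      p$sd_delta <= 0 || p$sd_delta >= 2 || abs(p$mu_delta) >= 1)
    return(-Inf)
  n <- length(design$y)
  om <- numeric(n)
  for (i in seq_len(n)) {
    om[i] <- p$alpha + sum(design$Xf[i, ] * p$beta)
    if (l > 0)
      om[i] <- om[i] + sum(design$Z[i, seq_len(l)] *
                             p$B[design$year_idx[i], seq_len(l)])
  }
  ll <- 0
  for (i in seq_len(n)) {
    mu <- om[i]
    if (design$prev_avail[i])
      mu <- mu + p$delta[design$site_idx[i]] *
        (design$t_prev[i] - om[design$prev_idx[i]])
    ll <- ll - 0.5 * log(2 * pi) - log(p$sd) -
      (design$y[i] - mu)^2 / (2 * p$sd^2)
  }
  for (s in seq_len(n_site)) {
    z <- (p$delta[s] - p$mu_delta) / p$sd_delta
    norm <- pnorm((1 - p$mu_delta) / p$sd_delta) -
      pnorm((-1 - p$mu_delta) / p$sd_delta)
    ll <- ll - 0.5 * log(2 * pi) - log(p$sd_delta) - 0.5 * z^2 - log(norm)
  }
  if (l > 0) {
    S <- p$Sigma[seq_len(l), seq_len(l), drop = FALSE]
    Si <- solve(S)
    for (y in seq_len(nrow(p$B))) {
      d <- p$B[y, seq_len(l)] - p$M[seq_len(l)]
      ll <- ll - 0.5 * l * log(2 * pi) - 0.5 * log(det(S)) -
        0.5 * as.numeric(t(d) %*% Si %*% d)
    }
    # inverse-Wishart(I_l, l + 1) via the Wishart density of W = Sigma^-1
    # with Jacobian |Sigma|^-(l+1)
    nu <- l + 1
    W <- Si
    lgammap <- 0.25 * l * (l - 1) * log(pi) +
      sum(lgamma((nu + 1 - seq_len(l)) / 2))
    lwish <- 0.5 * (nu - l - 1) * log(det(W)) - 0.5 * sum(diag(W)) -
      0.5 * nu * l * log(2) - lgammap
    ll <- ll + lwish + (l + 1) * log(det(Si))
    if (l > 1)
      for (j in 2:l)
        ll <- ll - 0.5 * log(2 * pi) - log(10) - p$M[j]^2 / 200
  }
  ll <- ll - 0.5 * log(2 * pi) - log(10) - p$alpha^2 / 200
  for (b in p$beta)
    ll <- ll - 0.5 * log(2 * pi) - log(10) - b^2 / 200
  ll + log(0.5) + log(0.5) + log(0.1)
}

# Random interior parameter set compatible with a design.
random_params <- function(design, years = NULL) {
  l <- max(design$meta$l, 1)
  n_site <- length(design$meta$site_levels)
  Y <- length(design$meta$year_levels)
  A <- matrix(rnorm(l * l, 0, 0.4), l)
  stream_params(alpha = rnorm(1, 15, 2),
                beta = rnorm(design$meta$kf, 0, 0.5),
                B = matrix(rnorm(Y * l, 0, 0.5), Y, l),
                M = c(0, rnorm(l - 1, 0, 0.4)),
                Sigma = crossprod(A) + diag(0.3, l),
                delta = runif(n_site, -0.6, 0.9),
                mu_delta = runif(1, -0.5, 0.8),
                sd_delta = runif(1, 0.1, 0.8),
                sd = runif(1, 0.3, 2))
}

# Small synthetic fixtures shared across test files.
small_sim <- function(n_sites = 2, years = 2001:2003, seed = 5, ...) {
  sites <- c("mainstem", "trib1", "trib2", "trib3")[seq_len(n_sites)]
  simulate_stream_data(synth_config(sites = sites, years = years,
                                    seed = seed, ...))
}

design_from_sim <- function(sim, ...) {
  build_design(sim$data, sim$truth$windows,
               standardization = sim$truth$standardization, ...)
}

# Hand-built canonical frame: one site, chosen year, air everywhere, water
# only on `water_days`.
toy_canonical <- function(water_days, year = 2005, site = "s1",
                          airT = NULL, flow = 1) {
  dates <- seq(as.Date(paste0(year, "-01-01")),
               as.Date(paste0(year, "-12-31")), by = "day")
  doy <- seq_along(dates)
  a <- if (is.null(airT)) 10 + 8 * sin(2 * pi * (doy - 110) / 365) else
    rep_len(airT, length(doy))
  w <- rep(NA_real_, length(doy))
  w[water_days] <- 12 + 6 * sin(2 * pi * (doy[water_days] - 120) / 365)
  data.frame(site = site, date = dates, year = year, doy = doy,
             airT = a, waterT = w, flow = rep_len(flow, length(doy)),
             stringsAsFactors = FALSE)
}
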