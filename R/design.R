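#' Build the model design from daily data and synchronized windows
#'
#' Restricts the data to in-window days (by default those with observed water
#' temperature), builds the fixed-effect design (air temperature at lags 0-2,
#' flow, air-by-flow, site offsets and site-by-air interactions relative to
#' the reference site) and the year-level cubic design in the standardized
#' day covariate, and computes the AR-availability flags: a row can use the
#' AR(1) residual path only when the immediately preceding calendar day is
#' also an in-window row of the same site-year with observed water.
#'
#' Covariates are standardized (air and log-flow centered and scaled over the
#' kept rows, all air lags sharing the lag-0 constants since they are the
#' same physical variable; day of year mapped linearly to `[-1, 1]` over the
#' union of the windows).  The constants are stored in the result for exact
#' inversion and for building prediction designs on the same scale; pass a
#' previously stored list (or `"none"` for raw covariates) as
#' `standardization`.
#'
#' @param data Canonical daily data frame (`site`, `date`, `year`, `doy`,
#'   `airT`, `waterT`, `flow`).  Air must be observed on the two days before
#'   every kept row (air-temperature lags always come from the year-round
#'   air series, even when prior water is missing).
#' @param windows Data frame with `site`, `year`, `spring_day`, `fall_day`;
#'   rows with `NA` days are dropped with a warning.
#' @param standardization `NULL` (compute from the kept rows), `"none"`, or a
#'   stored standardization list.
#' @param log_flow Log-transform flow before standardizing (default TRUE).
#' @param year_terms Number of year-level columns `l`: 4 = intercept +
#'   cubic (default), 1 = intercept only, 0 = no year effects.
#' @param site_levels Site factor levels; first level is the reference
#'   (mainstem).  Default: order of appearance in `data`.
#' @param allow_missing_response Keep in-window rows with missing water
#'   (used to build prediction designs); such rows never provide an AR
#'   previous day.
#' @return An object of class `stream_design`.
#' @export
build_design <- function(data, windows, standardization = NULL,
                         log_flow = TRUE, year_terms = 4,
                         site_levels = NULL, allow_missing_response = FALSE) {
  stopifnot(year_terms %in% 0:4)
  if ("status" %in% names(windows)) windows <- windows[windows$status == "ok", ]
  windows <- windows[!is.na(windows$spring_day) & !is.na(windows$fall_day), ]
  if (nrow(windows) == 0) stop("no usable windows")
  if (is.null(site_levels)) site_levels <- unique(data$site)
  if (!all(data$site %in% site_levels)) stop("unknown site in data")
  if (!all(windows$site %in% site_levels)) stop("unknown site in windows")

  data <- data[order(match(data$site, site_levels), data$date), ]
  wkey <- paste(windows$site, windows$year)
  widx <- match(paste(data$site, data$year), wkey)
  in_win <- !is.na(widx) & data$doy >= windows$spring_day[widx] &
    data$doy <= windows$fall_day[widx]
  keep <- in_win & (allow_missing_response | !is.na(data$waterT))
  if (!any(keep)) stop("no rows fall inside the windows")
  empty <- setdiff(wkey, unique(paste(data$site, data$year)[keep]))
  if (length(empty))
    warning("windows with zero usable rows dropped: ",
            paste(empty, collapse = "; "))

  # air lags from the full per-site series, keyed by calendar date
  akey <- paste(data$site, data$date)
  lag1 <- data$airT[match(paste(data$site, data$date - 1), akey)]
  lag2 <- data$airT[match(paste(data$site, data$date - 2), akey)]

  d <- data[keep, ]
  d$air_lag1 <- lag1[keep]
  d$air_lag2 <- lag2[keep]
  if (anyNA(d$airT) || anyNA(d$air_lag1) || anyNA(d$air_lag2))
    stop("air temperature must be observed on every kept day and its two lags")
  if (anyNA(d$flow)) stop("flow must be observed on every kept row")
  if (any(d$flow <= 0)) stop("flow must be positive")

  fl <- if (log_flow) log(d$flow) else d$flow
  if (identical(standardization, "none")) {
    std <- list(air_center = 0, air_scale = 1, flow_center = 0, flow_scale = 1,
                day_center = 0, day_halfrange = 1, log_flow = log_flow)
  } else if (is.null(standardization)) {
    std <- list(air_center = mean(d$airT), air_scale = sd(d$airT),
                flow_center = mean(fl), flow_scale = sd(fl),
                day_center = (min(windows$spring_day) + max(windows$fall_day)) / 2,
                day_halfrange = (max(windows$fall_day) - min(windows$spring_day)) / 2,
                log_flow = log_flow)
  } else {
    std <- standardization
    if (!identical(std$log_flow, log_flow))
      stop("log_flow disagrees with the stored standardization")
  }
  a0 <- (d$airT - std$air_center) / std$air_scale
  a1 <- (d$air_lag1 - std$air_center) / std$air_scale
  a2 <- (d$air_lag2 - std$air_center) / std$air_scale
  f <- (fl - std$flow_center) / std$flow_scale
  u <- (d$doy - std$day_center) / std$day_halfrange

  site_f <- factor(d$site, levels = site_levels)
  n_site <- length(site_levels)
  Xf <- cbind(air = a0, air_lag1 = a1, air_lag2 = a2, flow = f,
              `air:flow` = a0 * f)
  if (n_site > 1) {
    dum <- sapply(site_levels[-1], function(s) as.numeric(d$site == s))
    colnames(dum) <- paste0("site", site_levels[-1])
    inter <- dum * a0
    colnames(inter) <- paste0("site", site_levels[-1], ":air")
    Xf <- cbind(Xf, dum, inter)
  }
  l <- year_terms
  Z <- if (l > 0) {
    zz <- cbind(1, u, u^2, u^3)[, seq_len(l), drop = FALSE]
    colnames(zz) <- c("1", "u", "u2", "u3")[seq_len(l)]
    zz
  } else NULL
  year_levels <- sort(unique(d$year))
  year_idx <- match(d$year, year_levels)
  site_idx <- as.integer(site_f)

  # AR availability: previous calendar day is the previous kept row of the
  # same site-year and has observed water.
  n <- nrow(d)
  prev_is_yesterday <- c(FALSE, d$site[-1] == d$site[-n] &
                           d$year[-1] == d$year[-n] &
                           as.numeric(d$date[-1] - d$date[-n]) == 1)
  t_prev <- c(NA_real_, d$waterT[-n])
  prev_avail <- prev_is_yesterday & !is.na(t_prev)
  prev_idx <- ifelse(prev_avail, seq_len(n) - 1L, NA_integer_)
  t_prev[!prev_avail] <- NA_real_

  structure(list(y = d$waterT, Xf = Xf, Z = Z,
                 site_idx = site_idx, year_idx = year_idx,
                 prev_avail = prev_avail, prev_idx = prev_idx, t_prev = t_prev,
                 site = d$site, year = d$year, doy = d$doy, date = d$date,
                 meta = list(standardization = std, site_levels = site_levels,
                             year_levels = year_levels, l = l,
                             kf = ncol(Xf), fixed_names = colnames(Xf),
                             log_flow = log_flow)),
            class = "stream_design")
}

#' @export
print.stream_design <- function(x, ...) {
  cat("Stream model design:", length(x$y), "rows,",
      length(x$meta$site_levels), "sites,",
      length(x$meta$year_levels), "years,",
      x$meta$kf, "fixed-effect columns, l =", x$meta$l, "year terms\n")
  cat("  AR path available on", sum(x$prev_avail), "rows\n")
  invisible(x)
}

#' Linear predictor of the stream-temperature model
#'
#' The mean before the AR(1) residual adjustment: intercept + fixed effects +
#' the row's year-level cubic day effect.
#'
#' @param params A [stream_params] object whose `B` rows correspond (in
#'   order) to `design$meta$year_levels`.
#' @param design A [build_design()] result.
#' @param rows Optional row subset.
#' @return Numeric vector of linear predictors (deg C).
#' @export
linear_predictor <- function(params, design, rows = NULL) {
  kf <- design$meta$kf
  if (length(params$beta) != kf)
    stop("params$beta must have length ", kf)
  lp <- params$alpha + as.numeric(design$Xf %*% params$beta)
  l <- design$meta$l
  if (l > 0) {
    if (nrow(params$B) < max(design$year_idx))
      stop("a design year is absent from params$B")
    lp <- lp + rowSums(design$Z *
                         params$B[design$year_idx, seq_len(l), drop = FALSE])
  }
  if (is.null(rows)) lp else lp[rows]
}

#' Conditional mean including the AR(1) residual carryover
#'
#' `mu = omega + delta_s * (t_prev - omega_prev)` where the previous day is
#' an available in-window observed row of the same site-year; `mu = omega`
#' otherwise (series start or break in the series).
#'
#' @inheritParams linear_predictor
#' @return Numeric vector of conditional means (deg C).
#' @export
conditional_mean <- function(params, design) {
  om <- linear_predictor(params, design)
  mu <- om
  idx <- which(design$prev_avail)
  if (length(idx)) {
    mu[idx] <- om[idx] + params$delta[design$site_idx[idx]] *
      (design$t_prev[idx] - om[design$prev_idx[idx]])
  }
  mu
}
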