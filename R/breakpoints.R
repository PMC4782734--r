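#' Air-water temperature index
#'
#' `(waterT - airT) / waterT`, defined only where water temperature is
#' strictly positive and both temperatures are observed; `NA` otherwise.
#' The index is near 0 while water and air temperatures track each other and
#' departs strongly from 0 when they decouple (winter), so its flat period
#' delimits the synchronized season.  Scale-free: multiplying both
#' temperatures by a positive constant leaves it unchanged.
#'
#' @param waterT,airT Mean daily water and air temperatures (deg C).
#' @return Numeric vector of the same length; `NA` marks invalid days.
#' @export
temp_index <- function(waterT, airT) {
  out <- (waterT - airT) / waterT
  out[is.na(waterT) | is.na(airT) | !(waterT > 0)] <- NA_real_
  out
}

#' Centered moving average tolerant of invalid days
#'
#' Mean of the valid values in a centered window around each day.  An even
#' window is left-heavy by default (`window %/% 2` days before through
#' `window - window %/% 2 - 1` days after); `align = "right"` uses the
#' mirror convention.  The output is `NA` where fewer than `min_valid`
#' inputs in the window are valid; windows are truncated at the series edges.
#'
#' @param x Numeric series on consecutive days (`NA` = invalid).
#' @param window Window width in days (>= 1).
#' @param min_valid Minimum number of valid inputs for a valid output.
#' @param align `"left"` (default, left-heavy for even windows) or `"right"`.
#' @return Numeric vector of the same length as `x`.
#' @export
moving_average <- function(x, window = 10, min_valid = 5, align = c("left", "right")) {
  if (window < 1) stop("window must be >= 1")
  align <- match.arg(align)
  n <- length(x)
  before <- if (align == "left") window %/% 2 else window - window %/% 2 - 1
  after <- window - before - 1
  ok <- !is.na(x)
  xs <- ifelse(ok, x, 0)
  cs <- cumsum(c(0, xs))
  cn <- cumsum(c(0, as.numeric(ok)))
  i <- seq_len(n)
  lo <- pmax(i - before, 1)
  hi <- pmin(i + after, n)
  nv <- cn[hi + 1] - cn[lo]
  out <- (cs[hi + 1] - cs[lo]) / nv
  out[nv < min_valid] <- NA_real_
  out
}

#' Empirical flat-period interval of the temperature index
#'
#' Two-sided empirical percentile interval of the raw index over the middle
#' of the year (by default days 125-274, a 150-day span always inside the
#' flat period), computed separately per site-year.  The interval bounds the
#' typical index values of the synchronized season and is used to classify
#' days.
#'
#' @param raw_index Raw temperature index values.
#' @param doy Day-of-year (1-based) for each element of `raw_index`.
#' @param mid_days Length-2 day-of-year range to compute the interval over.
#' @param level Two-sided coverage level (default 0.999).
#' @param min_days Minimum number of valid index days required.
#' @return List with `lo`, `hi`, `n` and `ok` (FALSE when the site-year has
#'   too few valid mid-year days for the window to be detectable).
#' @export
flat_period_ci <- function(raw_index, doy, mid_days = c(125, 274),
                           level = 0.999, min_days = 30) {
  sel <- doy >= mid_days[1] & doy <= mid_days[2] & !is.na(raw_index)
  vals <- raw_index[sel]
  if (length(vals) < min_days)
    return(list(lo = NA_real_, hi = NA_real_, n = length(vals), ok = FALSE))
  a <- (1 - level) / 2
  q <- quantile(vals, c(a, 1 - a), names = FALSE, type = 7)
  list(lo = q[1], hi = q[2], n = length(vals), ok = TRUE)
}

#' Detect spring and fall synchronization breakpoints
#'
#' Runs analysis on the smoothed index: scanning day 1 toward `mid`, the
#' spring breakpoint is the first day `d` such that days `d .. d+run_len-1`
#' all have valid smoothed values inside `[lo, hi]`; scanning the end of the
#' year toward `mid`, the fall breakpoint is the first day `f` such that days
#' `f-run_len+1 .. f` all qualify.  Invalid smoothed days break a run.
#'
#' @param smoothed Smoothed index on consecutive days `doy`.
#' @param doy Day-of-year vector (consecutive, 1-based).
#' @param ci List with `lo` and `hi` (see [flat_period_ci()]).
#' @param run_len Required run length in days (default 10).
#' @param mid Day of year separating the two scans (default 150).
#' @return List with `spring_day` and `fall_day` (`NA` when no qualifying run
#'   exists on that side).
#' @export
detect_breakpoints <- function(smoothed, doy, ci, run_len = 10, mid = 150) {
  inside <- !is.na(smoothed) & smoothed >= ci$lo & smoothed <= ci$hi
  n <- length(inside)
  # run_from[i] = length of the qualifying run starting at i
  run_from <- rev(cumsum_reset(rev(inside)))
  run_to <- cumsum_reset(inside)  # run length ending at i
  spring <- NA_integer_
  cand <- which(doy <= mid & run_from >= run_len)
  if (length(cand)) spring <- doy[cand[1]]
  fall <- NA_integer_
  cand <- which(doy >= mid & run_to >= run_len)
  if (length(cand)) fall <- doy[cand[length(cand)]]
  list(spring_day = spring, fall_day = fall)
}

# Lengths of runs of TRUE ending at each position.
cumsum_reset <- function(x) {
  x <- as.logical(x)
  out <- integer(length(x))
  r <- 0L
  for (i in seq_along(x)) {
    r <- if (isTRUE(x[i])) r + 1L else 0L
    out[i] <- r
  }
  out
}

#' Find synchronized windows for every site-year
#'
#' Full per-site-year pipeline: raw temperature index, flat-period interval
#' from the middle of the year, centered moving average, runs analysis for
#' the spring and fall breakpoints, and data-coverage summaries inside the
#' detected window.
#'
#' @param data Canonical daily data frame (`site`, `year`, `doy`, `airT`,
#'   `waterT`).
#' @param level,mid_days,min_days Passed to [flat_period_ci()].
#' @param window,min_valid,align Passed to [moving_average()].
#' @param run_len,mid Passed to [detect_breakpoints()].
#' @return Data frame of class `sync_windows`: one row per site-year with
#'   columns `site`, `year`, `spring_day`, `fall_day`, `ci_lo`, `ci_hi`,
#'   `n_sync_days_with_data`, `pct_missing_in_window` and `status`
#'   (`"ok"`, `"undetectable"` for too few valid mid-year days, or
#'   `"not_found"` when a side has no qualifying run).
#' @export
find_sync_windows <- function(data, level = 0.999, mid_days = c(125, 274),
                              min_days = 30, window = 10, min_valid = 5,
                              align = "left", run_len = 10, mid = 150) {
  combos <- unique(data[, c("site", "year")])
  combos <- combos[order(combos$site, combos$year), ]
  res <- lapply(seq_len(nrow(combos)), function(i) {
    d <- data[data$site == combos$site[i] & data$year == combos$year[i], ]
    d <- d[order(d$doy), ]
    full <- data.frame(doy = seq_len(days_in_year(combos$year[i])))
    full$waterT <- d$waterT[match(full$doy, d$doy)]
    full$airT <- d$airT[match(full$doy, d$doy)]
    raw <- temp_index(full$waterT, full$airT)
    ci <- flat_period_ci(raw, full$doy, mid_days, level, min_days)
    out <- data.frame(site = combos$site[i], year = combos$year[i],
                      spring_day = NA_integer_, fall_day = NA_integer_,
                      ci_lo = ci$lo, ci_hi = ci$hi,
                      n_sync_days_with_data = 0L,
                      pct_missing_in_window = NA_real_,
                      status = "undetectable", stringsAsFactors = FALSE)
    if (!ci$ok) return(out)
    sm <- moving_average(raw, window, min_valid, align)
    bp <- detect_breakpoints(sm, full$doy, ci, run_len, mid)
    out$spring_day <- bp$spring_day
    out$fall_day <- bp$fall_day
    if (is.na(bp$spring_day) || is.na(bp$fall_day)) {
      out$status <- "not_found"
      return(out)
    }
    out$status <- "ok"
    win <- full$doy >= bp$spring_day & full$doy <= bp$fall_day
    n_days <- bp$fall_day - bp$spring_day + 1L
    n_obs <- sum(!is.na(full$waterT[win]))
    out$n_sync_days_with_data <- n_obs
    out$pct_missing_in_window <- 100 * (n_days - n_obs) / n_days
    out
  })
  out <- do.call(rbind, res)
  class(out) <- c("sync_windows", class(out))
  out
}

#' Summarize data coverage inside detected windows
#'
#' Per site-year: days with observed water data inside the window and the
#' percentage of window days missing (the shape of a deployment-history
#' table).  Site-years with no detected window report zero days.
#'
#' @param windows A [find_sync_windows()] result (or any data frame with
#'   `site`, `year`, `spring_day`, `fall_day`).
#' @param data Canonical daily data frame.
#' @param digits Rounding for the percent-missing column.
#' @return Data frame with `site`, `year`, `n_days_with_data`, `pct_missing`.
#' @export
summarize_windows <- function(windows, data, digits = 0) {
  res <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    out <- data.frame(site = w$site, year = w$year, n_days_with_data = 0L,
                      pct_missing = NA_real_, stringsAsFactors = FALSE)
    if (is.na(w$spring_day) || is.na(w$fall_day)) return(out)
    d <- data[data$site == w$site & data$year == w$year &
                data$doy >= w$spring_day & data$doy <= w$fall_day, ]
    n_days <- w$fall_day - w$spring_day + 1L
    n_obs <- sum(!is.na(d$waterT))
    out$n_days_with_data <- n_obs
    out$pct_missing <- round(100 * (n_days - n_obs) / n_days, digits)
    out
  })
  do.call(rbind, res)
}

#' Trend in breakpoint timing across years
#'
#' Fits the three nested least-squares models `day ~ year`,
#' `day ~ year + site` and `day ~ year * site`, compares them by AIC and
#' selects the simplest model whose AIC is within `delta_aic` of the minimum
#' (ties favor simplicity).  Returns the chosen model's year slope (days per
#' year; for the interaction model this is the reference-site slope) and its
#' decadal equivalent.
#'
#' @param windows Data frame with `site`, `year` and the breakpoint columns.
#' @param season `"spring"` or `"fall"`.
#' @param delta_aic Parsimony margin on the AIC scale (default 2).
#' @return List with `aic` (named vector), `chosen`, `model` (the `lm` fit),
#'   `slope` (days/year), `decadal` (days/decade) and `n`.
#' @export
breakpoint_trend <- function(windows, season = c("spring", "fall"),
                             delta_aic = 2) {
  season <- match.arg(season)
  col <- paste0(season, "_day")
  d <- windows[!is.na(windows[[col]]), c("site", "year", col)]
  names(d)[3] <- "day"
  if (nrow(d) < 3) stop("need at least 3 site-years with a detected breakpoint")
  d$site <- factor(d$site)
  forms <- list(year_only = day ~ year,
                year_site = day ~ year + site,
                year_x_site = day ~ year * site)
  if (nlevels(d$site) < 2) forms <- forms["year_only"]
  fits <- lapply(forms, function(f) {
    fit <- lm(f, data = d)
    if (any(is.na(coef(fit))))
      stop("rank-deficient design in breakpoint trend model; collinear term: ",
           paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
    fit
  })
  aics <- vapply(fits, AIC, numeric(1))
  # models are ordered simplest first; pick the first within delta_aic of min
  chosen <- names(aics)[which(aics <= min(aics) + delta_aic)[1]]
  fit <- fits[[chosen]]
  slope <- unname(coef(fit)["year"])
  list(aic = aics, chosen = chosen, model = fit,
       slope = slope, decadal = slope * 10, n = nrow(d))
}

#' Decadal widening of the synchronized window
#'
#' Fits [breakpoint_trend()] for both seasons and reports the widening rate
#' `(fall slope - spring slope) * 10` in days per decade.
#'
#' @inheritParams breakpoint_trend
#' @return List with `spring`, `fall` (the two trend fits) and
#'   `widening_per_decade`.
#' @export
breakpoint_widening <- function(windows, delta_aic = 2) {
  sp <- breakpoint_trend(windows, "spring", delta_aic)
  fa <- breakpoint_trend(windows, "fall", delta_aic)
  list(spring = sp, fall = fa,
       widening_per_decade = (fa$slope - sp$slope) * 10)
}
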