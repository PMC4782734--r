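#' Root mean square error
#'
#' `sqrt(mean((observed - predicted)^2))` over complete pairs.
#'
#' @param observed,predicted Equal-length numeric vectors with at least one
#'   complete pair.
#' @return RMSE (deg C for temperature series).
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length")
  ok <- complete.cases(observed, predicted)
  if (!any(ok)) stop("need at least one complete pair")
  sqrt(mean((observed[ok] - predicted[ok])^2))
}

# Row keys of in-window observed water days: the base observation set every
# experiment partitions into train and test.
eligible_keys <- function(data, windows) {
  if ("status" %in% names(windows)) windows <- windows[windows$status == "ok", ]
  windows <- windows[!is.na(windows$spring_day) & !is.na(windows$fall_day), ]
  wkey <- paste(windows$site, windows$year)
  widx <- match(paste(data$site, data$year), wkey)
  inw <- !is.na(widx) & data$doy >= windows$spring_day[widx] &
    data$doy <= windows$fall_day[widx]
  paste(data$site, data$date)[inw & !is.na(data$waterT)]
}

mask_water <- function(data, keys) {
  out <- data
  out$waterT[paste(data$site, data$date) %in% keys] <- NA_real_
  out
}

# Fit on masked data, score train rows (one-step) and held-out rows
# (one-step with the automatic no-AR fallback: a masked previous day gives a
# free-running prediction, so no information leaks through the AR term).
run_scenario <- function(data, windows, test_keys, mcmc, seed,
                         score_keys = test_keys, excluded_keys = character(0)) {
  elig <- eligible_keys(data, windows)
  stopifnot(all(test_keys %in% elig), all(excluded_keys %in% elig))
  if (length(intersect(test_keys, excluded_keys)))
    stop("test and excluded rows overlap")
  train <- mask_water(data, c(test_keys, excluded_keys))
  design <- suppressWarnings(build_design(train, windows))
  # invariant: train + test (+ excluded) partition the eligible rows
  train_keys <- paste(design$site, design$date)
  stopifnot(length(intersect(train_keys, c(test_keys, excluded_keys))) == 0,
            setequal(c(train_keys, test_keys, excluded_keys), elig))
  fit <- suppressWarnings(fit_stream_model(design, mcmc = mcmc,
                                           seed = child_seed(seed, "fit")))
  # point predictions only: 400 draws keep the Monte-Carlo error of the
  # posterior-mean prediction far below the residual scale
  pr_train <- predict(fit, mode = "one_step", draws = 400,
                      seed = child_seed(seed, "prtrain"))
  r_train <- rmse(pr_train$observed, pr_train$fit)
  r_test <- NA_real_
  n_test <- 0L
  if (length(score_keys)) {
    pr <- suppressWarnings(predict(fit, newdata = train, windows = windows,
                                   mode = "one_step", draws = 400,
                                   seed = child_seed(seed, "prtest")))
    pk <- paste(pr$site, pr$date)
    sel <- pk %in% score_keys
    truth <- data$waterT[match(pk[sel], paste(data$site, data$date))]
    r_test <- rmse(truth, pr$fit[sel])
    n_test <- sum(sel)
  }
  list(rmse_train = r_train, rmse_test = r_test, n_test = n_test, fit = fit)
}

experiment_row <- function(scheme, param, replicate, res, base_rmse) {
  data.frame(scheme = scheme, param = param, replicate = replicate,
             rmse_train = res$rmse_train, rmse_test = res$rmse_test,
             rmse_diff_from_base = if (is.na(res$rmse_test)) 0
                                   else res$rmse_test - base_rmse,
             n_test_rows = res$n_test, stringsAsFactors = FALSE)
}

# Base-case fit: all eligible data, no held-out rows.
base_case <- function(data, windows, mcmc, seed) {
  run_scenario(data, windows, character(0), mcmc, seed)
}

#' Leave-p-out cross-validation
#'
#' For each proportion `p` in the grid and each replicate, masks a uniformly
#' random `round(p * n)` of the in-window observed water days, refits the
#' model on the rest and scores predictions of the masked days (no-AR
#' fallback where the previous day is masked).  `p = 0` is the base case:
#' its training RMSE anchors `rmse_diff_from_base`.
#'
#' @param data Canonical daily data frame.
#' @param windows Synchronized windows (see [find_sync_windows()]).
#' @param p Proportion grid (default the full design grid
#'   0, 0.05, 0.1, ..., 0.8).
#' @param reps Replicates per nonzero `p`.
#' @param mcmc [mcmc_control()] settings (scaled-down default).
#' @param seed Master seed; every scenario is reproducible from it.
#' @return Data frame of class `experiment_result`: one row per scenario
#'   with `scheme`, `param` (p), `replicate`, `rmse_train`, `rmse_test`,
#'   `rmse_diff_from_base`, `n_test_rows`.
#' @export
leave_p_out <- function(data, windows,
                        p = c(0, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8),
                        reps = 10, mcmc = mcmc_control_small(), seed = 1) {
  elig <- eligible_keys(data, windows)
  base <- base_case(data, windows, mcmc, child_seed(seed, "base"))
  out <- list(experiment_row("leave_p_out", 0, 1, base, base$rmse_train))
  for (pp in setdiff(p, 0)) {
    for (r in seq_len(reps)) {
      keys <- with_seed(child_seed(seed, "lpo", round(1000 * pp), r),
                        sample(elig, round(pp * length(elig))))
      res <- run_scenario(data, windows, keys, mcmc,
                          child_seed(seed, "lpo-run", round(1000 * pp), r))
      out[[length(out) + 1]] <-
        experiment_row("leave_p_out", pp, r, res, base$rmse_train)
    }
  }
  out <- do.call(rbind, out)
  class(out) <- c("experiment_result", class(out))
  out
}

#' Missing-data design: quantity
#'
#' Trims `15 * d` observed days from the beginning and `15 * d` from the end
#' of every site-year series (shrinking each series symmetrically about its
#' median sampling date by 30 days per step), refits, and scores the
#' trimmed-out days.  A site-year shorter than the trim is left out entirely
#' for that scenario.  Also fits the least-squares line of RMSE difference
#' versus the proportion of days retained.
#'
#' @inheritParams leave_p_out
#' @param d Trim multipliers (default 1 to 9); `d = 0` is the base case.
#' @param step Days trimmed per unit `d` at each end (default 15).
#' @return List of class `quantity_result`: `results` (an
#'   `experiment_result` data frame), `slope` and `slope_se` of RMSE
#'   difference on proportion retained.
#' @export
quantity_scenarios <- function(data, windows, d = 1:9, step = 15,
                               mcmc = mcmc_control_small(), seed = 1) {
  elig <- eligible_keys(data, windows)
  base <- base_case(data, windows, mcmc, child_seed(seed, "base"))
  out <- list(experiment_row("quantity", 0, 1, base, base$rmse_train))
  key_df <- data[paste(data$site, data$date) %in% elig,
                 c("site", "year", "date")]
  key_df <- key_df[order(key_df$site, key_df$date), ]
  for (dd in sort(setdiff(d, 0))) {
    trim <- step * dd
    keys <- character(0)
    for (sy in split(key_df, paste(key_df$site, key_df$year))) {
      n_sy <- nrow(sy)
      if (2 * trim >= n_sy) {
        keys <- c(keys, paste(sy$site, sy$date))
      } else {
        cut <- c(seq_len(trim), n_sy - seq_len(trim) + 1)
        keys <- c(keys, paste(sy$site, sy$date)[cut])
      }
    }
    res <- run_scenario(data, windows, keys, mcmc,
                        child_seed(seed, "qty", dd))
    row <- experiment_row("quantity", dd, 1, res, base$rmse_train)
    row$prop_retained <- 1 - length(keys) / length(elig)
    out[[length(out) + 1]] <- row
  }
  out[[1]]$prop_retained <- 1
  res <- do.call(rbind, out)
  class(res) <- c("experiment_result", class(res))
  tr <- lm(rmse_diff_from_base ~ prop_retained, data = res)
  structure(list(results = res, slope = unname(coef(tr)[2]),
                 slope_se = summary(tr)$coefficients[2, "Std. Error"]),
            class = "quantity_result")
}

#' Missing-data design: timing
#'
#' Shifts a 30-day window of water-data availability across the year for a
#' target stream: in each scenario and target year, only the window's days
#' keep their water data at the target site; all its other in-window days
#' are held out and scored.  With `companion = FALSE` the other streams'
#' data for that year are removed as well (excluded from scoring), probing
#' how much nearby streams stabilize predictions.
#'
#' @inheritParams leave_p_out
#' @param target_site Site whose availability window is shifted (default:
#'   first site).
#' @param target_years Years to run (default: all years with target data).
#' @param n_windows Number of scenarios (default 13).
#' @param window_len Days of retained data per scenario (default 30).
#' @param first_start,last_start Day of year of the first and last window
#'   start (default 70 and 310; starts are evenly spaced between them).
#' @return `experiment_result` data frame, one row per scenario and target
#'   year; `param` is the window start day, `replicate` the target year.
#'   Scenarios whose window covers no observed target days are flagged via
#'   `n_kept = 0`.
#' @export
timing_scenarios <- function(data, windows, target_site = NULL,
                             target_years = NULL, n_windows = 13,
                             window_len = 30, first_start = 70,
                             last_start = 310, companion = TRUE,
                             mcmc = mcmc_control_small(), seed = 1) {
  target_site <- target_site %||% unique(data$site)[1]
  elig <- eligible_keys(data, windows)
  edf <- data[paste(data$site, data$date) %in% elig, ]
  target_years <- target_years %||%
    sort(unique(edf$year[edf$site == target_site]))
  starts <- round(seq(first_start, last_start, length.out = n_windows))
  base <- base_case(data, windows, mcmc, child_seed(seed, "base"))
  out <- list()
  for (ty in target_years) {
    tkeys_all <- paste(edf$site, edf$date)[edf$site == target_site &
                                             edf$year == ty]
    excl <- if (companion) character(0) else
      paste(edf$site, edf$date)[edf$site != target_site & edf$year == ty]
    for (st in starts) {
      tdoy <- edf$doy[match(tkeys_all, paste(edf$site, edf$date))]
      keep <- tdoy >= st & tdoy <= st + window_len - 1
      test_keys <- tkeys_all[!keep]
      res <- run_scenario(data, windows, test_keys, mcmc,
                          child_seed(seed, "timing", ty, st),
                          excluded_keys = excl)
      row <- experiment_row("timing", st, ty, res, base$rmse_train)
      row$n_kept <- sum(keep)
      row$companion <- companion
      out[[length(out) + 1]] <- row
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("experiment_result", class(res))
  res
}

#' Missing-data design: site holdout
#'
#' For each year, removes the whole year of water data for the target (one
#' site, or all sites), refits, and predicts the held-out year through the
#' hierarchical partial-pooling path.  Comparing the `one_site` and
#' `all_sites` modes shows how much data from nearby streams moderate the
#' cost of a missing year.
#'
#' @inheritParams leave_p_out
#' @param target `"one_site"` (default: mask only `site`) or `"all_sites"`.
#' @param site Target site for `one_site` (default: first site).
#' @param years Years to hold out (default: all with target data).
#' @return `experiment_result` data frame, one row per held-out year
#'   (`param` is the year).
#' @export
holdout_scenarios <- function(data, windows, target = c("one_site", "all_sites"),
                              site = NULL, years = NULL,
                              mcmc = mcmc_control_small(), seed = 1) {
  target <- match.arg(target)
  site <- site %||% unique(data$site)[1]
  elig <- eligible_keys(data, windows)
  edf <- data[paste(data$site, data$date) %in% elig, ]
  sel_site <- if (target == "one_site") edf$site == site else TRUE
  years <- years %||% sort(unique(edf$year[sel_site]))
  if (length(unique(edf$year)) < 2)
    stop("holdout experiments need at least 2 years of data")
  base <- base_case(data, windows, mcmc, child_seed(seed, "base"))
  out <- list()
  for (ty in years) {
    keys <- paste(edf$site, edf$date)[sel_site & edf$year == ty]
    if (!length(keys)) next
    remaining <- unique(edf$year[!(paste(edf$site, edf$date) %in% keys)])
    if (!length(remaining))
      stop("masking year ", ty, " leaves zero training years")
    res <- run_scenario(data, windows, keys, mcmc,
                        child_seed(seed, "holdout", target, ty))
    out[[length(out) + 1]] <- experiment_row(paste0("holdout_", target),
                                             ty, 1, res, base$rmse_train)
  }
  res <- do.call(rbind, out)
  class(res) <- c("experiment_result", class(res))
  res
}
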