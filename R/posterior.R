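#' Posterior predictions of daily water temperature
#'
#' Per-row posterior mean and central predictive interval.  In `one_step`
#' mode, rows whose previous calendar day has observed water use the AR(1)
#' conditional mean (today's linear predictor shifted by `delta_s` times
#' yesterday's residual); rows without an observed previous day fall back to
#' the no-AR mean, mirroring the model's own treatment of series starts and
#' breaks.  `free_running` mode uses the no-AR mean everywhere (the honest
#' mode for held-out streams or years).  Years absent from the training data
#' get year coefficients drawn from the fitted hyper-distribution
#' (`MVN(M, Sigma)` per retained draw): the partial-pooling fallback.
#'
#' @param object A `stream_fit`.
#' @param newdata Optional canonical daily data frame; default: predict the
#'   training rows.  Its water column is used only for AR availability, so
#'   held-out (masked) days are predicted without information leakage.
#' @param windows Windows for `newdata` (required with `newdata`).
#' @param mode `"one_step"` (default) or `"free_running"`.
#' @param level Central predictive-interval coverage (default 0.95).
#' @param draws Number of posterior draws to use (evenly subsampled;
#'   default: all retained draws).
#' @param seed Seed for the predictive noise and unseen-year coefficient
#'   draws.
#' @param ... Unused.
#' @return Data frame: `site`, `year`, `doy`, `date`, `observed`, `fit`
#'   (posterior mean), `lwr`, `upr` (predictive interval), `ar_used`.
#' @export
predict.stream_fit <- function(object, newdata = NULL, windows = NULL,
                               mode = c("one_step", "free_running"),
                               level = 0.95, draws = NULL, seed = 1, ...) {
  mode <- match.arg(mode)
  meta <- object$design$meta
  design <- if (is.null(newdata)) {
    object$design
  } else {
    if (is.null(windows)) stop("windows are required with newdata")
    build_design(newdata, windows, standardization = meta$standardization,
                 log_flow = meta$log_flow, year_terms = meta$l,
                 site_levels = meta$site_levels, allow_missing_response = TRUE)
  }
  sm <- as.matrix(object)
  S <- nrow(sm)
  if (!is.null(draws) && draws < S)
    sm <- sm[round(seq(1, S, length.out = draws)), , drop = FALSE]
  S <- nrow(sm)
  n <- length(design$y)
  kf <- meta$kf
  l <- meta$l

  lp <- matrix(sm[, "alpha"], n, S, byrow = TRUE)
  if (kf > 0)
    lp <- lp + design$Xf %*% t(sm[, paste0("beta[", seq_len(kf), "]"), drop = FALSE])
  if (l > 0) {
    pyears <- design$meta$year_levels
    new_years <- setdiff(pyears, meta$year_levels)
    Bd <- lapply(seq_len(l), function(j) matrix(0, S, length(pyears)))
    for (yi in seq_along(pyears)) {
      yv <- pyears[yi]
      if (yv %in% meta$year_levels) {
        for (j in seq_len(l))
          Bd[[j]][, yi] <- sm[, paste0("B[", yv, ",", j, "]")]
      } else {
        Bnew <- with_seed(child_seed(seed, "newyear", yv),
                          draw_hyper_B(sm, l))
        for (j in seq_len(l)) Bd[[j]][, yi] <- Bnew[, j]
      }
    }
    for (j in seq_len(l))
      lp <- lp + design$Z[, j] * t(Bd[[j]][, design$year_idx, drop = FALSE])
  }

  mu <- lp
  ar_used <- rep(FALSE, n)
  if (mode == "one_step") {
    idx <- which(design$prev_avail)
    if (length(idx)) {
      dd <- t(sm[, paste0("delta[", design$site_idx[idx], "]"), drop = FALSE])
      mu[idx, ] <- lp[idx, ] +
        dd * (design$t_prev[idx] - lp[design$prev_idx[idx], , drop = FALSE])
      ar_used[idx] <- TRUE
    }
  }

  sd_d <- sm[, "sd"]
  zmat <- with_seed(child_seed(seed, "prednoise"),
                    matrix(rnorm(n * S), n, S))
  ydraw <- mu + zmat * rep(sd_d, each = n)
  a <- (1 - level) / 2
  qs <- t(apply(ydraw, 1, quantile, probs = c(a, 1 - a), names = FALSE))
  data.frame(site = design$site, year = design$year, doy = design$doy,
             date = design$date, observed = design$y,
             fit = rowMeans(mu), lwr = qs[, 1], upr = qs[, 2],
             ar_used = ar_used, stringsAsFactors = FALSE)
}

# One MVN(M, Sigma) draw of a year-coefficient row per retained sample.
draw_hyper_B <- function(sm, l) {
  S <- nrow(sm)
  out <- matrix(0, S, l)
  M <- matrix(0, S, l)
  if (l > 1) for (j in 2:l) M[, j] <- sm[, paste0("M[", j, "]")]
  for (k in seq_len(S)) {
    Sg <- matrix(0, l, l)
    for (i in seq_len(l)) for (j in i:l) {
      v <- sm[k, paste0("Sigma[", i, ",", j, "]")]
      Sg[i, j] <- v; Sg[j, i] <- v
    }
    out[k, ] <- M[k, ] + as.numeric(crossprod(chol(Sg), rnorm(l)))
  }
  out
}

#' Yearly cubic temperature curves and their peaks
#'
#' Evaluates, per year and posterior draw, the curve
#' `alpha + alpha_y + b12 u + b13 u^2 + b14 u^3` over the synchronized day
#' range (on the original day-of-year scale via the stored standardization;
#' other covariates sit at their in-window means) and finds the yearly
#' maximum and its day analytically from the roots of the derivative,
#' clipped to the day range.  Curves with no interior critical point take
#' their maximum at a range edge and are flagged.
#'
#' @param fit A `stream_fit` with `l = 4` year terms.
#' @param years Years to evaluate (default: all training years).
#' @param step Day grid step for the returned curves.
#' @param level Central credible level for the summaries.
#' @return List of class `cubic_curves`: `curves` (year, doy, mean, lwr,
#'   upr) and `peaks` (year, posterior summaries of the maximum temperature
#'   and its day of year, and the fraction of draws peaking at an edge).
#' @export
cubic_curves <- function(fit, years = NULL, step = 1, level = 0.95) {
  meta <- fit$design$meta
  if (meta$l != 4) stop("cubic curves need year_terms = 4")
  years <- years %||% meta$year_levels
  years <- intersect(years, meta$year_levels)
  sm <- as.matrix(fit)
  std <- meta$standardization
  a <- (1 - level) / 2
  ugrid <- seq(-1, 1, length.out = max(2, round(2 * std$day_halfrange / step)))
  doy_grid <- std$day_center + std$day_halfrange * ugrid
  curves <- list(); peaks <- list()
  for (yv in years) {
    co <- cbind(sm[, "alpha"] + sm[, paste0("B[", yv, ",1]")],
                sm[, paste0("B[", yv, ",2]")],
                sm[, paste0("B[", yv, ",3]")],
                sm[, paste0("B[", yv, ",4]")])
    vals <- co[, 1] + outer(co[, 2], ugrid) + outer(co[, 3], ugrid^2) +
      outer(co[, 4], ugrid^3)
    curves[[length(curves) + 1]] <- data.frame(
      year = yv, doy = doy_grid, mean = colMeans(vals),
      lwr = apply(vals, 2, quantile, a), upr = apply(vals, 2, quantile, 1 - a))
    pk <- peak_cubic(co, -1, 1)
    day <- std$day_center + std$day_halfrange * pk$argmax
    peaks[[length(peaks) + 1]] <- data.frame(
      year = yv, max_mean = mean(pk$max), max_lwr = quantile(pk$max, a),
      max_upr = quantile(pk$max, 1 - a), day_mean = mean(day),
      day_lwr = quantile(day, a), day_upr = quantile(day, 1 - a),
      edge_frac = mean(pk$at_edge))
  }
  structure(list(curves = do.call(rbind, curves),
                 peaks = do.call(rbind, peaks)),
            class = "cubic_curves")
}

#' Analytic maximum of cubic curves over an interval
#'
#' For rows of coefficients `(a, b, c, e)` of `f(u) = a + b u + c u^2 +
#' e u^3`, returns the maximum of `f` over `[u_lo, u_hi]` and its location:
#' the candidates are the interval ends and the real roots of
#' `b + 2 c u + 3 e u^2`.
#'
#' @param coefs Numeric matrix with 4 columns (one cubic per row).
#' @param u_lo,u_hi Interval bounds.
#' @return List of vectors `max`, `argmax`, `at_edge` (TRUE when the maximum
#'   sits on an interval end).
#' @export
peak_cubic <- function(coefs, u_lo = -1, u_hi = 1) {
  coefs <- rbind(coefs)
  b <- coefs[, 2]; cc <- coefs[, 3]; e <- coefs[, 4]
  n <- nrow(coefs)
  r1 <- rep(NA_real_, n); r2 <- rep(NA_real_, n)
  cub <- e != 0
  disc <- cc^2 - 3 * e * b
  ok <- cub & disc >= 0
  r1[ok] <- (-cc[ok] + sqrt(disc[ok])) / (3 * e[ok])
  r2[ok] <- (-cc[ok] - sqrt(disc[ok])) / (3 * e[ok])
  quad <- !cub & cc != 0
  r1[quad] <- -b[quad] / (2 * cc[quad])
  r1[!is.na(r1) & (r1 < u_lo | r1 > u_hi)] <- NA
  r2[!is.na(r2) & (r2 < u_lo | r2 > u_hi)] <- NA
  cand <- cbind(u_lo, u_hi, r1, r2)
  evalf <- function(u) coefs[, 1] + b * u + cc * u^2 + e * u^3
  fv <- cbind(evalf(rep(u_lo, n)), evalf(rep(u_hi, n)),
              ifelse(is.na(r1), -Inf, evalf(r1)),
              ifelse(is.na(r2), -Inf, evalf(r2)))
  fv[is.na(fv)] <- -Inf
  best <- max.col(fv, ties.method = "first")
  list(max = fv[cbind(seq_len(n), best)],
       argmax = cand[cbind(seq_len(n), best)],
       at_edge = best <= 2)
}

#' Linear trend in a yearly quantity
#'
#' Ordinary least-squares slope of a yearly series (peak temperature, day of
#' peak, ...) on calendar year, with the standard F test and the decadal
#' rate (slope times 10).
#'
#' @param values Yearly values.
#' @param years Calendar years (>= 3).
#' @return List: `slope`, `slope_se`, `decadal`, `F`, `df`, `p_value`,
#'   `r_squared`, `model`.
#' @export
max_temp_trend <- function(values, years) {
  if (length(values) != length(years)) stop("values and years must match")
  if (length(years) < 3) stop("need at least 3 years for a trend")
  if (var(values) == 0)
    return(list(slope = 0, slope_se = 0, decadal = 0, F = 0,
                df = c(1L, length(years) - 2L), p_value = 1, r_squared = 0,
                model = NULL))
  fit <- lm(values ~ years)
  an <- anova(fit)
  sm <- summary(fit)
  list(slope = unname(coef(fit)["years"]),
       slope_se = sm$coefficients["years", "Std. Error"],
       decadal = unname(coef(fit)["years"]) * 10,
       F = an$`F value`[1], df = unname(an$Df),
       p_value = an$`Pr(>F)`[1], r_squared = sm$r.squared, model = fit)
}

#' Observed-versus-predicted regression
#'
#' Least-squares regression of observed on predicted values; a slope near 1
#' and intercept near 0 indicate an unbiased fit.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return List: `slope`, `slope_se`, `intercept`, `intercept_se`,
#'   `r_squared`.
#' @export
observed_vs_predicted <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("lengths differ")
  ok <- complete.cases(observed, predicted)
  if (var(predicted[ok]) == 0) stop("degenerate predictions (zero variance)")
  fit <- lm(observed[ok] ~ predicted[ok])
  sm <- summary(fit)$coefficients
  list(slope = unname(coef(fit)[2]), slope_se = sm[2, "Std. Error"],
       intercept = unname(coef(fit)[1]), intercept_se = sm[1, "Std. Error"],
       r_squared = summary(fit)$r.squared)
}
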