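#' Pooled seasonal spline of water temperature
#'
#' Penalized regression smooth of water temperature on day of year pooled
#' over all sites and years (basis dimension chosen generously, smoothing
#' strength by generalized cross-validation).  The fitted curve is the
#' all-data seasonal expectation that cumulative residual curves are
#' measured against.
#'
#' @param data Canonical daily data frame with observed `waterT` and `doy`.
#' @param k Spline basis dimension (passed to the smooth).
#' @return Object of class `seasonal_spline` with the underlying
#'   [mgcv::gam()] fit and an `eval(doy)` function.
#' @export
seasonal_spline <- function(data, k = 20) {
  d <- data[!is.na(data$waterT), ]
  if (nrow(d) < 50 || length(unique(d$doy)) < 100)
    stop("need >= 50 observations spanning >= 100 distinct days of year")
  fit <- mgcv::gam(waterT ~ s(doy, k = k), data = d, method = "GCV.Cp")
  structure(list(fit = fit,
                 eval = function(doy)
                   as.numeric(predict(fit, newdata = data.frame(doy = doy)))),
            class = "seasonal_spline")
}

#' Cumulative residual curves per site-year
#'
#' Running sum over day of year of (observed water temperature minus the
#' pooled seasonal spline).  Curves ending above zero mark warm years,
#' below zero cool years; missing days contribute zero and are marked.
#'
#' @param data Canonical daily data frame.
#' @param spline A [seasonal_spline()] fit.
#' @return Data frame: `site`, `year`, `doy`, `residual`, `cumres`,
#'   `observed` (FALSE for gap days that contributed 0).
#' @export
cumulative_residuals <- function(data, spline) {
  stopifnot(inherits(spline, "seasonal_spline"))
  combos <- unique(data[!is.na(data$waterT), c("site", "year")])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    d <- data[data$site == combos$site[i] & data$year == combos$year[i], ]
    d <- d[order(d$doy), ]
    r <- d$waterT - spline$eval(d$doy)
    obs <- !is.na(r)
    r[!obs] <- 0
    data.frame(site = combos$site[i], year = combos$year[i], doy = d$doy,
               residual = r, cumres = cumsum(r), observed = obs,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Between-site correlations of daily water temperature
#'
#' Pearson correlation of daily mean water temperatures for every site pair
#' on their shared observed days; pairs with fewer than `min_days` shared
#' days are `NA`.
#'
#' @param data Canonical daily data frame.
#' @param min_days Minimum shared observed days per pair (default 30).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
site_correlations <- function(data, min_days = 30) {
  sites <- unique(data$site)
  wide <- tapply(data$waterT, list(paste(data$date), data$site),
                 function(x) x[1])
  out <- matrix(NA_real_, length(sites), length(sites),
                dimnames = list(sites, sites))
  diag(out) <- 1
  for (i in seq_along(sites)) for (j in seq_along(sites)) {
    if (j <= i) next
    x <- wide[, sites[i]]; y <- wide[, sites[j]]
    ok <- complete.cases(x, y)
    if (sum(ok) >= min_days) {
      out[i, j] <- cor(x[ok], y[ok])
      out[j, i] <- out[i, j]
    }
  }
  out
}
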