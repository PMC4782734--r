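#' Read a canonical daily CSV
#'
#' Columns: `site`, `date` (ISO-8601), `year`, `doy`, `airT`, `waterT`,
#' `flow`.  Missing water or flow is an empty field or `NA`.  Validation is
#' row-numbered: duplicate (site, date) pairs, dates that do not parse,
#' `doy`/`date` mismatches (leap-aware), and temperatures outside the sanity
#' bounds are reported with the offending rows.
#'
#' @param path File path.
#' @param air_bounds,water_bounds Sanity bounds (deg C) for air and observed
#'   water temperature.
#' @return Validated data frame ordered by site and date.
#' @export
read_canonical <- function(path, air_bounds = c(-50, 50),
                           water_bounds = c(-5, 40)) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(site = "character"))
  need <- c("site", "date", "year", "doy", "airT", "waterT", "flow")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  dt <- as.Date(d$date, format = "%Y-%m-%d")
  bad <- which(is.na(dt) & !is.na(d$date))
  if (length(bad))
    stop("malformed date on rows: ", paste(head(bad, 10), collapse = ", "))
  d$date <- dt
  d$year <- as.integer(d$year)
  d$doy <- as.integer(d$doy)
  bad <- which(as.integer(format(dt, "%Y")) != d$year |
                 day_of_year(dt) != d$doy)
  if (length(bad))
    stop("year/doy inconsistent with date on rows: ",
         paste(head(bad, 10), collapse = ", "))
  key <- paste(d$site, d$date)
  if (anyDuplicated(key))
    stop("duplicate (site, date) rows: ",
         paste(head(key[duplicated(key)], 10), collapse = "; "))
  bad <- which(!is.na(d$airT) & (d$airT < air_bounds[1] | d$airT > air_bounds[2]))
  if (length(bad))
    stop("air temperature outside ", air_bounds[1], "..", air_bounds[2],
         " on rows: ", paste(head(bad, 10), collapse = ", "))
  bad <- which(!is.na(d$waterT) &
                 (d$waterT < water_bounds[1] | d$waterT > water_bounds[2]))
  if (length(bad))
    stop("water temperature outside ", water_bounds[1], "..", water_bounds[2],
         " on rows: ", paste(head(bad, 10), collapse = ", "))
  if (any(!is.na(d$flow) & d$flow <= 0))
    stop("flow must be positive where present")
  d[order(d$site, d$date), need]
}

#' Write a canonical daily CSV
#'
#' @param data Canonical daily data frame.
#' @param path Output path; missing values are written as `NA`.
#' @return `path`, invisibly.
#' @export
write_canonical <- function(data, path) {
  out <- data[, c("site", "date", "year", "doy", "airT", "waterT", "flow")]
  out$date <- format(out$date, "%Y-%m-%d")
  write.csv(out, path, row.names = FALSE, na = "NA", quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the method end to end on either supplied daily data or a
#' synthetic configuration: breakpoint detection, the hierarchical model
#' fit, yearly cubic curves and peak-temperature trend, optional
#' missing-data experiments, and descriptive diagnostics.  Every stage
#' writes plain CSV/JSON artifacts into `out_dir` plus a provenance record
#' (settings, seed, package and R version); inputs are never mutated, and a
#' rerun with identical inputs and seed reproduces the summary exactly.
#'
#' @param data Canonical daily data frame (or `NULL` to simulate).
#' @param sim_config A [synth_config()] used when `data` is `NULL`.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed.
#' @param mcmc [mcmc_control()] settings for the main fit.
#' @param breakpoint_args List of overrides for [find_sync_windows()].
#' @param experiments Character subset of
#'   `c("leave_p_out", "quantity", "timing", "holdout")` to run (scaled-down
#'   settings), or `NULL` for none.
#' @param experiment_args List of overrides passed to the experiment
#'   functions (e.g. `list(reps = 2, p = c(0, 0.3))`).
#' @param describe Run the descriptive stage (default TRUE).
#' @return Invisibly, a list with the main objects and the artifact paths.
#' @export
run_pipeline <- function(data = NULL, sim_config = NULL, out_dir, seed = 1,
                         mcmc = mcmc_control(), breakpoint_args = list(),
                         experiments = NULL, experiment_args = list(),
                         describe = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  art <- list()
  if (is.null(data)) {
    if (is.null(sim_config)) stop("supply data or sim_config")
    sim <- stage("simulate", simulate_stream_data(sim_config))
    data <- sim$data
    art$data <- file.path(out_dir, "data.csv")
    write_canonical(data, art$data)
    art$truth <- file.path(out_dir, "truth.json")
    jsonlite::write_json(list(params = unclass(sim$truth$params),
                              windows = sim$truth$windows,
                              standardization = sim$truth$standardization),
                         art$truth, auto_unbox = TRUE, digits = NA)
  }
  windows <- stage("breakpoints",
                   do.call(find_sync_windows, c(list(data), breakpoint_args)))
  art$windows <- file.path(out_dir, "windows.csv")
  write.csv(windows, art$windows, row.names = FALSE)
  trends <- NULL
  if (sum(windows$status == "ok") >= 3) {
    trends <- stage("breakpoint_trends", breakpoint_widening(windows))
    art$trends <- file.path(out_dir, "trends.json")
    jsonlite::write_json(list(spring = trends$spring[c("aic", "chosen", "slope", "decadal")],
                              fall = trends$fall[c("aic", "chosen", "slope", "decadal")],
                              widening_per_decade = trends$widening_per_decade),
                         art$trends, auto_unbox = TRUE, digits = NA)
  }
  design <- stage("design", suppressWarnings(build_design(data, windows)))
  fit <- stage("fit", fit_stream_model(design, mcmc = mcmc,
                                       seed = child_seed(seed, "fit")))
  ps <- posterior_summary(fit)
  art$posterior_summary <- file.path(out_dir, "posterior_summary.json")
  jsonlite::write_json(ps, art$posterior_summary, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  art$posterior_samples <- file.path(out_dir, "posterior_samples.csv")
  long <- do.call(rbind, lapply(seq_along(fit$samples), function(ch) {
    m <- fit$samples[[ch]]
    data.frame(parameter = rep(colnames(m), each = nrow(m)),
               chain = ch, iteration = rep(seq_len(nrow(m)), ncol(m)),
               value = as.vector(m))
  }))
  write.csv(long, art$posterior_samples, row.names = FALSE)
  curves <- NULL
  if (fit$design$meta$l == 4) {
    curves <- stage("curves", cubic_curves(fit))
    art$curves <- file.path(out_dir, "curves.csv")
    write.csv(curves$curves, art$curves, row.names = FALSE)
    art$peaks <- file.path(out_dir, "peaks.csv")
    write.csv(curves$peaks, art$peaks, row.names = FALSE)
  }
  exps <- NULL
  if (!is.null(experiments)) {
    exps <- list()
    run_exp <- function(name, fun, extra = list()) {
      args <- c(list(data, windows), extra,
                list(mcmc = mcmc_control_small(),
                     seed = child_seed(seed, name)))
      args <- utils::modifyList(args, experiment_args[intersect(names(experiment_args), names(formals(fun)))])
      stage(name, do.call(fun, args))
    }
    if ("leave_p_out" %in% experiments)
      exps$leave_p_out <- run_exp("leave_p_out", leave_p_out)
    if ("quantity" %in% experiments)
      exps$quantity <- run_exp("quantity", quantity_scenarios)$results
    if ("timing" %in% experiments)
      exps$timing <- run_exp("timing", timing_scenarios)
    if ("holdout" %in% experiments) {
      exps$holdout <- rbind(
        run_exp("holdout1", holdout_scenarios, list(target = "one_site")),
        run_exp("holdout2", holdout_scenarios, list(target = "all_sites")))
    }
    allx <- do.call(rbind, lapply(exps, function(e)
      e[, c("scheme", "param", "replicate", "rmse_train", "rmse_test",
            "rmse_diff_from_base", "n_test_rows")]))
    art$experiments <- file.path(out_dir, "experiments.csv")
    write.csv(allx, art$experiments, row.names = FALSE)
  }
  if (describe) {
    sp <- stage("describe", seasonal_spline(data))
    grid <- data.frame(doy = sort(unique(data$doy[!is.na(data$waterT)])))
    art$spline <- file.path(out_dir, "spline.csv")
    write.csv(data.frame(doy = grid$doy, fitted = sp$eval(grid$doy)),
              art$spline, row.names = FALSE)
    art$cumres <- file.path(out_dir, "cumres.csv")
    write.csv(cumulative_residuals(data, sp), art$cumres, row.names = FALSE)
    art$correlations <- file.path(out_dir, "correlations.csv")
    write.csv(site_correlations(data), art$correlations)
  }
  art$provenance <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(
    list(package = "streamsync",
         version = as.character(packageVersion("streamsync")),
         r_version = R.version.string, seed = seed,
         mcmc = unclass(mcmc), breakpoint_args = breakpoint_args,
         experiments = experiments,
         max_rhat = max(fit$rhat, na.rm = TRUE),
         timestamp = format(Sys.time(), tz = "UTC")),
    art$provenance, auto_unbox = TRUE)
  invisible(list(windows = windows, trends = trends, fit = fit,
                 curves = curves, experiments = exps, paths = art))
}
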