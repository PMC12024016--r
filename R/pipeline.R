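#' Run the full length-based assessment pipeline
#'
#' Executes, in order and per year: length-weight fit, ELEFAN growth
#' (with Pauly t0 and the growth performance index), length-converted
#' catch-curve mortality with Pauly's M, the length-based Bayesian
#' biomass fit with its reference points, length indicators and status
#' label, and finally the fishing-ground spatial summaries. Every stage
#' is logged to stderr with its timing; a stage failure aborts with the
#' stage named. Given the same config (including its seed) the report is
#' byte-identical across runs.
#'
#' The config is a nested list (or the path of a YAML file with the same
#' structure). Either `inputs:` names CSV files
#' (`length_frequency`, `length_weight`, `logbook`; see
#' [read_length_frequency()], [read_length_weight()], [read_logbook()])
#' or `simulate:` describes a [population_scenario()] plus logbook
#' settings and the data are generated. Optional sections `growth:`
#' (`linf_range`, `k_range`, `resolution`), `mortality:` (`mean_temp`,
#' scalar or per-year), `lbb:` (`priors`, `mcmc`, `use_elefan_linf`) and
#' `spatial:` (`cell_deg`) override defaults; when `lbb$priors` is
#' absent, data-driven defaults are derived and the choice logged.
#'
#' @param config list or YAML file path.
#' @param output_dir if given, [write_report()] is called on the result.
#' @param quiet suppress stage logging.
#' @return an `assessment_report`: `per_year` (one row per year with all
#'   growth, mortality, LBB and indicator fields), `lw_fits`, `lbb_fits`,
#'   `spatial` (grid, gravity centers, Spearman correlations), `config`.
#' @export
run_pipeline <- function(config, output_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_param("config must be a list or YAML path")
  seed <- as.integer(config$seed %||% 1L)
  bw <- config$bin_width %||% 10
  log_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop_data("stage '", name, "' failed: ", conditionMessage(e)))
    if (!quiet)
      message(sprintf("[lenstock] stage %-12s %6.2fs", name,
                      proc.time()[["elapsed"]] - t0))
    res
  }

  dat <- log_stage("inputs", load_pipeline_inputs(config, seed, bw))
  years <- sort(unique(dat$lf$year))

  gcfg <- config$growth %||% list()
  mcfg <- config$mortality %||% list()
  lcfg <- config$lbb %||% list()
  mcmc <- do.call(lbb_mcmc_control,
                  utils::modifyList(list(chains = 2, iter = 4000,
                                         burn = 1000, thin = 5),
                                    lcfg$mcmc %||% list()))
  rows <- list(); lw_fits <- list(); lbb_fits <- list()
  for (i in seq_along(years)) {
    y <- years[i]
    lf_y <- lf_year(dat$lf, y)
    max_cm <- (max(lf_y$bin_lower[lf_y$count > 0]) + lf_bin_width(lf_y)) / 10

    lw_rec <- dat$lw
    if (!is.null(lw_rec$year) && any(lw_rec$year == y))
      lw_rec <- lw_rec[lw_rec$year == y, , drop = FALSE]
    lw <- log_stage(paste0("lw/", y), fit_length_weight(lw_rec))
    lw_fits[[as.character(y)]] <- lw

    linf_range <- as.numeric(gcfg$linf_range %||% c(0.75 * max_cm, 1.3 * max_cm))
    k_range <- as.numeric(gcfg$k_range %||% c(0.2, 1.0))
    ef <- log_stage(paste0("growth/", y),
                    fit_elefan(lf_y, linf_range, k_range,
                               resolution = gcfg$resolution %||% 25,
                               ma_window = gcfg$ma_window %||% 5))
    t0_hat <- estimate_t0(ef$params$linf, ef$params$k)
    vb <- vbgf_params(ef$params$linf, ef$params$k, t0_hat)
    phi <- growth_performance(vb$linf, vb$k)

    temp <- mcfg$mean_temp %||% 25
    if (is.list(temp) || length(temp) > 1)
      temp <- as.numeric(temp[[as.character(y)]] %||% 25)
    mort <- log_stage(paste0("mortality/", y),
                      estimate_mortality(lf_y, vb, temp))

    priors <- if (!is.null(lcfg$priors))
      do.call(lbb_priors, lcfg$priors) else NULL
    linf_fixed <- if (isTRUE(lcfg$use_elefan_linf)) vb$linf else NULL
    lbb <- log_stage(paste0("lbb/", y),
                     fit_lbb(lf_y, priors = priors, mcmc = mcmc,
                             seed = seed + 1000L + i,
                             linf_fixed = linf_fixed))
    lbb_fits[[as.character(y)]] <- lbb
    est <- lbb$estimates
    rp <- reference_points(est$linf, est$lc, est$mk, est$fk)
    ind <- length_indicators(lf_y, lbb, rp)
    status <- classify_status(rp$bb0, rp$bbmsy, est$fm)

    rows[[i]] <- data.frame(
      year = y, n_lw = lw$n, lw_a = lw$a, lw_b = lw$b,
      lw_r2 = lw$r_squared, growth_type = lw$growth_type,
      linf_elefan = vb$linf, k = vb$k, t0 = t0_hat, phi_prime = phi,
      rn_score = ef$rn_score,
      z = mort$z, m = mort$m, f = mort$f, e_catch_curve = mort$e,
      mean_temp = mort$mean_temp,
      lbb_linf = est$linf, lbb_lc = est$lc, lbb_alpha = est$alpha,
      mk = est$mk, fk = est$fk, zk = est$zk, fm = est$fm, e_lbb = est$e,
      l_opt = rp$l_opt, lc_opt = rp$lc_opt, bb0 = rp$bb0,
      bmsy_b0 = rp$bmsy_b0, bbmsy = rp$bbmsy,
      l95_over_linf = ind$l95_over_linf,
      lmean_over_lcopt = ind$lmean_over_lcopt,
      lc_over_lcopt = ind$lc_over_lcopt,
      status = status)
  }
  per_year <- do.call(rbind, rows)

  spatial <- log_stage("spatial", {
    lb <- dat$logbook
    if (is.null(lb)) NULL else {
      cog <- do.call(rbind, lapply(years, function(y) {
        g <- center_of_gravity(lb, y)
        data.frame(year = y, lat = g$lat, lon = g$lon)
      }))
      yrs <- as.integer(format(as.Date(lb$date), "%Y"))
      mon <- as.integer(format(as.Date(lb$date), "%m"))
      cpue <- cpue_per_operation(lb$catch, lb$nets)
      sp <- lapply(list(year = yrs, month = mon, lon = lb$lon,
                        lat = lb$lat),
                   function(v) spearman_rho(cpue, v))
      list(grid = grid_aggregate(lb, (config$spatial %||% list())$cell_deg %||% 0.5),
           gravity_centers = cog,
           spearman = data.frame(
             variable = names(sp),
             rho = vapply(sp, `[[`, numeric(1), "rho"),
             p_value = vapply(sp, `[[`, numeric(1), "p_value"),
             row.names = NULL))
    }
  })

  report <- structure(list(per_year = per_year, lw_fits = lw_fits,
                           lbb_fits = lbb_fits, spatial = spatial,
                           config = config),
                      class = "assessment_report")
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

load_pipeline_inputs <- function(config, seed, bw) {
  if (!is.null(config$inputs)) {
    inp <- config$inputs
    if (is.null(inp$length_frequency))
      stop_data("config$inputs$length_frequency is required")
    list(lf = read_length_frequency(inp$length_frequency, bin_width = bw),
         lw = if (!is.null(inp$length_weight)) read_length_weight(inp$length_weight),
         logbook = if (!is.null(inp$logbook)) read_logbook(inp$logbook))
  } else if (!is.null(config$simulate)) {
    sim <- config$simulate
    years <- as.integer(sim$years %||% 2016:2021)
    sc_base <- sim$scenario %||% list()
    lf <- do.call(rbind, lapply(seq_along(years), function(i) {
      sc <- do.call(population_scenario,
                    utils::modifyList(sc_base, list(seed = seed + i)))
      simulate_length_frequency(sc, bin_width = bw, year = years[i],
                                recruitment = sim$recruitment %||% "pulsed")
    }))
    lf <- as_length_frequency(lf, bin_width = bw)
    lw <- do.call(rbind, lapply(seq_along(years), function(i) {
      sc <- do.call(population_scenario,
                    utils::modifyList(sc_base, list(seed = seed + 100L + i)))
      r <- simulate_length_weight(sc, n = sim$lw_n %||% 500,
                                  noise_sd = sim$lw_noise_sd %||% 0.05)
      r$year <- years[i]
      r
    }))
    lb_cfg <- sim$logbook %||% list()
    drift <- lapply(seq_along(years), function(i)
      c(39 + 0.4 * i, 150 + 0.6 * i))
    logbook <- do.call(simulate_logbook,
                       utils::modifyList(
                         list(years = years, ops_per_year = 500,
                              centroid_path = drift, spread_deg = 1,
                              seed = seed + 500L),
                         lb_cfg))
    list(lf = lf, lw = lw, logbook = logbook)
  } else stop_data("config must contain either 'inputs' or 'simulate'")
}

#' @export
print.assessment_report <- function(x, ...) {
  cat("Assessment report:", nrow(x$per_year), "year(s)\n")
  cols <- c("year", "linf_elefan", "k", "z", "m", "f", "mk", "fk",
            "bb0", "bbmsy", "status")
  print(format_report_display(x$per_year)[intersect(cols, names(x$per_year))])
  invisible(x)
}

# display rounding: lengths Lopt/Lc-opt to integer cm, ratios to 2
# decimals, B/Bmsy to 1 decimal (full precision lives in the JSON mirror)
format_report_display <- function(df) {
  out <- df
  for (v in intersect(c("l_opt", "lc_opt"), names(out)))
    out[[v]] <- round(out[[v]])
  one_dp <- "bbmsy"
  for (v in setdiff(names(out)[vapply(out, is.numeric, logical(1))],
                    c("year", "n_lw", "lw_a", one_dp)))
    out[[v]] <- round(out[[v]], 2)
  for (v in intersect(one_dp, names(out))) out[[v]] <- round(out[[v]], 1)
  if ("lw_a" %in% names(out)) out$lw_a <- signif(out$lw_a, 3)
  out
}

#' Write an assessment report to disk
#'
#' `report.csv` carries the per-year table rounded for display as the
#' field reports such numbers (optimal lengths to integer cm, ratios to
#' 2 decimals, B/Bmsy to 1 decimal); `report.json` mirrors the full
#' precision, plus the spatial summaries as CSV.
#'
#' @param report an `assessment_report`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!inherits(report, "assessment_report")) stop_param("not an assessment_report")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(format_report_display(report$per_year),
                   file.path(dir, "report.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(
    list(per_year = report$per_year,
         spearman = report$spatial$spearman,
         gravity_centers = report$spatial$gravity_centers),
    file.path(dir, "report.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = 12, pretty = TRUE)
  if (!is.null(report$spatial)) {
    utils::write.csv(report$spatial$grid, file.path(dir, "grid.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(report$spatial$gravity_centers,
                     file.path(dir, "gravity_centers.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
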