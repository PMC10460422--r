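# End-to-end orchestration: generate -> expose -> forecast -> burden ->
# decompose, as a configurable, logged, reproducible run over synthetic
# inputs. Every stochastic stage draws its seed from the run seed, so a rerun
# with the same configuration reproduces all outputs bit-identically.

#' Default scenario set
#'
#' Four scenario specifications spanning the joint climate/socioeconomic
#' futures the pipeline contrasts: a sustainability path (strong pollution
#' decline, pronounced aging, steady population), a middle-of-the-road path
#' (moderate decline, pronounced aging, mild growth), a regional-rivalry
#' path (pollution increase, slower aging, faster growth) and a
#' fossil-fueled path (decline, the strongest aging, steady population).
#' Concentration trends compound to roughly -47%, -29%, +8% and -37% over
#' 2020--2035.
#'
#' @param years future years covered by each scenario.
#' @param n_models ensemble members per scenario.
#' @return Named list of [scenario_spec()]s.
#' @export
default_scenarios <- function(years = 2020:2035, n_models = 3L) {
  mk <- function(name, conc, aging, growth) {
    scenario_spec(name, years, concentration_trend = conc,
                  aging_rate = aging, pop_growth = growth,
                  n_models = n_models)
  }
  list(
    "SSP1-2.6" = mk("SSP1-2.6", -0.040, 0.018, 0),
    "SSP2-4.5" = mk("SSP2-4.5", -0.021, 0.018, 0.0018),
    "SSP3-7.0" = mk("SSP3-7.0",  0.005, 0.014, 0.0035),
    "SSP5-8.5" = mk("SSP5-8.5", -0.029, 0.019, 0)
  )
}

#' Pipeline run configuration
#'
#' Collects every knob of a pipeline run. All stochastic stages derive
#' their seeds from `seed`; the configuration round-trips losslessly
#' through [save_config()] / [load_config()].
#'
#' @param seed integer master seed.
#' @param regions region labels.
#' @param grid_shape grid-cell counts `c(rows, cols)`.
#' @param history_years years of the fitted mortality/exposure history.
#' @param future_years projection years.
#' @param baseline_window calibration window (within the history).
#' @param arima_order residual-model order.
#' @param orientation envelope-constraining orientation
#'   (`"envelope"` or `"as-printed"`).
#' @param ci_mode forecast prediction-variance mode
#'   (`"standard"` or `"as-printed"`).
#' @param interval burden interval propagation (`"bounds"` or
#'   `"montecarlo"`).
#' @param smoothing_window reporting-layer smoothing window (years).
#' @param n_draws exposure-response curve draws.
#' @param scenarios named list of [scenario_spec()]s
#'   (default [default_scenarios()] over `future_years`).
#' @param sdi_gain_mult named per-scenario multiplier on the logit-scale
#'   SDI gain beyond the history (faster development = faster mortality
#'   decline).
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       regions = paste0("R", 1:6),
                       grid_shape = c(12L, 12L),
                       history_years = 2000:2019,
                       future_years = 2020:2035,
                       baseline_window = c(2015L, 2019L),
                       arima_order = c(1L, 0L, 0L),
                       orientation = "envelope",
                       ci_mode = "standard",
                       interval = "bounds",
                       smoothing_window = 5L,
                       n_draws = 100L,
                       scenarios = NULL,
                       sdi_gain_mult = c("SSP1-2.6" = 1.3, "SSP2-4.5" = 1.0,
                                         "SSP3-7.0" = 0.6, "SSP5-8.5" = 1.2)) {
  if (is.null(scenarios)) scenarios <- default_scenarios(future_years)
  cfg <- list(seed = as.integer(seed), regions = regions,
              grid_shape = as.integer(grid_shape),
              history_years = as.integer(history_years),
              future_years = as.integer(future_years),
              baseline_window = as.integer(baseline_window),
              arima_order = as.integer(arima_order),
              orientation = orientation, ci_mode = ci_mode,
              interval = interval,
              smoothing_window = as.integer(smoothing_window),
              n_draws = as.integer(n_draws),
              scenarios = scenarios, sdi_gain_mult = sdi_gain_mult)
  if (!all(names(cfg$sdi_gain_mult) %in% c(names(scenarios)))) {
    stop_invalid("`sdi_gain_mult` names must match scenario names")
  }
  structure(cfg, class = "run_config")
}

#' Save / load a run configuration (lossless YAML round trip)
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  ser <- unclass(config)
  ser$scenarios <- lapply(config$scenarios, unclass)
  ser$sdi_gain_mult <- as.list(config$sdi_gain_mult)
  yaml::write_yaml(ser, path, precision = 15)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  scen <- lapply(raw$scenarios, function(s) {
    scenario_spec(s$name, s$years, s$concentration_trend, s$aging_rate,
                  s$pop_growth, s$n_models)
  })
  run_config(seed = raw$seed, regions = raw$regions,
             grid_shape = raw$grid_shape,
             history_years = raw$history_years,
             future_years = raw$future_years,
             baseline_window = raw$baseline_window,
             arima_order = raw$arima_order, orientation = raw$orientation,
             ci_mode = raw$ci_mode, interval = raw$interval,
             smoothing_window = raw$smoothing_window, n_draws = raw$n_draws,
             scenarios = scen,
             sdi_gain_mult = unlist(raw$sdi_gain_mult))
}

# Long-format CSV writer for a 4-d (member, year, lat, lon) component set.
write_fields_csv <- function(fields, path) {
  comp <- names(fields$components)
  rows <- lapply(comp, function(cn) {
    arr <- fields$components[[cn]]
    d <- dim(arr)
    grid <- expand.grid(member = seq_len(d[1L]), year = fields$years,
                        lat = fields$lat, lon = fields$lon,
                        KEEP.OUT.ATTRS = FALSE)
    grid$component <- cn
    grid$value <- as.vector(arr)
    grid
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df[, c("component", "member", "year", "lat", "lon", "value")],
                   path, row.names = FALSE)
  invisible(path)
}

# Scenario future SDI: continue the base trajectory beyond the history with
# a scenario-specific multiplier on the logit-scale increment.
scenario_sdi <- function(sdi_full, last_history_year, future_years, mult) {
  base <- sdi_full[sdi_full$year == last_history_year, ]
  fut <- sdi_full[sdi_full$year %in% future_years, ]
  b <- stats::qlogis(base$sdi[match(fut$region, base$region)])
  fut$sdi <- stats::plogis(b + mult * (stats::qlogis(fut$sdi) - b))
  fut
}

# Build per-year factor-state component tables for decomposition, smoothing
# each component series over years at the reporting layer.
build_states <- function(demog, paf, rates, years, window) {
  demog <- demog[demog$year %in% years, ]
  paf <- paf[paf$year %in% years, ]
  rates <- rates[rates$year %in% years & rates$cause %in% pm25_causes(), ]
  demog <- smooth_reporting(demog[, c("region", "year", "age", "pop", "age_prop")],
                            c("pop", "age_prop"),
                            by = c("region", "age"), window = window)
  paf <- smooth_reporting(paf[, c("region", "year", "disease", "age", "paf")],
                          "paf", by = c("region", "disease", "age"),
                          window = window)
  rates <- smooth_reporting(rates[, c("region", "year", "cause", "age", "rate")],
                            "rate", by = c("region", "cause", "age"),
                            window = window)
  lapply(stats::setNames(years, years), function(y) {
    d <- demog[demog$year == y, ]
    factor_state(
      agep = d[, c("region", "age", "age_prop")],
      pop = unique(d[, c("region", "pop")]),
      paf = paf[paf$year == y, c("region", "disease", "age", "paf")],
      rate = rates[rates$year == y, c("region", "cause", "age", "rate")]
    )
  })
}

#' Run the full synthetic pipeline
#'
#' Executes the five stages (generate, expose, forecast, burden, decompose)
#' under one configuration, writing tidy CSV outputs, a structured run log
#' and a YAML manifest into `outdir`. Rerunning with the same configuration
#' reproduces all data outputs bit-identically.
#'
#' @param config a [run_config()].
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list with the manifest path, per-stage file lists
#'   and the key in-memory tables (`exposure`, `forecast`, `burden`,
#'   `decomposition`).
#' @export
run_pipeline <- function(config = run_config(), outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("inputs", "exposure", "forecast", "burden", "decomposition")) {
    dir.create(file.path(outdir, d), showWarnings = FALSE)
  }
  log_path <- file.path(outdir, "run.log")
  cat("", file = log_path)
  logf <- function(...) {
    cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  }
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(code), error = function(e) {
      logf("stage=%s status=failed error=%s", name, conditionMessage(e))
      stop(errorCondition(paste0("stage '", name, "' failed: ",
                                 conditionMessage(e)),
                          class = "stage_failure"))
    })
    logf("stage=%s status=ok elapsed_s=%.2f", name,
         proc.time()[["elapsed"]] - t0)
    res
  }
  files <- character()
  add_file <- function(p) files <<- c(files, p)
  seed <- config$seed
  regions <- config$regions
  scen_names <- names(config$scenarios)

  ## stage 1: generate ------------------------------------------------------
  gen <- stage("generate", {
    hist_spec <- scenario_spec("historical", config$history_years,
                               concentration_trend = 0.019,
                               aging_rate = 0.008, pop_growth = 0.003,
                               n_models = config$scenarios[[1L]]$n_models)
    aer_hist <- generate_aerosol_fields(hist_spec, config$grid_shape, seed + 11L)
    # scenario fields continue from the end-of-history concentration level
    hist_end <- (1 + hist_spec$concentration_trend)^
      (length(config$history_years) - 1L)
    fut_levels <- c(BC = 2, OA = 8, SO4 = 10, SS = 3, dust = 5) * hist_end
    aer_fut <- lapply(scen_names, function(sn) {
      generate_aerosol_fields(config$scenarios[[sn]], config$grid_shape,
                              seed + 11L, base_levels = fut_levels)
    })
    names(aer_fut) <- scen_names
    rows <- config$grid_shape[1L]; cols <- config$grid_shape[2L]
    mask <- matrix(regions[1L + (seq_len(rows * cols) - 1L) %/%
                             ceiling(rows * cols / length(regions))],
                   rows, cols)
    totals <- with_seed(seed + 13L, {
      stats::setNames(round(stats::runif(length(regions), 5e6, 3e7)), regions)
    })
    popgrid <- generate_population(config$grid_shape, mask, totals, seed + 17L)
    demog_hist <- generate_demography(regions, hist_spec, seed + 19L)
    # projections continue from the end-of-history population level and
    # accumulated aging tilt
    nh <- length(config$history_years) - 1L
    demog_fut <- lapply(scen_names, function(sn) {
      generate_demography(regions, config$scenarios[[sn]], seed + 19L,
                          base_pop = 2e7 * (1 + hist_spec$pop_growth)^(nh + 1L),
                          tilt_offset = hist_spec$aging_rate * (nh + 1L))
    })
    names(demog_fut) <- scen_names
    all_years <- c(config$history_years, config$future_years)
    sdi_full <- generate_sdi(regions, all_years, seed + 23L)
    truth <- ground_truth(
      beta1 = -2.5, beta2 = -4.5, theta_a = -0.01,
      alpha = c(COPD = -9, lung_cancer = -9, IHD = -8, stroke = -8,
                diabetes_t2 = -10, rest_NCD = -7, LRI = -9.5,
                rest_CMNND = -9, injuries = -8),
      ar_phi = 0.3, sigma = 0.05
    )
    hist_sdi <- sdi_full[sdi_full$year %in% config$history_years, ]
    mort_hist <- generate_mortality_history(truth, regions,
                                            config$history_years, hist_sdi,
                                            seed + 29L)
    curves <- generate_rr_curves(seed = seed + 31L, n_draws = config$n_draws)

    p <- file.path(outdir, "inputs")
    add_file(write_fields_csv(aer_hist, file.path(p, "aerosol_historical.csv")))
    for (sn in scen_names) {
      add_file(write_fields_csv(
        aer_fut[[sn]], file.path(p, paste0("aerosol_", gsub("[^A-Za-z0-9]", "", sn), ".csv"))))
    }
    popdf <- expand.grid(lat = aer_hist$lat, lon = aer_hist$lon,
                         KEEP.OUT.ATTRS = FALSE)
    popdf$count <- as.vector(popgrid)
    utils::write.csv(popdf, file.path(p, "population.csv"), row.names = FALSE)
    add_file(file.path(p, "population.csv"))
    maskdf <- popdf[, c("lat", "lon")]
    maskdf$region_id <- match(as.vector(mask), regions)
    utils::write.csv(maskdf, file.path(p, "region_mask.csv"), row.names = FALSE)
    add_file(file.path(p, "region_mask.csv"))
    utils::write.csv(data.frame(region_id = seq_along(regions), region = regions),
                     file.path(p, "region_labels.csv"), row.names = FALSE)
    add_file(file.path(p, "region_labels.csv"))
    demog_all <- rbind(demog_hist, do.call(rbind, demog_fut))
    utils::write.csv(demog_all, file.path(p, "demography.csv"), row.names = FALSE)
    add_file(file.path(p, "demography.csv"))
    utils::write.csv(sdi_full, file.path(p, "sdi.csv"), row.names = FALSE)
    add_file(file.path(p, "sdi.csv"))
    utils::write.csv(mort_hist, file.path(p, "mortality_history.csv"),
                     row.names = FALSE)
    add_file(file.path(p, "mortality_history.csv"))
    add_file(write_rr_curves(curves, file.path(p, "rr_curves.csv")))

    list(aer_hist = aer_hist, aer_fut = aer_fut, mask = mask,
         popgrid = popgrid, demog_hist = demog_hist, demog_fut = demog_fut,
         sdi_full = sdi_full, mort_hist = mort_hist, curves = curves,
         truth = truth)
  })

  ## stage 2: expose --------------------------------------------------------
  expo <- stage("expose", {
    pm_hist <- compose_pm25(gen$aer_hist)
    # synthetic "observations": ensemble-mean history scaled by a smooth
    # positive bias field (models under-read the observations)
    obs_bias <- with_seed(seed + 37L, {
      1.3 * exp(0.1 * gaussian_smooth(
        matrix(stats::rnorm(prod(config$grid_shape)),
               config$grid_shape[1L], config$grid_shape[2L]), 2))
    })
    ens_mean <- apply(pm_hist$values, c(2L, 3L, 4L), mean)
    obs_vals <- array(0, dim = c(1L, dim(ens_mean)))
    for (y in seq_len(dim(ens_mean)[1L])) {
      obs_vals[1L, y, , ] <- ens_mean[y, , ] * obs_bias
    }
    pm_obs <- conc_field(obs_vals, pm_hist$years, pm_hist$lat, pm_hist$lon)

    pwc_one <- function(field, scen) {
      pw <- population_weighted_concentration(field, gen$popgrid, gen$mask)
      agg <- lapply(split(pw, list(pw$region, pw$year)), function(g) {
        ci <- ensemble_interval(g$conc)
        data.frame(region = g$region[1L], scenario = scen, year = g$year[1L],
                   mean = ci$mean, lower = max(ci$lower, 0), upper = ci$upper,
                   n = ci$n)
      })
      out <- do.call(rbind, agg)
      out[order(out$region, out$year), ]
    }
    hist_pwc <- pwc_one(calibrate_pm25(pm_hist, pm_hist, pm_obs,
                                       config$baseline_window), "historical")
    fut_pwc <- lapply(scen_names, function(sn) {
      pm_fut <- compose_pm25(gen$aer_fut[[sn]])
      cal <- calibrate_pm25(pm_fut, pm_hist, pm_obs, config$baseline_window)
      pwc_one(cal, sn)
    })
    exposure <- rbind(hist_pwc, do.call(rbind, fut_pwc))
    rownames(exposure) <- NULL
    utils::write.csv(exposure, file.path(outdir, "exposure", "pwc.csv"),
                     row.names = FALSE)
    add_file(file.path(outdir, "exposure", "pwc.csv"))
    exposure
  })

  ## stage 3: forecast ------------------------------------------------------
  fc <- stage("forecast", {
    causes <- unique(gen$mort_hist$cause)
    hist_sdi <- gen$sdi_full[gen$sdi_full$year %in% config$history_years, ]
    fits <- lapply(causes, function(cz) {
      fit_trend(gen$mort_hist, hist_sdi, cz)
    })
    names(fits) <- causes
    per_scen <- lapply(scen_names, function(sn) {
      fsdi <- scenario_sdi(gen$sdi_full, max(config$history_years),
                           config$future_years, config$sdi_gain_mult[[sn]])
      tab <- do.call(rbind, lapply(causes, function(cz) {
        forecast_rates(fits[[cz]], fsdi, order = config$arima_order,
                       ci_mode = config$ci_mode)
      }))
      tab <- constrain_hierarchy(tab, orientation = config$orientation)
      tab$scenario <- sn
      tab
    })
    forecast <- do.call(rbind, per_scen)
    rownames(forecast) <- NULL
    utils::write.csv(forecast, file.path(outdir, "forecast", "rates.csv"),
                     row.names = FALSE)
    add_file(file.path(outdir, "forecast", "rates.csv"))
    forecast
  })

  ## stage 4: burden --------------------------------------------------------
  brd <- stage("burden", {
    per_scen <- lapply(scen_names, function(sn) {
      expo_s <- expo[expo$scenario == sn, ]
      exposure <- data.frame(region = expo_s$region, year = expo_s$year,
                             scenario = sn, conc = expo_s$mean,
                             conc_lower = expo_s$lower,
                             conc_upper = expo_s$upper)
      pt <- paf_table(gen$curves, exposure)
      rates <- fc[fc$scenario == sn, ]
      demog <- gen$demog_fut[[sn]]
      burden <- compute_dapp(pt, demog, rates, interval = config$interval,
                             seed = seed + 41L)
      list(paf = pt, burden = burden)
    })
    names(per_scen) <- scen_names
    burden <- do.call(rbind, lapply(per_scen, `[[`, "burden"))
    rownames(burden) <- NULL
    utils::write.csv(burden, file.path(outdir, "burden", "dapp.csv"),
                     row.names = FALSE)
    add_file(file.path(outdir, "burden", "dapp.csv"))
    nat <- dapp_total(burden, by = c("year", "scenario"))
    nat <- smooth_reporting(nat, c("deaths", "deaths_lower", "deaths_upper"),
                            by = "scenario", window = config$smoothing_window)
    utils::write.csv(nat, file.path(outdir, "burden", "national.csv"),
                     row.names = FALSE)
    add_file(file.path(outdir, "burden", "national.csv"))
    oshare <- suppressWarnings(older_share_by_disease(burden))
    utils::write.csv(oshare, file.path(outdir, "burden", "older_share.csv"),
                     row.names = FALSE)
    add_file(file.path(outdir, "burden", "older_share.csv"))
    pcap <- do.call(rbind, lapply(scen_names, function(sn) {
      per_capita(burden[burden$scenario == sn, ], gen$demog_fut[[sn]])
    }))
    utils::write.csv(pcap, file.path(outdir, "burden", "per_capita.csv"),
                     row.names = FALSE)
    add_file(file.path(outdir, "burden", "per_capita.csv"))
    list(burden = burden, paf = lapply(per_scen, `[[`, "paf"),
         national = nat)
  })

  ## stage 5: decompose -----------------------------------------------------
  dec <- stage("decompose", {
    y_end <- max(config$future_years)
    y0 <- max(config$history_years)
    mids <- config$future_years[config$future_years %in%
                                  c(y0 + 6L, y0 + 11L)]
    periods <- list()
    bounds <- unique(c(y0, mids, y_end))
    for (i in seq_len(length(bounds) - 1L)) {
      periods[[i]] <- c(bounds[i], bounds[i + 1L])
    }
    periods[[length(periods) + 1L]] <- c(y0, y_end)

    hist_2019_rates <- gen$mort_hist[gen$mort_hist$year == y0, ]
    hist_2019_demog <- gen$demog_hist[gen$demog_hist$year == y0, ]
    rows <- lapply(scen_names, function(sn) {
      expo_all <- expo[expo$scenario %in% c("historical", sn), ]
      exposure <- data.frame(region = expo_all$region, year = expo_all$year,
                             scenario = sn, conc = expo_all$mean)
      pt <- paf_table(gen$curves, exposure)
      demog <- rbind(
        cbind(hist_2019_demog[, c("region", "year", "age", "pop", "age_prop")],
              scenario = sn),
        gen$demog_fut[[sn]][, c("region", "year", "age", "pop", "age_prop",
                                "scenario")]
      )
      rates <- rbind(
        hist_2019_rates[, c("region", "year", "cause", "age", "rate")],
        fc[fc$scenario == sn, c("region", "year", "cause", "age", "rate")]
      )
      states <- build_states(demog, pt, rates, c(y0, config$future_years),
                             config$smoothing_window)
      decs <- period_decomposition(states, periods)
      do.call(rbind, lapply(names(decs), function(pd) {
        d <- decs[[pd]]
        gross <- sum(pmax(d$contributions, 0))
        data.frame(scenario = sn, period = pd,
                   factor = names(d$contributions),
                   contribution_deaths = unname(d$contributions),
                   share_of_gross_increase =
                     ifelse(d$contributions > 0 & gross > 0,
                            d$contributions / gross, NA_real_),
                   net_change = d$net_change)
      }))
    })
    drivers <- do.call(rbind, rows)
    rownames(drivers) <- NULL
    utils::write.csv(drivers, file.path(outdir, "decomposition", "drivers.csv"),
                     row.names = FALSE)
    add_file(file.path(outdir, "decomposition", "drivers.csv"))
    drivers
  })

  ## manifest ---------------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("pm25burden")),
    seed = seed,
    stages = c("generate", "expose", "forecast", "burden", "decompose"),
    files = ifelse(startsWith(files, paste0(outdir, "/")),
                   substring(files, nchar(outdir) + 2L), files),
    config = local({
      ser <- unclass(config)
      ser$scenarios <- lapply(config$scenarios, unclass)
      ser$sdi_gain_mult <- as.list(config$sdi_gain_mult)
      ser
    })
  )
  manifest_path <- file.path(outdir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path, precision = 15)
  logf("stage=manifest status=ok files=%d", length(files))

  invisible(list(manifest = manifest_path, files = files,
                 exposure = expo, forecast = fc, burden = brd$burden,
                 national = brd$national, decomposition = dec))
}

#' Validate a run directory's input files
#'
#' Schema and invariant checks over the generated input bundle: aerosol
#' concentrations non-negative (violations reported with coordinates),
#' demography age proportions summing to 1, SDI within \[0, 1\], mortality
#' rates strictly positive, curve tables anchored at RR(0) = 1 and
#' non-decreasing.
#'
#' @param dir a run directory containing an `inputs/` folder (or the
#'   `inputs/` folder itself).
#' @return Data frame with columns `file`, `issue`, `detail`; zero rows
#'   when everything passes.
#' @export
validate_inputs <- function(dir) {
  p <- if (dir.exists(file.path(dir, "inputs"))) file.path(dir, "inputs") else dir
  if (!dir.exists(p)) {
    stop(errorCondition(paste0("cannot read input directory: ", dir),
                        class = "io_error"))
  }
  issues <- list()
  flag <- function(file, issue, detail = "") {
    issues[[length(issues) + 1L]] <<- data.frame(
      file = file, issue = issue, detail = detail, stringsAsFactors = FALSE)
  }
  for (f in list.files(p, pattern = "^aerosol_.*\\.csv$", full.names = TRUE)) {
    df <- utils::read.csv(f)
    bad <- which(df$value < 0)
    for (i in utils::head(bad, 10L)) {
      flag(basename(f), "negative concentration",
           sprintf("component=%s member=%d year=%d lat=%.3f lon=%.3f",
                   df$component[i], df$member[i], df$year[i],
                   df$lat[i], df$lon[i]))
    }
  }
  f <- file.path(p, "demography.csv")
  if (file.exists(f)) {
    df <- utils::read.csv(f)
    s <- stats::aggregate(age_prop ~ region + year + scenario, df, sum)
    bad <- s[abs(s$age_prop - 1) > 1e-6, ]
    for (i in seq_len(nrow(bad))) {
      flag("demography.csv", "age proportions do not sum to 1",
           sprintf("region=%s year=%d scenario=%s sum=%.6f",
                   bad$region[i], bad$year[i], bad$scenario[i], bad$age_prop[i]))
    }
  }
  f <- file.path(p, "sdi.csv")
  if (file.exists(f)) {
    df <- utils::read.csv(f)
    if (any(df$sdi < 0 | df$sdi > 1)) {
      flag("sdi.csv", "SDI outside [0, 1]",
           sprintf("%d row(s)", sum(df$sdi < 0 | df$sdi > 1)))
    }
  }
  f <- file.path(p, "mortality_history.csv")
  if (file.exists(f)) {
    df <- utils::read.csv(f)
    if (any(df$rate <= 0)) {
      flag("mortality_history.csv", "non-positive mortality rate",
           sprintf("%d row(s)", sum(df$rate <= 0)))
    }
  }
  f <- file.path(p, "rr_curves.csv")
  if (file.exists(f)) {
    ok <- tryCatch({ read_rr_curves(f); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) flag("rr_curves.csv", "invalid curve table", ok)
  }
  if (!length(issues)) {
    return(data.frame(file = character(), issue = character(),
                      detail = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}
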