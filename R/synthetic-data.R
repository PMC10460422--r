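# Synthetic inputs with known ground truth. These generators emulate the
# statistical structure of the pipeline's real-world inputs (climate-model
# aerosol fields, gridded population, cause-specific mortality histories,
# tabulated exposure-response curves) so that every downstream stage can be
# exercised and calibrated against a known generative model.

#' Scenario specification for the synthetic generators
#'
#' A scenario bundles the knobs that differ between socioeconomic/climate
#' futures: the multiplicative per-year drift of aerosol concentrations, the
#' rate at which the age structure tilts toward older bands, total population
#' growth, and the number of ensemble members emulating multi-model spread.
#'
#' @param name scenario label (e.g. "SSP1-2.6"); free text.
#' @param years ordered integer vector of calendar years (strictly increasing).
#' @param concentration_trend per-year multiplicative drift of component
#'   fields; e.g. -0.04 for a 4% annual decline.
#' @param aging_rate per-year tilt of the age-proportion vector toward older
#'   bands (0 = stationary age structure).
#' @param pop_growth per-year multiplicative total-population growth.
#' @param n_models number of ensemble members (>= 2).
#' @return An object of class `scenario_spec`.
#' @export
#' @examples
#' scenario_spec("SSP2-4.5", 2020:2035, concentration_trend = -0.02)
scenario_spec <- function(name, years, concentration_trend = 0,
                          aging_rate = 0, pop_growth = 0, n_models = 3L) {
  if (length(years) < 1L || any(diff(years) <= 0)) {
    stop_invalid("`years` must be strictly increasing")
  }
  if (n_models < 2L) stop_invalid("`n_models` must be >= 2")
  drifts <- c(concentration_trend, aging_rate, pop_growth)
  if (!all(is.finite(drifts))) stop_invalid("scenario drifts must be finite")
  structure(
    list(
      name = as.character(name), years = as.integer(years),
      concentration_trend = concentration_trend, aging_rate = aging_rate,
      pop_growth = pop_growth, n_models = as.integer(n_models)
    ),
    class = "scenario_spec"
  )
}

#' Ground-truth parameters of the mortality generative model
#'
#' Parameters of the log-rate model
#' `ln(m) = beta1 * min(SDI, 0.8) + beta2 * max(SDI - 0.8, 0) + theta_a * t
#'  + alpha_la + eps`, where `eps` follows an AR(1) process. The hinge in the
#' sociodemographic index (SDI) is continuous with a knot at 0.8, `t` is the
#' year index from the first generated year, and `alpha_la` are
#' region-by-age intercepts drawn by the generator (and recorded for
#' recovery tests).
#'
#' @param beta1,beta2 SDI slopes below/above the 0.8 knot.
#' @param theta_a per-age slope on the year index: a scalar (shared by all
#'   bands) or a vector named by age band.
#' @param alpha named numeric vector of per-cause baseline log-rate
#'   intercepts, or a scalar applied to every generated cause.
#' @param ar_phi AR(1) coefficient of the residual process (|phi| < 1).
#' @param sigma innovation standard deviation of the residual process.
#' @param rr_shape named list of exposure-response shape parameters handed to
#'   [generate_rr_curves()] (optional).
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(beta1 = -2.5, beta2 = -4.5, theta_a = -0.01,
                         alpha = -6, ar_phi = 0, sigma = 0.05,
                         rr_shape = NULL) {
  vals <- c(beta1, beta2, theta_a, alpha, ar_phi, sigma)
  if (!all(is.finite(vals))) stop_invalid("ground-truth parameters must be finite")
  if (abs(ar_phi) >= 1) stop_invalid("`ar_phi` must satisfy |phi| < 1 (stationary)")
  if (sigma < 0) stop_invalid("`sigma` must be >= 0")
  structure(
    list(beta1 = beta1, beta2 = beta2, theta_a = theta_a, alpha = alpha,
         arima_params = list(phi = ar_phi, sigma = sigma),
         rr_curve_params = rr_shape),
    class = "ground_truth"
  )
}

#' Generate smooth gridded aerosol component fields
#'
#' Produces non-negative, spatially smooth fields for black carbon (BC),
#' organic aerosol (OA), sulfate (SO4), sea salt (SS) and dust for each
#' ensemble member and scenario year. Spatial structure comes from a
#' Gaussian-blurred log-normal surface; member spread from smooth
#' multiplicative perturbations; the scenario's concentration trend enters as
#' a compounded per-year multiplier.
#'
#' @param spec a [scenario_spec()].
#' @param grid_shape integer vector `c(rows, cols)` of grid-cell counts.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param smoothness Gaussian-blur standard deviation in grid cells
#'   (free parameter of the generator; larger = smoother fields).
#' @param base_levels named vector of mean component levels in ug/m^3.
#' @param member_sd standard deviation of the smooth log-scale member
#'   perturbation.
#' @param year_sd standard deviation of the log-scale year-to-year noise.
#' @return An `aerosol_fields` object: list with `components` (named list of
#'   arrays with dim `(member, year, lat, lon)`), `years`, `lat`, `lon`.
#' @export
generate_aerosol_fields <- function(spec, grid_shape, seed,
                                    smoothness = 2,
                                    base_levels = c(BC = 2, OA = 8, SO4 = 10,
                                                    SS = 3, dust = 5),
                                    member_sd = 0.1, year_sd = 0.05) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (length(grid_shape) != 2L || any(grid_shape < 1)) {
    stop_invalid("`grid_shape` must be two positive integers")
  }
  rows <- as.integer(grid_shape[1L]); cols <- as.integer(grid_shape[2L])
  ny <- length(spec$years); nm <- spec$n_models
  comp_names <- c("BC", "OA", "SO4", "SS", "dust")
  if (!all(comp_names %in% names(base_levels))) {
    stop_invalid("`base_levels` must name BC, OA, SO4, SS, dust")
  }
  growth <- (1 + spec$concentration_trend)^(seq_len(ny) - 1L)

  with_seed(seed, {
    components <- lapply(comp_names, function(comp) {
      base <- base_levels[[comp]] *
        exp(gaussian_smooth(matrix(stats::rnorm(rows * cols), rows, cols),
                            smoothness))
      member_fields <- lapply(seq_len(nm), function(m) {
        exp(member_sd *
              gaussian_smooth(matrix(stats::rnorm(rows * cols), rows, cols),
                              smoothness))
      })
      year_noise <- matrix(exp(year_sd * stats::rnorm(nm * ny)), nm, ny)
      arr <- array(0, dim = c(nm, ny, rows, cols))
      for (m in seq_len(nm)) {
        for (y in seq_len(ny)) {
          arr[m, y, , ] <- base * member_fields[[m]] *
            growth[y] * year_noise[m, y]
        }
      }
      arr
    })
    names(components) <- comp_names
    structure(
      list(components = components, years = spec$years,
           lat = seq(20.5, by = 1, length.out = rows),
           lon = seq(100.5, by = 1, length.out = cols)),
      class = "aerosol_fields"
    )
  })
}

#' Allocate regional population totals onto a grid
#'
#' Spreads each region's requested total over its grid cells with exact
#' conservation: cell weights (log-normal-like smooth random weights by
#' default, or user-supplied) are converted to integer counts by
#' largest-remainder allocation, so per-region sums equal the requested
#' totals exactly.
#'
#' @param grid_shape integer `c(rows, cols)`.
#' @param regions character matrix of region labels (same shape); `NA` cells
#'   are masked and receive no population.
#' @param totals named numeric vector of non-negative per-region person
#'   counts (integers); names must cover every region label in `regions`.
#' @param seed integer seed for the random weights.
#' @param weights optional non-negative weight matrix overriding the random
#'   weights (e.g. uniform weights for exact allocation checks).
#' @return Numeric matrix of per-cell person counts.
#' @export
generate_population <- function(grid_shape, regions, totals, seed,
                                weights = NULL) {
  rows <- as.integer(grid_shape[1L]); cols <- as.integer(grid_shape[2L])
  if (!is.matrix(regions) || !all(dim(regions) == c(rows, cols))) {
    stop_invalid("`regions` raster shape must match `grid_shape`")
  }
  labs <- unique(stats::na.omit(as.vector(regions)))
  if (!all(labs %in% names(totals))) {
    stop_invalid("`totals` must name every region present in `regions`")
  }
  if (any(totals < 0)) stop_invalid("`totals` must be >= 0")
  if (is.null(weights)) {
    weights <- with_seed(seed, {
      exp(1.5 * gaussian_smooth(matrix(stats::rnorm(rows * cols), rows, cols), 1.5))
    })
  }
  if (!all(dim(weights) == c(rows, cols)) || any(weights < 0)) {
    stop_invalid("`weights` must be a non-negative matrix matching `grid_shape`")
  }
  counts <- matrix(0, rows, cols)
  for (lab in labs) {
    idx <- which(!is.na(regions) & regions == lab)
    counts[idx] <- largest_remainder(weights[idx], totals[[lab]])
  }
  counts
}

#' Generate regional demography tables (totals and age structure)
#'
#' Builds a plausible adult age-proportion vector over the 15 bands and
#' drifts it toward older bands at the scenario's aging rate; total
#' population compounds at the scenario's growth rate with mild per-region
#' level differences.
#'
#' @param regions character vector of region labels.
#' @param spec a [scenario_spec()] providing years, aging and growth rates.
#' @param seed integer seed.
#' @param base_pop baseline per-region population (persons) at the first
#'   scenario year.
#' @param tilt_offset accumulated aging tilt at the first scenario year
#'   (lets a projection continue smoothly from the end of a history
#'   generated with a nonzero aging rate).
#' @return Data frame with columns `region`, `year`, `scenario`, `age`,
#'   `pop` (regional total, repeated across bands) and `age_prop`
#'   (proportions summing to 1 within each region-year).
#' @export
generate_demography <- function(regions, spec, seed, base_pop = 2e7,
                                tilt_offset = 0) {
  stopifnot(inherits(spec, "scenario_spec"))
  bands <- age_bands()
  nb <- length(bands)
  # Gentle adult pyramid: near-flat through middle age, declining after ~60.
  base_profile <- exp(-((seq_len(nb) - 4) / 6)^2 / 2)
  base_profile <- base_profile / sum(base_profile)
  tilt <- (seq_len(nb) - 8) / 7  # -1 (youngest) .. +1 (oldest)
  years <- spec$years
  with_seed(seed, {
    region_level <- stats::setNames(
      exp(stats::rnorm(length(regions), 0, 0.3)), regions)
    out <- expand.grid(age = bands, year = years, region = regions,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    out <- out[, c("region", "year", "age")]
    out$scenario <- spec$name
    t_idx <- match(out$year, years) - 1L
    prop <- base_profile[match(out$age, bands)] *
      exp((tilt_offset + spec$aging_rate * t_idx) * tilt[match(out$age, bands)])
    # normalize within region-year
    key <- paste(out$region, out$year)
    prop <- prop / stats::ave(prop, key, FUN = sum)
    out$age_prop <- prop
    out$pop <- round(base_pop * region_level[out$region] *
                       (1 + spec$pop_growth)^t_idx)
    out[, c("region", "year", "scenario", "age", "pop", "age_prop")]
  })
}

#' Generate regional sociodemographic-index (SDI) series
#'
#' Smooth logistic development trajectories in \[0, 1\]: each region gets a
#' baseline level and a per-year logit-scale gain, so regions straddle the
#' 0.8 hinge knot over multi-decade histories.
#'
#' @param regions character vector of region labels.
#' @param years integer years.
#' @param seed integer seed.
#' @param start_range range of baseline SDI values regions are drawn from.
#' @param gain_range range of per-year logit-scale gains.
#' @return Data frame `region`, `year`, `sdi`.
#' @export
generate_sdi <- function(regions, years, seed,
                         start_range = c(0.5, 0.78),
                         gain_range = c(0.04, 0.10)) {
  with_seed(seed, {
    start <- stats::runif(length(regions), start_range[1], start_range[2])
    gain <- stats::runif(length(regions), gain_range[1], gain_range[2])
    out <- expand.grid(year = years, region = regions,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    i <- match(out$region, regions)
    t_idx <- out$year - years[1L]
    out$sdi <- stats::plogis(stats::qlogis(start[i]) + gain[i] * t_idx)
    out[, c("region", "year", "sdi")]
  })
}

#' Generate a cause-specific mortality history from the ground-truth model
#'
#' Leaf causes of the hierarchy (those without children, i.e. the level-3
#' causes and childless level-2 causes such as injuries) are simulated from
#' the hinged-SDI log-rate model with AR(1) residuals; parent causes are the
#' exact sums of their children, so hierarchy consistency holds by
#' construction and every parent strictly exceeds the sum of its named
#' children thanks to the positive "rest" causes.
#'
#' @param truth a [ground_truth()] object.
#' @param regions character vector of region labels.
#' @param years integer years (>= 10 for downstream identifiability).
#' @param sdi data frame `region`, `year`, `sdi` covering all region-years.
#' @param seed integer seed.
#' @param ages age-band labels (default the 15 standard bands).
#' @param hierarchy cause-hierarchy data frame (default [cause_hierarchy()]).
#' @param age_gradient per-band increment of the intercept with age (log
#'   scale); mortality rises steeply with age.
#' @param alpha_sd standard deviation of per-(region, age) intercept offsets.
#' @return A mortality table: data frame `region`, `year`, `cause`,
#'   `cause_level`, `parent`, `age`, `rate` (strictly positive person-year
#'   rates), with the realized per-stratum intercepts attached as
#'   `attr(, "alpha")`.
#' @export
generate_mortality_history <- function(truth, regions, years, sdi, seed,
                                       ages = age_bands(),
                                       hierarchy = cause_hierarchy(),
                                       age_gradient = 0.25,
                                       alpha_sd = 0.2) {
  stopifnot(inherits(truth, "ground_truth"))
  check_columns(sdi, c("region", "year", "sdi"), "`sdi`")
  if (any(sdi$sdi < 0 | sdi$sdi > 1)) stop_invalid("SDI values must lie in [0, 1]")
  if (length(years) < 10L) stop_invalid("need >= 10 years of history")
  leaves <- hierarchy$cause[!(hierarchy$cause %in% hierarchy$parent)]
  theta <- truth$theta_a
  if (length(theta) == 1L) theta <- stats::setNames(rep(theta, length(ages)), ages)
  if (!all(ages %in% names(theta))) {
    stop_invalid("`theta_a` must be scalar or named by every age band")
  }
  alpha_base <- truth$alpha
  if (length(alpha_base) == 1L) {
    alpha_base <- stats::setNames(rep(alpha_base, length(leaves)), leaves)
  }
  if (!all(leaves %in% names(alpha_base))) {
    stop_invalid("`alpha` must be scalar or named by every leaf cause")
  }
  phi <- truth$arima_params$phi
  sigma <- truth$arima_params$sigma
  ny <- length(years)

  sdi_key <- paste(sdi$region, sdi$year)
  grid <- expand.grid(year = years, age = ages, region = regions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  s <- sdi$sdi[match(paste(grid$region, grid$year), sdi_key)]
  if (anyNA(s)) stop_invalid("`sdi` must cover every region-year")
  h1 <- pmin(s, 0.8)
  h2 <- pmax(s - 0.8, 0)
  t_idx <- grid$year - years[1L]
  th <- theta[grid$age]
  n_strata <- length(regions) * length(ages)

  with_seed(seed, {
    alpha_tab <- expand.grid(age = ages, region = regions,
                             KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    out_list <- vector("list", length(leaves))
    for (k in seq_along(leaves)) {
      cz <- leaves[k]
      alpha_la <- alpha_base[[cz]] +
        age_gradient * (match(alpha_tab$age, ages) - 1L) +
        stats::rnorm(n_strata, 0, alpha_sd)
      # AR(1) residual per stratum over years (stationary start)
      eps <- matrix(0, n_strata, ny)
      if (sigma > 0) {
        innov <- matrix(stats::rnorm(n_strata * ny, 0, sigma), n_strata, ny)
        eps[, 1L] <- innov[, 1L] / sqrt(1 - phi^2)
        if (ny > 1L) for (y in 2L:ny) eps[, y] <- phi * eps[, y - 1L] + innov[, y]
      }
      stratum <- match(paste(grid$region, grid$age),
                       paste(alpha_tab$region, alpha_tab$age))
      log_rate <- truth$beta1 * h1 + truth$beta2 * h2 + th * t_idx +
        alpha_la[stratum] + eps[cbind(stratum, match(grid$year, years))]
      df <- grid
      df$cause <- cz
      df$rate <- exp(log_rate)
      out_list[[k]] <- df
      alpha_tab[[cz]] <- alpha_la
    }
    leaf_tab <- do.call(rbind, out_list)

    # Aggregate parents bottom-up (deepest level first): rates are additive
    # across causes, so each parent is the exact sum of its children.
    add_parent <- function(tab, parent_cause) {
      kids <- hierarchy$cause[!is.na(hierarchy$parent) &
                                hierarchy$parent == parent_cause]
      kid_rows <- tab[tab$cause %in% kids, ]
      if (!nrow(kid_rows)) return(tab)
      agg <- stats::aggregate(rate ~ region + year + age, data = kid_rows, FUN = sum)
      agg$cause <- parent_cause
      rbind(tab, agg[, names(tab)])
    }
    tab <- leaf_tab[, c("region", "year", "age", "cause", "rate")]
    parents <- unique(stats::na.omit(hierarchy$parent))
    parents <- parents[order(-hierarchy$level[match(parents, hierarchy$cause)])]
    for (p in parents) if (!(p %in% tab$cause)) tab <- add_parent(tab, p)
    tab$cause_level <- hierarchy$level[match(tab$cause, hierarchy$cause)]
    tab$parent <- hierarchy$parent[match(tab$cause, hierarchy$cause)]
    tab <- tab[order(tab$cause, tab$region, tab$age, tab$year),
               c("region", "year", "cause", "cause_level", "parent", "age", "rate")]
    rownames(tab) <- NULL
    attr(tab, "alpha") <- alpha_tab
    tab
  })
}

#' Generate tabulated exposure-response curves with draw ensembles
#'
#' Each curve is tabulated on a fixed concentration grid starting at 0 with
#' RR(0) = 1, is non-decreasing, and carries `n_draws` draw-level curves
#' scattering around the mean curve (each draw itself non-decreasing,
#' emulating an ensemble of curve fits).
#'
#' Shapes: `"concave"` (default) `RR(c) = 1 + a (1 - exp(-c / b))`, the
#' saturating form typical of fitted PM2.5 risk curves; `"loglinear"`
#' `RR(c) = exp(s c)`; `"flat"` `RR == 1`.
#'
#' @param diseases character vector of cause labels (default the six
#'   PM2.5-related causes).
#' @param seed integer seed.
#' @param ages age label(s) per curve; default a single "all-age" curve per
#'   disease.
#' @param shape curve shape, one of "concave", "loglinear", "flat".
#' @param shape_params optional named list per disease overriding defaults:
#'   for "concave" `list(a=, b=)`, for "loglinear" `list(s=)`.
#' @param n_draws number of draw curves (>= 2).
#' @param draw_sd log-scale spread of the per-draw shape perturbation.
#' @param grid concentration grid in ug/m^3, starting at 0.
#' @return A named list of [rr_curve()] objects (one per disease-age), class
#'   `rr_curve_set`.
#' @export
generate_rr_curves <- function(diseases = pm25_causes(), seed,
                               ages = "all-age",
                               shape = c("concave", "loglinear", "flat"),
                               shape_params = NULL,
                               n_draws = 100L, draw_sd = 0.15,
                               grid = seq(0, 150, by = 5)) {
  shape <- match.arg(shape)
  if (n_draws < 2L) stop_invalid("`n_draws` must be >= 2")
  default_a <- stats::setNames(
    rep(c(0.9, 1.2, 0.7, 0.5, 0.6, 0.4), length.out = length(diseases)),
    diseases)
  with_seed(seed, {
    curves <- list()
    for (dz in diseases) {
      pars <- shape_params[[dz]]
      for (ag in ages) {
        mean_rr <- switch(shape,
          flat = rep(1, length(grid)),
          loglinear = exp((if (is.null(pars$s)) 0.005 else pars$s) * grid),
          concave = {
            a <- if (is.null(pars$a)) default_a[[dz]] else pars$a
            b <- if (is.null(pars$b)) 40 else pars$b
            1 + a * (1 - exp(-grid / b))
          })
        draws <- NULL
        if (shape != "flat") {
          scale <- exp(stats::rnorm(n_draws, 0, draw_sd))
          draws <- 1 + outer(scale, mean_rr - 1)
        } else {
          draws <- matrix(1, n_draws, length(grid))
        }
        curves[[paste(dz, ag, sep = "|")]] <-
          rr_curve(dz, ag, grid, mean_rr, draws)
      }
    }
    structure(curves, class = "rr_curve_set")
  })
}
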