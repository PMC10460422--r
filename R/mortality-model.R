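# Cause-specific mortality forecasting: a hinged sociodemographic-index
# (SDI) regression of log death rates with per-age time trends and
# per-(region, age) intercepts, ARIMA-modelled residuals, prediction
# intervals on the log scale, and two-round constraining of forecasts to
# the cause-hierarchy envelope.

fit_key <- function(region, age) paste(region, age, sep = "|")

#' Fit the hinged-SDI mortality trend for one cause
#'
#' Least-squares fit of `ln(rate)` on a continuous linear spline in SDI
#' with a knot at `knot` (two slopes `beta1`/`beta2`, continuity enforced),
#' a per-age linear term in the year index, and a per-(region, age)
#' intercept. The SDI slopes are pooled across regions and ages ("global"
#' coefficients); region and age level differences are absorbed by the
#' intercepts. In-sample residuals are stored per stratum for residual
#' modelling.
#'
#' @param history mortality table (columns `region`, `year`, `cause`,
#'   `age`, `rate`) with strictly positive rates and >= 10 years per
#'   stratum.
#' @param sdi data frame `region`, `year`, `sdi`.
#' @param cause the cause label to fit.
#' @param knot SDI hinge knot (default 0.8).
#' @return An object of class `trend_fit`: `beta1`, `beta2`, `theta`
#'   (named by age), `alpha` (named by region|age stratum), `residuals`
#'   (data frame `region`, `age`, `year`, `resid`), `sigma`, plus the
#'   fitted `lm` object and bookkeeping needed for forecasting.
#' @export
fit_trend <- function(history, sdi, cause, knot = 0.8) {
  check_columns(history, c("region", "year", "cause", "age", "rate"), "`history`")
  check_columns(sdi, c("region", "year", "sdi"), "`sdi`")
  df <- history[history$cause == cause, ]
  if (!nrow(df)) stop_invalid("no rows for cause ", cause)
  if (any(df$rate <= 0)) {
    stop_invalid("rates must be strictly positive (log link)")
  }
  n_years <- tapply(df$year, fit_key(df$region, df$age),
                    function(y) length(unique(y)))
  if (any(n_years < 10L)) stop_invalid("need >= 10 years per stratum")
  s <- sdi$sdi[match(paste(df$region, df$year), paste(sdi$region, sdi$year))]
  if (anyNA(s)) stop_invalid("`sdi` must cover every region-year in the history")

  year0 <- min(df$year)
  age_levels <- unique(df$age)
  ord <- match(age_levels, age_bands())
  age_levels <- if (anyNA(ord)) sort(age_levels) else age_levels[order(ord)]
  key <- fit_key(df$region, df$age)
  strata_levels <- sort(unique(key))
  t_idx <- df$year - year0
  # explicit design columns (robust to single-level strata or ages)
  dat <- data.frame(log_rate = log(df$rate),
                    h1 = pmin(s, knot), h2 = pmax(s - knot, 0),
                    check.names = FALSE)
  for (ag in age_levels) dat[[paste0("th_", ag)]] <- t_idx * (df$age == ag)
  for (lab in strata_levels) dat[[paste0("a_", lab)]] <- as.numeric(key == lab)
  rhs <- paste(sprintf("`%s`", setdiff(names(dat), "log_rate")),
               collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste("log_rate ~ 0 +", rhs)), data = dat)
  cf <- stats::coef(fit)
  beta1 <- unname(cf["h1"]); beta2 <- unname(cf["h2"])
  pinned <- "none"
  if (is.na(beta2) && !is.na(beta1)) {
    warning("all SDI values on one side of the knot; beta2 pinned to beta1")
    beta2 <- beta1; pinned <- "beta2"
  } else if (is.na(beta1) && !is.na(beta2)) {
    warning("all SDI values on one side of the knot; beta1 pinned to beta2")
    beta1 <- beta2; pinned <- "beta1"
  }
  cn <- gsub("`", "", names(cf))
  theta <- cf[startsWith(cn, "th_")]
  names(theta) <- sub("^th_", "", gsub("`", "", names(theta)))
  alpha <- cf[startsWith(cn, "a_")]
  names(alpha) <- sub("^a_", "", gsub("`", "", names(alpha)))

  res <- data.frame(region = df$region, age = df$age, year = df$year,
                    resid = stats::residuals(fit))
  res <- res[order(res$region, res$age, res$year), ]
  rownames(res) <- NULL
  n <- nrow(dat)
  dfres <- fit$df.residual
  structure(
    list(cause = cause, knot = knot, year0 = year0,
         beta1 = beta1, beta2 = beta2, theta = theta, alpha = alpha,
         residuals = res,
         sigma = sqrt(sum(stats::residuals(fit)^2) / dfres),
         n = n, df_residual = dfres, pinned = pinned,
         sdi_mean = mean(s), sdi_ss = sum((s - mean(s))^2),
         last_year = max(df$year), age_levels = age_levels,
         strata_levels = strata_levels, lm = fit),
    class = "trend_fit"
  )
}

#' Fit a residual process model
#'
#' ARIMA of configurable order (default AR(1)) fit to a stratum's residual
#' series; a fit failure or a degenerate (zero-variance) series falls back
#' to a white-noise model with a warning. The returned model forecasts a
#' mean path and a standard-error path via [predict_residual()].
#'
#' @param residual_series numeric vector of in-sample residuals (>= 10).
#' @param order ARIMA order `c(p, d, q)`.
#' @return An object of class `residual_model`.
#' @export
fit_residual <- function(residual_series, order = c(1L, 0L, 0L)) {
  x <- as.numeric(residual_series)
  if (length(x) < 10L) stop_invalid("need >= 10 residuals")
  if (stats::sd(x) == 0) {
    return(structure(list(type = "white", sd = 0, mean = x[1L]),
                     class = "residual_model"))
  }
  fit <- tryCatch(
    stats::arima(x, order = order, include.mean = FALSE),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    warning("ARIMA fit did not converge; falling back to a white-noise model")
    return(structure(list(type = "white", sd = stats::sd(x), mean = 0),
                     class = "residual_model"))
  }
  structure(list(type = "arima", fit = fit, order = order),
            class = "residual_model")
}

#' Forecast a residual process
#'
#' @param model a [fit_residual()] result.
#' @param h forecast horizon (steps ahead).
#' @return List with numeric vectors `mean` and `se` of length `h`.
#' @export
predict_residual <- function(model, h) {
  stopifnot(inherits(model, "residual_model"))
  if (h < 1L) stop_invalid("`h` must be >= 1")
  if (model$type == "white") {
    return(list(mean = rep(model$mean, h), se = rep(model$sd, h)))
  }
  p <- stats::predict(model$fit, n.ahead = h)
  list(mean = as.numeric(p$pred), se = as.numeric(p$se))
}

#' Forecast cause-specific mortality rates with prediction intervals
#'
#' Point forecast `exp(yhat + eps_hat)` where `yhat` comes from the fitted
#' trend evaluated at the future SDI and year index and `eps_hat` is the
#' residual-model forecast. The interval is symmetric on the log scale:
#' `yhat + eps_hat +/- t * sqrt(pred_var)`. In mode `"standard"` the
#' prediction variance is the full-regression form
#' `s^2 (1 + x_f' (X'X)^{-1} x_f)` with `t` on the residual degrees of
#' freedom (this reduces to the textbook simple-regression formula
#' `s^2 (1 + 1/n + (x_f - xbar)^2 / Sxx)` when a single covariate is fit).
#' Mode `"as-printed"` instead uses the literal reduced form
#' `s^2 * (1/n) * (x_f - xbar)^2 / Sxx` with `x` = SDI and `t(n - 2)`,
#' offered for comparison.
#'
#' @param fit a [fit_trend()] result.
#' @param future_sdi data frame `region`, `year`, `sdi` for every forecast
#'   year (years after the last fitted year).
#' @param residual_models optional named list of [fit_residual()] models
#'   keyed `"region|age"`; fitted from the stored residuals when NULL.
#' @param order ARIMA order used when fitting residual models here.
#' @param ci_mode prediction-variance mode, see above.
#' @return Data frame `region`, `year`, `cause`, `cause_level`, `parent`,
#'   `age`, `rate`, `lower`, `upper`.
#' @export
forecast_rates <- function(fit, future_sdi, residual_models = NULL,
                           order = c(1L, 0L, 0L),
                           ci_mode = c("standard", "as-printed")) {
  stopifnot(inherits(fit, "trend_fit"))
  ci_mode <- match.arg(ci_mode)
  check_columns(future_sdi, c("region", "year", "sdi"), "`future_sdi`")
  strata <- unique(fit$residuals[, c("region", "age")])
  years <- sort(unique(future_sdi$year))
  horizons <- years - fit$last_year
  if (any(horizons < 1L)) stop_invalid("forecast years must follow the fitted span")

  if (is.null(residual_models)) {
    residual_models <- lapply(seq_len(nrow(strata)), function(i) {
      r <- fit$residuals
      fit_residual(r$resid[r$region == strata$region[i] &
                             r$age == strata$age[i]], order = order)
    })
    names(residual_models) <- fit_key(strata$region, strata$age)
  }

  out <- vector("list", nrow(strata))
  H <- max(horizons)
  for (i in seq_len(nrow(strata))) {
    rg <- strata$region[i]; ag <- strata$age[i]
    srows <- future_sdi[future_sdi$region == rg, ]
    s <- srows$sdi[match(years, srows$year)]
    if (anyNA(s)) stop_invalid("missing future SDI for region ", rg)
    nd <- data.frame(h1 = pmin(s, fit$knot), h2 = pmax(s - fit$knot, 0),
                     check.names = FALSE)
    t_f <- years - fit$year0
    for (a2 in fit$age_levels) {
      nd[[paste0("th_", a2)]] <- if (a2 == ag) t_f else 0
    }
    for (lab in fit$strata_levels) {
      nd[[paste0("a_", lab)]] <- as.numeric(lab == fit_key(rg, ag))
    }
    if (fit$pinned == "beta2") { nd$h1 <- nd$h1 + nd$h2; nd$h2 <- 0 }
    if (fit$pinned == "beta1") { nd$h2 <- nd$h1 + nd$h2; nd$h1 <- 0 }
    pr <- suppressWarnings(stats::predict(fit$lm, newdata = nd, se.fit = TRUE))
    eps <- predict_residual(residual_models[[fit_key(rg, ag)]], H)
    mu <- as.numeric(pr$fit) + eps$mean[horizons]
    if (ci_mode == "standard") {
      pred_var <- as.numeric(pr$se.fit)^2 + fit$sigma^2
      dfree <- fit$df_residual
    } else {
      pred_var <- fit$sigma^2 * (1 / fit$n) * (s - fit$sdi_mean)^2 / fit$sdi_ss
      dfree <- fit$n - 2L
    }
    half <- stats::qt(0.975, df = dfree) * sqrt(pred_var)
    out[[i]] <- data.frame(region = rg, year = years, cause = fit$cause,
                           age = ag, rate = exp(mu),
                           lower = exp(mu - half), upper = exp(mu + half),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  hier <- cause_hierarchy()
  res$cause_level <- hier$level[match(res$cause, hier$cause)]
  res$parent <- hier$parent[match(res$cause, hier$cause)]
  rownames(res) <- NULL
  res[, c("region", "year", "cause", "cause_level", "parent", "age",
          "rate", "lower", "upper")]
}

#' Fit and forecast every cause in a history
#'
#' Convenience wrapper: [fit_trend()] + [forecast_rates()] per cause, with
#' shared settings.
#'
#' @inheritParams fit_trend
#' @inheritParams forecast_rates
#' @param causes causes to forecast (default: all in the history).
#' @return Row-bound forecast table across causes.
#' @export
forecast_cause_rates <- function(history, sdi, future_sdi,
                                 causes = unique(history$cause),
                                 knot = 0.8, order = c(1L, 0L, 0L),
                                 ci_mode = c("standard", "as-printed")) {
  ci_mode <- match.arg(ci_mode)
  res <- lapply(causes, function(cz) {
    fit <- fit_trend(history, sdi, cz, knot = knot)
    forecast_rates(fit, future_sdi, order = order, ci_mode = ci_mode)
  })
  do.call(rbind, res)
}

# Common-factor rescaling of child rates toward a parent envelope, per key.
constrain_scale <- function(children, parent, keys, orientation) {
  pk <- do.call(paste, parent[keys])
  ck <- do.call(paste, children[keys])
  env <- parent$rate[match(ck, pk)]
  if (anyNA(env)) stop_invalid("envelope missing for some strata")
  if (any(env <= 0)) stop_invalid("envelope must be > 0")
  tot <- stats::ave(children$rate, ck, FUN = sum)
  if (any(tot <= 0)) stop_undefined("child rates sum to zero; factor undefined")
  f <- if (orientation == "envelope") env / tot else tot / env
  for (col in intersect(c("rate", "lower", "upper"), names(children))) {
    children[[col]] <- children[[col]] * f
  }
  children
}

#' Constrain level-2 rates to the all-cause envelope
#'
#' Rescales the level-2 cause rates (NCD, CMNND, injuries) by a common
#' factor per stratum. The default orientation `"envelope"` uses
#' `factor = envelope / sum(level-2 rates)` so the constrained rates sum
#' exactly to the all-cause envelope, which is the stated purpose of the
#' constraining step; orientation `"as-printed"` applies the literal
#' published factor `sum(level-2 rates) / envelope` (which scales away from
#' the envelope whenever the children exceed it) for comparison.
#'
#' @param level2 mortality table of level-2 causes (column `rate`, plus
#'   optional `lower`/`upper` rescaled by the same factor).
#' @param envelope all-cause mortality table (column `rate`, > 0).
#' @param keys join keys; defaults to the shared identifier columns among
#'   `region`, `year`, `scenario`, `age`.
#' @param orientation `"envelope"` (default) or `"as-printed"`.
#' @return `level2` with rescaled rates.
#' @export
constrain_level2 <- function(level2, envelope,
                             keys = NULL,
                             orientation = c("envelope", "as-printed")) {
  orientation <- match.arg(orientation)
  if (is.null(keys)) {
    keys <- intersect(c("region", "year", "scenario", "age"),
                      intersect(names(level2), names(envelope)))
  }
  if (!length(keys)) stop_invalid("no join keys between level-2 table and envelope")
  constrain_scale(level2, envelope, keys, orientation)
}

#' Constrain level-3 rates (including the rest-cause) to their parent
#'
#' Same common-factor rescaling as [constrain_level2()], applied within
#' each level-2 parent so children (named causes plus the explicit "rest"
#' cause) sum exactly to the constrained parent rate.
#'
#' @param level3 mortality table of one parent's children.
#' @param parent_constrained the parent's constrained mortality table.
#' @inheritParams constrain_level2
#' @return `level3` with rescaled rates.
#' @export
constrain_level3 <- function(level3, parent_constrained,
                             keys = NULL,
                             orientation = c("envelope", "as-printed")) {
  orientation <- match.arg(orientation)
  if (is.null(keys)) {
    keys <- intersect(c("region", "year", "scenario", "age"),
                      intersect(names(level3), names(parent_constrained)))
  }
  if (!length(keys)) stop_invalid("no join keys between level-3 table and parent")
  constrain_scale(level3, parent_constrained, keys, orientation)
}

#' Two-round envelope constraining of a full hierarchy table
#'
#' Round 1 constrains the level-2 causes to the level-1 (all-cause)
#' envelope; round 2 constrains each level-2 parent's children (including
#' rest-causes) to the constrained parent. Parents without modelled
#' children (e.g. injuries) are unaffected by round 2.
#'
#' @param tbl mortality table with `cause`, `cause_level`, `parent` and
#'   `rate` columns covering all three levels.
#' @inheritParams constrain_level2
#' @return The table with levels 2 and 3 constrained.
#' @export
constrain_hierarchy <- function(tbl, orientation = c("envelope", "as-printed")) {
  orientation <- match.arg(orientation)
  check_columns(tbl, c("cause", "cause_level", "parent", "rate"), "`tbl`")
  l1 <- tbl[tbl$cause_level == 1L, ]
  l2 <- tbl[tbl$cause_level == 2L, ]
  l3 <- tbl[tbl$cause_level == 3L, ]
  if (!nrow(l1) || !nrow(l2)) stop_invalid("hierarchy table must hold levels 1 and 2")
  l2c <- constrain_level2(l2, l1, orientation = orientation)
  parts <- list(l1, l2c)
  for (p in unique(l3$parent)) {
    kids <- l3[l3$parent == p, ]
    parts[[length(parts) + 1L]] <-
      constrain_level3(kids, l2c[l2c$cause == p, ], orientation = orientation)
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
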