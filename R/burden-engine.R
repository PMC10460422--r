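# Attributable-death assembly: PAF x population x mortality rate x age
# structure summed over age bands and causes, with interval propagation and
# reporting summaries.

#' Compute deaths attributable to PM2.5 by stratum
#'
#' Per stratum (region, year, scenario, disease, age band),
#' `deaths = PAF * POP * Rate * AgeP`. Interval propagation follows simple
#' bound combination: the lower bound evaluates the product with every
#' input at its lower bound, and analogously for the upper bound (inputs
#' without bounds contribute their point value). A Monte-Carlo mode is
#' provided for comparison: it treats the supplied bounds as 95% intervals
#' (normal on the PAF scale truncated to \[0, 1); log-normal for rates) and
#' reports empirical 2.5%/97.5% quantiles of the product.
#'
#' @param paf PAF table: `region`, `year`, `scenario`, `disease`, `age`,
#'   `paf`, optionally `paf_lower`, `paf_upper`.
#' @param demog demography table: `region`, `year`, `scenario`, `age`,
#'   `pop`, `age_prop`.
#' @param rates mortality table: `region`, `year`, `cause`, `age`, `rate`,
#'   optionally `lower`, `upper` (and optionally `scenario`).
#' @param causes causes to include (default the six PM2.5-related causes).
#' @param interval `"bounds"` (default) or `"montecarlo"`.
#' @param n_mc Monte-Carlo sample size per stratum.
#' @param seed seed for the Monte-Carlo mode.
#' @return Data frame of class `burden_result`: stratum identifiers plus
#'   `deaths`, `deaths_lower`, `deaths_upper` (persons/year).
#' @export
compute_dapp <- function(paf, demog, rates, causes = pm25_causes(),
                         interval = c("bounds", "montecarlo"),
                         n_mc = 500L, seed = 1L) {
  interval <- match.arg(interval)
  check_columns(paf, c("region", "year", "scenario", "disease", "age", "paf"),
                "`paf`")
  check_columns(demog, c("region", "year", "scenario", "age", "pop", "age_prop"),
                "`demog`")
  check_columns(rates, c("region", "year", "cause", "age", "rate"), "`rates`")
  out <- paf[paf$disease %in% causes, ]
  if (!nrow(out)) stop_invalid("no PAF rows for the requested causes")

  dkey <- paste(demog$region, demog$year, demog$scenario, demog$age)
  di <- match(paste(out$region, out$year, out$scenario, out$age), dkey)
  if (anyNA(di)) {
    stop_invalid(sum(is.na(di)), " PAF strata missing from the demography table")
  }
  # rates without a scenario column are scenario-invariant (e.g. history)
  ri <- if ("scenario" %in% names(rates)) {
    match(paste(out$region, out$year, out$scenario, out$disease, out$age),
          paste(rates$region, rates$year, rates$scenario, rates$cause, rates$age))
  } else {
    match(paste(out$region, out$year, out$disease, out$age),
          paste(rates$region, rates$year, rates$cause, rates$age))
  }
  if (anyNA(ri)) {
    stop_invalid(sum(is.na(ri)), " PAF strata missing from the mortality table")
  }

  pop <- demog$pop[di]; agep <- demog$age_prop[di]
  rate <- rates$rate[ri]
  rate_lo <- if ("lower" %in% names(rates)) rates$lower[ri] else rate
  rate_hi <- if ("upper" %in% names(rates)) rates$upper[ri] else rate
  paf_lo <- if ("paf_lower" %in% names(out)) out$paf_lower else out$paf
  paf_hi <- if ("paf_upper" %in% names(out)) out$paf_upper else out$paf

  out$deaths <- out$paf * pop * rate * agep
  if (interval == "bounds") {
    out$deaths_lower <- paf_lo * pop * rate_lo * agep
    out$deaths_upper <- paf_hi * pop * rate_hi * agep
  } else {
    qs <- with_seed(seed, {
      n <- nrow(out)
      lo <- hi <- numeric(n)
      for (i in seq_len(n)) {
        paf_sd <- (paf_hi[i] - paf_lo[i]) / (2 * stats::qnorm(0.975))
        p_mc <- pmin(pmax(stats::rnorm(n_mc, out$paf[i], paf_sd), 0), 1 - 1e-12)
        lsd <- (log(rate_hi[i]) - log(rate_lo[i])) / (2 * stats::qnorm(0.975))
        if (!is.finite(lsd)) lsd <- 0
        r_mc <- exp(stats::rnorm(n_mc, log(rate[i]), lsd))
        d <- p_mc * pop[i] * r_mc * agep[i]
        q <- stats::quantile(d, c(0.025, 0.975), names = FALSE)
        lo[i] <- q[1L]; hi[i] <- q[2L]
      }
      list(lo = lo, hi = hi)
    })
    out$deaths_lower <- qs$lo
    out$deaths_upper <- qs$hi
  }
  keep <- c("region", "year", "scenario", "disease", "age",
            "deaths", "deaths_lower", "deaths_upper")
  res <- out[, keep]
  rownames(res) <- NULL
  class(res) <- c("burden_result", "data.frame")
  attr(res, "interval_mode") <- interval
  res
}

#' Aggregate attributable deaths over strata
#'
#' @param burden a [compute_dapp()] result.
#' @param by grouping columns (default region/year/scenario).
#' @return Data frame of summed `deaths`, `deaths_lower`, `deaths_upper`.
#' @export
dapp_total <- function(burden, by = c("region", "year", "scenario")) {
  check_columns(burden, c(by, "deaths"), "`burden`")
  cols <- intersect(c("deaths", "deaths_lower", "deaths_upper"), names(burden))
  stats::aggregate(burden[cols], burden[by], FUN = sum)
}

#' Attributable deaths per 100,000 persons
#'
#' @param burden a [compute_dapp()] result.
#' @param demog demography table providing regional totals.
#' @param by grouping columns identifying one population total each.
#' @return Data frame with `deaths_per_100k` (and bounds when present).
#' @export
per_capita <- function(burden, demog, by = c("region", "year", "scenario")) {
  tot <- dapp_total(burden, by = by)
  dpop <- unique(demog[, c(by, "pop")])
  key <- do.call(paste, dpop[by])
  p <- dpop$pop[match(do.call(paste, tot[by]), key)]
  if (anyNA(p)) stop_invalid("demography does not cover every burden group")
  bad <- p == 0
  if (any(bad)) {
    warn_undefined("zero population in ", sum(bad), " group(s); per-capita undefined")
    p[bad] <- NA_real_
  }
  for (col in intersect(c("deaths", "deaths_lower", "deaths_upper"), names(tot))) {
    tot[[sub("deaths", "deaths_per_100k", col)]] <- tot[[col]] / p * 1e5
  }
  tot
}

#' Share of attributable deaths among older adults, by disease
#'
#' Fraction of each disease's attributable deaths occurring in the age
#' bands at or above 65 years.
#'
#' @param burden a [compute_dapp()] result.
#' @param older age bands counted as older (default [older_bands()]).
#' @param by grouping columns (default disease/year/scenario).
#' @return Data frame with column `older_share` in \[0, 1\] (NA with a
#'   warning where a group has zero deaths).
#' @export
older_share_by_disease <- function(burden, older = older_bands(),
                                   by = c("disease", "year", "scenario")) {
  check_columns(burden, c(by, "age", "deaths"), "`burden`")
  tot <- stats::aggregate(burden["deaths"], burden[by], FUN = sum)
  old <- burden[burden$age %in% older, ]
  if (nrow(old)) {
    otot <- stats::aggregate(old["deaths"], old[by], FUN = sum)
    key <- do.call(paste, otot[by])
    onum <- otot$deaths[match(do.call(paste, tot[by]), key)]
    onum[is.na(onum)] <- 0
  } else {
    onum <- rep(0, nrow(tot))
  }
  bad <- tot$deaths == 0
  if (any(bad)) {
    warn_undefined("zero total deaths in ", sum(bad), " group(s); share undefined")
  }
  tot$older_share <- ifelse(bad, NA_real_, onum / tot$deaths)
  tot$deaths <- NULL
  tot
}

#' Centered moving-average smoothing for reporting series
#'
#' Applies a centered moving mean (default window 5 years, shrinking at the
#' series ends) to the value columns within each group, as a reporting-layer
#' smoother of annual outputs.
#'
#' @param df data frame with a `year` column.
#' @param value_cols columns to smooth.
#' @param by grouping columns (default all non-year, non-value columns).
#' @param window odd window length in years.
#' @return `df` with smoothed value columns, ordered by group and year.
#' @export
smooth_reporting <- function(df, value_cols, by = NULL, window = 5L) {
  check_columns(df, c("year", value_cols), "`df`")
  if (is.null(by)) by <- setdiff(names(df), c("year", value_cols))
  key <- if (length(by)) do.call(paste, df[by]) else rep("all", nrow(df))
  df <- df[order(key, df$year), ]
  key <- if (length(by)) do.call(paste, df[by]) else rep("all", nrow(df))
  for (col in value_cols) {
    df[[col]] <- stats::ave(df[[col]], key,
                            FUN = function(x) roll_mean_partial(x, window))
  }
  rownames(df) <- NULL
  df
}

#' Summarize values across regions
#'
#' Regional roll-ups are reported either as sums (totals such as deaths) or
#' as means across regions (per-capita-style quantities).
#'
#' @param df data frame with a `region` column.
#' @param value_cols columns to aggregate.
#' @param mode `"sum"` or `"mean"`.
#' @param by residual grouping columns (default year and scenario where
#'   present).
#' @return Aggregated data frame without the region column.
#' @export
summarize_regions <- function(df, value_cols, mode = c("sum", "mean"),
                              by = intersect(c("year", "scenario"), names(df))) {
  mode <- match.arg(mode)
  check_columns(df, c("region", value_cols), "`df`")
  fun <- if (mode == "sum") sum else mean
  stats::aggregate(df[value_cols], df[by], FUN = fun)
}
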