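# From aerosol component fields to calibrated PM2.5 and region-level
# population-weighted exposure with multi-model uncertainty.

#' Construct a gridded PM2.5 concentration field
#'
#' @param values numeric array with dim `(member, year, lat, lon)`.
#' @param years integer years (length = dim 2).
#' @param lat,lon cell-center coordinates (ascending; lon in \[-180, 180)).
#' @param calibrated logical flag; calibrated fields must record their
#'   baseline window.
#' @param baseline_window year range used for calibration (length-2), or NULL.
#' @param n_masked count of cells masked during calibration.
#' @return An object of class `conc_field`.
#' @export
conc_field <- function(values, years, lat, lon, calibrated = FALSE,
                       baseline_window = NULL, n_masked = 0L) {
  if (length(dim(values)) != 4L) {
    stop_invalid("`values` must be a 4-d array (member, year, lat, lon)")
  }
  if (dim(values)[2L] != length(years)) {
    stop_invalid("year dimension does not match `years`")
  }
  if (any(values < 0, na.rm = TRUE)) stop_invalid("concentrations must be >= 0")
  if (calibrated && is.null(baseline_window)) {
    stop_invalid("a calibrated field must record its baseline window")
  }
  structure(
    list(values = values, years = as.integer(years), lat = lat, lon = lon,
         calibrated = calibrated, baseline_window = baseline_window,
         n_masked = as.integer(n_masked)),
    class = "conc_field"
  )
}

#' Impute ammonium from sulfate
#'
#' Ammonium is assumed to exist only as ammonium sulfate, so its
#' concentration follows from sulfate by the molar-mass ratio
#' `NH4 = 36 * SO4 / 96`.
#'
#' @param so4 sulfate concentration(s) in ug/m^3 (>= 0).
#' @return Ammonium concentration(s) in ug/m^3.
#' @export
#' @examples
#' impute_nh4(96) # 36
impute_nh4 <- function(so4) {
  if (any(so4 < 0, na.rm = TRUE)) stop_invalid("SO4 must be >= 0")
  36 * so4 / 96
}

#' Compose surface PM2.5 from aerosol components
#'
#' Per cell, `PM2.5 = BC + OA + SO4 + NH4 + 0.25 * SS + 0.1 * dust`, with
#' ammonium imputed from sulfate via [impute_nh4()]. The sea-salt and dust
#' coefficients down-weight the coarse fractions of those species. The
#' output field is uncalibrated.
#'
#' @param fields an `aerosol_fields` object (see
#'   [generate_aerosol_fields()]); the `dust` component may be absent, in
#'   which case it is treated as zero with a warning.
#' @return A [conc_field()] with the same members, years and grid.
#' @export
compose_pm25 <- function(fields) {
  stopifnot(inherits(fields, "aerosol_fields"))
  comp <- fields$components
  need <- c("BC", "OA", "SO4", "SS")
  if (!all(need %in% names(comp))) {
    stop_invalid("aerosol fields must include BC, OA, SO4, SS")
  }
  if (is.null(comp$dust)) {
    warning("no dust component supplied; treating dust as zero")
    comp$dust <- array(0, dim = dim(comp$BC))
  }
  for (nm in c(need, "dust")) {
    if (any(comp[[nm]] < 0)) stop_invalid("negative ", nm, " concentration")
  }
  pm <- comp$BC + comp$OA + comp$SO4 + impute_nh4(comp$SO4) +
    0.25 * comp$SS + 0.1 * comp$dust
  conc_field(pm, fields$years, fields$lat, fields$lon, calibrated = FALSE)
}

# Multi-year (and optionally multi-member) mean of a conc_field over a window.
baseline_mean <- function(field, window, collapse_members = TRUE) {
  yrs <- which(field$years >= window[1L] & field$years <= window[2L])
  if (!length(yrs)) stop_invalid("field does not cover the baseline window")
  v <- field$values[, yrs, , , drop = FALSE]
  if (collapse_members) {
    apply(v, c(3L, 4L), mean)
  } else {
    apply(v, c(1L, 3L, 4L), mean)
  }
}

#' Calibrate a modelled PM2.5 field against baseline observations
#'
#' Per cell, `calibrated = obs_baseline * future_est / est_baseline`, where
#' the baseline quantities are multi-year means over the window. If the
#' estimated baseline covers the same ensemble members as the future field,
#' the ratio is applied member-wise (preserving spread); otherwise the
#' ensemble-mean baseline is used for all members. Cells where the
#' estimated baseline is zero but the observed baseline is positive are
#' masked (`NA`) and counted rather than crashing the aggregation; cells
#' where both are zero stay zero.
#'
#' @param future_est uncalibrated future [conc_field()].
#' @param baseline_est modelled [conc_field()] covering the baseline window.
#' @param baseline_obs observed [conc_field()] covering the same window
#'   (typically a single "member").
#' @param window length-2 year range; default 2015--2019 (an alternative
#'   window such as 2012--2019 may be supplied).
#' @return A calibrated [conc_field()]; masked-cell count in `n_masked`.
#' @export
calibrate_pm25 <- function(future_est, baseline_est, baseline_obs,
                           window = c(2015L, 2019L)) {
  stopifnot(inherits(future_est, "conc_field"),
            inherits(baseline_est, "conc_field"),
            inherits(baseline_obs, "conc_field"))
  if (!identical(dim(future_est$values)[3:4], dim(baseline_est$values)[3:4]) ||
      !identical(dim(future_est$values)[3:4], dim(baseline_obs$values)[3:4])) {
    stop_invalid("calibration fields must share one grid")
  }
  obs <- baseline_mean(baseline_obs, window)
  nm <- dim(future_est$values)[1L]
  memberwise <- dim(baseline_est$values)[1L] == nm && nm > 1L
  est <- if (memberwise) {
    baseline_mean(baseline_est, window, collapse_members = FALSE)
  } else {
    baseline_mean(baseline_est, window)
  }

  vals <- future_est$values
  ny <- dim(vals)[2L]
  n_masked <- 0L
  for (m in seq_len(nm)) {
    est_m <- if (memberwise) est[m, , ] else est
    bad <- est_m == 0 & obs > 0
    both_zero <- est_m == 0 & obs == 0
    n_masked <- n_masked + sum(bad)
    for (y in seq_len(ny)) {
      # obs * (future/est): when future == est the ratio is exactly 1,
      # so the identity case reproduces the observation field bit-exactly
      v <- obs * (vals[m, y, , ] / est_m)
      v[both_zero] <- 0
      v[bad] <- NA_real_
      vals[m, y, , ] <- v
    }
  }
  if (n_masked > 0) {
    warning(sprintf("calibration masked %d cell(s) with zero baseline estimate",
                    n_masked))
  }
  conc_field(vals, future_est$years, future_est$lat, future_est$lon,
             calibrated = TRUE, baseline_window = window, n_masked = n_masked)
}

#' Regrid an intensive (concentration) field by bilinear interpolation
#'
#' @param mat matrix of values on the source grid (rows = lat, cols = lon).
#' @param src_lat,src_lon ascending cell-center coordinates of the source.
#' @param dst_lat,dst_lon ascending cell-center coordinates of the target.
#' @return Matrix on the target grid. Target points outside the span of the
#'   source centers are clamped to the boundary (flat edge extension);
#'   fully non-overlapping domains are an error.
#' @export
regrid_concentration <- function(mat, src_lat, src_lon, dst_lat, dst_lon) {
  if (max(dst_lat) < min(src_lat) || min(dst_lat) > max(src_lat) ||
      max(dst_lon) < min(src_lon) || min(dst_lon) > max(src_lon)) {
    stop_invalid("source and target domains do not overlap")
  }
  yp <- pmin(pmax(dst_lat, min(src_lat)), max(src_lat))
  xp <- pmin(pmax(dst_lon, min(src_lon)), max(src_lon))
  pts <- expand.grid(y = yp, x = xp, KEEP.OUT.ATTRS = FALSE)
  z <- pracma::interp2(x = src_lon, y = src_lat, Z = mat,
                       xp = pts$x, yp = pts$y, method = "linear")
  matrix(z, nrow = length(dst_lat), ncol = length(dst_lon))
}

# Overlap-fraction allocation matrix along one axis: rows index target
# cells, columns source cells; each source column sums to 1 when the target
# grid covers the source cell.
overlap_matrix <- function(src_centers, dst_centers) {
  edges <- function(centers, span = NULL) {
    if (length(centers) == 1L) {
      # degenerate axis: a single cell is taken to cover the full span of
      # the other grid (collapse), or unit width when no span is known
      if (!is.null(span)) return(span)
      return(c(centers - 0.5, centers + 0.5))
    }
    mid <- (centers[-1] + centers[-length(centers)]) / 2
    c(2 * centers[1] - mid[1], mid,
      2 * centers[length(centers)] - mid[length(mid)])
  }
  se <- edges(src_centers)
  de <- edges(dst_centers, span = range(se))
  ns <- length(src_centers); nd <- length(dst_centers)
  A <- matrix(0, nd, ns)
  for (j in seq_len(ns)) {
    w <- se[j + 1L] - se[j]
    for (i in seq_len(nd)) {
      ov <- min(se[j + 1L], de[i + 1L]) - max(se[j], de[i])
      if (ov > 0) A[i, j] <- ov / w
    }
  }
  A
}

#' Regrid an extensive (count) field conservatively
#'
#' Population counts are reallocated in proportion to cell-area overlap, so
#' the global sum is preserved whenever the target grid covers the source
#' domain (checked to 1e-9 relative; a warning is raised otherwise).
#'
#' @inheritParams regrid_concentration
#' @return Matrix of counts on the target grid.
#' @export
regrid_population <- function(mat, src_lat, src_lon, dst_lat, dst_lon) {
  if (max(dst_lat) < min(src_lat) || min(dst_lat) > max(src_lat) ||
      max(dst_lon) < min(src_lon) || min(dst_lon) > max(src_lon)) {
    stop_invalid("source and target domains do not overlap")
  }
  A_lat <- overlap_matrix(src_lat, dst_lat)
  A_lon <- overlap_matrix(src_lon, dst_lon)
  out <- A_lat %*% mat %*% t(A_lon)
  tot_in <- sum(mat); tot_out <- sum(out)
  if (tot_in > 0 && abs(tot_out - tot_in) > 1e-9 * tot_in) {
    warning(sprintf(
      "target grid does not fully cover the source: %.6g of %.6g persons retained",
      tot_out, tot_in))
  }
  out
}

#' Population-weighted mean concentration per region
#'
#' `sum(pop * conc) / sum(pop)` over the grid cells of each region. With a
#' `conc_field` input the weighting is applied per member and year,
#' returning a tidy series.
#'
#' @param conc a matrix (single field) or a [conc_field()].
#' @param pop numeric matrix of per-cell person counts on the same grid.
#' @param regions character matrix of region labels (`NA` = masked).
#' @return For a matrix input, a data frame `region`, `conc`; for a
#'   `conc_field`, a data frame `member`, `year`, `region`, `conc`. Regions
#'   with zero population get `NA` with an `undefined_value` warning.
#' @export
population_weighted_concentration <- function(conc, pop, regions) {
  if (inherits(conc, "conc_field")) {
    d <- dim(conc$values)
    out <- vector("list", d[1L] * d[2L])
    k <- 0L
    for (m in seq_len(d[1L])) {
      for (y in seq_len(d[2L])) {
        pw <- population_weighted_concentration(conc$values[m, y, , ], pop, regions)
        k <- k + 1L
        out[[k]] <- cbind(member = m, year = conc$years[y], pw)
      }
    }
    return(do.call(rbind, out))
  }
  if (!all(dim(conc) == dim(pop)) || !all(dim(conc) == dim(regions))) {
    stop_invalid("concentration, population and region rasters must share a grid")
  }
  labs <- unique(stats::na.omit(as.vector(regions)))
  vals <- vapply(labs, function(lab) {
    idx <- !is.na(regions) & regions == lab & !is.na(conc)
    w <- sum(pop[idx])
    if (w <= 0) {
      warn_undefined("region ", lab, " has zero population; weighted mean undefined")
      return(NA_real_)
    }
    sum(pop[idx] * conc[idx]) / w
  }, numeric(1))
  data.frame(region = labs, conc = unname(vals), stringsAsFactors = FALSE)
}

#' Multi-model uncertainty interval for an ensemble of scalars
#'
#' Default mode `"as-reported"` computes `mean +/- sd * t_0.975(n - 1)`,
#' i.e. a t interval on the ensemble spread without the 1/sqrt(n)
#' standard-error factor; mode `"standard-error"` provides the textbook
#' t interval on the mean (`sd / sqrt(n)`).
#'
#' @param member_values numeric vector of per-member values (n >= 2 for
#'   finite bounds; n < 2 yields infinite bounds with a warning).
#' @param mode interval mode, see above.
#' @return List of class `uncertainty_interval` with `mean`, `lower`,
#'   `upper`, `n`.
#' @export
#' @examples
#' ensemble_interval(c(0, 2))
ensemble_interval <- function(member_values,
                              mode = c("as-reported", "standard-error")) {
  mode <- match.arg(mode)
  x <- member_values[is.finite(member_values)]
  n <- length(x)
  m <- if (n) mean(x) else NA_real_
  if (n < 2L) {
    warning("fewer than 2 ensemble members; interval is degenerate")
    half <- Inf
  } else {
    spread <- sqrt(stats::var(x))
    if (mode == "standard-error") spread <- spread / sqrt(n)
    half <- spread * stats::qt(0.975, df = n - 1L)
  }
  structure(list(mean = m, lower = m - half, upper = m + half, n = n),
            class = "uncertainty_interval")
}
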