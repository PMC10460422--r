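# Relative risk and population attributable fraction from tabulated
# exposure-response curves with draw-based uncertainty. Curves are always
# consumed as tables (the meta-regression that produces them is upstream of
# this package).

#' Construct a tabulated exposure-response curve
#'
#' The curve maps PM2.5 concentration to relative risk (RR) on an ordered
#' grid starting at 0 ug/m^3 with RR(0) = 1. Construction floors sub-unity
#' values at 1 and monotonizes via a running maximum (counts of both
#' adjustments are retained), so all stored RR values are >= 1 and
#' non-decreasing, as required by the attributable-fraction arithmetic.
#'
#' @param disease cause label.
#' @param age age-band label, or "all-age" for causes without age-specific
#'   curves.
#' @param grid strictly increasing concentrations in ug/m^3, `grid[1] == 0`.
#' @param mean_rr RR values on the grid (mean curve).
#' @param draws optional matrix of draw-level RR values, one row per draw,
#'   columns matching `grid`.
#' @return An object of class `rr_curve` with fields `disease`, `age`,
#'   `grid`, `mean_rr`, `draws`, `n_floored`, `n_monotonized`.
#' @export
rr_curve <- function(disease, age, grid, mean_rr, draws = NULL) {
  if (length(grid) < 2L || any(diff(grid) <= 0) || grid[1L] != 0) {
    stop_invalid("`grid` must be strictly increasing and start at 0")
  }
  if (length(mean_rr) != length(grid)) {
    stop_invalid("`mean_rr` length must match `grid`")
  }
  fix <- function(v) {
    floored <- sum(v < 1)
    v <- pmax(v, 1)
    mono <- cummax(v)
    list(v = mono, floored = floored, monotonized = sum(mono != v))
  }
  mfix <- fix(mean_rr)
  if (mfix$v[1L] != 1) stop_invalid("RR at 0 ug/m^3 must equal 1")
  n_floored <- mfix$floored
  n_mono <- mfix$monotonized
  if (!is.null(draws)) {
    draws <- as.matrix(draws)
    if (ncol(draws) != length(grid) || nrow(draws) < 2L) {
      stop_invalid("`draws` must have >= 2 rows and columns matching `grid`")
    }
    for (i in seq_len(nrow(draws))) {
      dfix <- fix(draws[i, ])
      if (dfix$v[1L] != 1) stop_invalid("every draw must have RR(0) = 1")
      draws[i, ] <- dfix$v
      n_floored <- n_floored + dfix$floored
      n_mono <- n_mono + dfix$monotonized
    }
  }
  structure(
    list(disease = disease, age = age, grid = grid, mean_rr = mfix$v,
         draws = draws, n_floored = n_floored, n_monotonized = n_mono),
    class = "rr_curve"
  )
}

#' Evaluate relative risk at a concentration
#'
#' Linear interpolation between grid nodes; flat extrapolation beyond the
#' last node (risk is not extrapolated upward past the tabulated range).
#'
#' @param curve an [rr_curve()].
#' @param concentration PM2.5 concentration(s) in ug/m^3 (>= 0).
#' @param draw optional draw index; default evaluates the mean curve.
#' @return Relative risk value(s), always >= 1.
#' @export
#' @examples
#' cv <- rr_curve("IHD", "all-age", c(0, 10, 20), c(1, 1.2, 1.4))
#' relative_risk(cv, 15) # 1.3
relative_risk <- function(curve, concentration, draw = NULL) {
  stopifnot(inherits(curve, "rr_curve"))
  if (any(concentration < 0)) stop_invalid("concentration must be >= 0")
  vals <- if (is.null(draw)) curve$mean_rr else {
    if (draw < 1 || draw > nrow(curve$draws)) stop_invalid("draw index out of range")
    curve$draws[draw, ]
  }
  stats::approx(curve$grid, vals, xout = concentration, rule = 2)$y
}

#' Population attributable fraction from relative risk
#'
#' `PAF = (RR - 1) / RR`, strictly increasing in RR and bounded in \[0, 1).
#'
#' @param rr relative risk value(s), each >= 1.
#' @return Attributable fraction(s).
#' @export
#' @examples
#' paf(2) # 0.5
paf <- function(rr) {
  if (any(rr < 1)) stop_invalid("PAF requires RR >= 1")
  (rr - 1) / rr
}

#' Empirical 95% interval over curve-fit draws
#'
#' The 2.5th and 97.5th percentiles of the per-draw values under the
#' linear-interpolation quantile definition (type 7), around a central
#' value (default the draw mean; pass the mean-curve result via `center` to
#' report the interval around it).
#'
#' @param per_draw_values numeric vector (>= 2 draws).
#' @param center central value; default `mean(per_draw_values)`.
#' @return List of class `uncertainty_interval` (`mean`, `lower`, `upper`,
#'   `n`).
#' @export
draw_quantile_interval <- function(per_draw_values, center = NULL) {
  if (length(per_draw_values) < 2L) stop_invalid("need >= 2 draws")
  q <- stats::quantile(per_draw_values, c(0.025, 0.975), names = FALSE, type = 7)
  m <- if (is.null(center)) mean(per_draw_values) else center
  structure(list(mean = m, lower = q[1L], upper = q[2L],
                 n = length(per_draw_values)),
            class = "uncertainty_interval")
}

#' Build a PAF table from curves and region-level exposure
#'
#' Evaluates each curve at the region-level population-weighted
#' concentration (the default exposure assignment; per-cell evaluation is
#' available upstream by passing cell-level "regions"). The mean PAF comes
#' from the mean curve at the mean concentration; the bounds combine the
#' draw ensemble's 2.5%/97.5% RR quantiles with the concentration bounds
#' comonotonically (lower RR quantile at the lower concentration bound,
#' upper at upper). Draw RRs below 1 are floored at 1 before the PAF
#' transform, with a message reporting the count.
#'
#' @param curves an `rr_curve_set` (named list of [rr_curve()]s) or a single
#'   curve.
#' @param exposure data frame with columns `region`, `year`, `scenario`,
#'   `conc` and optionally `conc_lower`, `conc_upper`.
#' @param ages age bands to expand "all-age" curves over (default the 15
#'   standard bands).
#' @return Data frame `region`, `year`, `scenario`, `disease`, `age`,
#'   `paf`, `paf_lower`, `paf_upper`.
#' @export
paf_table <- function(curves, exposure, ages = age_bands()) {
  if (inherits(curves, "rr_curve")) curves <- list(curves)
  check_columns(exposure, c("region", "year", "scenario", "conc"), "`exposure`")
  lo <- if ("conc_lower" %in% names(exposure)) {
    pmax(exposure$conc_lower, 0)
  } else exposure$conc
  hi <- if ("conc_upper" %in% names(exposure)) exposure$conc_upper else exposure$conc
  out <- vector("list", length(curves))
  for (k in seq_along(curves)) {
    cv <- curves[[k]]
    rr_mean <- relative_risk(cv, exposure$conc)
    if (!is.null(cv$draws)) {
      draw_at <- function(conc_vec) {
        # draws x obs matrix of RR, then 2.5/97.5 quantiles per observation
        rr <- apply(cv$draws, 1L, function(v) {
          stats::approx(cv$grid, v, xout = conc_vec, rule = 2)$y
        })
        rr <- matrix(rr, nrow = length(conc_vec))
        t(apply(rr, 1L, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE, type = 7))
      }
      rr_lo <- draw_at(lo)[, 1L]
      rr_hi <- draw_at(hi)[, 2L]
    } else {
      rr_lo <- relative_risk(cv, lo)
      rr_hi <- relative_risk(cv, hi)
    }
    n_sub <- sum(rr_lo < 1) + sum(rr_hi < 1)
    if (n_sub > 0) {
      message(sprintf("floored %d sub-unity RR value(s) at 1 before PAF", n_sub))
    }
    band <- if (identical(cv$age, "all-age")) ages else cv$age
    base <- exposure[, c("region", "year", "scenario")]
    df <- do.call(rbind, lapply(band, function(ag) {
      cbind(base, disease = cv$disease, age = ag,
            paf = paf(pmax(rr_mean, 1)),
            paf_lower = paf(pmax(rr_lo, 1)),
            paf_upper = paf(pmax(rr_hi, 1)),
            stringsAsFactors = FALSE)
    }))
    out[[k]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read and write tabulated curve files
#'
#' Curve files are CSV with columns `disease`, `age`, `concentration`,
#' `draw_id` (0 = mean curve) and `rr`; the schema is validated strictly.
#'
#' @param path file path.
#' @return `read_rr_curves()` returns an `rr_curve_set`.
#' @export
read_rr_curves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("disease", "age", "concentration", "draw_id", "rr"),
                "curve file")
  if (any(!is.finite(df$rr)) || any(df$concentration < 0)) {
    stop_invalid("curve file contains non-finite RR or negative concentration")
  }
  keys <- unique(df[, c("disease", "age")])
  curves <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- df[df$disease == keys$disease[i] & df$age == keys$age[i], ]
    grid <- sort(unique(sub$concentration))
    getvals <- function(id) {
      s <- sub[sub$draw_id == id, ]
      s <- s[order(s$concentration), ]
      if (!identical(s$concentration, grid)) {
        stop_invalid("draw ", id, " of ", keys$disease[i],
                     " is not tabulated on the common grid")
      }
      s$rr
    }
    mean_rr <- getvals(0L)
    draw_ids <- sort(setdiff(unique(sub$draw_id), 0L))
    draws <- if (length(draw_ids) >= 2L) {
      do.call(rbind, lapply(draw_ids, getvals))
    } else NULL
    curves[[paste(keys$disease[i], keys$age[i], sep = "|")]] <-
      rr_curve(keys$disease[i], keys$age[i], grid, mean_rr, draws)
  }
  structure(curves, class = "rr_curve_set")
}

#' @rdname read_rr_curves
#' @param curves an `rr_curve_set`.
#' @export
write_rr_curves <- function(curves, path) {
  rows <- lapply(curves, function(cv) {
    mean_df <- data.frame(disease = cv$disease, age = cv$age,
                          concentration = cv$grid, draw_id = 0L, rr = cv$mean_rr)
    if (is.null(cv$draws)) return(mean_df)
    draw_df <- do.call(rbind, lapply(seq_len(nrow(cv$draws)), function(i) {
      data.frame(disease = cv$disease, age = cv$age, concentration = cv$grid,
                 draw_id = i, rr = cv$draws[i, ])
    }))
    rbind(mean_df, draw_df)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
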