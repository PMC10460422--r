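# Decomposition of the change in attributable deaths between two time
# points into the contributions of four drivers -- age structure, total
# population, air quality (entering through the PAF) and disease mortality
# -- by stepwise factor introduction averaged over all 4! = 24 orderings.

DECOMP_FACTORS <- c("age_structure", "population", "air_quality", "mortality")

#' Snapshot of the burden inputs at one time point
#'
#' A factor state bundles the four inputs of the attributable-death product
#' for one scenario and time point. Air quality enters as the PAF table
#' (the concentration -> RR -> PAF composition), so introducing the air
#' quality factor swaps PAFs wholesale and the decomposition's
#' factorization stays exact.
#'
#' @param agep data frame `region`, `age`, `age_prop`.
#' @param pop data frame `region`, `pop`.
#' @param paf data frame `region`, `disease`, `age`, `paf`.
#' @param rate data frame `region`, `disease` (or `cause`), `age`, `rate`.
#' @return An object of class `factor_state`.
#' @export
factor_state <- function(agep, pop, paf, rate) {
  check_columns(agep, c("region", "age", "age_prop"), "`agep`")
  check_columns(pop, c("region", "pop"), "`pop`")
  check_columns(paf, c("region", "disease", "age", "paf"), "`paf`")
  if ("cause" %in% names(rate) && !("disease" %in% names(rate))) {
    names(rate)[names(rate) == "cause"] <- "disease"
  }
  check_columns(rate, c("region", "disease", "age", "rate"), "`rate`")
  if (any(agep$age_prop < 0) || any(pop$pop < 0) ||
      any(paf$paf < 0 | paf$paf >= 1) || any(rate$rate < 0)) {
    stop_invalid("factor-state components violate their invariants")
  }
  structure(list(agep = agep, pop = pop, paf = paf, rate = rate),
            class = "factor_state")
}

# Align two factor states on the strata of the start state's PAF table and
# return per-factor start/end vectors over those strata.
align_states <- function(start, end) {
  stopifnot(inherits(start, "factor_state"), inherits(end, "factor_state"))
  strata <- start$paf[, c("region", "disease", "age")]
  pull <- function(state) {
    k3 <- paste(strata$region, strata$disease, strata$age)
    paf <- state$paf$paf[match(k3, paste(state$paf$region, state$paf$disease,
                                         state$paf$age))]
    rate <- state$rate$rate[match(k3, paste(state$rate$region,
                                            state$rate$disease,
                                            state$rate$age))]
    agep <- state$agep$age_prop[match(paste(strata$region, strata$age),
                                      paste(state$agep$region, state$agep$age))]
    pop <- state$pop$pop[match(strata$region, state$pop$region)]
    m <- cbind(age_structure = agep, population = pop,
               air_quality = paf, mortality = rate)
    if (anyNA(m)) stop_invalid("factor states are not index-aligned")
    m
  }
  list(strata = strata, start = pull(start), end = pull(end))
}

dapp_from_matrix <- function(m) sum(m[, "age_structure"] * m[, "population"] *
                                      m[, "air_quality"] * m[, "mortality"])

#' Total attributable deaths implied by one factor state
#'
#' @param state a [factor_state()].
#' @return Scalar deaths per year.
#' @export
dapp_from_state <- function(state) {
  dapp_from_matrix(align_states(state, state)$start)
}

#' Factor contributions along one introduction ordering
#'
#' Walks the ordering: at step k the k-th factor's start values are
#' replaced with its end values across all strata simultaneously and the
#' burden recomputed; the factor's contribution is the difference between
#' the post- and pre-introduction totals. Contributions telescope exactly
#' to the net change.
#'
#' @param start,end [factor_state()] snapshots at the period endpoints.
#' @param ordering permutation of
#'   `c("age_structure", "population", "air_quality", "mortality")`.
#' @return Named numeric vector of 4 contributions (deaths).
#' @export
contribution_for_ordering <- function(start, end, ordering) {
  if (length(ordering) != length(DECOMP_FACTORS) ||
      anyDuplicated(ordering) ||
      !all(ordering %in% DECOMP_FACTORS)) {
    stop_invalid("`ordering` must be a permutation of: ",
                 paste(DECOMP_FACTORS, collapse = ", "))
  }
  al <- align_states(start, end)
  cur <- al$start
  prev <- dapp_from_matrix(cur)
  contrib <- stats::setNames(numeric(length(ordering)), ordering)
  for (f in ordering) {
    cur[, f] <- al$end[, f]
    now <- dapp_from_matrix(cur)
    contrib[f] <- now - prev
    prev <- now
  }
  contrib[DECOMP_FACTORS]
}

#' Decompose a burden change into four driver contributions
#'
#' Enumerates all 24 orderings of factor introduction, computes the
#' contribution of each factor under each ordering, and averages. The
#' averaged contributions sum exactly to the net change (telescoping is
#' exact per ordering, hence for the mean).
#'
#' @inheritParams contribution_for_ordering
#' @return List of class `decomposition_result`: `contributions` (named
#'   length-4 vector of averaged contributions), `per_ordering` (24 x 4
#'   matrix, row names give the ordering), `net_change`, `n_orderings`.
#' @export
decompose_drivers <- function(start, end) {
  perms <- permutations(DECOMP_FACTORS)
  per <- matrix(NA_real_, nrow(perms), length(DECOMP_FACTORS),
                dimnames = list(apply(perms, 1L, paste, collapse = " > "),
                                DECOMP_FACTORS))
  for (i in seq_len(nrow(perms))) {
    per[i, ] <- contribution_for_ordering(start, end, perms[i, ])
  }
  al <- align_states(start, end)
  structure(
    list(contributions = colMeans(per), per_ordering = per,
         net_change = dapp_from_matrix(al$end) - dapp_from_matrix(al$start),
         n_orderings = nrow(per)),
    class = "decomposition_result"
  )
}

#' Decompose burden change over consecutive reporting periods
#'
#' Decomposes between the endpoint states of each period. Net changes are
#' additive across consecutive periods (the burden itself telescopes), but
#' per-factor contributions are path dependent and need not sum across
#' sub-periods to the full-period contribution.
#'
#' @param states_by_year named list of [factor_state()]s keyed by year.
#' @param periods list of length-2 year vectors, e.g.
#'   `list(c(2019, 2025), c(2025, 2035))`.
#' @return Named list of [decompose_drivers()] results, one per period.
#' @export
period_decomposition <- function(states_by_year, periods) {
  out <- list()
  for (p in periods) {
    y0 <- as.character(p[1L]); y1 <- as.character(p[2L])
    if (is.null(states_by_year[[y0]]) || is.null(states_by_year[[y1]])) {
      stop_invalid("missing endpoint state for period ", y0, "-", y1)
    }
    out[[paste(y0, y1, sep = "-")]] <-
      decompose_drivers(states_by_year[[y0]], states_by_year[[y1]])
  }
  out
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat("Driver decomposition over", x$n_orderings, "orderings\n")
  cat(sprintf("net change: %.1f deaths\n", x$net_change))
  print(round(x$contributions, 1))
  invisible(x)
}
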