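# Shared fixtures, built in code.

# Single-cell aerosol field set with prescribed component values.
unit_fields <- function(BC = 0, OA = 0, SO4 = 0, SS = 0, dust = 0,
                        years = 2020L) {
  ny <- length(years)
  arr <- function(v) array(rep(v, each = 1), dim = c(1L, ny, 1L, 1L))
  structure(
    list(components = list(BC = arr(BC), OA = arr(OA), SO4 = arr(SO4),
                           SS = arr(SS), dust = arr(dust)),
         years = as.integer(years), lat = 0.5, lon = 0.5),
    class = "aerosol_fields"
  )
}

# Constant-valued conc_field on an arbitrary grid.
const_field <- function(value, years = 2020L, nlat = 2L, nlon = 2L,
                        members = 1L) {
  conc_field(array(value, dim = c(members, length(years), nlat, nlon)),
             years, seq_len(nlat) - 0.5, seq_len(nlon) - 0.5)
}

# Random positive conc_field.
random_field <- function(seed, years = 2020L, nlat = 3L, nlon = 3L,
                         members = 1L) {
  set.seed(seed)
  vals <- array(exp(rnorm(members * length(years) * nlat * nlon)),
                dim = c(members, length(years), nlat, nlon))
  conc_field(vals, years, seq_len(nlat) - 0.5, seq_len(nlon) - 0.5)
}

# One-cause hierarchy for fast single-stratum mortality simulations.
one_cause_hierarchy <- function(cause = "X") {
  data.frame(cause = cause, level = 1L, parent = NA_character_,
             stringsAsFactors = FALSE)
}

# A small random full-hierarchy mortality table (one year) for
# envelope-constraining checks.
random_hierarchy_table <- function(seed, regions = c("A", "B"),
                                   ages = c("25-30", "65-70")) {
  set.seed(seed)
  h <- cause_hierarchy()
  df <- expand.grid(region = regions, age = ages, cause = h$cause,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$year <- 2030L
  df$cause_level <- h$level[match(df$cause, h$cause)]
  df$parent <- h$parent[match(df$cause, h$cause)]
  df$rate <- runif(nrow(df), 0.1, 1)
  df
}

# Tiny aligned factor state over a stratum grid.
random_factor_state <- function(seed, regions, ages, diseases) {
  set.seed(seed)
  agep <- expand.grid(region = regions, age = ages,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  agep$age_prop <- runif(nrow(agep), 0.01, 0.1)
  pop <- data.frame(region = regions,
                    pop = runif(length(regions), 1e6, 1e8))
  pafd <- expand.grid(region = regions, disease = diseases, age = ages,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pafd$paf <- runif(nrow(pafd), 0, 0.6)
  rate <- pafd[, c("region", "disease", "age")]
  rate$rate <- runif(nrow(rate), 1e-5, 1e-2)
  factor_state(agep, pop, pafd, rate)
}
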