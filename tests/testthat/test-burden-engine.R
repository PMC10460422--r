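one_stratum <- function(pafv = 0.5, pop = 1e6, rate = 1e-3, agep = 0.1,
                        region = "A", age = "65-70") {
  list(
    paf = data.frame(region = region, year = 2030L, scenario = "S",
                     disease = "IHD", age = age, paf = pafv),
    demog = data.frame(region = region, year = 2030L, scenario = "S",
                       age = age, pop = pop, age_prop = agep),
    rates = data.frame(region = region, year = 2030L, cause = "IHD",
                       age = age, rate = rate)
  )
}

test_that("attributable deaths follow the PAF x POP x Rate x AgeP product", {
  s <- one_stratum()
  b <- compute_dapp(s$paf, s$demog, s$rates)
  expect_equal(b$deaths, 50)
  # zero PAF, zero deaths
  s0 <- one_stratum(pafv = 0)
  expect_equal(compute_dapp(s0$paf, s0$demog, s0$rates)$deaths, 0)
  # linearity in population
  s2 <- one_stratum(pop = 2e6)
  expect_equal(compute_dapp(s2$paf, s2$demog, s2$rates)$deaths, 100)
  # misalignment is an explicit error
  bad <- s$demog; bad$age <- "25-30"
  expect_error(compute_dapp(s$paf, bad, s$rates), class = "invalid_argument")
})

test_that("bound propagation evaluates the product at joint bounds", {
  s <- one_stratum()
  s$paf$paf_lower <- 0.4; s$paf$paf_upper <- 0.6
  s$rates$lower <- 8e-4; s$rates$upper <- 1.2e-3
  b <- compute_dapp(s$paf, s$demog, s$rates)
  expect_equal(b$deaths_lower, 0.4 * 1e6 * 8e-4 * 0.1)
  expect_equal(b$deaths_upper, 0.6 * 1e6 * 1.2e-3 * 0.1)
  mc <- compute_dapp(s$paf, s$demog, s$rates, interval = "montecarlo",
                     n_mc = 2000, seed = 1)
  expect_true(mc$deaths_lower < mc$deaths & mc$deaths < mc$deaths_upper)
  # the joint-bounds interval is conservative relative to Monte Carlo
  expect_lte(b$deaths_lower, mc$deaths_lower + 1e-9)
  expect_gte(b$deaths_upper, mc$deaths_upper - 1e-9)
})

test_that("regional sums equal the pooled national computation", {
  set.seed(10)
  regions <- paste0("R", 1:5)
  ages <- age_bands()
  pafd <- expand.grid(region = regions, age = ages, disease = pm25_causes(),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pafd$year <- 2030L; pafd$scenario <- "S"
  pafd$paf <- runif(nrow(pafd), 0, 0.5)
  demog <- expand.grid(region = regions, age = ages,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  demog$year <- 2030L; demog$scenario <- "S"
  demog$pop <- rep(runif(5, 1e6, 1e7), times = 15)
  demog$age_prop <- runif(nrow(demog), 0.02, 0.08)
  rates <- pafd[, c("region", "age", "disease", "year")]
  names(rates)[3] <- "cause"
  rates$rate <- runif(nrow(rates), 1e-5, 1e-3)
  b <- compute_dapp(pafd, demog, rates)
  regional <- dapp_total(b)
  national <- dapp_total(b, by = c("year", "scenario"))
  expect_equal(sum(regional$deaths), national$deaths, tolerance = 1e-12)
  # attributable deaths never exceed cause deaths (PAF < 1)
  cause_deaths <- sum(demog$pop[match(paste(rates$region, rates$age),
                                      paste(demog$region, demog$age))] *
                        rates$rate *
                        demog$age_prop[match(paste(rates$region, rates$age),
                                             paste(demog$region, demog$age))])
  expect_lt(national$deaths, cause_deaths)
})

test_that("per-capita burden matches its closed form and aggregates", {
  s <- one_stratum()
  b <- compute_dapp(s$paf, s$demog, s$rates)
  pc <- per_capita(b, s$demog)
  expect_equal(pc$deaths_per_100k, 5)
  # splitting a region into two equal halves with identical rates
  # leaves per-capita burden unchanged
  s2 <- one_stratum(pop = 5e5, region = "A1")
  s3 <- one_stratum(pop = 5e5, region = "A2")
  paf2 <- rbind(s2$paf, s3$paf); dem2 <- rbind(s2$demog, s3$demog)
  rat2 <- rbind(s2$rates, s3$rates)
  b2 <- compute_dapp(paf2, dem2, rat2)
  pc2 <- per_capita(b2, dem2)
  expect_equal(pc2$deaths_per_100k, c(5, 5))
  dem0 <- s$demog; dem0$pop <- 0
  b0 <- compute_dapp(s$paf, dem0, s$rates)
  expect_warning(pc0 <- per_capita(b0, dem0), class = "undefined_value")
  expect_true(is.na(pc0$deaths_per_100k))
})

test_that("older-adult death shares follow the band partition", {
  mk <- function(age, deaths) {
    data.frame(region = "A", year = 2030L, scenario = "S", disease = "IHD",
               age = age, deaths = deaths)
  }
  expect_equal(older_share_by_disease(mk("70-75", 10))$older_share, 1)
  expect_equal(older_share_by_disease(mk("30-35", 10))$older_share, 0)
  b <- rbind(mk("30-35", 30), mk("80-85", 70))
  expect_equal(older_share_by_disease(b)$older_share, 0.7)
  expect_warning(z <- older_share_by_disease(mk("30-35", 0)),
                 class = "undefined_value")
  expect_true(is.na(z$older_share))
})

test_that("reporting smoother applies a centered partial-window mean", {
  df <- data.frame(scenario = "S", year = 2020:2026, deaths = c(1, 2, 3, 4, 5, 6, 7))
  sm <- smooth_reporting(df, "deaths", by = "scenario", window = 5)
  expect_equal(sm$deaths[3], mean(1:5))  # full window
  expect_equal(sm$deaths[1], mean(1:3))  # shrunk at the edge
  expect_equal(sm$deaths[7], mean(5:7))
})

test_that("higher concentrations never decrease the burden", {
  curves <- generate_rr_curves(diseases = "IHD", seed = 11, n_draws = 10)
  s <- one_stratum()
  concs <- sort(runif(20, 0, 120))
  deaths <- vapply(concs, function(cc) {
    expo <- data.frame(region = "A", year = 2030L, scenario = "S", conc = cc)
    pt <- paf_table(curves, expo, ages = "65-70")
    compute_dapp(pt, s$demog, s$rates)$deaths
  }, numeric(1))
  expect_true(all(diff(deaths) >= 0))
})

test_that("region summaries offer sums and means", {
  df <- data.frame(region = c("A", "B"), year = 2030L, scenario = "S",
                   deaths = c(10, 30))
  expect_equal(summarize_regions(df, "deaths", "sum")$deaths, 40)
  expect_equal(summarize_regions(df, "deaths", "mean")$deaths, 20)
})
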