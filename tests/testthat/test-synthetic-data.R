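test_that("generators are bit-identical under a fixed seed", {
  sp <- scenario_spec("S", 2020:2024, concentration_trend = -0.02,
                      aging_rate = 0.01, pop_growth = 0.002, n_models = 3)
  expect_identical(generate_aerosol_fields(sp, c(5, 6), seed = 7),
                   generate_aerosol_fields(sp, c(5, 6), seed = 7))
  mask <- matrix(c("A", "A", "B", "B"), 2, 2)
  expect_identical(
    generate_population(c(2, 2), mask, c(A = 1000, B = 500), seed = 7),
    generate_population(c(2, 2), mask, c(A = 1000, B = 500), seed = 7))
  expect_identical(generate_demography(c("A", "B"), sp, seed = 7),
                   generate_demography(c("A", "B"), sp, seed = 7))
  expect_identical(generate_sdi(c("A", "B"), 2000:2019, seed = 7),
                   generate_sdi(c("A", "B"), 2000:2019, seed = 7))
  expect_identical(generate_rr_curves(seed = 7, n_draws = 5),
                   generate_rr_curves(seed = 7, n_draws = 5))
  sdi <- generate_sdi(c("A", "B"), 2000:2019, seed = 7)
  tr <- ground_truth()
  expect_identical(
    generate_mortality_history(tr, c("A", "B"), 2000:2019, sdi, seed = 7),
    generate_mortality_history(tr, c("A", "B"), 2000:2019, sdi, seed = 7))
})

test_that("aerosol fields are non-negative and reject bad grids", {
  sp <- scenario_spec("S", 2020:2022, n_models = 3)
  af <- generate_aerosol_fields(sp, c(6, 6), seed = 11)
  for (comp in af$components) expect_true(all(comp >= 0))
  expect_equal(dim(af$components$BC), c(3, 3, 6, 6))
  expect_error(generate_aerosol_fields(sp, c(0, 5), seed = 1),
               class = "invalid_argument")
})

test_that("zero drift keeps expected field means constant across years", {
  sp <- scenario_spec("S", 2020:2021, concentration_trend = 0, n_models = 2)
  diffs <- vapply(1:100, function(s) {
    af <- generate_aerosol_fields(sp, c(4, 4), seed = s)
    mean(af$components$SO4[, 2, , ]) - mean(af$components$SO4[, 1, , ])
  }, numeric(1))
  # Monte-Carlo mean difference must be within sampling error of zero
  expect_lt(abs(mean(diffs)), 4 * sd(diffs) / sqrt(length(diffs)))
})

test_that("population allocation conserves totals exactly", {
  mask <- matrix(c("A", "A", "A", "B"), 2, 2)
  pop <- generate_population(c(2, 2), mask, c(A = 1000, B = 77), seed = 3)
  expect_identical(sum(pop[mask == "A"]), 1000)
  expect_identical(sum(pop[mask == "B"]), 77)
  zero <- generate_population(c(2, 2), mask, c(A = 0, B = 0), seed = 3)
  expect_true(all(zero == 0))
  # largest-remainder under uniform weights: 7 persons over 3 cells
  m3 <- matrix("A", 1, 3)
  alloc <- generate_population(c(1, 3), m3, c(A = 7), seed = 1,
                               weights = matrix(1, 1, 3))
  expect_equal(sum(alloc), 7)
  expect_lte(max(alloc) - min(alloc), 1)
  expect_error(generate_population(c(3, 3), mask, c(A = 1, B = 1), seed = 1),
               class = "invalid_argument")
})

test_that("noise-free mortality equals the generative mean exactly", {
  regions <- c("A", "B")
  years <- 2000:2014
  sdi <- data.frame(region = rep(regions, each = length(years)),
                    year = rep(years, 2), sdi = 0.6)
  th <- setNames(rep(0, 15), age_bands())
  tr <- ground_truth(beta1 = -2, beta2 = -4, theta_a = th, alpha = -7,
                     ar_phi = 0, sigma = 0)
  hist <- generate_mortality_history(tr, regions, years, sdi, seed = 9)
  # constant SDI, zero trend, zero noise: constant rate within each stratum
  spread <- tapply(hist$rate, paste(hist$region, hist$cause, hist$age),
                   function(x) diff(range(x)))
  expect_true(all(spread == 0))
  # and log-rates equal the model mean exactly for a leaf cause
  al <- attr(hist, "alpha")
  one <- hist[hist$cause == "COPD" & hist$region == "A" &
                hist$age == "25-30" & hist$year == 2000, ]
  a <- al$COPD[al$region == "A" & al$age == "25-30"]
  expect_equal(log(one$rate), -2 * 0.6 + a, tolerance = 1e-12)
})

test_that("a per-age time trend moves log-rates by exactly theta per year", {
  th <- setNames(rep(0, 15), age_bands())
  th["65-70"] <- 0.01
  tr <- ground_truth(theta_a = th, alpha = -7, ar_phi = 0, sigma = 0)
  years <- 2000:2011
  sdi <- data.frame(region = "A", year = years, sdi = 0.5)
  hist <- generate_mortality_history(tr, "A", years, sdi, seed = 2)
  g <- hist[hist$cause == "IHD" & hist$age == "65-70", ]
  g <- g[order(g$year), ]
  expect_equal(diff(log(g$rate)), rep(0.01, length(years) - 1),
               tolerance = 1e-12)
  flat <- hist[hist$cause == "IHD" & hist$age == "25-30", ]
  expect_equal(diff(log(flat$rate[order(flat$year)])),
               rep(0, length(years) - 1), tolerance = 1e-12)
})

test_that("generated hierarchies are internally consistent", {
  sdi <- generate_sdi(c("A", "B"), 2000:2012, seed = 4)
  hist <- generate_mortality_history(ground_truth(ar_phi = 0.3, sigma = 0.05),
                                     c("A", "B"), 2000:2012, sdi, seed = 4)
  expect_true(all(hist$rate > 0))
  key <- c("region", "year", "age")
  l2 <- aggregate(rate ~ region + year + age,
                  hist[hist$cause_level == 2, ], sum)
  l1 <- hist[hist$cause_level == 1, c(key, "rate")]
  m <- merge(l2, l1, by = key)
  expect_equal(m$rate.x, m$rate.y, tolerance = 1e-12)
  # named level-3 causes sum to strictly less than their parent
  ncd_named <- aggregate(rate ~ region + year + age,
                         hist[hist$parent %in% "NCD" &
                                hist$cause != "rest_NCD", ], sum)
  ncd <- hist[hist$cause == "NCD", c(key, "rate")]
  m2 <- merge(ncd_named, ncd, by = key)
  expect_true(all(m2$rate.x < m2$rate.y))
  bad_sdi <- data.frame(region = "A", year = 2000:2012, sdi = 1.2)
  expect_error(
    generate_mortality_history(ground_truth(), "A", 2000:2012, bad_sdi, 1),
    class = "invalid_argument")
})

test_that("rr-curve generation honors shape contracts", {
  flat <- generate_rr_curves(diseases = "IHD", seed = 1, shape = "flat",
                             n_draws = 5)[[1]]
  expect_true(all(flat$mean_rr == 1))
  ll <- generate_rr_curves(diseases = "IHD", seed = 1, shape = "loglinear",
                           shape_params = list(IHD = list(s = 0.004)),
                           n_draws = 5)[[1]]
  expect_equal(ll$mean_rr, exp(0.004 * ll$grid), tolerance = 1e-12)
  cc <- generate_rr_curves(seed = 2, n_draws = 20)
  for (cv in cc) {
    expect_identical(cv$mean_rr[1], 1)
    expect_true(all(diff(cv$mean_rr) >= 0))
    expect_true(all(cv$draws[, 1] == 1))
    expect_true(all(apply(cv$draws, 1, function(d) all(diff(d) >= -1e-12))))
  }
  expect_error(generate_rr_curves(seed = 1, n_draws = 1),
               class = "invalid_argument")
})

test_that("demography age proportions sum to one and drift with aging", {
  sp <- scenario_spec("S", 2020:2035, aging_rate = 0.02, n_models = 2)
  d <- generate_demography(c("A", "B"), sp, seed = 5)
  sums <- tapply(d$age_prop, paste(d$region, d$year), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  old <- d[d$age %in% older_bands(), ]
  oshare <- tapply(old$age_prop, paste(old$region, old$year), sum)
  first <- oshare[paste("A", 2020)]
  last <- oshare[paste("A", 2035)]
  expect_gt(last, first)
})
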