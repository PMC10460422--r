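test_that("PM2.5 composition reproduces the component coefficients", {
  expect_equal(as.numeric(compose_pm25(unit_fields())$values), 0)
  expect_equal(as.numeric(compose_pm25(unit_fields(SS = 1))$values), 0.25)
  expect_equal(as.numeric(compose_pm25(unit_fields(dust = 10))$values), 1.0)
  # sulfate carries imputed ammonium: 96 + 36*96/96 = 132
  expect_equal(as.numeric(compose_pm25(unit_fields(SO4 = 96))$values), 132)
  expect_equal(impute_nh4(96), 36)
  expect_error(compose_pm25(unit_fields(BC = -1)), class = "invalid_argument")
  expect_error(impute_nh4(-1), class = "invalid_argument")
})

test_that("composition is linear and monotone in every component", {
  set.seed(1)
  for (i in 1:20) {
    base <- runif(5, 0, 20)
    f0 <- unit_fields(base[1], base[2], base[3], base[4], base[5])
    v0 <- as.numeric(compose_pm25(f0)$values)
    comp <- sample(c("BC", "OA", "SO4", "SS", "dust"), 1)
    args <- as.list(base)
    names(args) <- c("BC", "OA", "SO4", "SS", "dust")
    args[[comp]] <- args[[comp]] + runif(1, 0, 5)
    v1 <- as.numeric(compose_pm25(do.call(unit_fields, args))$values)
    expect_gte(v1, v0)
  }
})

test_that("calibration identity and ratio cases hold", {
  est <- random_field(1, years = 2015L)
  obs <- random_field(2, years = 2015L)
  fut <- conc_field(est$values, 2030L, est$lat, est$lon)
  cal <- calibrate_pm25(fut, est, obs, window = c(2015L, 2015L))
  # future equal to the baseline estimate returns the observations bit-exactly
  expect_identical(cal$values[1, 1, , ], obs$values[1, 1, , ])
  expect_true(cal$calibrated)
  expect_identical(cal$baseline_window, c(2015L, 2015L))
  # observations equal to the estimate: unit ratio returns the future field
  cal2 <- calibrate_pm25(random_field(3, years = 2030L), est, est,
                         window = c(2015L, 2015L))
  expect_equal(as.numeric(cal2$values), as.numeric(random_field(3, 2030L)$values))
  # worked ratio: 30 * 10 / 20 = 15
  cal3 <- calibrate_pm25(const_field(10, 2030L), const_field(20, 2015L),
                         const_field(30, 2015L), window = c(2015L, 2015L))
  expect_equal(as.numeric(cal3$values), rep(15, 4))
})

test_that("zero-estimate cells are masked and counted, not fatal", {
  est <- const_field(2, 2015L)
  est$values[1, 1, 1, 1] <- 0
  obs <- const_field(3, 2015L)
  fut <- const_field(5, 2030L)
  expect_warning(
    cal <- calibrate_pm25(fut, est, obs, window = c(2015L, 2015L)),
    "masked")
  expect_identical(cal$n_masked, 1L)
  expect_true(is.na(cal$values[1, 1, 1, 1]))
  expect_equal(cal$values[1, 1, 2, 2], 3 * 5 / 2)
})

test_that("calibrating a calibrated field against itself is a no-op", {
  fut <- random_field(4, years = 2016L)
  cal <- calibrate_pm25(fut, random_field(5, 2015L), random_field(6, 2015L),
                        window = c(2015L, 2015L))
  again <- calibrate_pm25(cal, cal, cal, window = c(2016L, 2016L))
  expect_identical(again$values, cal$values)
})

test_that("regridding is exact for constants and conserves population", {
  src_lat <- c(0.5, 1.5, 2.5, 3.5); src_lon <- c(10.5, 11.5, 12.5)
  m <- matrix(7, 4, 3)
  out <- regrid_concentration(m, src_lat, src_lon,
                              c(0.7, 2.2, 3.1), c(10.8, 12.1))
  expect_equal(as.numeric(out), rep(7, 6))
  set.seed(2)
  p <- matrix(rpois(12, 50), 4, 3)
  pr <- regrid_population(p, src_lat, src_lon,
                          seq(0.25, 3.75, by = 0.5), c(10.4, 11.5, 12.6))
  expect_equal(sum(pr), sum(p), tolerance = 1e-12)
  # 2x2 -> 1x1 collapse: the single target cell holds the four-cell sum
  p4 <- matrix(c(1, 2, 3, 4), 2, 2)
  coll <- regrid_population(p4, c(0.5, 1.5), c(0.5, 1.5), 1, 1)
  expect_equal(as.numeric(coll), 10)
  expect_error(
    regrid_concentration(m, src_lat, src_lon, c(100, 101), c(200, 201)),
    class = "invalid_argument")
})

test_that("population weighting matches closed forms and bounds", {
  regions <- matrix("A", 1, 2)
  conc <- matrix(c(10, 20), 1, 2)
  pop <- matrix(c(1, 3), 1, 2)
  expect_equal(population_weighted_concentration(conc, pop, regions)$conc, 17.5)
  # uniform concentration is population-invariant
  expect_equal(
    population_weighted_concentration(matrix(5, 1, 2), pop, regions)$conc, 5)
  # all mass on one cell picks that cell's value
  expect_equal(
    population_weighted_concentration(conc, matrix(c(0, 9), 1, 2), regions)$conc,
    20)
  expect_warning(
    res <- population_weighted_concentration(conc, matrix(0, 1, 2), regions),
    class = "undefined_value")
  expect_true(is.na(res$conc))
  # weighted mean lies within the regional field range
  set.seed(3)
  for (i in 1:20) {
    cm <- matrix(runif(12, 5, 50), 3, 4)
    pm <- matrix(rpois(12, 30), 3, 4)
    rg <- matrix("A", 3, 4)
    w <- population_weighted_concentration(cm, pm, rg)$conc
    expect_gte(w, min(cm)); expect_lte(w, max(cm))
  }
})

test_that("ensemble intervals follow the spread-times-t form", {
  ei <- ensemble_interval(c(3, 3, 3))
  expect_equal(c(ei$mean, ei$lower, ei$upper), c(3, 3, 3))
  ei2 <- ensemble_interval(c(0, 2))
  half <- sqrt(2) * qt(0.975, df = 1)
  expect_equal(ei2$mean, 1)
  expect_equal(ei2$upper - ei2$mean, half, tolerance = 1e-12)
  expect_equal(ei2$mean - ei2$lower, half, tolerance = 1e-12)
  # location equivariance of the width
  ei3 <- ensemble_interval(c(0, 2) + 100)
  expect_equal(ei3$upper - ei3$lower, ei2$upper - ei2$lower, tolerance = 1e-12)
  expect_warning(deg <- ensemble_interval(5), "fewer than 2")
  expect_identical(deg$lower, -Inf)
  # the standard-error mode narrows by sqrt(n)
  se <- ensemble_interval(c(0, 2), mode = "standard-error")
  expect_equal(se$upper - se$mean, half / sqrt(2), tolerance = 1e-12)
})
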