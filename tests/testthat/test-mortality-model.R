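make_history <- function(seed, regions = paste0("R", 1:4), years = 2000:2014,
                         truth = ground_truth(beta1 = -2, beta2 = -4,
                                              theta_a = -0.01, alpha = -7,
                                              ar_phi = 0, sigma = 0),
                         ages = c("25-30", "65-70", ">95")) {
  sdi <- generate_sdi(regions, years, seed = seed)
  list(hist = generate_mortality_history(truth, regions, years, sdi,
                                         seed = seed, ages = ages,
                                         hierarchy = one_cause_hierarchy()),
       sdi = sdi, truth = truth)
}

test_that("noise-free histories give exact coefficient recovery", {
  d <- make_history(1)
  fit <- fit_trend(d$hist, d$sdi, "X")
  expect_lt(abs(fit$beta1 - d$truth$beta1), 1e-8)
  expect_lt(abs(fit$beta2 - d$truth$beta2), 1e-8)
  expect_true(all(abs(fit$theta - d$truth$theta_a) < 1e-8))
  al <- attr(d$hist, "alpha")
  key <- paste(al$region, al$age)
  expect_true(all(abs(fit$alpha[paste(al$region, al$age, sep = "|")] - al$X)
                  < 1e-8))
  expect_equal(fit$sigma, 0, tolerance = 1e-7)
})

test_that("shifting all log-rates moves only the intercepts", {
  d <- make_history(2)
  f0 <- fit_trend(d$hist, d$sdi, "X")
  shifted <- d$hist
  shifted$rate <- shifted$rate * exp(0.7)
  f1 <- fit_trend(shifted, d$sdi, "X")
  expect_equal(f1$beta1, f0$beta1, tolerance = 1e-8)
  expect_equal(f1$beta2, f0$beta2, tolerance = 1e-8)
  expect_equal(unname(f1$theta), unname(f0$theta), tolerance = 1e-8)
  expect_equal(unname(f1$alpha - f0$alpha),
               rep(0.7, length(f0$alpha)), tolerance = 1e-8)
})

test_that("one-sided SDI pins the unidentifiable slope", {
  regions <- c("A", "B")
  years <- 2000:2011
  sdi <- data.frame(region = rep(regions, each = 12), year = rep(years, 2),
                    sdi = rep(seq(0.3, 0.6, length.out = 12), 2))
  hist <- generate_mortality_history(
    ground_truth(beta1 = -2, beta2 = -4, theta_a = 0, alpha = -7,
                 ar_phi = 0, sigma = 0),
    regions, years, sdi, seed = 3, ages = "65-70",
    hierarchy = one_cause_hierarchy())
  expect_warning(fit <- fit_trend(hist, sdi, "X"), "pinned")
  expect_identical(fit$beta2, fit$beta1)
  expect_identical(fit$pinned, "beta2")
})

test_that("trend fitting rejects degenerate inputs", {
  d <- make_history(4)
  bad <- d$hist; bad$rate[1] <- 0
  expect_error(fit_trend(bad, d$sdi, "X"), class = "invalid_argument")
  short <- d$hist[d$hist$year < 2007, ]
  expect_error(fit_trend(short, d$sdi, "X"), class = "invalid_argument")
})

test_that("residual models forecast zero for zero series and decay for AR", {
  z <- fit_residual(rep(0, 12))
  pz <- predict_residual(z, 3)
  expect_equal(pz$mean, rep(0, 3))
  expect_equal(pz$se, rep(0, 3))
  set.seed(6)
  x <- as.numeric(arima.sim(list(ar = 0.6), n = 300))
  m <- fit_residual(x)
  p <- predict_residual(m, 5)
  phi <- as.numeric(m$fit$coef["ar1"])
  # analytic AR(1) forecast: each step scales the previous by phi
  expect_equal(p$mean[-1] / p$mean[-5], rep(phi, 4), tolerance = 1e-8)
  expect_true(all(diff(p$se) >= 0))
})

test_that("zero-noise forecasts extend the fitted surface exactly", {
  regions <- "A"
  years <- 2000:2014
  sdi <- data.frame(region = "A", year = years, sdi = 0.6)
  hist <- generate_mortality_history(
    ground_truth(beta1 = -2, beta2 = -4, theta_a = 0, alpha = -7,
                 ar_phi = 0, sigma = 0),
    regions, years, sdi, seed = 5, ages = c("25-30", "65-70"),
    hierarchy = one_cause_hierarchy())
  fit <- suppressWarnings(fit_trend(hist, sdi, "X"))
  fut <- data.frame(region = "A", year = 2015:2020, sdi = 0.6)
  fc <- suppressWarnings(forecast_rates(fit, fut))
  last <- hist[hist$year == 2014, ]
  for (ag in c("25-30", "65-70")) {
    expect_equal(fc$rate[fc$age == ag],
                 rep(last$rate[last$age == ag], 6), tolerance = 1e-10)
  }
  expect_error(suppressWarnings(
    forecast_rates(fit, data.frame(region = "A", year = 2015, sdi = NA))),
    class = "invalid_argument")
})

test_that("forecast intervals are symmetric on the log scale", {
  d <- make_history(7, truth = ground_truth(beta1 = -2, beta2 = -4,
                                            theta_a = -0.01, alpha = -7,
                                            ar_phi = 0, sigma = 0.05))
  fit <- fit_trend(d$hist, d$sdi, "X")
  fut <- generate_sdi(paste0("R", 1:4), 2015:2019, seed = 7)
  for (mode in c("standard", "as-printed")) {
    fc <- forecast_rates(fit, fut, ci_mode = mode)
    expect_equal(fc$upper / fc$rate, fc$rate / fc$lower, tolerance = 1e-10)
    expect_true(all(fc$lower <= fc$rate & fc$rate <= fc$upper))
  }
})

test_that("negative age trends give strictly decreasing noise-free forecasts", {
  d <- make_history(8, truth = ground_truth(beta1 = -2, beta2 = -4,
                                            theta_a = -0.02, alpha = -7,
                                            ar_phi = 0, sigma = 0),
                    years = 2000:2013)
  fit <- fit_trend(d$hist, d$sdi, "X")
  last <- d$sdi[d$sdi$year == 2013, ]
  fut <- expand.grid(region = paste0("R", 1:4), year = 2014:2019,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  fut$sdi <- last$sdi[match(fut$region, last$region)]
  fc <- suppressWarnings(forecast_rates(fit, fut))
  g <- fc[fc$age == "65-70" & fc$region == "R1", ]
  expect_true(all(diff(g$rate[order(g$year)]) < 0))
})

test_that("envelope constraining matches worked factors and conserves", {
  base <- data.frame(region = "A", year = 2030L, age = "65-70")
  l2 <- rbind(cbind(base, cause = "NCD", rate = 0.006),
              cbind(base, cause = "CMNND", rate = 0.003),
              cbind(base, cause = "injuries", rate = 0.001))
  env <- cbind(base, cause = "all", rate = 0.008)
  out <- constrain_level2(l2, env)
  expect_equal(out$rate, c(0.0048, 0.0024, 0.0008), tolerance = 1e-15)
  # already consistent: unit factor
  env2 <- cbind(base, cause = "all", rate = 0.010)
  expect_equal(constrain_level2(l2, env2)$rate, l2$rate, tolerance = 1e-15)
  # printed orientation scales by sum/envelope instead
  out_printed <- constrain_level2(l2, env, orientation = "as-printed")
  expect_equal(out_printed$rate, l2$rate * 0.010 / 0.008, tolerance = 1e-15)
  # level-3 children (2, 2, 1)e-4 against a 4e-4 parent
  l3 <- rbind(cbind(base, cause = "COPD", rate = 2e-4),
              cbind(base, cause = "IHD", rate = 2e-4),
              cbind(base, cause = "rest_NCD", rate = 1e-4))
  parent <- cbind(base, cause = "NCD", rate = 4e-4)
  out3 <- constrain_level3(l3, parent)
  expect_equal(out3$rate, c(1.6e-4, 1.6e-4, 0.8e-4), tolerance = 1e-15)
  expect_error(constrain_level2(transform(l2, rate = 0), env),
               class = "undefined_value")
})

test_that("two-round constraining nests exactly at both levels", {
  for (s in 1:5) {
    tab <- random_hierarchy_table(s)
    out <- constrain_hierarchy(tab)
    key <- c("region", "year", "age")
    l1 <- out[out$cause_level == 1, c(key, "rate")]
    l2 <- aggregate(rate ~ region + year + age, out[out$cause_level == 2, ], sum)
    m <- merge(l2, l1, by = key)
    expect_equal(m$rate.x, m$rate.y, tolerance = 1e-12)
    for (p in c("NCD", "CMNND")) {
      kids <- aggregate(rate ~ region + year + age,
                        out[out$cause_level == 3 & out$parent == p, ], sum)
      par <- out[out$cause == p, c(key, "rate")]
      mp <- merge(kids, par, by = key)
      expect_equal(mp$rate.x, mp$rate.y, tolerance = 1e-12)
    }
  }
})
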