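lake_rec <- function(dates, values, lake = "testlake", depth = 5,
                     variable = "temperature") {
  data.frame(lake = lake, date = as.Date(dates), depth_m = depth,
             variable = variable, value = values)
}

test_that("growing-season summaries average within years first", {
  rec <- lake_rec(c("2020-08-15", "2020-09-15", "2020-10-15"), c(18, 16, 14))
  s <- summarize_lake(rec, years = 2020)
  expect_equal(s$mean_value, 16)
  expect_equal(s$method, "direct")

  # identical records across years reproduce the constant
  rec5 <- do.call(rbind, lapply(2018:2022, function(y) {
    lake_rec(sprintf("%d-09-01", y), 15.5)
  }))
  expect_equal(summarize_lake(rec5)$mean_value, 15.5)

  # unbalanced years: equal year weights, not record weights
  recu <- rbind(
    lake_rec(sprintf("2020-08-%02d", 1:9), rep(16, 9)),
    lake_rec("2021-09-01", 18)
  )
  s2 <- summarize_lake(recu, years = 2020:2021)
  expect_equal(s2$mean_value, 17)              # (16 + 18) / 2
  expect_false(isTRUE(all.equal(mean(recu$value), 17))) # pooled mean differs
})

test_that("out-of-window or off-depth records are rejected with the lake named", {
  rec <- lake_rec("2020-02-01", 4)
  expect_error(summarize_lake(rec), "testlake")
  deep <- lake_rec("2020-09-01", 8, depth = 30)
  expect_error(summarize_lake(deep), "testlake")
  # depth-integrated records (all depths missing) pass with method noted
  integr <- lake_rec("2020-09-01", 12, depth = NA)
  s <- summarize_lake(integr, years = 2020)
  expect_equal(s$method, "integrated")
  expect_equal(s$mean_value, 12)
})

test_that("the seasonal regression recovers a noiseless generating model exactly", {
  dates <- seq(as.Date("2018-01-10"), as.Date("2022-12-10"), by = "month")
  rec <- simulate_lake_monitoring(dates, mean = 11, trend = 0.3, amplitude = 6,
                                  phase = 0.7, noise_sd = 0, seed = 1)
  m <- fit_seasonal_model(rec)
  expect_equal(m$year_slope, 0.3, tolerance = 1e-9)
  expect_equal(m$amplitude, 6, tolerance = 1e-9)
  expect_equal(m$sin_coef, 6 * cos(0.7), tolerance = 1e-9)
  expect_equal(m$cos_coef, 6 * sin(0.7), tolerance = 1e-9)
  expect_lt(m$residual_sd, 1e-9)

  # zero-amplitude truth yields null harmonic terms
  rec0 <- simulate_lake_monitoring(dates, mean = 11, trend = 0.3, amplitude = 0,
                                   noise_sd = 0, seed = 1)
  m0 <- fit_seasonal_model(rec0)
  expect_equal(m0$amplitude, 0, tolerance = 1e-9)
})

test_that("seasonal amplitude is recovered within 10% from noisy monthly records", {
  dates <- seq(as.Date("2018-01-15"), as.Date("2022-12-15"), by = "month")
  rec <- simulate_lake_monitoring(dates, mean = 12, trend = 0.1, amplitude = 7,
                                  phase = -2, noise_sd = 0.2, seed = 7)
  m <- fit_seasonal_model(rec)
  expect_equal(m$amplitude, 7, tolerance = 0.1)
})

test_that("degenerate seasonal inputs are rejected", {
  same_day <- lake_rec(sprintf("%d-06-15", 2014:2022), 10 + 0.1 * (1:9))
  expect_error(fit_seasonal_model(same_day), "day of year")
  few <- lake_rec(c("2020-01-01", "2021-06-01"), c(4, 18))
  expect_error(fit_seasonal_model(few), ">= 8")
})

test_that("modeled growing-season means agree with direct means on dense data", {
  dates <- seq(as.Date("2018-01-02"), as.Date("2022-12-30"), by = "week")
  rec <- simulate_lake_monitoring(dates, mean = 12, trend = 0.2, amplitude = 6,
                                  phase = -2, noise_sd = 0, seed = 1)
  m <- fit_seasonal_model(rec)
  modeled <- predict_season_mean(m, 2018:2022)
  direct <- summarize_lake(rec)$mean_value
  expect_equal(modeled, direct, tolerance = 0.1)

  # trivial models
  flat <- fit_seasonal_model(simulate_lake_monitoring(dates, mean = 9, trend = 0,
                                                      amplitude = 0, noise_sd = 0))
  expect_equal(predict_season_mean(flat, 2018:2022), 9, tolerance = 1e-9)
  # a pure linear trend averages to the line's value at the window midpoint
  lin <- fit_seasonal_model(simulate_lake_monitoring(dates, mean = 9, trend = 1,
                                                     amplitude = 0, noise_sd = 0))
  mid <- mean(vapply(2018:2022, function(y) {
    d6 <- seq(as.Date(sprintf("%d-08-01", y)), as.Date(sprintf("%d-10-31", y)), length.out = 6)
    yy <- as.integer(format(d6, "%Y"))
    mean(yy + as.numeric(d6 - as.Date(sprintf("%d-01-01", yy[1]))) /
           as.numeric(as.Date(sprintf("%d-01-01", yy[1] + 1)) - as.Date(sprintf("%d-01-01", yy[1]))))
  }, numeric(1)))
  expect_equal(predict_season_mean(lin, 2018:2022), 9 + 1 * (mid - 2018), tolerance = 1e-9)
})

test_that("summaries shift by exactly a constant temperature offset", {
  dates <- seq(as.Date("2018-01-15"), as.Date("2022-12-15"), by = "month")
  rec <- simulate_lake_monitoring(dates, mean = 12, amplitude = 6, noise_sd = 0.3, seed = 2)
  rec2 <- rec; rec2$value <- rec2$value + 3.3
  expect_equal(summarize_lake(rec2)$mean_value,
               summarize_lake(rec)$mean_value + 3.3, tolerance = 1e-12)
  expect_equal(predict_season_mean(fit_seasonal_model(rec2)),
               predict_season_mean(fit_seasonal_model(rec)) + 3.3, tolerance = 1e-9)
})
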