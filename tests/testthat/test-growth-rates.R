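test_that("detection limit is half the median blank fluorescence", {
  expect_equal(compute_detection_limit(c(4, 4.5, 5)), 2.25)
  expect_equal(compute_detection_limit(rep(3, 10)), 1.5)
  expect_equal(compute_detection_limit(c(1, 2, 100)), 1) # robust to outliers
  expect_error(compute_detection_limit(numeric(0)), "nonempty")
})

test_that("below-detection readings are removed, metadata and order preserved", {
  s <- data.frame(strain = "s", time_days = 0:10, rfu = c(1, 2, 11:16, 2.2, 18, 19))
  expect_identical(filter_series(s, 0.5), s)                  # all retained
  expect_equal(nrow(filter_series(s, 100)), 0)                # all removed
  kept <- filter_series(s, 2.25)
  expect_equal(nrow(kept), 8)
  expect_true(!is.unsorted(kept$time_days))
  expect_true(all(kept$rfu >= 2.25))
  expect_equal(kept$strain, rep("s", 8))
  expect_error(filter_series(s, 0), "positive")
})

test_that("AICc matches the closed form and penalizes parameters", {
  # hand evaluation of n log(rss/n) + 2p + 2p(p+1)/(n-p-1)
  expect_equal(aicc(1, 10, 2), 10 * log(1 / 10) + 4 + 12 / 7, tolerance = 1e-12)
  # penalty monotonicity at equal rss
  expect_gt(aicc(2, 10, 3), aicc(2, 10, 2))
  # AICc converges to AIC at large n
  n <- 1e6
  expect_equal(aicc(1, n, 2) - (n * log(1 / n) + 4), 0, tolerance = 1e-4)
  expect_identical(aicc(1, 4, 3), Inf)
})

test_that("noiseless exponential input recovers the generating slope in all models", {
  t <- c(0, seq(0.5, 4, by = 0.5), 5, 6)
  s <- data.frame(time_days = t, rfu = 10 * exp(0.8 * t))
  fits <- fit_growth_models(s)
  expect_setequal(names(fits),
                  c("exponential", "lag", "saturation", "lag_saturation"))
  for (f in fits) expect_equal(f$mu, 0.8, tolerance = 1e-9)
  # the penalty forces the simplest model
  expect_equal(select_best(fits)$model, "exponential")
})

test_that("a noiseless lag series is attributed to the lag model with the right breakpoint", {
  t <- seq(0, 5, by = 0.5)
  y <- ifelse(t <= 1, log(10), log(10) + 0.5 * (t - 1))
  s <- data.frame(time_days = t, rfu = exp(y))
  best <- select_best(fit_growth_models(s))
  expect_equal(best$model, "lag")
  expect_equal(best$mu, 0.5, tolerance = 1e-9)
  expect_equal(best$lag_time, 1.0)
})

test_that("short series only admit the single-line model", {
  s <- data.frame(time_days = c(0, 1, 2), rfu = c(10, 20, 41))
  fits <- fit_growth_models(s)
  expect_named(fits, "exponential")
  expect_error(fit_growth_models(s[1:2, ]), ">= 3")
  expect_error(select_best(list()), "no growth model")
})

test_that("AICc ties break toward the model with fewer parameters", {
  f1 <- structure(list(model = "exponential", p = 2L, aicc = 5, mu = 1), class = "growth_fit")
  f2 <- structure(list(model = "lag", p = 3L, aicc = 5, mu = 1), class = "growth_fit")
  expect_equal(select_best(list(f2, f1))$model, "exponential")
})

test_that("growth-rate estimates are invariant to rescaling fluorescence", {
  set.seed(42)
  t <- c(0, seq(0.5, 4, by = 0.5), 5, 6)
  for (i in 1:5) {
    rfu <- 10 * exp(0.4 * t) * exp(rnorm(length(t), 0, 0.1))
    f1 <- select_best(fit_growth_models(data.frame(time_days = t, rfu = rfu)))
    f2 <- select_best(fit_growth_models(data.frame(time_days = t, rfu = 7.3 * rfu)))
    expect_equal(f2$mu, f1$mu, tolerance = 1e-10)
    expect_equal(f2$model, f1$model)
    expect_equal(f2$intercept - f1$intercept, log(7.3), tolerance = 1e-10)
  }
})

test_that("segmented fits equal the brute-force breakpoint oracle on noisy series", {
  set.seed(7)
  t <- c(0, seq(0.5, 4, by = 0.5), 5, 6)
  for (i in 1:20) {
    lag <- runif(1, 0, 2); sat <- runif(1, 3, 6); mu <- runif(1, 0.2, 1)
    y <- log(10) + mu * (pmin(pmax(t, lag), sat) - lag) + rnorm(length(t), 0, 0.08)
    s <- data.frame(time_days = t, rfu = exp(y))
    fits <- fit_growth_models(s)
    oracle <- oracle_segmented(t, y)
    for (m in names(oracle$per_model)) {
      expect_equal(fits[[m]]$rss, oracle$per_model[[m]]$rss, tolerance = 1e-9)
      expect_equal(fits[[m]]$mu, oracle$per_model[[m]]$mu, tolerance = 1e-9)
    }
    best <- select_best(fits)
    expect_equal(best$model, oracle$best$model)
    expect_equal(best$aicc, oracle$best$aicc, tolerance = 1e-9)
  }
})

test_that("the batched well table matches per-well fits and counts wells", {
  truth <- make_truth(2, 1, seed = 3)[[1]]
  design <- experiment_design(temperature_levels = c(12, 20, 26),
                              phosphorus_levels = c(1.94, 7.75, 47.47),
                              replicates = 2)
  series <- simulate_series(truth, design, seed = 8)
  tab <- growth_rate_table(series, 2.25)
  expect_equal(attr(tab, "wells_read"), 3 * 3 * 2)
  for (k in seq_len(nrow(tab))) {
    w <- series[series$temperature_C == tab$temperature_C[k] &
                  series$phosphorus_umol_L == tab$phosphorus_umol_L[k] &
                  series$replicate == tab$replicate[k], ]
    f <- fit_growth(w, 2.25)
    expect_equal(tab$mu_per_day[k], f$mu, tolerance = 1e-12)
    expect_equal(tab$model[k], f$model)
  }
})

test_that("wells left with fewer than three usable points are excluded", {
  s <- data.frame(strain = "s", temperature_C = 12, phosphorus_umol_L = 1.94,
                  replicate = c(rep(1, 11), rep(2, 11)),
                  time_days = rep(c(0, seq(0.5, 4, 0.5), 5, 6), 2),
                  rfu = c(rep(1, 9), 8, 9, 10 * exp(0.3 * c(0, seq(0.5, 4, 0.5), 5, 6))))
  tab <- growth_rate_table(s, 2.25)
  expect_equal(nrow(tab), 1)
  expect_equal(length(attr(tab, "excluded")), 1)
  expect_equal(attr(tab, "wells_read"), 2)
})
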