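make_tpc_rates <- function(a, b, t_ref, w, temps = c(12, 16, 20, 22, 24, 26),
                           reps = 4, cv = 0, seed = 1) {
  set.seed(seed)
  tt <- rep(temps, reps)
  mu <- thomas_tpc(tt, a, b, t_ref, w)
  if (cv > 0) mu <- mu * exp(rnorm(length(mu), 0, sqrt(log(1 + cv^2))))
  data.frame(temperature = tt, mu = mu)
}

test_that("noiseless forward-simulated curves are recovered exactly", {
  rates <- make_tpc_rates(0.2, 0.05, 18, 30)
  fit <- fit_tpc(rates, n_starts = 100, seed = 1)
  expect_true(fit$estimable)
  expect_lt(fit$rss, 1e-10)
  expect_equal(unname(fit$par), c(0.2, 0.05, 18, 30), tolerance = 1e-4)
  # structural zeros at the niche limits
  expect_equal(predict(fit, fit$par[["t_ref"]] - fit$par[["w"]] / 2), 0, tolerance = 1e-10)
  expect_equal(predict(fit, fit$par[["t_ref"]] + fit$par[["w"]] / 2), 0, tolerance = 1e-10)
})

test_that("multi-start fitting never does worse than the default start and is seeded", {
  rates <- make_tpc_rates(0.15, 0.06, 20, 35, cv = 0.15, seed = 3)
  f1 <- fit_tpc(rates, n_starts = 60, seed = 2)
  f2 <- fit_tpc(rates, n_starts = 60, seed = 2)
  expect_identical(f1$par, f2$par)
  f0 <- fit_tpc(rates, n_starts = 0, seed = 2) # default start only
  expect_lte(f1$rss, f0$rss + 1e-12)
})

test_that("all-negative rates are flagged non-estimable", {
  rates <- data.frame(temperature = rep(c(12, 16, 20, 24), 2), mu = -runif(8, 0.1, 0.5))
  fit <- fit_tpc(rates, n_starts = 10, seed = 1)
  expect_false(fit$estimable)
  expect_error(rising_part(rates, fit), "not estimable")
})

test_that("the optimum temperature matches its closed form and limits", {
  # b -> 0 reduces to the quadratic maximum
  expect_equal(tpc_topt(0, 18, 30), 18)
  expect_equal(tpc_topt(1e-14, 18, 30), 18, tolerance = 1e-8)
  # grid-search oracle
  expect_equal(tpc_topt(0.05, 18, 30), oracle_topt_grid(1, 0.05, 18, 30),
               tolerance = 1e-2)
  expect_equal(tpc_topt(-0.2, 25, 20), oracle_topt_grid(1, -0.2, 25, 20),
               tolerance = 1e-2)
  # sign symmetry
  expect_lt(tpc_topt(-0.05, 18, 30), 18)
  expect_gt(tpc_topt(0.05, 18, 30), 18)
})

test_that("the area under the curve is a converged trapezoidal integral", {
  rates <- make_tpc_rates(0.2, 0.05, 18, 30)
  fit <- fit_tpc(rates, n_starts = 50, seed = 1)
  a1 <- autpc(fit, 12, 26, grid_step = 0.1)
  a2 <- autpc(fit, 12, 26, grid_step = 0.001)
  expect_equal(a1, a2, tolerance = 1e-3) # refinement changes < 0.1%
  # a pointwise-dominating curve has a larger area
  hi <- fit; hi$par[["a"]] <- fit$par[["a"]] * 1.3
  expect_gt(autpc(hi, 12, 26), autpc(fit, 12, 26))
})

test_that("an effectively constant unit curve integrates to the range width", {
  flat <- structure(list(par = c(a = 1, b = 0, t_ref = 19, w = 1e9),
                         estimable = TRUE), class = "tpc_fit")
  expect_equal(autpc(flat, 12, 26), 14, tolerance = 1e-9)
})

test_that("bootstrap bands are seeded and collapse on noise-free data", {
  rates <- make_tpc_rates(0.2, 0.05, 18, 30)
  bt1 <- bootstrap_tpc(rates, B = 20, seed = 5, n_starts = 2)
  bt2 <- bootstrap_tpc(rates, B = 20, seed = 5, n_starts = 2)
  expect_identical(bt1$band, bt2$band)
  expect_lt(max(bt1$band$upper - bt1$band$lower), 1e-6)
  expect_lt(diff(bt1$autpc_ci), 1e-6)
})

test_that("the rising limb keeps positive rates up to the fitted optimum", {
  # T_opt inside the experimental range: warmer points are excluded
  rates <- make_tpc_rates(0.4, 0.01, 21, 30) # T_opt ~ 22.1 degC
  fit <- fit_tpc(rates, n_starts = 80, seed = 1)
  expect_equal(fit$t_opt, 22, tolerance = 0.3)
  rp <- rising_part(rates, fit)
  expect_true(all(rp$temperature <= fit$t_opt))
  expect_false(any(rp$temperature %in% c(24, 26)))
  # monotonically rising curve: every positive rate retained
  rates2 <- make_tpc_rates(0.1, 0.08, 24, 40) # T_opt above 26 degC
  fit2 <- fit_tpc(rates2, n_starts = 80, seed = 1)
  expect_gt(fit2$t_opt, 26)
  expect_equal(nrow(rising_part(rates2, fit2)), nrow(rates2))
})

test_that("activation energy regression matches Arrhenius hand computations", {
  k <- boltzmann_ev
  # noiseless truth Ea = 0.32 eV
  temps <- seq(12, 26, by = 2)
  mu <- 5e4 * exp(-0.32 / (k * (temps + 273.15)))
  af <- fit_arrhenius(data.frame(temperature = temps, mu = mu))
  expect_equal(af$ea, 0.32, tolerance = 1e-10)
  expect_equal(af$r2, 1, tolerance = 1e-10)
  # temperature-independent growth has zero activation energy
  af0 <- fit_arrhenius(data.frame(temperature = temps, mu = rep(0.5, length(temps))))
  expect_equal(af0$ea, 0, tolerance = 1e-12)
  # two-point hand case (T = 285 K and 295 K, rate doubling):
  # Ea = ln 2 * k / (1/285 - 1/295) = 0.5023 eV; add a third midpoint on the
  # same line to satisfy the n >= 3 contract
  tk <- c(285, 290, 295)
  ea_hand <- log(2) * k / (1 / 285 - 1 / 295)
  mu3 <- exp(log(2) * (1 / 285 - 1 / tk) / (1 / 285 - 1 / 295))
  af2 <- fit_arrhenius(data.frame(temperature = tk - 273.15, mu = mu3))
  expect_equal(af2$ea, ea_hand, tolerance = 1e-6)
  expect_equal(ea_hand, 0.502, tolerance = 1e-3)
  # rescaling rates shifts only the pre-exponential factor
  af3 <- fit_arrhenius(data.frame(temperature = tk - 273.15, mu = 3.7 * mu3))
  expect_equal(af3$ea, af2$ea, tolerance = 1e-12)
  expect_equal(af3$ln_a - af2$ln_a, log(3.7), tolerance = 1e-9)
  expect_error(fit_arrhenius(data.frame(temperature = c(12, 16, 20), mu = c(1, -1, 2))),
               "positive")
  expect_error(fit_arrhenius(data.frame(temperature = c(12, 16), mu = c(1, 2))), ">= 3")
})

test_that("strain-level activation energy summaries test against the reference", {
  s <- ea_summary(rep(0.32, 5))
  expect_equal(s$t_stat, 0)
  expect_equal(s$p_value, 1)
  s2 <- ea_summary(c(0.22, 0.32, 0.42)) # symmetric about the reference
  expect_equal(s2$mean_ea, 0.32)
  expect_equal(s2$t_stat, 0, tolerance = 1e-12)
  # textbook one-sample t-test
  vals <- c(0.5, 0.6, 0.7)
  s3 <- ea_summary(vals)
  t_hand <- (mean(vals) - 0.32) / (sd(vals) / sqrt(3))
  expect_equal(s3$t_stat, t_hand, tolerance = 1e-12)
  expect_equal(s3$p_value, 2 * pt(-abs(t_hand), df = 2), tolerance = 1e-12)
})
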