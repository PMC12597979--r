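#' Thermal performance curve (exponential envelope times downward quadratic)
#'
#' R(T) = a exp(b T) (1 - ((T - T_ref) / (w / 2))^2). The curve has
#' structural zeros at T_ref +/- w/2 (the thermal niche limits), is positive
#' between them, and its maximum lies at
#' T_ref + (sqrt(1 + b^2 (w/2)^2) - 1) / b.
#'
#' @param temperature degC.
#' @param a rate scale (per day).
#' @param b exponential envelope scale (per degC).
#' @param t_ref centre of the quadratic term, degC.
#' @param w thermal niche width, degC (> 0).
#' @return growth rate, per day.
#' @export
thomas_tpc <- function(temperature, a, b, t_ref, w) {
  a * exp(b * temperature) * (1 - ((temperature - t_ref) / (w / 2))^2)
}

#' Optimum temperature of a fitted thermal performance curve
#'
#' Closed form: T_opt = T_ref + (sqrt(1 + b^2 (w/2)^2) - 1) / b, reducing to
#' T_ref as b -> 0.
#'
#' @param b,t_ref,w curve parameters, or a `tpc_fit` as first argument.
#' @return T_opt in degC.
#' @export
tpc_topt <- function(b, t_ref, w) {
  if (inherits(b, "tpc_fit")) {
    fit <- b
    b <- fit$par[["b"]]; t_ref <- fit$par[["t_ref"]]; w <- fit$par[["w"]]
  }
  if (abs(b) < 1e-12) return(t_ref)
  t_ref + (sqrt(1 + b^2 * (w / 2)^2) - 1) / b
}

# default multi-start bounds: generous biological ranges
.tpc_lower <- c(a = 1e-6, b = -1, t_ref = 0, w = 5 + 1e-6)
.tpc_upper <- c(a = 10, b = 1, t_ref = 40, w = 80)

#' Fit a thermal performance curve by multi-start least squares
#'
#' Minimises the residual sum of squares of [thomas_tpc()] against observed
#' (temperature, growth rate) pairs. Starting values are drawn uniformly
#' within documented bounds (a in (0,10], b in [-1,1], T_ref in [0,40],
#' w in (5,80]) plus one fixed default start; each start is refined by
#' bounded Levenberg-Marquardt and the lowest-RSS solution is returned.
#' Refitting with the same seed reproduces the result exactly.
#'
#' @param rates data.frame with columns `temperature` (degC) and `mu`
#'   (per day); negative rates are allowed.
#' @param n_starts number of random starts (default 250).
#' @param seed integer RNG seed for the random starts.
#' @param lower,upper named bounds for (a, b, t_ref, w).
#' @return object of class `tpc_fit` with elements `par` (a, b, t_ref, w),
#'   `t_opt`, `rss`, `estimable`, `data`.
#' @export
fit_tpc <- function(rates, n_starts = 250L, seed = 1L,
                    lower = .tpc_lower, upper = .tpc_upper) {
  stopf(length(unique(rates$temperature)) >= 4,
        "need >= 4 distinct temperatures to fit a 4-parameter curve")
  out <- structure(list(par = c(a = NA_real_, b = NA_real_, t_ref = NA_real_, w = NA_real_),
                        t_opt = NA_real_, rss = NA_real_, estimable = FALSE,
                        data = rates, n_starts = n_starts, seed = seed),
                   class = "tpc_fit")
  if (all(rates$mu <= 0)) return(out)
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  starts <- rbind(
    c(a = 0.1, b = 0.05, t_ref = mean(range(rates$temperature)), w = 40),
    matrix(stats::runif(4 * n_starts, lower, upper), ncol = 4, byrow = TRUE,
           dimnames = list(NULL, names(lower)))
  )
  best <- NULL
  sse <- function(p) {
    r <- rates$mu - thomas_tpc(rates$temperature, p[1], p[2], p[3], p[4])
    sum(r * r)
  }
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        mu ~ thomas_tpc(temperature, a, b, t_ref, w),
        data = rates, start = as.list(starts[i, ]),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15, ptol = 1e-15)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    p <- stats::coef(fit)
    val <- sse(p)
    if (is.null(best) || val < best$rss) best <- list(par = p, rss = val)
  }
  if (is.null(best)) {
    # fall back to bounded quasi-Newton on the SSE surface
    for (i in seq_len(nrow(starts))) {
      o <- tryCatch(stats::optim(starts[i, ], sse, method = "L-BFGS-B",
                                 lower = lower, upper = upper,
                                 control = list(maxit = 500)),
                    error = function(e) NULL)
      if (is.null(o)) next
      if (is.null(best) || o$value < best$rss) best <- list(par = o$par, rss = o$value)
    }
  }
  if (is.null(best)) return(out)
  out$par <- best$par
  out$rss <- best$rss
  out$t_opt <- tpc_topt(best$par[["b"]], best$par[["t_ref"]], best$par[["w"]])
  out$estimable <- TRUE
  out
}

# trapezoidal rule on an ordered grid
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Area under a fitted thermal performance curve
#'
#' Trapezoidal integral of the fitted curve on a uniform temperature grid
#' over the experimental range (12-26 degC by default, 0.1 degC steps).
#'
#' @param fit a `tpc_fit`.
#' @param t_min,t_max integration range, degC.
#' @param grid_step grid spacing, degC.
#' @return area in (per day) x degC.
#' @export
autpc <- function(fit, t_min = 12, t_max = 26, grid_step = 0.1) {
  stopf(t_min < t_max, "t_min must be below t_max")
  stopf(grid_step > 0, "grid_step must be positive")
  grid <- seq(t_min, t_max, by = grid_step)
  if (grid[length(grid)] < t_max) grid <- c(grid, t_max)
  trapz(grid, predict(fit, grid))
}

#' Bootstrap confidence band for a thermal performance curve
#'
#' Nonparametric case resampling of the observed (temperature, rate) pairs:
#' each resample is refitted (starting from the point estimate plus a few
#' random starts), and pointwise 2.5/97.5 percentile bands, an AUTPC
#' interval and a T_opt interval are taken over the resamples. Resamples
#' retaining fewer than 4 distinct temperatures, or failing to fit, are
#' skipped and counted. Resampling can optionally be stratified by
#' temperature level; the unstratified default keeps interval widths honest
#' when levels carry only a handful of replicates each.
#'
#' @param rates data.frame with `temperature` and `mu`.
#' @param B number of bootstrap resamples (study convention 1000).
#' @param seed integer RNG seed.
#' @param n_starts random starts per refit (the point estimate is always
#'   included as a start).
#' @param temp_grid temperatures at which the band is evaluated.
#' @param t_min,t_max AUTPC integration range.
#' @param stratify resample within each temperature level instead of from
#'   the pooled observations.
#' @return list with `band` (data.frame temperature, lower, upper),
#'   `autpc_ci`, `t_opt_ci`, `n_ok`, `n_skipped`, and the point `fit`.
#' @export
bootstrap_tpc <- function(rates, B = 1000L, seed = 1L, n_starts = 10L,
                          temp_grid = seq(12, 26, by = 0.5),
                          t_min = 12, t_max = 26, stratify = FALSE) {
  stopf(B >= 2, "B must be >= 2")
  fit <- fit_tpc(rates, seed = seed)
  stopf(fit$estimable, "point fit is not estimable; cannot bootstrap")
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  n <- nrow(rates)
  strata <- if (stratify) split(seq_len(n), rates$temperature) else NULL
  preds <- matrix(NA_real_, B, length(temp_grid))
  areas <- topts <- rep(NA_real_, B)
  n_skipped <- 0L
  for (b in seq_len(B)) {
    idx <- if (stratify) {
      unlist(lapply(strata, function(s) s[sample.int(length(s), length(s), replace = TRUE)]),
             use.names = FALSE)
    } else {
      sample.int(n, n, replace = TRUE)
    }
    rs <- rates[idx, , drop = FALSE]
    if (length(unique(rs$temperature)) < 4) { n_skipped <- n_skipped + 1L; next }
    bfit <- .refit_tpc(rs, fit$par, n_starts)
    if (is.null(bfit)) { n_skipped <- n_skipped + 1L; next }
    preds[b, ] <- thomas_tpc(temp_grid, bfit$par[1], bfit$par[2], bfit$par[3], bfit$par[4])
    tmp <- fit; tmp$par <- bfit$par
    areas[b] <- autpc(tmp, t_min, t_max)
    topts[b] <- tpc_topt(bfit$par[["b"]], bfit$par[["t_ref"]], bfit$par[["w"]])
  }
  qs <- function(v) stats::quantile(v, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  band <- apply(preds, 2, qs)
  list(
    band = data.frame(temperature = temp_grid, lower = band[1, ], upper = band[2, ]),
    autpc_ci = qs(areas), t_opt_ci = qs(topts),
    autpc_boot_mean = mean(areas, na.rm = TRUE),
    n_ok = sum(is.finite(areas)), n_skipped = n_skipped, fit = fit
  )
}

# refit helper used by the bootstrap: point-estimate start plus a few random
# starts, Levenberg-Marquardt only (no exhaustive multi-start)
.refit_tpc <- function(rates, par0, n_starts) {
  starts <- rbind(par0,
                  matrix(stats::runif(4 * n_starts, .tpc_lower, .tpc_upper),
                         ncol = 4, byrow = TRUE, dimnames = list(NULL, names(par0))))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(mu ~ thomas_tpc(temperature, a, b, t_ref, w),
                        data = rates, start = as.list(starts[i, ]),
                        lower = .tpc_lower, upper = .tpc_upper,
                        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(par = stats::coef(fit), rss = rss)
  }
  best
}

#' Observations on the rising limb of a thermal performance curve
#'
#' Retains positive growth rates at temperatures at or below the fitted
#' optimum (or the empirical maximum-rate temperature). When T_opt exceeds
#' the warmest experimental temperature, every positive rate is retained.
#'
#' @param rates data.frame with `temperature` and `mu`.
#' @param fit a `tpc_fit` for the same data.
#' @param method `"fitted_topt"` (default) or `"empirical_max"`.
#' @return subset of `rates`.
#' @export
rising_part <- function(rates, fit, method = c("fitted_topt", "empirical_max")) {
  method <- match.arg(method)
  stopf(fit$estimable, "TPC fit is not estimable")
  cut <- if (method == "fitted_topt") fit$t_opt else
    rates$temperature[which.max(rates$mu)]
  # if T_opt exceeds the warmest experimental temperature the cut is inactive
  # and every positive-rate observation is retained
  rates[rates$mu > 0 & rates$temperature <= cut, , drop = FALSE]
}

#' Arrhenius activation energy of population growth
#'
#' Ordinary least squares of ln(mu) on 1/(k T) with T in Kelvin and k the
#' Boltzmann constant (8.62e-5 eV/K). The activation energy is minus the
#' regression slope, so growth that accelerates with temperature yields a
#' positive E_a, consistent with R = A exp(-E_a / kT).
#'
#' @param rates data.frame with `temperature` (degC) and `mu` (per day, all
#'   positive; use [rising_part()] first).
#' @return object of class `arrhenius_fit`: `ea` (eV), `se_ea`, `ln_a`,
#'   `r2`, `n`.
#' @export
fit_arrhenius <- function(rates) {
  stopf(nrow(rates) >= 3, "need >= 3 points for an Arrhenius regression")
  stopf(all(rates$mu > 0), "all growth rates must be positive on the rising limb")
  x <- 1 / (boltzmann_ev * (rates$temperature + 273.15))
  fit <- stats::lm(log(rates$mu) ~ x)
  sm <- summary(fit)
  structure(list(
    ea = -unname(stats::coef(fit)[2]),
    se_ea = unname(sm$coefficients[2, 2]),
    ln_a = unname(stats::coef(fit)[1]),
    r2 = sm$r.squared,
    n = nrow(rates),
    lm = fit
  ), class = "arrhenius_fit")
}

#' Summarise a strain's activation energies against a theoretical reference
#'
#' Mean and SD of activation energies across phosphorus levels and a
#' two-sided one-sample t-test against the metabolic expectation for C3
#' photoautotrophs (0.32 eV).
#'
#' @param eas numeric vector of activation energies (eV).
#' @param reference reference value, eV.
#' @return list with mean_ea, sd_ea, t_stat, p_value, n, reference.
#' @export
ea_summary <- function(eas, reference = 0.32) {
  eas <- eas[is.finite(eas)]
  out <- list(mean_ea = mean(eas), sd_ea = stats::sd(eas),
              t_stat = NA_real_, p_value = NA_real_,
              n = length(eas), reference = reference)
  if (length(eas) >= 2 && stats::sd(eas) > 0) {
    tt <- stats::t.test(eas, mu = reference)
    out$t_stat <- unname(tt$statistic)
    out$p_value <- tt$p.value
  } else if (length(eas) >= 2) {
    out$t_stat <- if (mean(eas) == reference) 0 else Inf * sign(mean(eas) - reference)
    out$p_value <- if (mean(eas) == reference) 1 else 0
  }
  class(out) <- "ea_summary"
  out
}

#' @export
print.tpc_fit <- function(x, ...) {
  if (!x$estimable) {
    cat("<tpc_fit> not estimable (no positive growth or degenerate data)\n")
    return(invisible(x))
  }
  cat(sprintf("<tpc_fit> a = %.4f, b = %.4f, T_ref = %.2f, w = %.2f\n",
              x$par[["a"]], x$par[["b"]], x$par[["t_ref"]], x$par[["w"]]))
  cat(sprintf("  T_opt = %.2f degC, niche (%.2f, %.2f) degC, rss = %.3g\n",
              x$t_opt, x$par[["t_ref"]] - x$par[["w"]] / 2,
              x$par[["t_ref"]] + x$par[["w"]] / 2, x$rss))
  invisible(x)
}

#' @export
coef.tpc_fit <- function(object, ...) object$par

#' @export
predict.tpc_fit <- function(object, newdata = NULL, ...) {
  temperature <- if (is.null(newdata)) object$data$temperature
                 else if (is.data.frame(newdata)) newdata$temperature
                 else newdata
  p <- object$par
  thomas_tpc(temperature, p[["a"]], p[["b"]], p[["t_ref"]], p[["w"]])
}

#' @export
plot.tpc_fit <- function(x, ...) {
  grid <- seq(min(x$data$temperature) - 2, max(x$data$temperature) + 2, length.out = 200)
  graphics::plot(x$data$temperature, x$data$mu, xlab = "Temperature (degC)",
                 ylab = "Growth rate (per day)", ...)
  graphics::lines(grid, predict(x, grid))
  graphics::abline(v = x$t_opt, lty = 2)
  invisible(x)
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("<arrhenius_fit> E_a = %.3f eV (SE %.3f), ln A = %.2f, R^2 = %.3f, n = %d\n",
              x$ea, x$se_ea, x$ln_a, x$r2, x$n))
  invisible(x)
}

#' @export
print.ea_summary <- function(x, ...) {
  cat(sprintf("<ea_summary> mean E_a = %.3f eV (SD %.3f, n = %d); t = %.2f vs %.2f eV, p = %.3g\n",
              x$mean_ea, x$sd_ea, x$n, x$t_stat, x$reference, x$p_value))
  invisible(x)
}
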