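#' Stage-1 regression of a strain trait on its source-lake environment
#'
#' Ordinary least squares of a trait (for example P* measured at one
#' experimental temperature) on a lake environmental variable (for example
#' growing-season total phosphorus) across strains. Strains with missing
#' trait or environment values are dropped; at least 3 complete pairs are
#' required for a test.
#'
#' @param trait numeric vector, one value per strain.
#' @param env numeric vector, same length (lake environmental values).
#' @param temperature optional experimental temperature label carried along.
#' @return list of class `slope_estimate`: `slope`, `se`, `p_value`,
#'   `n_strains`, `experimental_temperature`, `testable`.
#' @export
trait_env_regression <- function(trait, env, temperature = NA_real_) {
  ok <- is.finite(trait) & is.finite(env)
  trait <- trait[ok]; env <- env[ok]
  n <- length(trait)
  if (n < 3) {
    return(structure(list(experimental_temperature = temperature,
                          slope = NA_real_, se = NA_real_, p_value = NA_real_,
                          n_strains = n, testable = FALSE),
                     class = "slope_estimate"))
  }
  fit <- stats::lm(trait ~ env)
  sm <- summary(fit)$coefficients
  structure(list(
    experimental_temperature = temperature,
    slope = unname(sm["env", "Estimate"]),
    se = unname(sm["env", "Std. Error"]),
    p_value = unname(sm["env", "Pr(>|t|)"]),
    n_strains = n,
    testable = TRUE
  ), class = "slope_estimate")
}

#' Stage-2 inverse-variance weighted trend of slopes on temperature
#'
#' Weighted least squares of stage-1 slopes on experimental temperature with
#' weights 1/SE^2, so precisely estimated slopes dominate. A positive trend
#' means the trait-environment association steepens with experimental
#' temperature — the signature of temperature-dependent local adaptation.
#'
#' @param slopes data.frame with columns `temperature`, `slope`, `se`
#'   (for example the `$slopes` of [fit_adaptation()]), or a list of
#'   `slope_estimate` objects.
#' @return object of class `slope_trend`: `trend_slope`, `trend_se`,
#'   `trend_p`, `weights`, `n`, `lm`.
#' @export
slope_trend <- function(slopes) {
  if (is.list(slopes) && !is.data.frame(slopes)) {
    slopes <- do.call(rbind, lapply(slopes, function(s) data.frame(
      temperature = s$experimental_temperature, slope = s$slope, se = s$se
    )))
  }
  slopes <- slopes[is.finite(slopes$slope) & is.finite(slopes$se), , drop = FALSE]
  stopf(nrow(slopes) >= 3, "need >= 3 slope estimates with finite SEs")
  stopf(all(slopes$se > 0), "slope SEs must be positive (weights are 1/SE^2)")
  w <- 1 / slopes$se^2
  fit <- stats::lm(slope ~ temperature, data = slopes, weights = w)
  sm <- summary(fit)$coefficients
  structure(list(
    trend_slope = unname(sm["temperature", "Estimate"]),
    trend_se = unname(sm["temperature", "Std. Error"]),
    trend_p = unname(sm["temperature", "Pr(>|t|)"]),
    weights = w,
    n = nrow(slopes),
    lm = fit
  ), class = "slope_trend")
}

#' Two-stage test for temperature-dependent local adaptation
#'
#' The headline analysis: at each experimental temperature, regress a strain
#' trait on a lake environmental variable across strains (stage 1); then
#' regress the resulting slopes on experimental temperature, weighting by
#' 1/SE^2 (stage 2). The canonical configuration is P* against source-lake
#' total phosphorus, but any per-strain trait table and environmental
#' variable can be supplied.
#'
#' @param trait_table data.frame with columns `strain`, `temperature_C` and
#'   `value` (invalid trait values already excluded or set NA).
#' @param env_table data.frame with columns `strain` and `env_value`; strains
#'   without environmental data are dropped from every stage-1 regression.
#' @return object of class `adaptation_fit`: `slopes` (one row per
#'   temperature), `trend` (a `slope_trend`), `trait`/`env` labels.
#' @export
fit_adaptation <- function(trait_table, env_table) {
  merged <- merge(trait_table, env_table, by = "strain")
  temps <- sort(unique(merged$temperature_C))
  est <- lapply(temps, function(tc) {
    d <- merged[merged$temperature_C == tc, , drop = FALSE]
    trait_env_regression(d$value, d$env_value, temperature = tc)
  })
  slopes <- do.call(rbind, lapply(est, function(s) data.frame(
    temperature = s$experimental_temperature, slope = s$slope, se = s$se,
    p_value = s$p_value, n_strains = s$n_strains, testable = s$testable
  )))
  trend <- slope_trend(slopes[slopes$testable, , drop = FALSE])
  structure(list(slopes = slopes, trend = trend), class = "adaptation_fit")
}

#' @export
print.slope_estimate <- function(x, ...) {
  cat(sprintf("<slope_estimate> T = %s: slope = %.4g (SE %.3g), p = %.3g, n = %d%s\n",
              format(x$experimental_temperature), x$slope, x$se, x$p_value,
              x$n_strains, if (x$testable) "" else " [untestable]"))
  invisible(x)
}

#' @export
print.slope_trend <- function(x, ...) {
  cat(sprintf("<slope_trend> %.4g per degC (SE %.3g), p = %.3g, n = %d\n",
              x$trend_slope, x$trend_se, x$trend_p, x$n))
  invisible(x)
}

#' @export
coef.slope_trend <- function(object, ...) stats::coef(object$lm)

#' @export
print.adaptation_fit <- function(x, ...) {
  cat("<adaptation_fit> stage-1 slopes:\n")
  print(x$slopes, row.names = FALSE)
  cat("stage-2 trend: ")
  print(x$trend)
  invisible(x)
}

#' @export
plot.adaptation_fit <- function(x, ...) {
  s <- x$slopes
  graphics::plot(s$temperature, s$slope, xlab = "Experimental temperature (degC)",
                 ylab = "Trait-environment slope", pch = 19, ...)
  graphics::arrows(s$temperature, s$slope - s$se, s$temperature, s$slope + s$se,
                   angle = 90, code = 3, length = 0.04)
  graphics::abline(x$trend$lm, lty = 2)
  invisible(x)
}
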