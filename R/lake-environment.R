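#' Growing-season summary of lake monitoring records
#'
#' Mean of all in-window measurements (August-October, 2018-2022, at the
#' reference sampling depth) computed per year first and then averaged across
#' years, so unevenly sampled years carry equal weight. Records whose depth
#' is missing are treated as depth-integrated samples and retained, with the
#' method noted.
#'
#' @param records data.frame with columns lake, date, depth_m, variable,
#'   value.
#' @param variable which variable to summarise (`"temperature"` or
#'   `"total_phosphorus"`).
#' @param months calendar months of the growing-season window.
#' @param years years to average over (intersection with available data).
#' @param depth_m reference sampling depth.
#' @param depth_tol tolerance around `depth_m` (m).
#' @return list of class `lake_summary`: `lake`, `mean_value`, `method`
#'   (`"direct"` or `"integrated"`), `years_used`, `n_records`.
#' @export
summarize_lake <- function(records, variable = "temperature",
                           months = 8:10, years = 2018:2022,
                           depth_m = 5, depth_tol = 1) {
  lake <- if (nrow(records)) as.character(records$lake[1]) else "<unknown>"
  r <- records[records$variable == variable, , drop = FALSE]
  integrated <- nrow(r) > 0 && all(is.na(r$depth_m))
  if (!integrated) r <- r[!is.na(r$depth_m) & abs(r$depth_m - depth_m) <= depth_tol, , drop = FALSE]
  d <- as.Date(r$date)
  keep <- as.integer(format(d, "%m")) %in% months & as.integer(format(d, "%Y")) %in% years
  r <- r[keep, , drop = FALSE]
  stopf(nrow(r) > 0, "no in-window %s records for lake %s", variable, lake)
  yr <- as.integer(format(as.Date(r$date), "%Y"))
  year_means <- tapply(r$value, yr, mean)
  structure(list(
    lake = lake,
    mean_value = unname(mean(year_means)),
    method = if (integrated) "integrated" else "direct",
    years_used = as.integer(names(year_means)),
    n_records = nrow(r)
  ), class = "lake_summary")
}

#' Seasonal regression model for sparsely monitored lake temperature
#'
#' OLS of temperature on calendar year plus one annual harmonic:
#' value ~ (year - year0) + sin(2 pi dayfrac) + cos(2 pi dayfrac), where
#' dayfrac is the fraction of the calendar year elapsed. Used to densify
#' temperature series from lakes with low monitoring frequency before taking
#' growing-season means.
#'
#' @param records data.frame with `date` and `value` (temperature records;
#'   filter by variable/depth first if needed), >= 8 records spanning >= 2
#'   calendar years.
#' @return object of class `seasonal_model` with `intercept`, `year_slope`,
#'   `sin_coef`, `cos_coef`, `amplitude`, `residual_sd`, `year0`.
#' @export
fit_seasonal_model <- function(records) {
  if ("variable" %in% names(records)) {
    records <- records[records$variable == "temperature", , drop = FALSE]
  }
  stopf(nrow(records) >= 8, "need >= 8 records to fit the seasonal model")
  dy <- decimal_year(records$date)
  stopf(length(unique(floor(dy))) >= 2, "records must span >= 2 calendar years")
  dayfrac <- dy - floor(dy)
  # records clustered on one day of year (sd below ~4 days) leave the annual
  # harmonic collinear with the intercept
  stopf(stats::sd(dayfrac) > 0.01,
        "records fall on a single day of year; seasonal terms are not identifiable")
  year0 <- floor(min(dy))
  d <- data.frame(value = records$value, yr = dy - year0,
                  s = sin(2 * pi * dayfrac), c = cos(2 * pi * dayfrac))
  fit <- stats::lm(value ~ yr + s + c, data = d)
  cf <- stats::coef(fit)
  structure(list(
    intercept = unname(cf["(Intercept)"]),
    year_slope = unname(cf["yr"]),
    sin_coef = unname(cf["s"]),
    cos_coef = unname(cf["c"]),
    amplitude = sqrt(cf[["s"]]^2 + cf[["c"]]^2),
    residual_sd = summary(fit)$sigma,
    year0 = year0,
    lm = fit
  ), class = "seasonal_model")
}

#' @export
predict.seasonal_model <- function(object, newdates, ...) {
  dy <- decimal_year(as.Date(newdates))
  dayfrac <- dy - floor(dy)
  object$intercept + object$year_slope * (dy - object$year0) +
    object$sin_coef * sin(2 * pi * dayfrac) +
    object$cos_coef * cos(2 * pi * dayfrac)
}

#' Growing-season mean temperature from a seasonal model
#'
#' Evaluates the fitted seasonal model at six dates evenly spaced from
#' 1 August to 31 October (inclusive) of each requested year, averages
#' within each year and then across years — the modeled counterpart of
#' [summarize_lake()] for lakes monitored too sparsely for direct means.
#'
#' @param model a `seasonal_model`.
#' @param years integer vector of years.
#' @return mean temperature, degC.
#' @export
predict_season_mean <- function(model, years = 2018:2022) {
  year_means <- vapply(years, function(y) {
    dates <- seq(as.Date(sprintf("%d-08-01", y)), as.Date(sprintf("%d-10-31", y)),
                 length.out = 6)
    mean(predict(model, dates))
  }, numeric(1))
  mean(year_means)
}

#' @export
print.seasonal_model <- function(x, ...) {
  cat(sprintf("<seasonal_model> %.2f + %.3f (yr - %d) + %.2f sin + %.2f cos (amplitude %.2f, resid SD %.2f)\n",
              x$intercept, x$year_slope, x$year0, x$sin_coef, x$cos_coef,
              x$amplitude, x$residual_sd))
  invisible(x)
}

#' @export
print.lake_summary <- function(x, ...) {
  cat(sprintf("<lake_summary> %s: %.2f (%s; %d records over years %s)\n",
              x$lake, x$mean_value, x$method, x$n_records,
              paste(range(x$years_used), collapse = "-")))
  invisible(x)
}
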