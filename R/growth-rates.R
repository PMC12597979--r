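#' Operational fluorescence detection limit from blank media
#'
#' The detection limit is half the median fluorescence of all blank-media
#' readings; measurements below it are treated as indistinguishable from
#' background and dropped before growth-rate estimation.
#'
#' @param blank_rfu numeric vector of blank readings, or a data.frame with an
#'   `rfu` column (as returned by [simulate_blanks()]).
#' @return threshold in RFU.
#' @export
compute_detection_limit <- function(blank_rfu) {
  if (is.data.frame(blank_rfu)) blank_rfu <- blank_rfu$rfu
  stopf(length(blank_rfu) > 0, "blank_rfu must be nonempty")
  stats::median(blank_rfu) / 2
}

#' Remove fluorescence readings below the detection limit
#'
#' Drops rows with `rfu` strictly below the threshold; all metadata columns
#' and the original ordering are preserved. The log transform downstream is
#' applied only after this filter, so non-positive readings never reach it.
#'
#' @param series data.frame with at least `time_days` and `rfu` columns.
#' @param threshold detection limit in RFU (> 0).
#' @return the filtered data.frame (possibly zero rows).
#' @export
filter_series <- function(series, threshold) {
  stopf(threshold > 0, "threshold must be positive")
  series[series$rfu >= threshold, , drop = FALSE]
}

#' Small-sample corrected AIC for a Gaussian least-squares fit
#'
#' AICc = n log(rss / n) + 2 p + 2 p (p + 1) / (n - p - 1), the
#' constant-dropped Gaussian form; only differences between models on the
#' same data are meaningful. `p` counts the free mean parameters
#' (intercept, slope, breakpoints); the error variance is not counted, as
#' the same convention applies to every candidate. When n = p + 1 the
#' correction diverges and `Inf` is returned (model not comparable); rss is
#' clamped away from zero so exactly interpolated fits remain comparable
#' through the penalty term.
#'
#' @param rss residual sum of squares.
#' @param n number of observations.
#' @param p number of free mean parameters.
#' @return AICc value (dimensionless), `Inf` when `n <= p + 1`.
#' @export
aicc <- function(rss, n, p) {
  if (n <= p + 1) return(Inf)
  n * log(max(rss, 1e-300) / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

# Candidate segmented-model configurations for a fixed time grid.
# Each candidate is linear in (intercept-like, slope) given its breakpoints:
#   line    : y = c0 + mu * t
#   lag     : y = c  + mu * max(t - tL, 0)        (flat, then growth)
#   sat     : y = c  + mu * min(t - tS, 0)        (growth, then flat)
#   lag_sat : y = c  + mu * (clamp(t, tL, tS) - tL)
# Breakpoints are restricted to observed timepoints; the growth segment
# always spans >= 2 points, and the boundary timepoints are admitted as
# degenerate breakpoints (zero-length lag or saturation phase) so that every
# richer model nests the plain line — noiseless exponential data are then
# recovered at the generating slope by all four models. Exhaustive
# enumeration is exact and cheap for the 11-point plate-reader grids this
# targets.
segment_configs <- function(t) {
  n <- length(t)
  cfg <- list(list(model = "exponential", p = 2L, lag = NA_real_, sat = NA_real_, g = t))
  if (n >= 4) {
    for (k in 1:(n - 1)) {
      cfg[[length(cfg) + 1L]] <- list(
        model = "lag", p = 3L, lag = t[k], sat = NA_real_,
        g = pmax(t - t[k], 0)
      )
      cfg[[length(cfg) + 1L]] <- list(
        model = "saturation", p = 3L, lag = NA_real_, sat = t[n + 1L - k],
        g = pmin(t - t[n + 1L - k], 0)
      )
    }
  }
  if (n >= 5) {
    for (k1 in 1:(n - 1)) {
      for (k2 in (k1 + 1):n) {
        cfg[[length(cfg) + 1L]] <- list(
          model = "lag_saturation", p = 4L, lag = t[k1], sat = t[k2],
          g = pmin(pmax(t, t[k1]), t[k2]) - t[k1]
        )
      }
    }
  }
  cfg
}

# cache of segment_configs + stacked basis matrices keyed by the time grid
.segment_cache <- new.env(parent = emptyenv())

segment_configs_cached <- function(t) {
  key <- paste(format(t, digits = 15), collapse = "|")
  hit <- .segment_cache[[key]]
  if (!is.null(hit)) return(hit)
  cfg <- segment_configs(t)
  G <- vapply(cfg, `[[`, numeric(length(t)), "g")
  val <- list(cfg = cfg, G = G, Sg = colSums(G), Sgg = colSums(G * G))
  .segment_cache[[key]] <- val
  val
}

#' Fit the four candidate growth models to one fluorescence series
#'
#' Fits, on y = log(rfu) versus time, (i) a single line, (ii) flat-then-line
#' (lag), (iii) line-then-flat (saturation) and (iv) flat-line-flat, each by
#' exact least squares over all admissible breakpoints on the observed time
#' grid. The growth rate mu is the slope of the line segment in every model.
#' Models are returned only when the series has at least one more point than
#' free parameters.
#'
#' @param series data.frame with `time_days` and `rfu` (already filtered);
#'   rfu must be positive.
#' @return list of `growth_fit` candidates, one per estimable model.
#' @seealso [fit_growth()] for the filter + fit + select pipeline per well.
#' @export
fit_growth_models <- function(series) {
  t <- series$time_days
  y <- log(series$rfu)
  n <- length(t)
  stopf(n >= 3, "need >= 3 usable points after filtering (got %d)", n)
  stopf(all(diff(t) > 0), "time_days must be strictly increasing")
  stopf(all(is.finite(y)), "rfu must be positive and finite")
  cc <- segment_configs_cached(t)
  Sy <- sum(y); Syy <- sum(y * y)
  Sgy <- as.numeric(crossprod(cc$G, y))
  det <- n * cc$Sgg - cc$Sg^2
  slope <- (n * Sgy - cc$Sg * Sy) / det
  c0 <- (Sy - slope * cc$Sg) / n
  rss <- pmax(Syy + n * c0^2 + slope^2 * cc$Sgg +
                2 * c0 * slope * cc$Sg - 2 * c0 * Sy - 2 * slope * Sgy, 0)
  models <- vapply(cc$cfg, `[[`, character(1), "model")
  pvec <- vapply(cc$cfg, `[[`, integer(1), "p")
  fits <- list()
  for (m in unique(models)) {
    idx <- which(models == m)
    idx <- idx[pvec[idx] + 1L <= n]
    if (!length(idx)) next
    best <- idx[which.min(rss[idx])]
    cfg <- cc$cfg[[best]]
    # intercept reported as the t = 0 value of the exponential-phase line:
    # in the lag models c is the flat level and the line starts at tL, so the
    # extrapolated intercept is c - mu tL; in the saturation model c is the
    # plateau and the line is y = c + mu (t - tS), intercept c - mu tS.
    intercept <- switch(m,
      exponential = c0[best],
      lag = c0[best] - slope[best] * cfg$lag,
      saturation = c0[best] - slope[best] * cfg$sat,
      lag_saturation = c0[best] - slope[best] * cfg$lag
    )
    fits[[m]] <- structure(list(
      model = m,
      mu = slope[best],
      intercept = intercept,
      lag_time = cfg$lag,
      sat_time = cfg$sat,
      rss = rss[best],
      n_points = n,
      p = cfg$p,
      aicc = aicc(rss[best], n, cfg$p),
      times = t,
      log_rfu = y
    ), class = "growth_fit")
  }
  fits
}

#' Select the best growth model by AICc
#'
#' Minimum AICc wins; exact ties (including all-infinite AICc on very short
#' series) are broken toward the model with fewer parameters.
#'
#' @param fits nonempty list of `growth_fit` candidates.
#' @return the selected `growth_fit`.
#' @export
select_best <- function(fits) {
  stopf(length(fits) > 0, "no growth model fits to select from")
  a <- vapply(fits, `[[`, numeric(1), "aicc")
  p <- vapply(fits, `[[`, numeric(1), "p")
  ord <- order(a, p)
  fits[[ord[1]]]
}

#' Estimate the exponential growth rate of one well
#'
#' Convenience wrapper: filter below-detection readings, fit the four
#' segmented candidates, select by AICc.
#'
#' @param series data.frame with `time_days` and `rfu`.
#' @param detection_limit RFU threshold; readings strictly below are dropped.
#' @return a `growth_fit` with the selected model; its `mu` (per day) is the
#'   slope of the log-linear growth segment.
#' @export
fit_growth <- function(series, detection_limit = 2.25) {
  kept <- filter_series(series, detection_limit)
  select_best(fit_growth_models(kept))
}

#' Per-well growth-rate table for a whole experiment
#'
#' Splits a long-format fluorescence table into wells (strain x temperature x
#' phosphorus x replicate), applies the detection-limit filter and AICc model
#' selection to each, and returns one row per estimable well. Wells with
#' fewer than 3 usable points are excluded and listed in the `"excluded"`
#' attribute. Negative rates are retained; downstream stages decide exclusion.
#'
#' @param data data.frame with columns strain, temperature_C,
#'   phosphorus_umol_L, replicate, time_days, rfu.
#' @param detection_limit RFU threshold (default the half-median-blank value
#'   2.25 RFU).
#' @return data.frame: strain, temperature_C, phosphorus_umol_L, replicate,
#'   mu_per_day, model, aicc, n_points.
#' @export
growth_rate_table <- function(data, detection_limit = 2.25) {
  key <- interaction(data$strain, data$temperature_C, data$phosphorus_umol_L,
                     data$replicate, drop = TRUE)
  wells <- split(seq_len(nrow(data)), key)
  nw <- length(wells)
  meta_idx <- vapply(wells, `[`, integer(1), 1L)

  # wells sharing one complete time grid with no below-detection reading are
  # fitted in a single batch of matrix operations; the rest fall back to the
  # per-well path (filtered points, ragged grids)
  nt0 <- length(wells[[1]])
  same_grid <- rep(FALSE, nw)
  t0 <- sort(data$time_days[wells[[1]]])
  if (nt0 >= 3 && all(diff(t0) > 0)) {
    for (i in seq_len(nw)) {
      idx <- wells[[i]]
      if (length(idx) != nt0) next
      tw <- data$time_days[idx]
      same_grid[i] <- !is.unsorted(tw, strictly = TRUE) && all(tw == t0) &&
        all(data$rfu[idx] >= detection_limit)
    }
  }

  res_mu <- rep(NA_real_, nw); res_model <- rep(NA_character_, nw)
  res_aicc <- rep(NA_real_, nw); res_n <- rep(NA_integer_, nw)
  excluded <- character(0)

  bi <- which(same_grid)
  if (length(bi)) {
    Y <- matrix(log(data$rfu[unlist(wells[bi], use.names = FALSE)]), nt0, length(bi))
    batch <- .fit_growth_batch(t0, Y)
    res_mu[bi] <- batch$mu
    res_model[bi] <- batch$model
    res_aicc[bi] <- batch$aicc
    res_n[bi] <- nt0
  }

  for (i in which(!same_grid)) {
    well <- data[wells[[i]], , drop = FALSE]
    well <- well[order(well$time_days), , drop = FALSE]
    kept <- filter_series(well, detection_limit)
    if (nrow(kept) < 3) {
      excluded <- c(excluded, names(wells)[i])
      next
    }
    fit <- select_best(fit_growth_models(kept))
    res_mu[i] <- fit$mu; res_model[i] <- fit$model
    res_aicc[i] <- fit$aicc; res_n[i] <- fit$n_points
  }

  ok <- !is.na(res_mu)
  out <- data.frame(
    strain = data$strain[meta_idx][ok],
    temperature_C = data$temperature_C[meta_idx][ok],
    phosphorus_umol_L = data$phosphorus_umol_L[meta_idx][ok],
    replicate = data$replicate[meta_idx][ok],
    mu_per_day = res_mu[ok],
    model = res_model[ok],
    aicc = res_aicc[ok],
    n_points = res_n[ok]
  )
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "wells_read") <- nw
  out
}

# Batched segmented fits for wells sharing one time grid: solves every
# breakpoint configuration for every well at once by the 2-parameter
# normal equations, then applies AICc selection per well. Returns the same
# selections as the per-well path.
.fit_growth_batch <- function(t, Y) {
  cc <- segment_configs_cached(t)
  n <- length(t)
  m <- ncol(cc$G)
  nw <- ncol(Y)
  Sy <- colSums(Y); Syy <- colSums(Y * Y)
  Sgy <- crossprod(cc$G, Y)                      # m x nw
  det <- n * cc$Sgg - cc$Sg^2
  slope <- (n * Sgy - outer(cc$Sg, Sy)) / det    # m x nw (det recycles by row)
  c0 <- (matrix(Sy, m, nw, byrow = TRUE) - slope * cc$Sg) / n
  rss <- pmax(matrix(Syy, m, nw, byrow = TRUE) + n * c0^2 + slope^2 * cc$Sgg +
                2 * c0 * slope * cc$Sg - 2 * c0 * matrix(Sy, m, nw, byrow = TRUE) -
                2 * slope * Sgy, 0)
  models <- vapply(cc$cfg, `[[`, character(1), "model")
  pvec <- vapply(cc$cfg, `[[`, integer(1), "p")
  # model groups in increasing parameter order so that exact AICc ties break
  # toward fewer parameters via which.min
  groups <- c("exponential", "lag", "saturation", "lag_saturation")
  groups <- groups[groups %in% models[pvec + 1L <= n]]
  ng <- length(groups)
  g_aicc <- matrix(Inf, ng, nw)
  g_mu <- matrix(NA_real_, ng, nw)
  for (gi in seq_len(ng)) {
    idx <- which(models == groups[gi] & pvec + 1L <= n)
    p <- pvec[idx[1]]
    sub <- rss[idx, , drop = FALSE]
    best <- max.col(-t(sub), ties.method = "first")   # config index per well
    brss <- sub[cbind(best, seq_len(nw))]
    g_mu[gi, ] <- slope[idx, , drop = FALSE][cbind(best, seq_len(nw))]
    g_aicc[gi, ] <- if (n > p + 1)
      n * log(pmax(brss, 1e-300) / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
    else Inf
  }
  sel <- max.col(-t(g_aicc), ties.method = "first")
  list(mu = g_mu[cbind(sel, seq_len(nw))],
       model = groups[sel],
       aicc = g_aicc[cbind(sel, seq_len(nw))])
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> model = %s, mu = %.4f /day (n = %d, AICc = %.2f)\n",
              x$model, x$mu, x$n_points, x$aicc))
  if (!is.na(x$lag_time)) cat(sprintf("  lag until t = %.2f d\n", x$lag_time))
  if (!is.na(x$sat_time)) cat(sprintf("  saturation from t = %.2f d\n", x$sat_time))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) {
  c(mu = object$mu, intercept = object$intercept,
    lag_time = object$lag_time, sat_time = object$sat_time)
}

#' @export
predict.growth_fit <- function(object, newtimes = object$times, ...) {
  tL <- if (is.na(object$lag_time)) -Inf else object$lag_time
  tS <- if (is.na(object$sat_time)) Inf else object$sat_time
  object$intercept + object$mu * pmin(pmax(newtimes, tL), tS)
}

#' @export
residuals.growth_fit <- function(object, ...) {
  object$log_rfu - predict(object)
}
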