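#' Construct a factorial growth-experiment design
#'
#' Describes a temperature x phosphorus factorial plate experiment: the
#' default values mirror a 6 x 6 factorial with 4 replicate wells per
#' treatment, inoculated at 10 RFU and read 11 times over 6 days (twice daily
#' for the first four days, then daily), with phosphate levels spanning
#' 1.94-47.47 umol/L (60-1470 ug/L PO4-P) and temperatures 12-26 degC.
#'
#' @param temperature_levels increasing numeric vector, degC.
#' @param phosphorus_levels increasing numeric vector, umol/L phosphate-P.
#' @param replicates wells per strain x treatment.
#' @param timepoints increasing numeric vector of measurement times, days.
#' @param initial_rfu inoculation fluorescence, RFU.
#' @param detection_floor instrument background fluorescence scale, RFU.
#'   Blank-media readings are centred at twice this value so that the
#'   half-median detection limit equals `detection_floor`.
#' @param noise_cv coefficient of variation of multiplicative lognormal
#'   measurement noise on RFU (dimensionless).
#' @param saturation_cap carrying capacity (RFU) for an optional logistic
#'   saturation of the latent trajectory; `Inf` disables saturation.
#' @return object of class `experiment_design`.
#' @export
experiment_design <- function(temperature_levels = c(12, 16, 20, 22, 24, 26),
                              phosphorus_levels = c(1.94, 3.87, 7.75, 15.50, 31.00, 47.47),
                              replicates = 4L,
                              timepoints = c(0, seq(0.5, 4, by = 0.5), 5, 6),
                              initial_rfu = 10,
                              detection_floor = 2.25,
                              noise_cv = 0.1,
                              saturation_cap = Inf) {
  stopf(all(diff(temperature_levels) > 0), "temperature_levels must be strictly increasing")
  stopf(all(diff(phosphorus_levels) > 0), "phosphorus_levels must be strictly increasing")
  stopf(replicates >= 1, "replicates must be >= 1")
  stopf(all(diff(timepoints) > 0), "timepoints must be strictly increasing")
  stopf(initial_rfu > 0, "initial_rfu must be positive")
  stopf(noise_cv >= 0, "noise_cv must be non-negative")
  structure(list(
    temperature_levels = temperature_levels,
    phosphorus_levels = phosphorus_levels,
    replicates = as.integer(replicates),
    timepoints = timepoints,
    initial_rfu = initial_rfu,
    detection_floor = detection_floor,
    noise_cv = noise_cv,
    saturation_cap = saturation_cap
  ), class = "experiment_design")
}

#' Draw ground-truth trait parameters for a set of synthetic strains
#'
#' Each synthetic strain carries a thermal performance curve (exponential
#' envelope times downward quadratic), a temperature-dependent half-saturation
#' constant for phosphate, a mean lag time, and the total-phosphorus
#' concentration of its lake of origin. The half-saturation constant rises
#' quadratically away from a strain-specific coolest-K temperature,
#' K_s(T) = ks_base + ks_temp_sensitivity * (T - ks_t_min)^2, which yields the
#' expected U-shaped minimal-requirement response to temperature. Local
#' adaptation is planted by making `ks_temp_sensitivity` a deterministic
#' increasing function of source-lake phosphorus, scaled by
#' `adaptation_strength`; at strength 0 every strain shares the same
#' sensitivity and no trait-environment association exists.
#'
#' @param n_strains number of strains (>= 2; one lake each).
#' @param adaptation_strength non-negative scalar scaling the planted
#'   dependence of K_s temperature sensitivity on source-lake phosphorus.
#' @param seed integer RNG seed.
#' @return list of `strain_truth` objects.
#' @export
make_truth <- function(n_strains = 8L, adaptation_strength = 1, seed = 1L) {
  stopf(n_strains >= 2, "n_strains must be >= 2 (trait-environment regressions need >= 2 lakes)")
  stopf(adaptation_strength >= 0, "adaptation_strength must be non-negative")
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  lake_p <- sort(stats::runif(n_strains, 5, 60)) # ug/L total P, oligo- to eutrophic
  out <- vector("list", n_strains)
  for (i in seq_len(n_strains)) {
    out[[i]] <- structure(list(
      strain_id = sprintf("strain_%02d", i),
      tpc_params = c(
        a = stats::runif(1, 0.05, 0.15),
        b = stats::runif(1, 0.04, 0.08),
        t_ref = stats::runif(1, 16, 22),
        w = stats::runif(1, 38, 50)
      ),
      ks_base = stats::runif(1, 0.3, 1.2),          # umol/L
      ks_t_min = stats::runif(1, 12, 15),           # degC, coolest-K temperature
      ks_temp_sensitivity = 0.001 + adaptation_strength * 4e-4 * lake_p[i],
      lag_mean = stats::runif(1, 0.1, 0.5),         # days
      source_lake_phosphorus = lake_p[i]            # ug/L
    ), class = "strain_truth")
  }
  out
}

#' True growth rate surface of a synthetic strain
#'
#' Evaluates R(T, S) = mu_max(T) * S / (K_s(T) + S), where mu_max(T) is the
#' strain's thermal performance curve and K_s(T) its temperature-dependent
#' half-saturation constant.
#'
#' @param truth a `strain_truth`.
#' @param temperature degC (vectorised with recycling).
#' @param phosphorus umol/L.
#' @return growth rate, per day.
#' @export
true_growth_rate <- function(truth, temperature, phosphorus) {
  p <- truth$tpc_params
  mu <- thomas_tpc(temperature, p[["a"]], p[["b"]], p[["t_ref"]], p[["w"]])
  ks <- true_ks(truth, temperature)
  mu * phosphorus / (ks + phosphorus)
}

#' @rdname true_growth_rate
#' @export
true_ks <- function(truth, temperature) {
  truth$ks_base + truth$ks_temp_sensitivity * (temperature - truth$ks_t_min)^2
}

#' Simulate plate-reader fluorescence trajectories for one strain
#'
#' Latent well density starts at the design's inoculation level, stays flat
#' for a lag drawn per well from an exponential distribution with the strain's
#' mean lag, then grows exponentially at the true rate R(T, S); if the design
#' sets a finite `saturation_cap` the post-lag trajectory is logistic with
#' that carrying capacity. Observed RFU multiply the latent trajectory by
#' mean-one lognormal noise with the design's CV. Readings below the detection
#' floor are emitted unchanged; filtering is the estimation stage's job.
#'
#' @param truth a `strain_truth`.
#' @param design an `experiment_design`.
#' @param seed integer RNG seed.
#' @return data.frame with columns strain, temperature_C, phosphorus_umol_L,
#'   replicate, time_days, rfu.
#' @export
simulate_series <- function(truth, design, seed = 1L) {
  stopifnot(inherits(truth, "strain_truth"), inherits(design, "experiment_design"))
  stopf(design$noise_cv >= 0, "noise_cv must be non-negative")
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  wells <- expand.grid(
    replicate = seq_len(design$replicates),
    phosphorus_umol_L = design$phosphorus_levels,
    temperature_C = design$temperature_levels,
    KEEP.OUT.ATTRS = FALSE
  )
  tt <- design$timepoints
  nt <- length(tt)
  nw <- nrow(wells)
  n0 <- design$initial_rfu
  sdlog <- sqrt(log(1 + design$noise_cv^2))
  r <- true_growth_rate(truth, wells$temperature_C, wells$phosphorus_umol_L)
  lag <- if (truth$lag_mean > 0) stats::rexp(nw, rate = 1 / truth$lag_mean) else numeric(nw)
  # rows: timepoints, columns: wells
  te <- pmax(outer(tt, lag, "-"), 0) # time spent growing
  ert <- exp(te * rep(r, each = nt))
  latent <- if (is.finite(design$saturation_cap)) {
    k <- design$saturation_cap
    k * n0 * ert / (k - n0 + n0 * ert)
  } else {
    n0 * ert
  }
  noise <- if (sdlog > 0) exp(matrix(stats::rnorm(nt * nw, -sdlog^2 / 2, sdlog), nt, nw)) else 1
  out <- data.frame(
    strain = truth$strain_id,
    temperature_C = rep(wells$temperature_C, each = nt),
    phosphorus_umol_L = rep(wells$phosphorus_umol_L, each = nt),
    replicate = rep(wells$replicate, each = nt),
    time_days = rep(tt, nw),
    rfu = as.vector(latent * noise)
  )
  rownames(out) <- NULL
  out
}

#' Simulate blank-media fluorescence readings
#'
#' Background readings of sterile media at each phosphorus level, lognormal
#' around twice the design's detection floor so that half the median of all
#' blanks recovers the floor (the operational detection limit).
#'
#' @param design an `experiment_design`.
#' @param n_per_level readings per phosphorus level.
#' @param sdlog lognormal log-scale spread of blank readings.
#' @param seed integer RNG seed.
#' @return data.frame with columns phosphorus_umol_L, rfu.
#' @export
simulate_blanks <- function(design, n_per_level = 8L, sdlog = 0.03, seed = 1L) {
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  lev <- design$phosphorus_levels
  data.frame(
    phosphorus_umol_L = rep(lev, each = n_per_level),
    rfu = 2 * design$detection_floor *
      exp(stats::rnorm(n_per_level * length(lev), 0, sdlog))
  )
}

#' Simulate sparse lake temperature (or phosphorus) monitoring records
#'
#' Generates records from a linear-trend-plus-annual-sinusoid model:
#' value(date) = mean + trend * (year - year0) + amplitude * sin(2 pi dayfrac
#' + phase) + Gaussian noise, with `dayfrac` the fraction of the calendar year
#' elapsed and year0 the first calendar year sampled.
#'
#' @param sampling_dates Date vector (nonempty).
#' @param mean long-term mean, degC (or ug/L for phosphorus records).
#' @param trend linear change per year.
#' @param amplitude seasonal amplitude.
#' @param phase phase of the annual harmonic, radians.
#' @param noise_sd Gaussian measurement noise SD.
#' @param lake lake label.
#' @param depth_m recorded sampling depth.
#' @param variable `"temperature"` or `"total_phosphorus"`.
#' @param seed integer RNG seed.
#' @return data.frame with columns lake, date, depth_m, variable, value.
#' @export
simulate_lake_monitoring <- function(sampling_dates, mean = 12, trend = 0,
                                     amplitude = 6, phase = -2, noise_sd = 0.5,
                                     lake = "lake", depth_m = 5,
                                     variable = "temperature", seed = 1L) {
  stopf(length(sampling_dates) > 0, "sampling_dates must be nonempty")
  stopf(noise_sd >= 0, "noise_sd must be non-negative")
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  sampling_dates <- as.Date(sampling_dates)
  dy <- decimal_year(sampling_dates)
  year0 <- floor(min(dy))
  dayfrac <- dy - floor(dy)
  value <- mean + trend * (dy - year0) + amplitude * sin(2 * pi * dayfrac + phase)
  if (noise_sd > 0) value <- value + stats::rnorm(length(value), 0, noise_sd)
  data.frame(
    lake = lake,
    date = sampling_dates,
    depth_m = depth_m,
    variable = variable,
    value = value
  )
}

# Save/restore .Random.seed so seeded generators do not disturb the caller's
# RNG stream.
.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
.Random.seed.restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.strain_truth <- function(x, ...) {
  p <- x$tpc_params
  cat(sprintf(
    "<strain_truth %s>\n  TPC: a=%.3f b=%.3f T_ref=%.1f w=%.1f (T_opt %.1f degC)\n  K_s(T) = %.3f + %.5f (T - %.1f)^2 umol/L\n  lag mean %.2f d; source-lake TP %.1f ug/L\n",
    x$strain_id, p[["a"]], p[["b"]], p[["t_ref"]], p[["w"]],
    tpc_topt(p[["b"]], p[["t_ref"]], p[["w"]]),
    x$ks_base, x$ks_temp_sensitivity, x$ks_t_min,
    x$lag_mean, x$source_lake_phosphorus
  ))
  invisible(x)
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(
    "<experiment_design> %d temperatures x %d phosphorus levels x %d replicates, %d timepoints over %g d\n  inoculum %g RFU, detection floor %g RFU, noise CV %g, saturation cap %s\n",
    length(x$temperature_levels), length(x$phosphorus_levels), x$replicates,
    length(x$timepoints), max(x$timepoints), x$initial_rfu, x$detection_floor,
    x$noise_cv, if (is.finite(x$saturation_cap)) format(x$saturation_cap) else "none"
  ))
  invisible(x)
}
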