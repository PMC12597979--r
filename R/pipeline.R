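#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis: the mortality rate
#' entering P*, multi-start counts of the nonlinear fits, bootstrap size,
#' detection-limit override, the activation-energy reference, the EDF
#' linearity cut, the lake summary window, and the master seed. Per-stage
#' seeds are derived deterministically from the master seed (fixed offsets),
#' so each stage is independently reproducible. The configuration is a plain
#' list and round-trips through JSON unchanged.
#'
#' @param m mortality rate for P*, per day.
#' @param detection_limit RFU threshold; `NULL` derives it from blank media
#'   via [compute_detection_limit()] (or falls back to 2.25 RFU).
#' @param tpc_n_starts,monod_n_starts multi-start counts for the nonlinear
#'   fits inside the pipeline.
#' @param bootstrap_B bootstrap resamples per fit (0 disables bootstrap
#'   intervals in the pipeline run).
#' @param ea_reference activation-energy reference, eV.
#' @param linearity_threshold EDF cut for [classify_linearity()].
#' @param months,years,depth_m lake growing-season window.
#' @param sparse_threshold minimum number of in-window temperature records
#'   for a direct lake mean; below it the seasonal regression model is used.
#' @param seed master integer seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(m = 0.1, detection_limit = NULL,
                            tpc_n_starts = 50L, monod_n_starts = 10L,
                            bootstrap_B = 0L, ea_reference = 0.32,
                            linearity_threshold = 1.5,
                            months = 8:10, years = 2018:2022, depth_m = 5,
                            sparse_threshold = 15L, seed = 1L) {
  structure(list(
    m = m, detection_limit = detection_limit,
    tpc_n_starts = as.integer(tpc_n_starts),
    monod_n_starts = as.integer(monod_n_starts),
    bootstrap_B = as.integer(bootstrap_B),
    ea_reference = ea_reference,
    linearity_threshold = linearity_threshold,
    months = as.integer(months), years = as.integer(years), depth_m = depth_m,
    sparse_threshold = as.integer(sparse_threshold),
    seed = as.integer(seed)
  ), class = c("pipeline_config", "list"))
}

# deterministic per-stage seed scheme
stage_seed <- function(config, stage) {
  config$seed + c(tpc = 101L, monod = 202L, boot = 303L, simulate = 404L)[[stage]]
}

#' Write a synthetic experiment to disk
#'
#' Generates ground-truth strains, their plate-reader trajectories, blank
#' media readings and per-lake monitoring records, and writes them as plain
#' CSV plus a JSON file of the generating truth parameters.
#'
#' @param out_dir output directory (created if needed).
#' @param n_strains number of strains/lakes.
#' @param adaptation_strength planted adaptation signal (see [make_truth()]).
#' @param design an [experiment_design()].
#' @param seed integer seed.
#' @return invisibly, a list with the generated objects and file paths.
#' @export
simulate_experiment <- function(out_dir, n_strains = 8L, adaptation_strength = 1,
                                design = experiment_design(), seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stopf(dir.exists(out_dir), "cannot create output directory %s", out_dir)
  sim <- simulate_study(n_strains = n_strains, adaptation_strength = adaptation_strength,
                        design = design, seed = seed)
  paths <- list(
    series = file.path(out_dir, "fluorescence_series.csv"),
    blanks = file.path(out_dir, "blank_media.csv"),
    lakes = file.path(out_dir, "lake_monitoring.csv"),
    truth = file.path(out_dir, "truth.json")
  )
  utils::write.csv(sim$series, paths$series, row.names = FALSE)
  utils::write.csv(sim$blanks, paths$blanks, row.names = FALSE)
  utils::write.csv(sim$lake_records, paths$lakes, row.names = FALSE)
  truth_list <- lapply(sim$truth, function(s) {
    s <- unclass(s)
    s$tpc_params <- as.list(s$tpc_params)
    s
  })
  jsonlite::write_json(list(seed = seed, adaptation_strength = adaptation_strength,
                            strains = truth_list),
                       paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(c(sim, list(paths = paths)))
}

#' Generate a full synthetic study in memory
#'
#' Convenience generator used by [simulate_experiment()], the test-suite and
#' power analyses: strains with known truth, their fluorescence series,
#' blanks, per-lake monitoring records (temperature and total phosphorus,
#' monthly, at 5 m, over the summary window years), and the strain-lake map.
#'
#' @inheritParams simulate_experiment
#' @param lake_sparse fraction of lakes given sparse (quarterly) temperature
#'   monitoring, exercising the seasonal-model path.
#' @return list: `truth`, `series`, `blanks`, `lake_records`, `strain_lake`,
#'   `design`.
#' @export
simulate_study <- function(n_strains = 8L, adaptation_strength = 1,
                           design = experiment_design(), seed = 1L,
                           lake_sparse = 0.25) {
  truth <- make_truth(n_strains, adaptation_strength, seed = seed)
  series <- do.call(rbind, lapply(seq_along(truth), function(i) {
    simulate_series(truth[[i]], design, seed = seed + 17L * i)
  }))
  blanks <- simulate_blanks(design, seed = seed + 7L)
  monthly <- seq(as.Date("2018-01-15"), as.Date("2022-12-15"), by = "month")
  quarterly <- monthly[seq(1, length(monthly), by = 3)]
  n_sparse <- floor(lake_sparse * n_strains)
  lake_records <- do.call(rbind, lapply(seq_along(truth), function(i) {
    lake <- sub("strain", "lake", truth[[i]]$strain_id)
    dates <- if (i <= n_sparse) quarterly else monthly
    temp <- simulate_lake_monitoring(
      dates, mean = 10 + 4 * (i - 1) / max(n_strains - 1, 1),
      trend = 0.05, amplitude = 7, phase = -2, noise_sd = 0.4,
      lake = lake, depth_m = 5, variable = "temperature", seed = seed + 29L * i
    )
    phos <- simulate_lake_monitoring(
      monthly, mean = truth[[i]]$source_lake_phosphorus,
      trend = 0, amplitude = 0, phase = 0,
      noise_sd = 0.02 * truth[[i]]$source_lake_phosphorus,
      lake = lake, depth_m = 5, variable = "total_phosphorus", seed = seed + 31L * i
    )
    rbind(temp, phos)
  }))
  strain_lake <- data.frame(
    strain = vapply(truth, `[[`, character(1), "strain_id"),
    lake = vapply(truth, function(s) sub("strain", "lake", s$strain_id), character(1))
  )
  list(truth = truth, series = series, blanks = blanks,
       lake_records = lake_records, strain_lake = strain_lake, design = design)
}

#' Run the full trait pipeline
#'
#' Executes, in order: detection-limit filtering and per-well growth-rate
#' estimation; thermal performance curves, AUTPC and Arrhenius activation
#' energies per strain x phosphorus level; Monod curves and P* per strain x
#' temperature; penalized-spline trait responses along the opposing
#' gradient; lake growing-season summaries (seasonal regression model for
#' sparsely monitored lakes); and the two-stage P*-versus-lake-phosphorus
#' local-adaptation test. Every intermediate table is returned (and written
#' as CSV when `out_dir` is given) together with a manifest of counts and
#' seeds.
#'
#' @param series long-format fluorescence table (columns strain,
#'   temperature_C, phosphorus_umol_L, replicate, time_days, rfu).
#' @param blanks optional blank-media readings for the detection limit.
#' @param lake_records optional lake monitoring table (columns lake, date,
#'   depth_m, variable, value).
#' @param strain_lake optional data.frame mapping `strain` to `lake`;
#'   required for the local-adaptation stage when `lake_records` is given.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @param run_thermal run the thermal-traits branch (TPC/AUTPC/Ea).
#' @param run_smooths run the trait-response smooths.
#' @return list of class `trait_pipeline`: `growth`, `tpc`, `ea`,
#'   `ea_by_strain`, `monod`, `smooths`, `lakes`, `adaptation`, `manifest`.
#' @export
run_pipeline <- function(series, blanks = NULL, lake_records = NULL,
                         strain_lake = NULL, config = pipeline_config(),
                         out_dir = NULL, run_thermal = TRUE, run_smooths = TRUE) {
  manifest <- list(seed = config$seed, m = config$m,
                   r_version = as.character(getRversion()))

  ## stage: growth rates -----------------------------------------------------
  detection_limit <- config$detection_limit
  if (is.null(detection_limit)) {
    detection_limit <- if (!is.null(blanks)) compute_detection_limit(blanks) else 2.25
  }
  growth <- growth_rate_table(series, detection_limit)
  manifest$detection_limit <- detection_limit
  manifest$wells_read <- attr(growth, "wells_read")
  manifest$wells_excluded <- length(attr(growth, "excluded"))

  strains <- unique(growth$strain)

  ## stage: thermal traits ---------------------------------------------------
  tpc_tab <- ea_tab <- ea_strain <- NULL
  if (run_thermal) {
    rows <- list(); earows <- list()
    for (st in strains) {
      for (p in sort(unique(growth$phosphorus_umol_L))) {
        d <- growth[growth$strain == st & growth$phosphorus_umol_L == p, ]
        rates <- data.frame(temperature = d$temperature_C, mu = d$mu_per_day)
        fit <- tryCatch(fit_tpc(rates, n_starts = config$tpc_n_starts,
                                seed = stage_seed(config, "tpc")),
                        error = function(e) NULL)
        est <- !is.null(fit) && fit$estimable
        rows[[length(rows) + 1L]] <- data.frame(
          strain = st, phosphorus_umol_L = p,
          a = if (est) fit$par[["a"]] else NA, b = if (est) fit$par[["b"]] else NA,
          t_ref = if (est) fit$par[["t_ref"]] else NA,
          w = if (est) fit$par[["w"]] else NA,
          t_opt = if (est) fit$t_opt else NA,
          autpc = if (est) autpc(fit, min(rates$temperature), max(rates$temperature)) else NA,
          rss = if (est) fit$rss else NA, estimable = est
        )
        ea <- NA_real_; ea_se <- NA_real_; ea_n <- 0L
        if (est) {
          rp <- rising_part(rates, fit)
          if (nrow(rp) >= 3) {
            af <- fit_arrhenius(rp)
            ea <- af$ea; ea_se <- af$se_ea; ea_n <- af$n
          }
        }
        earows[[length(earows) + 1L]] <- data.frame(
          strain = st, phosphorus_umol_L = p, ea = ea, se_ea = ea_se, n = ea_n
        )
      }
    }
    tpc_tab <- do.call(rbind, rows)
    ea_tab <- do.call(rbind, earows)
    ea_strain <- do.call(rbind, lapply(strains, function(st) {
      eas <- ea_tab$ea[ea_tab$strain == st]
      s <- ea_summary(eas, reference = config$ea_reference)
      data.frame(strain = st, mean_ea = s$mean_ea, sd_ea = s$sd_ea,
                 t_stat = s$t_stat, p_value = s$p_value, n = s$n)
    }))
    manifest$tpc_fits <- nrow(tpc_tab)
    manifest$tpc_nonestimable <- sum(!tpc_tab$estimable)
  }

  ## stage: Monod traits -----------------------------------------------------
  mrows <- list()
  for (st in strains) {
    for (tc in sort(unique(growth$temperature_C))) {
      d <- growth[growth$strain == st & growth$temperature_C == tc, ]
      rates <- data.frame(phosphorus = d$phosphorus_umol_L, mu = d$mu_per_day)
      fit <- tryCatch(fit_monod(rates, m = config$m, n_starts = config$monod_n_starts,
                                seed = stage_seed(config, "monod")),
                      error = function(e) NULL)
      if (is.null(fit)) {
        mrows[[length(mrows) + 1L]] <- data.frame(
          strain = st, temperature_C = tc, mu_max = NA_real_, ks = NA_real_,
          p_star = NA_real_, rss = NA_real_, valid = FALSE,
          reason = "fit failed"
        )
        next
      }
      v <- validate_monod(fit)
      mrows[[length(mrows) + 1L]] <- data.frame(
        strain = st, temperature_C = tc, mu_max = fit$mu_max, ks = fit$ks,
        p_star = fit$p_star, rss = fit$rss, valid = v$valid, reason = v$reason
      )
    }
  }
  monod_tab <- do.call(rbind, mrows)
  manifest$monod_fits <- nrow(monod_tab)
  manifest$monod_excluded <- sum(!monod_tab$valid)

  ## stage: trait-response smooths -------------------------------------------
  smooth_tab <- NULL
  if (run_smooths) {
    srows <- list()
    add_smooth <- function(st, trait, gradient, x, y) {
      fit <- tryCatch(fit_trait_smooth(x, y, linearity_threshold = config$linearity_threshold),
                      error = function(e) NULL)
      srows[[length(srows) + 1L]] <<- data.frame(
        strain = st, trait = trait, gradient = gradient,
        edf = if (is.null(fit)) NA_real_ else fit$edf,
        p_value = if (is.null(fit)) NA_real_ else fit$p_value,
        deviance_explained = if (is.null(fit)) NA_real_ else fit$deviance_explained,
        linearity = if (is.null(fit)) NA_character_ else fit$linearity
      )
    }
    for (st in strains) {
      md <- monod_tab[monod_tab$strain == st, ]
      add_smooth(st, "mu_max", "temperature", md$temperature_C, md$mu_max)
      add_smooth(st, "ks", "temperature",
                 md$temperature_C[md$valid], md$ks[md$valid])
      add_smooth(st, "p_star", "temperature",
                 md$temperature_C[md$valid], md$p_star[md$valid])
      if (run_thermal) {
        td <- tpc_tab[tpc_tab$strain == st, ]
        add_smooth(st, "autpc", "phosphorus", td$phosphorus_umol_L, td$autpc)
        ed <- ea_tab[ea_tab$strain == st & is.finite(ea_tab$ea), ]
        add_smooth(st, "ea", "phosphorus", ed$phosphorus_umol_L, ed$ea)
      }
    }
    smooth_tab <- do.call(rbind, srows)
  }

  ## stage: lake environment -------------------------------------------------
  lakes_tab <- NULL
  if (!is.null(lake_records)) {
    lrows <- list()
    for (lk in unique(lake_records$lake)) {
      rec <- lake_records[lake_records$lake == lk, , drop = FALSE]
      temp <- tryCatch({
        direct <- summarize_lake(rec, "temperature", config$months, config$years,
                                 config$depth_m)
        if (direct$n_records >= config$sparse_threshold) {
          list(value = direct$mean_value, method = direct$method)
        } else {
          mod <- fit_seasonal_model(rec)
          list(value = predict_season_mean(mod, config$years), method = "modeled")
        }
      }, error = function(e) list(value = NA_real_, method = "missing"))
      phos <- tryCatch({
        s <- summarize_lake(rec, "total_phosphorus", config$months, config$years,
                            config$depth_m)
        list(value = s$mean_value, method = s$method)
      }, error = function(e) list(value = NA_real_, method = "missing"))
      if (is.na(phos$value)) {
        warning(sprintf("lake %s has no in-window chemistry; excluded from trait-environment regressions", lk),
                call. = FALSE)
      }
      lrows[[length(lrows) + 1L]] <- data.frame(
        lake = lk, mean_temperature = temp$value, temperature_method = temp$method,
        mean_phosphorus = phos$value, phosphorus_method = phos$method
      )
    }
    lakes_tab <- do.call(rbind, lrows)
  }

  ## stage: local adaptation -------------------------------------------------
  adaptation <- NULL
  if (!is.null(lakes_tab) && !is.null(strain_lake)) {
    env_table <- merge(strain_lake, lakes_tab, by = "lake")
    env_table <- data.frame(strain = env_table$strain,
                            env_value = env_table$mean_phosphorus)
    env_table <- env_table[is.finite(env_table$env_value), , drop = FALSE]
    valid <- monod_tab[monod_tab$valid, , drop = FALSE]
    trait_table <- data.frame(strain = valid$strain,
                              temperature_C = valid$temperature_C,
                              value = valid$p_star)
    adaptation <- fit_adaptation(trait_table, env_table)
    manifest$adaptation_trend_slope <- adaptation$trend$trend_slope
    manifest$adaptation_trend_p <- adaptation$trend$trend_p
  }

  out <- structure(list(
    growth = growth, tpc = tpc_tab, ea = ea_tab, ea_by_strain = ea_strain,
    monod = monod_tab, smooths = smooth_tab, lakes = lakes_tab,
    adaptation = adaptation, manifest = manifest, config = config
  ), class = "trait_pipeline")

  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

# write every pipeline table as CSV (JSON for nested outputs)
write_pipeline <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(d, f) if (!is.null(d)) utils::write.csv(d, file.path(out_dir, f), row.names = FALSE)
  wcsv(x$growth, "growth_rates.csv")
  wcsv(x$tpc, "tpc_traits.csv")
  wcsv(x$ea, "activation_energy.csv")
  wcsv(x$ea_by_strain, "activation_energy_by_strain.csv")
  wcsv(x$monod, "monod_traits.csv")
  wcsv(x$smooths, "trait_smooths.csv")
  wcsv(x$lakes, "lake_environment.csv")
  if (!is.null(x$adaptation)) {
    wcsv(x$adaptation$slopes, "adaptation_slopes.csv")
    jsonlite::write_json(list(trend_slope = x$adaptation$trend$trend_slope,
                              trend_se = x$adaptation$trend$trend_se,
                              trend_p = x$adaptation$trend$trend_p,
                              n = x$adaptation$trend$n),
                         file.path(out_dir, "adaptation_trend.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(x$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(x)
}

#' @export
print.trait_pipeline <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<trait_pipeline> %d wells read, %d excluded (< 3 points above %.3g RFU)\n",
              m$wells_read, m$wells_excluded, m$detection_limit))
  if (!is.null(x$tpc)) cat(sprintf("  TPC fits: %d (%d non-estimable)\n",
                                   m$tpc_fits, m$tpc_nonestimable))
  cat(sprintf("  Monod fits: %d (%d excluded from P*/K_s analyses)\n",
              m$monod_fits, m$monod_excluded))
  if (!is.null(x$adaptation)) {
    cat("  local adaptation: ")
    print(x$adaptation$trend)
  }
  invisible(x)
}
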