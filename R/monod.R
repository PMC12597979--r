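#' Monod growth curve
#'
#' mu(S) = mu_max S / (K_s + S): saturating dependence of growth rate on the
#' concentration of the limiting resource.
#'
#' @param s resource concentration, umol/L.
#' @param mu_max asymptotic maximum growth rate, per day.
#' @param ks half-saturation constant, umol/L.
#' @return growth rate, per day.
#' @export
monod <- function(s, mu_max, ks) mu_max * s / (ks + s)

#' Minimal resource requirement P* from Monod parameters
#'
#' P* = K_s m / (mu_max - m), the resource concentration at which growth
#' exactly balances the mortality (loss) rate m. Negative values — arising
#' when mu_max < m — are returned as-is; callers flag them as biologically
#' meaningless and exclude them from trait analyses.
#'
#' @param ks half-saturation constant, umol/L.
#' @param mu_max maximum growth rate, per day.
#' @param m mortality rate, per day (study convention 0.1).
#' @return P* in umol/L.
#' @export
pstar <- function(ks, mu_max, m = 0.1) {
  stopf(all(mu_max != m), "P* is undefined when mu_max equals the mortality rate")
  ks * m / (mu_max - m)
}

.monod_lower <- c(mu_max = 1e-6, ks = 1e-4)
.monod_upper <- c(mu_max = 5, ks = 100)

#' Fit a Monod curve by multi-start least squares
#'
#' Least squares of mu = mu_max S / (K_s + S) with bounded
#' Levenberg-Marquardt from multiple starting points: a data-driven default
#' start (mu_max near the largest observed rate, K_s near the median
#' substrate level) plus random starts within the bounds. Fits that land on
#' the K_s lower bound (flat response, unidentifiable half-saturation) or
#' give non-positive P* are flagged invalid; negative-rate observations are
#' included in the least squares by default.
#'
#' @param rates data.frame with columns `phosphorus` (umol/L) and `mu`
#'   (per day).
#' @param m mortality rate used for P*, per day.
#' @param n_starts number of random starts.
#' @param seed integer RNG seed.
#' @param lower,upper named bounds for (mu_max, ks).
#' @param include_negative keep negative-rate observations in the fit
#'   (default TRUE).
#' @return object of class `monod_fit`: `mu_max`, `ks`, `m`, `p_star`,
#'   `rss`, `valid`, `boundary`, `data`.
#' @export
fit_monod <- function(rates, m = 0.1, n_starts = 50L, seed = 1L,
                      lower = .monod_lower, upper = .monod_upper,
                      include_negative = TRUE) {
  if (!include_negative) rates <- rates[rates$mu > 0, , drop = FALSE]
  stopf(length(unique(rates$phosphorus)) >= 3,
        "need >= 3 distinct phosphorus levels to fit a Monod curve")
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  starts <- rbind(
    c(mu_max = max(max(rates$mu), 0.1), ks = stats::median(rates$phosphorus)),
    matrix(stats::runif(2 * n_starts, lower, upper), ncol = 2, byrow = TRUE,
           dimnames = list(NULL, names(lower)))
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(mu ~ monod(phosphorus, mu_max, ks),
                        data = rates, start = as.list(starts[i, ]),
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200,
                                                             ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(par = stats::coef(fit), rss = rss)
  }
  stopf(!is.null(best), "Monod fit failed from every starting point")
  mu_max <- unname(best$par["mu_max"])
  ks <- unname(best$par["ks"])
  boundary <- ks <= lower[["ks"]] * (1 + 1e-6) || mu_max >= upper[["mu_max"]] * (1 - 1e-6)
  p_star <- if (mu_max == m) NA_real_ else ks * m / (mu_max - m)
  structure(list(
    mu_max = mu_max, ks = ks, m = m, p_star = p_star, rss = best$rss,
    valid = is.finite(p_star) && ks > lower[["ks"]] * (1 + 1e-6) &&
      p_star > 0 && mu_max > m,
    boundary = boundary,
    data = rates, seed = seed, n_starts = n_starts
  ), class = "monod_fit")
}

#' Validate a Monod fit for downstream trait analyses
#'
#' Applies the exclusion rule for resource-use traits: fits with negative or
#' boundary-degenerate K_s, non-positive P*, or mu_max at or below the
#' mortality rate are excluded from K_s/P* analyses (mu_max itself is
#' retained wherever the curve was estimable).
#'
#' @param fit a `monod_fit`.
#' @return list with `valid`, `retain_mu_max`, and a human-readable `reason`
#'   (empty when valid).
#' @export
validate_monod <- function(fit) {
  reason <- character(0)
  if (!is.finite(fit$p_star)) reason <- c(reason, "P* undefined (mu_max = m)")
  else if (fit$p_star <= 0) reason <- c(reason, "non-positive P*")
  if (fit$ks <= .monod_lower[["ks"]] * (1 + 1e-6)) reason <- c(reason, "K_s at lower bound")
  if (fit$mu_max <= fit$m) reason <- c(reason, "mu_max <= mortality rate")
  list(valid = length(reason) == 0, retain_mu_max = TRUE,
       reason = paste(reason, collapse = "; "))
}

#' Bootstrap confidence intervals for Monod parameters and P*
#'
#' Nonparametric case resampling of the observed (substrate, rate) pairs;
#' each resample is refitted starting from the point estimate (plus random
#' starts), and 2.5/97.5 percentile intervals are reported for mu_max, K_s
#' and P*, together with the bootstrap mean of P* for comparison with the
#' point estimate. Resamples retaining fewer than 3 distinct substrate
#' levels are skipped and counted. Resampling can optionally be stratified
#' by substrate level; the unstratified default keeps interval widths
#' honest when levels carry only a handful of replicates each.
#'
#' @param rates data.frame with `phosphorus` and `mu`.
#' @param m mortality rate, per day.
#' @param B number of resamples (study convention 1000).
#' @param seed integer RNG seed.
#' @param n_starts random starts per refit.
#' @param stratify resample within each substrate level instead of from the
#'   pooled observations.
#' @return list with `ci` (matrix, rows mu_max/ks/p_star), `p_star_boot_mean`,
#'   `n_ok`, `n_skipped`, and the point `fit`.
#' @export
bootstrap_monod <- function(rates, m = 0.1, B = 1000L, seed = 1L, n_starts = 3L,
                            stratify = FALSE) {
  stopf(B >= 2, "B must be >= 2")
  fit <- fit_monod(rates, m = m, seed = seed)
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  n <- nrow(rates)
  strata <- if (stratify) split(seq_len(n), rates$phosphorus) else NULL
  draws <- matrix(NA_real_, B, 3, dimnames = list(NULL, c("mu_max", "ks", "p_star")))
  n_skipped <- 0L
  par0 <- c(mu_max = fit$mu_max, ks = fit$ks)
  for (b in seq_len(B)) {
    idx <- if (stratify) {
      unlist(lapply(strata, function(s) s[sample.int(length(s), length(s), replace = TRUE)]),
             use.names = FALSE)
    } else {
      sample.int(n, n, replace = TRUE)
    }
    rs <- rates[idx, , drop = FALSE]
    if (length(unique(rs$phosphorus)) < 3) { n_skipped <- n_skipped + 1L; next }
    starts <- rbind(par0,
                    matrix(stats::runif(2 * n_starts, .monod_lower, .monod_upper),
                           ncol = 2, byrow = TRUE, dimnames = list(NULL, names(par0))))
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      bf <- tryCatch(
        minpack.lm::nlsLM(mu ~ monod(phosphorus, mu_max, ks),
                          data = rs, start = as.list(starts[i, ]),
                          lower = .monod_lower, upper = .monod_upper,
                          control = minpack.lm::nls.lm.control(maxiter = 100)),
        error = function(e) NULL
      )
      if (is.null(bf)) next
      rss <- sum(stats::resid(bf)^2)
      if (is.null(best) || rss < best$rss) best <- list(par = stats::coef(bf), rss = rss)
    }
    if (is.null(best)) { n_skipped <- n_skipped + 1L; next }
    mm <- unname(best$par["mu_max"]); kk <- unname(best$par["ks"])
    draws[b, ] <- c(mm, kk, if (mm == m) NA else kk * m / (mm - m))
  }
  ci <- t(apply(draws, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE))
  colnames(ci) <- c("lower", "upper")
  list(ci = ci, p_star_boot_mean = mean(draws[, "p_star"], na.rm = TRUE),
       n_ok = sum(stats::complete.cases(draws)), n_skipped = n_skipped, fit = fit)
}

#' @export
print.monod_fit <- function(x, ...) {
  cat(sprintf("<monod_fit> mu_max = %.3f /day, K_s = %.3f umol/L, P* = %.4f umol/L (m = %g)\n",
              x$mu_max, x$ks, x$p_star, x$m))
  cat(sprintf("  rss = %.3g, %s%s\n", x$rss,
              if (x$valid) "valid" else "flagged invalid",
              if (x$boundary) " (boundary hit)" else ""))
  invisible(x)
}

#' @export
coef.monod_fit <- function(object, ...) {
  c(mu_max = object$mu_max, ks = object$ks, p_star = object$p_star)
}

#' @export
predict.monod_fit <- function(object, newdata = NULL, ...) {
  s <- if (is.null(newdata)) object$data$phosphorus
       else if (is.data.frame(newdata)) newdata$phosphorus
       else newdata
  monod(s, object$mu_max, object$ks)
}

#' @export
plot.monod_fit <- function(x, ...) {
  grid <- seq(0, max(x$data$phosphorus) * 1.05, length.out = 200)
  graphics::plot(x$data$phosphorus, x$data$mu, xlab = "Phosphate (umol/L)",
                 ylab = "Growth rate (per day)", ...)
  graphics::lines(grid, predict(x, grid))
  graphics::abline(h = x$m, lty = 3)
  invisible(x)
}
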