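# Independent oracles used to cross-check the package's fitters.
# These deliberately take a different computational route (stats::lm on
# explicit predictors, exhaustive lattice search, closed-form normal
# equations) from the implementation they verify.

# Brute-force segmented growth fit: enumerate every admissible breakpoint
# (observed timepoints, >= 2 points per segment), fit each configuration with
# stats::lm, and select by the AICc formula computed inline.
oracle_segmented <- function(t, y) {
  n <- length(t)
  cands <- list()
  add <- function(model, p, g, lag = NA, sat = NA) {
    fit <- stats::lm(y ~ g)
    cands[[length(cands) + 1L]] <<- list(
      model = model, p = p, lag = lag, sat = sat,
      mu = unname(stats::coef(fit)[2]),
      rss = sum(stats::resid(fit)^2)
    )
  }
  add("exponential", 2L, t)
  if (n >= 4) {
    for (k in 1:(n - 1)) {
      add("lag", 3L, pmax(t - t[k], 0), lag = t[k])
      add("saturation", 3L, pmin(t - t[k + 1L], 0), sat = t[k + 1L])
    }
  }
  if (n >= 5) {
    for (k1 in 1:(n - 1)) for (k2 in (k1 + 1):n) {
      add("lag_saturation", 4L, pmin(pmax(t, t[k1]), t[k2]) - t[k1],
          lag = t[k1], sat = t[k2])
    }
  }
  per_model <- list()
  for (cand in cands) {
    if (cand$p + 1L > n) next
    cur <- per_model[[cand$model]]
    if (is.null(cur) || cand$rss < cur$rss) per_model[[cand$model]] <- cand
  }
  for (m in names(per_model)) {
    cand <- per_model[[m]]
    per_model[[m]]$aicc <- if (n > cand$p + 1)
      n * log(max(cand$rss, 1e-300) / n) + 2 * cand$p +
        2 * cand$p * (cand$p + 1) / (n - cand$p - 1)
    else Inf
  }
  a <- vapply(per_model, `[[`, numeric(1), "aicc")
  p <- vapply(per_model, `[[`, numeric(1), "p")
  best <- per_model[[order(a, p)[1]]]
  list(per_model = per_model, best = best)
}

# Iteratively refined lattice search for the Monod least-squares optimum.
oracle_monod_grid <- function(rates, mu_range = c(1e-6, 5), ks_range = c(1e-4, 100),
                              n_grid = 61, n_zoom = 8) {
  sse <- function(mu_max, ks) {
    pred <- outer(rates$phosphorus, ks, function(s, k) s / (k + s))
    # rows: observations, cols: ks; evaluate all (mu, ks) pairs
    sapply(seq_along(mu_max), function(i) {
      sum((rates$mu - mu_max[i] * pred[, i])^2)
    })
  }
  for (z in seq_len(n_zoom)) {
    mu_g <- seq(mu_range[1], mu_range[2], length.out = n_grid)
    ks_g <- seq(ks_range[1], ks_range[2], length.out = n_grid)
    grid <- expand.grid(mu = mu_g, ks = ks_g)
    vals <- sse(grid$mu, grid$ks)
    best <- grid[which.min(vals), ]
    mu_step <- diff(mu_g[1:2]); ks_step <- diff(ks_g[1:2])
    mu_range <- c(max(1e-6, best$mu - 2 * mu_step), min(5, best$mu + 2 * mu_step))
    ks_range <- c(max(1e-4, best$ks - 2 * ks_step), min(100, best$ks + 2 * ks_step))
  }
  list(mu_max = best$mu, ks = best$ks, sse = min(vals))
}

# Closed-form weighted least squares via the normal equations.
oracle_wls <- function(x, y, w) {
  X <- cbind(1, x)
  XtWX <- t(X) %*% (w * X)
  beta <- solve(XtWX, t(X) %*% (w * y))
  resid <- y - X %*% beta
  s2 <- sum(w * resid^2) / (length(y) - 2)
  se <- sqrt(diag(solve(XtWX)) * s2)
  list(intercept = unname(beta[1]), slope = unname(beta[2]),
       se_slope = unname(se[2]))
}

# Grid-search argmax of the thermal performance curve.
oracle_topt_grid <- function(a, b, t_ref, w, step = 1e-3) {
  grid <- seq(t_ref - w / 2, t_ref + w / 2, by = step)
  grid[which.max(thomas_tpc(grid, a, b, t_ref, w))]
}
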