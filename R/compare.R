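# Bootstrap comparison of conditional-GMM parameters between conditions,
# and a thin OLS utility for the correlation analyses.

refit_model <- function(cycles, k_fit_bins, bin_x, control, ...) {
  bins <- suppressWarnings(fit_bin_mixtures(cycles, control = control, ...))
  suppressWarnings(fit_parameter_curves(bins, k_fit_bins = k_fit_bins, bin_x = bin_x))
}

#' Bootstrap comparison of model parameters between two conditions
#'
#' Cycles are resampled with replacement within each condition (light and
#' dark phase, typically), the full conditional model is refitted per
#' iteration, and each parameter curve is averaged over a common
#' `rem_pre` grid spanning `[max(domain_min_A, domain_min_B),
#' rem_pre_max)` in 2.5 s steps (the `k_long` curve is clamped to
#' `[0, 1]` before averaging). The two per-condition distributions of
#' grid averages are summarised by the difference of means, percentile
#' confidence intervals and Welch's unequal-variance t-test.
#'
#' @param cycles_a,cycles_b Cycle tibbles for the two conditions.
#' @param params Parameters to compare.
#' @param n_boot Bootstrap iterations (the published analysis used
#'   10,000).
#' @param k_fit_bins_a,k_fit_bins_b Leading `k_long` bins per condition
#'   (6 for light, 4 for dark in the published fits).
#' @param bin_x Bin x-coordinate convention, see [fit_parameter_curves()].
#' @param grid_step Grid step (s) for the domain average.
#' @param seed Optional integer seed.
#' @param control [em_control()] for the per-iteration refits (kept light).
#' @param max_drop_frac Error out when more than this fraction of
#'   iterations fails to refit.
#' @return A list of class `remcycle_boot` with per-parameter iteration
#'   values (`draws`) and a `summary` tibble (`difference` is mean A
#'   minus mean B).
#' @export
bootstrap_phase_comparison <- function(cycles_a, cycles_b,
                                       params = c("k_long", "mu_long", "sigma_long"),
                                       n_boot = 10000L,
                                       k_fit_bins_a = 6L, k_fit_bins_b = 4L,
                                       bin_x = "midpoint",
                                       grid_step = 2.5, seed = NULL,
                                       control = em_control(restarts = 3L, tol = 1e-6, max_iter = 200L),
                                       max_drop_frac = 0.05) {
  if (n_boot < 1) {
    stop_remcycle("`n_boot` must be at least 1.", "remcycle_parameter_error")
  }
  fit_a <- refit_model(cycles_a, k_fit_bins_a, bin_x, control)
  fit_b <- refit_model(cycles_b, k_fit_bins_b, bin_x, control)
  grid_lo <- max(fit_a$domain_min, fit_b$domain_min)
  grid_hi <- min(fit_a$rem_pre_max_fit, fit_b$rem_pre_max_fit)
  grid <- seq(grid_lo, grid_hi - grid_step, by = grid_step)
  grid_average <- function(m) {
    p <- eval_params_raw(m, grid) # k_long clamped before averaging
    purrr::map_dbl(setNames(params, params), ~ mean(p[[.x]]))
  }
  one_iter <- function(cycles, k_fit_bins) {
    idx <- sample.int(nrow(cycles), replace = TRUE)
    m <- tryCatch(
      refit_model(cycles[idx, ], k_fit_bins, bin_x, control),
      error = function(e) NULL
    )
    if (is.null(m)) NULL else grid_average(m)
  }
  res <- with_seed_maybe(seed, {
    a <- purrr::map(seq_len(n_boot), ~ one_iter(cycles_a, k_fit_bins_a))
    b <- purrr::map(seq_len(n_boot), ~ one_iter(cycles_b, k_fit_bins_b))
    list(a = a, b = b)
  })
  dropped <- sum(purrr::map_lgl(res$a, is.null)) + sum(purrr::map_lgl(res$b, is.null))
  if (dropped > max_drop_frac * 2 * n_boot) {
    stop_remcycle(sprintf("%d of %d bootstrap refits failed.", dropped, 2L * n_boot),
                  "remcycle_bootstrap_error")
  }
  mat_a <- do.call(rbind, purrr::compact(res$a))
  mat_b <- do.call(rbind, purrr::compact(res$b))
  summary <- purrr::map_dfr(params, function(p) {
    da <- mat_a[, p]
    db <- mat_b[, p]
    tt <- if (length(da) > 1 && length(db) > 1 && (sd(da) > 0 || sd(db) > 0)) {
      t.test(da, db) # Welch by default
    } else {
      NULL
    }
    # percentile CI of the difference, pairing iterations (independent
    # streams, so pairing is just a convenient equal-length resampling)
    m <- min(length(da), length(db))
    d <- da[seq_len(m)] - db[seq_len(m)]
    tibble(
      parameter = p,
      mean_a = mean(da), mean_b = mean(db),
      difference = mean(da) - mean(db),
      ci_lo = quantile(d, 0.025, names = FALSE),
      ci_hi = quantile(d, 0.975, names = FALSE),
      t_statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
      p_value = if (is.null(tt)) NA_real_ else tt$p.value
    )
  })
  structure(
    list(
      draws_a = mat_a, draws_b = mat_b, n_boot = n_boot,
      n_dropped = dropped, grid = grid, summary = summary
    ),
    class = "remcycle_boot"
  )
}

#' @export
print.remcycle_boot <- function(x, ...) {
  cat(sprintf("Bootstrap comparison (%d iterations, %d refits dropped)\n",
              x$n_boot, x$n_dropped))
  print(x$summary)
  invisible(x)
}

#' Ordinary least squares fit
#'
#' Thin wrapper around [stats::lm()] for the regression analyses (e.g.
#' REM duration against inter-REM interval, or propensity at REM onset
#' against the following REM duration).
#'
#' @param data A data frame.
#' @param x,y Column names (tidy-eval) of predictor and response.
#' @return A one-row tibble with `slope`, `intercept`, `r_squared`,
#'   `p_value` (slope test; `NA` with zero residual degrees of freedom)
#'   and `n`.
#' @export
ols_fit <- function(data, x, y) {
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]
  yv <- yv[ok]
  if (length(xv) < 2L) {
    stop_remcycle("Need at least 2 finite (x, y) pairs.", "remcycle_parameter_error")
  }
  if (var(xv) == 0) {
    stop_remcycle("Zero variance in x; slope undefined.", "remcycle_parameter_error")
  }
  fit <- lm(yv ~ xv)
  # summary.lm warns on saturated two-point fits; the NA p-value below
  # already flags that case
  sm <- suppressWarnings(summary(fit))
  p <- if (fit$df.residual > 0) sm$coefficients["xv", "Pr(>|t|)"] else NA_real_
  tibble(
    slope = unname(coef(fit)["xv"]),
    intercept = unname(coef(fit)["(Intercept)"]),
    r_squared = sm$r.squared,
    p_value = p,
    n = length(xv)
  )
}
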