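# Lilliefors-corrected KS goodness-of-fit and whole-model simulation.

# two-component Gaussian mixture cdf with explicit parameters
gmm2_cdf <- function(x, k_long, mu_long, mu_short, sigma_long, sigma_short) {
  if (!is.finite(mu_short) || k_long >= 1) {
    pnorm((x - mu_long) / sigma_long)
  } else {
    k_long * pnorm((x - mu_long) / sigma_long) +
      (1 - k_long) * pnorm((x - mu_short) / sigma_short)
  }
}

gmm2_sample <- function(n, k_long, mu_long, mu_short, sigma_long, sigma_short) {
  long <- runif(n) < k_long
  mu <- ifelse(long, mu_long, mu_short)
  sig <- ifelse(long, sigma_long, sigma_short)
  rnorm(n, mu, sig)
}

# exact two-sided KS sup-distance given the model cdf evaluated at the
# sorted sample
ks_statistic <- function(cdf_values_sorted) {
  n <- length(cdf_values_sorted)
  i <- seq_len(n)
  max(pmax(i / n - cdf_values_sorted, cdf_values_sorted - (i - 1) / n))
}

#' Lilliefors-corrected Kolmogorov-Smirnov test for a per-bin mixture fit
#'
#' The plain KS test is invalid when the tested distribution's parameters
#' were estimated from the same data. The Monte-Carlo correction draws
#' `n_sim` samples of the original size from the fitted mixture, refits
#' the mixture on each (the essence of the Lilliefors correction;
#' disable with `refit = FALSE` for the uncorrected-parameter variant)
#' and records each sample's KS statistic against its (re)fitted CDF.
#' The observed statistic is then ranked within this null distribution:
#' the fit is rejected when `ks_obs` exceeds its 95th percentile.
#'
#' @param ln_n The `ln(n_total)` sample of one `rem_pre` bin.
#' @param fit The bin's fitted parameters: a list or one-row data frame
#'   with `k_long`, `mu_long`, `mu_short`, `sigma_long`, `sigma_short`
#'   (and optionally `unimodal`).
#' @param n_sim Number of Monte-Carlo rounds (the published analysis used
#'   10,000).
#' @param refit Re-estimate the mixture on each simulated sample.
#' @param seed Optional integer seed.
#' @param control [em_control()] used for the re-fits; lighter than the
#'   primary-fit default since thousands of fits are run.
#' @param keep_sim Retain the full simulated KS distribution.
#' @return A list of class `remcycle_gof` with `n`, `ks_obs`, `ks_sim_q95`,
#'   `p_value` (fraction of simulated statistics at least `ks_obs`) and
#'   `reject`.
#' @export
lilliefors_ks <- function(ln_n, fit, n_sim = 10000L, refit = TRUE, seed = NULL,
                          control = em_control(restarts = 3L, tol = 1e-6, max_iter = 200L),
                          keep_sim = FALSE) {
  if (n_sim < 1) {
    stop_remcycle("`n_sim` must be at least 1.", "remcycle_parameter_error")
  }
  if (length(ln_n) < 3L) {
    stop_remcycle("Need at least 3 observations.", "remcycle_parameter_error")
  }
  fit <- as.list(fit)
  unimodal <- isTRUE(fit$unimodal) || !is.finite(fit$mu_short %||% NA_real_) ||
    fit$k_long >= 1
  n <- length(ln_n)
  obs_cdf <- gmm2_cdf(sort(ln_n), fit$k_long, fit$mu_long, fit$mu_short,
                      fit$sigma_long, fit$sigma_short)
  ks_obs <- ks_statistic(obs_cdf)
  ks_sim <- with_seed_maybe(seed, {
    vapply(seq_len(n_sim), function(s) {
      y <- gmm2_sample(n, fit$k_long, fit$mu_long, fit$mu_short,
                       fit$sigma_long, fit$sigma_short)
      f <- fit
      if (refit) {
        f <- if (unimodal) {
          list(k_long = 1, mu_long = mean(y), mu_short = NA_real_,
               sigma_long = max(sd(y), 1e-6), sigma_short = NA_real_)
        } else {
          tryCatch(fit_gmm2(y, control = control), error = function(e) fit)
        }
      }
      cdf <- gmm2_cdf(sort(y), f$k_long, f$mu_long, f$mu_short,
                      f$sigma_long, f$sigma_short)
      ks_statistic(cdf)
    }, numeric(1))
  })
  q95 <- quantile(ks_sim, 0.95, names = FALSE)
  structure(
    list(
      n = n, n_sim = n_sim, ks_obs = ks_obs,
      ks_sim_q95 = q95,
      p_value = mean(ks_sim >= ks_obs),
      reject = ks_obs > q95,
      ks_sim = if (keep_sim) ks_sim else NULL
    ),
    class = "remcycle_gof"
  )
}

#' @export
print.remcycle_gof <- function(x, ...) {
  cat(sprintf(
    "Lilliefors-corrected KS test: n = %d, KS_obs = %.4f, 95%% of KS_sim = %.4f, p = %.4f -> %s\n",
    x$n, x$ks_obs, x$ks_sim_q95, x$p_value,
    if (x$reject) "reject" else "no evidence against the fit"
  ))
  invisible(x)
}

#' Goodness of fit for every bin of a fitted model
#'
#' Runs [lilliefors_ks()] on each fitted `rem_pre` bin of a cycle data
#' set.
#'
#' @param cycles Cycle tibble used for the fit.
#' @param bins A [fit_bin_mixtures()] result.
#' @inheritParams lilliefors_ks
#' @return A tibble with one row per bin: `bin_lo`, `bin_hi`, `n`,
#'   `ks_obs`, `p_value`, `reject`.
#' @export
gof_by_bin <- function(cycles, bins, n_sim = 10000L, refit = TRUE, seed = NULL,
                       control = em_control(restarts = 3L, tol = 1e-6, max_iter = 200L)) {
  seeds <- if (is.null(seed)) rep(list(NULL), nrow(bins)) else as.list(seed + seq_len(nrow(bins)))
  purrr::map_dfr(seq_len(nrow(bins)), function(i) {
    b <- bins[i, ]
    ln_n <- log(cycles$n_total[cycles$rem_pre >= b$bin_lo & cycles$rem_pre < b$bin_hi])
    g <- lilliefors_ks(ln_n, b, n_sim = n_sim, refit = refit,
                       seed = seeds[[i]], control = control)
    tibble(
      bin_lo = b$bin_lo, bin_hi = b$bin_hi, n = g$n,
      ks_obs = g$ks_obs, p_value = g$p_value, reject = g$reject
    )
  })
}

#' Simulate the whole-model distribution of `ln(|N|)`
#'
#' For each repetition, one `ln(|N|)` value is drawn from the conditional
#' mixture at every supplied `rem_pre` (values outside
#' `[domain_min, rem_pre_max_fit)` are skipped with a message, mirroring
#' the published simulation range). The pooled sample can be compared
#' against the empirical `ln(|N|)` distribution with a two-sample KS test.
#'
#' @param m A `remcycle_cgmm` model.
#' @param rem_pre_values The data set's `rem_pre` values (s).
#' @param reps Number of repetitions (the published check used 10,000).
#' @param empirical Optional empirical `ln(|N|)` sample to compare with.
#' @param seed Optional integer seed.
#' @return A list with `sample` (pooled simulated `ln(|N|)`),
#'   `n_skipped`, and — when `empirical` is given — `ks` (the
#'   [stats::ks.test()] result).
#' @export
simulate_model_distribution <- function(m, rem_pre_values, reps = 10000L,
                                        empirical = NULL, seed = NULL) {
  if (length(rem_pre_values) == 0L) {
    stop_remcycle("`rem_pre_values` must be non-empty.", "remcycle_parameter_error")
  }
  keep <- rem_pre_values >= m$domain_min & rem_pre_values < m$rem_pre_max_fit
  if (any(!keep)) {
    inform(sprintf("%d rem_pre value(s) outside [%g, %g) s skipped.",
                   sum(!keep), m$domain_min, m$rem_pre_max_fit))
  }
  x <- rem_pre_values[keep]
  if (length(x) == 0L) {
    stop_remcycle("No rem_pre values inside the model domain.", "remcycle_parameter_error")
  }
  p <- eval_params_raw(m, x)
  sample <- with_seed_maybe(seed, {
    unlist(lapply(seq_len(reps), function(r) {
      long <- runif(length(x)) < p$k_long
      rnorm(
        length(x),
        ifelse(long, p$mu_long, p$mu_short),
        ifelse(long, p$sigma_long, p$sigma_short)
      )
    }))
  })
  out <- list(sample = sample, n_skipped = sum(!keep))
  if (!is.null(empirical)) {
    out$ks <- suppressWarnings(ks.test(sample, empirical))
  }
  out
}
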