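#' Control parameters for the mixture EM
#'
#' @param restarts Number of random restarts in addition to the
#'   median-split initialisation.
#' @param tol Convergence tolerance on the log-likelihood increment.
#' @param max_iter Iteration cap per start.
#' @param var_floor Lower bound on component variances, guarding against
#'   collapse onto a single point.
#' @return A list of class `remcycle_em_control`.
#' @export
em_control <- function(restarts = 20L, tol = 1e-8, max_iter = 500L, var_floor = 1e-6) {
  structure(
    list(
      restarts = as.integer(restarts), tol = tol,
      max_iter = as.integer(max_iter), var_floor = var_floor
    ),
    class = "remcycle_em_control"
  )
}

# one EM run from a given initialisation; returns parameters ordered so
# that component "long" has the larger mean
em_run <- function(x, w0, mu0, var0, control) {
  n <- length(x)
  k <- w0
  mu <- mu0
  v <- pmax(var0, control$var_floor)
  ll_old <- -Inf
  ll_trace <- numeric(0)
  for (iter in seq_len(control$max_iter)) {
    d1 <- k * dnorm(x, mu[1], sqrt(v[1]))
    d2 <- (1 - k) * dnorm(x, mu[2], sqrt(v[2]))
    tot <- d1 + d2
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(tot))
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && ll - ll_old < control$tol) break
    ll_old <- ll
    g <- d1 / tot
    s <- sum(g)
    k <- s / n
    if (s < 1e-10 || n - s < 1e-10) break # one component vanished
    mu[1] <- sum(g * x) / s
    mu[2] <- sum((1 - g) * x) / (n - s)
    v[1] <- max(sum(g * (x - mu[1])^2) / s, control$var_floor)
    v[2] <- max(sum((1 - g) * (x - mu[2])^2) / (n - s), control$var_floor)
  }
  list(k1 = k, mu = mu, var = v, loglik = ll_old, ll_trace = ll_trace, n_iter = iter)
}

#' Fit a two-component Gaussian mixture to a univariate sample by EM
#'
#' Maximum-likelihood fit of `k * N(mu1, s1^2) + (1 - k) * N(mu2, s2^2)`
#' used on `ln(|N|)` within each 30 s bin of preceding REM duration.
#' Initialisation splits the sample at its median (plus `restarts` random
#' quantile splits); the best run by final log-likelihood is kept and the
#' components are relabelled so that the "long" component is the one with
#' the larger mean. The per-iteration log-likelihood trace is monotone
#' non-decreasing.
#'
#' @param x Numeric sample (typically `ln(n_total)` of a REM-duration bin).
#' @param control An [em_control()] list.
#' @return A list with `k_long`, `mu_long`, `mu_short`, `sigma_long`,
#'   `sigma_short`, `loglik`, `ll_trace` and `n_iter`.
#' @export
fit_gmm2 <- function(x, control = em_control()) {
  x <- as.numeric(x)
  if (length(x) < 4L) {
    stop_remcycle("Need at least 4 observations for a two-component fit.", "remcycle_parameter_error")
  }
  if (var(x) < control$var_floor) {
    stop_remcycle("Sample is (numerically) constant; mixture fit is degenerate.", "remcycle_degenerate_error")
  }
  splits <- c(0.5, runif(control$restarts, 0.15, 0.85))
  best <- NULL
  for (q in splits) {
    cut <- quantile(x, q, names = FALSE)
    lo <- x[x <= cut]
    hi <- x[x > cut]
    if (length(lo) < 2L || length(hi) < 2L) next
    fit <- em_run(
      x,
      w0 = length(lo) / length(x),
      mu0 = c(mean(lo), mean(hi)),
      var0 = c(var(lo), var(hi)),
      control = control
    )
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) {
    stop_remcycle("All EM initialisations failed.", "remcycle_degenerate_error")
  }
  # label-switching guard: "long" is the larger-mean component
  if (best$mu[1] >= best$mu[2]) {
    kl <- best$k1
    ml <- best$mu[1]; ms <- best$mu[2]
    vl <- best$var[1]; vs <- best$var[2]
  } else {
    kl <- 1 - best$k1
    ml <- best$mu[2]; ms <- best$mu[1]
    vl <- best$var[2]; vs <- best$var[1]
  }
  list(
    k_long = kl, mu_long = ml, mu_short = ms,
    sigma_long = sqrt(vl), sigma_short = sqrt(vs),
    loglik = best$loglik, ll_trace = best$ll_trace, n_iter = best$n_iter
  )
}

# log-likelihood of a 2-component mixture (used by tests and the
# Lilliefors machinery)
gmm2_loglik <- function(x, k_long, mu_long, mu_short, sigma_long, sigma_short) {
  d <- k_long * dnorm(x, mu_long, sigma_long) +
    (1 - k_long) * dnorm(x, mu_short, sigma_short)
  d[d < .Machine$double.xmin] <- .Machine$double.xmin
  sum(log(d))
}

#' Fit per-bin mixtures of `ln(|N|)` across REM-duration bins
#'
#' Sleep cycles are grouped into non-overlapping `bin_width` s bins of
#' `rem_pre` (default `[0,30), [30,60), ..., [210,240)`), and within each
#' bin the distribution of `ln(n_total)` is fitted. Bins whose lower edge
#' is at or beyond `unimodal_from` (150 s by default) are treated as
#' unimodal: a single Gaussian is fitted (`k_long = 1`) and the short
#' component is absent (`NA`). Bins with fewer than `min_count` cycles are
#' skipped with a warning.
#'
#' @param cycles Cycle tibble from [extract_cycles()] (needs `rem_pre` and
#'   `n_total`).
#' @param bin_width Bin width in seconds.
#' @param unimodal_from `rem_pre` (s) from which a single Gaussian is used.
#' @param rem_pre_max Upper fitting limit on `rem_pre` (s); cycles at or
#'   beyond it are excluded.
#' @param min_count Minimum number of cycles per bin.
#' @param control An [em_control()] list.
#' @return A tibble of class `remcycle_bin_fits` with one row per fitted
#'   bin: `bin_lo`, `bin_hi`, `x_mid`, `x_mean`, `n`, `k_long`, `mu_long`,
#'   `mu_short`, `sigma_long`, `sigma_short`, `unimodal`, `loglik`.
#' @export
fit_bin_mixtures <- function(cycles, bin_width = 30, unimodal_from = 150,
                             rem_pre_max = 240, min_count = 10L,
                             control = em_control()) {
  stopifnot(is.data.frame(cycles), all(c("rem_pre", "n_total") %in% names(cycles)))
  if (any(cycles$n_total <= 0)) {
    stop_remcycle("Cycles with n_total = 0 found; ln(|N|) is undefined.", "remcycle_parameter_error")
  }
  cyc <- dplyr::filter(cycles, .data$rem_pre < rem_pre_max)
  edges <- seq(0, rem_pre_max, by = bin_width)
  out <- purrr::map_dfr(seq_len(length(edges) - 1L), function(i) {
    lo <- edges[i]
    hi <- edges[i + 1L]
    in_bin <- cyc$rem_pre >= lo & cyc$rem_pre < hi
    n <- sum(in_bin)
    if (n < min_count) {
      warn(sprintf("Bin [%g, %g) has %d < %d cycles; skipped.", lo, hi, n, min_count))
      return(NULL)
    }
    ln_n <- log(cyc$n_total[in_bin])
    if (lo >= unimodal_from) {
      fit <- list(
        k_long = 1, mu_long = mean(ln_n), mu_short = NA_real_,
        sigma_long = max(sd(ln_n), sqrt(control$var_floor)),
        sigma_short = NA_real_,
        loglik = sum(dnorm(ln_n, mean(ln_n), max(sd(ln_n), sqrt(control$var_floor)), log = TRUE))
      )
      unimodal <- TRUE
    } else {
      fit <- fit_gmm2(ln_n, control = control)
      unimodal <- FALSE
    }
    tibble(
      bin_lo = lo, bin_hi = hi, x_mid = (lo + hi) / 2,
      x_mean = mean(cyc$rem_pre[in_bin]), n = n,
      k_long = fit$k_long, mu_long = fit$mu_long, mu_short = fit$mu_short,
      sigma_long = fit$sigma_long, sigma_short = fit$sigma_short,
      unimodal = unimodal, loglik = fit$loglik
    )
  })
  if (nrow(out) == 0L) {
    stop_remcycle("No bin reached the minimum cycle count.", "remcycle_parameter_error")
  }
  class(out) <- c("remcycle_bin_fits", class(out))
  out
}
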