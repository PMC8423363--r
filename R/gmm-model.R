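# Conditional Gaussian mixture model: parameter curves over rem_pre and
# the derived pdf/cdf/sampler.

# evaluate a parameter curve at rem_pre values
eval_curve <- function(curve, x) {
  switch(curve$kind,
    logarithmic = curve$a * log(x + curve$b) + curve$c,
    linear = curve$a * x + curve$b,
    stop_remcycle(sprintf("Unknown curve kind %s.", dQuote(curve$kind)), "remcycle_parameter_error")
  )
}

new_curve <- function(kind, a, b, c = NA_real_, rss = NA_real_) {
  list(kind = kind, a = a, b = b, c = c, rss = rss)
}

# least-squares fit of a single parameter curve: both the linear and the
# bounded logarithmic form are fitted and the lower-RSS one is kept
fit_one_curve <- function(x, y) {
  if (length(x) < 3L) {
    stop_remcycle("Need at least 3 bins to fit a parameter curve.", "remcycle_parameter_error")
  }
  lin <- lm(y ~ x)
  lin_curve <- new_curve(
    "linear",
    a = unname(coef(lin)[2]), b = unname(coef(lin)[1]),
    rss = sum(residuals(lin)^2)
  )
  log_curve <- NULL
  df <- data.frame(x = x, y = y)
  for (b0 in c(0, 1, 10, 100)) {
    # crude linear-in-(a,c) start given b0
    z <- log(x + b0)
    st <- lm(y ~ z)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a * log(x + b) + c,
        data = df,
        start = list(a = unname(coef(st)[2]), b = b0, c = unname(coef(st)[1])),
        lower = c(a = -Inf, b = 0, c = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(log_curve) || rss < log_curve$rss) {
      cf <- coef(fit)
      log_curve <- new_curve("logarithmic", a = unname(cf["a"]), b = unname(cf["b"]),
                             c = unname(cf["c"]), rss = rss)
    }
  }
  if (is.null(log_curve)) {
    warn("Logarithmic curve fit did not converge; falling back to the linear fit.")
    return(lin_curve)
  }
  if (log_curve$rss <= lin_curve$rss) log_curve else lin_curve
}

new_cond_gmm <- function(curves, phase = "unknown", rem_pre_max_fit = 240,
                         domain_min = NA_real_, bin_fits = NULL) {
  structure(
    list(
      curves = curves, phase = phase, rem_pre_max_fit = rem_pre_max_fit,
      domain_min = domain_min, bin_fits = bin_fits
    ),
    class = "remcycle_cgmm"
  )
}

#' Build a conditional Gaussian mixture model from explicit parameter curves
#'
#' Mostly used to define ground-truth models for simulation; [fit_parameter_curves()]
#' builds the same object from per-bin fits. Each curve is a list
#' `list(kind, a, b, c)` with `kind` `"logarithmic"` (`y = a*ln(x+b)+c`,
#' `b >= 0`) or `"linear"` (`y = a*x+b`).
#'
#' @param k_long,mu_long,mu_short,sigma_long,sigma_short Parameter curves.
#' @param phase Circadian phase label carried by the model.
#' @param rem_pre_max_fit Upper end (s) of the `rem_pre` range used in
#'   fitting; evaluation beyond it warns of extrapolation.
#' @param domain_step Grid step (s) for locating the domain minimum.
#' @param domain_min Explicit domain minimum (s); `NULL` (default)
#'   derives it from the intersection rule. Setting it is mainly useful
#'   for single-component (`k_long = 1`) models, where no intersection
#'   exists.
#' @return A `remcycle_cgmm` object.
#' @export
cond_gmm <- function(k_long, mu_long, mu_short, sigma_long, sigma_short,
                     phase = "unknown", rem_pre_max_fit = 240, domain_step = 2.5,
                     domain_min = NULL) {
  m <- new_cond_gmm(
    curves = list(
      k_long = k_long, mu_long = mu_long, mu_short = mu_short,
      sigma_long = sigma_long, sigma_short = sigma_short
    ),
    phase = phase, rem_pre_max_fit = rem_pre_max_fit
  )
  m$domain_min <- domain_min %||% compute_domain_min(m, step = domain_step)
  m
}

#' Fit the parameter curves of the conditional model
#'
#' For each of the five mixture parameters, both a linear and a bounded
#' logarithmic function of `rem_pre` is fitted by least squares to the
#' per-bin estimates and the lower-RSS form kept. `k_long` only uses the
#' first `k_fit_bins` bins, since the weight saturates at 1 for long
#' preceding REM episodes; the short-component parameters only use the
#' bimodal bins. The domain minimum — the smallest `rem_pre` on a 2.5 s
#' grid for which the two weighted component densities intersect strictly
#' between their means — is computed and stored.
#'
#' @param bins A [fit_bin_mixtures()] result.
#' @param k_fit_bins Number of leading bins used for the `k_long` curve
#'   (6 for light-phase data, 4 for dark-phase data).
#' @param bin_x Which x-coordinate represents a bin: the mean `rem_pre`
#'   of its cycles (default — unbiased whatever the within-bin
#'   distribution of REM durations) or the bin midpoint (unbiased only
#'   for uniform-in-bin data).
#' @param phase Circadian phase label.
#' @param domain_step Grid step (s) for the domain search.
#' @return A fitted `remcycle_cgmm` object.
#' @export
fit_parameter_curves <- function(bins, k_fit_bins = 6L,
                                 bin_x = c("mean", "midpoint"),
                                 phase = "unknown", domain_step = 2.5) {
  bin_x <- match.arg(bin_x)
  stopifnot(is.data.frame(bins))
  bins <- dplyr::arrange(bins, .data$bin_lo)
  x_all <- if (bin_x == "midpoint") bins$x_mid else bins$x_mean
  bimodal <- !bins$unimodal
  if (sum(bimodal) < 3L) {
    stop_remcycle("Fewer than 3 bimodal bins; cannot fit short-component curves.",
                  "remcycle_parameter_error")
  }
  kk <- seq_len(min(k_fit_bins, nrow(bins)))
  curves <- list(
    k_long = fit_one_curve(x_all[kk], bins$k_long[kk]),
    mu_long = fit_one_curve(x_all, bins$mu_long),
    mu_short = fit_one_curve(x_all[bimodal], bins$mu_short[bimodal]),
    sigma_long = fit_one_curve(x_all, bins$sigma_long),
    sigma_short = fit_one_curve(x_all[bimodal], bins$sigma_short[bimodal])
  )
  m <- new_cond_gmm(
    curves = curves,
    phase = phase,
    rem_pre_max_fit = max(bins$bin_hi),
    bin_fits = bins
  )
  m$domain_min <- compute_domain_min(m, step = domain_step)
  m
}

# raw parameter evaluation without domain checks (internal); k_long is
# clamped to [0, 1], sigmas floored at a small epsilon
eval_params_raw <- function(m, rem_pre) {
  sig_eps <- 1e-6
  tibble(
    rem_pre = rem_pre,
    k_long = pmin(pmax(eval_curve(m$curves$k_long, rem_pre), 0), 1),
    mu_long = eval_curve(m$curves$mu_long, rem_pre),
    mu_short = eval_curve(m$curves$mu_short, rem_pre),
    sigma_long = pmax(eval_curve(m$curves$sigma_long, rem_pre), sig_eps),
    sigma_short = pmax(eval_curve(m$curves$sigma_short, rem_pre), sig_eps)
  ) |>
    dplyr::mutate(k_short = 1 - .data$k_long, .after = "k_long")
}

check_domain <- function(m, rem_pre, warn_extrapolate = TRUE) {
  if (any(rem_pre < m$domain_min)) {
    stop_remcycle(
      sprintf("rem_pre below the model domain minimum (%g s).", m$domain_min),
      "remcycle_domain_error"
    )
  }
  if (warn_extrapolate && any(rem_pre >= m$rem_pre_max_fit)) {
    warn(sprintf(
      "Evaluating the conditional model beyond the fitted range (rem_pre >= %g s); extrapolating.",
      m$rem_pre_max_fit
    ))
  }
  invisible(TRUE)
}

#' Evaluate the conditional mixture parameters at given `rem_pre`
#'
#' Returns the six mixture parameters at each `rem_pre`: the long-component
#' weight is clamped to `[0, 1]` (the fitted logarithmic weight curve is
#' capped at 1, as a weight is a probability), `k_short = 1 - k_long`, and
#' the standard deviations are floored at a small positive epsilon.
#'
#' @param m A `remcycle_cgmm` model.
#' @param rem_pre Preceding REM durations (s), each at least the model's
#'   `domain_min`.
#' @return A tibble with columns `rem_pre`, `k_long`, `k_short`,
#'   `mu_long`, `mu_short`, `sigma_long`, `sigma_short`.
#' @export
evaluate_parameters <- function(m, rem_pre) {
  check_domain(m, rem_pre)
  eval_params_raw(m, rem_pre)
}

#' Conditional density of `ln(|N|)` given `rem_pre`
#'
#' The density `P(ln(|N|) | rem_pre) = k_long * f(mu_long, sigma_long^2) +
#' k_short * f(mu_short, sigma_short^2)` with all parameters evaluated at
#' `rem_pre`.
#'
#' @param m A `remcycle_cgmm` model.
#' @param rem_pre Preceding REM duration (s), scalar or of the length of
#'   `ln_n`.
#' @param ln_n Values of `ln(n_total)` (ln-seconds) at which to evaluate.
#' @return Densities, same length as `ln_n`.
#' @export
mixture_pdf <- function(m, rem_pre, ln_n) {
  check_domain(m, rem_pre)
  p <- eval_params_raw(m, rem_pre)
  p$k_long * dnorm(ln_n, p$mu_long, p$sigma_long) +
    p$k_short * dnorm(ln_n, p$mu_short, p$sigma_short)
}

#' Conditional CDF: probability of entering REM within `n` seconds of NREM
#'
#' `F(n | rem_pre) = k_long * Phi((ln n - mu_long)/sigma_long) + k_short *
#' Phi((ln n - mu_short)/sigma_short)`, i.e. the probability that the next
#' REM episode is entered within `n` seconds of accumulated NREM sleep.
#'
#' @inheritParams mixture_pdf
#' @param n Accumulated NREM time in seconds (>= 0).
#' @return Probabilities in `[0, 1]`, non-decreasing in `n`; `n = 0`
#'   yields 0.
#' @export
mixture_cdf <- function(m, rem_pre, n) {
  if (any(n < 0)) {
    stop_remcycle("`n` must be non-negative.", "remcycle_parameter_error")
  }
  check_domain(m, rem_pre)
  p <- eval_params_raw(m, rem_pre)
  ln_n <- ifelse(n == 0, -Inf, log(n))
  p$k_long * pnorm((ln_n - p$mu_long) / p$sigma_long) +
    p$k_short * pnorm((ln_n - p$mu_short) / p$sigma_short)
}

#' Sample NREM amounts from the conditional model
#'
#' For each draw a component is chosen with probability
#' `(k_short, k_long)` and `ln(|N|)` is drawn from the selected Gaussian;
#' the returned values are on the seconds scale.
#'
#' @inheritParams mixture_pdf
#' @param n Number of draws (when `rem_pre` is scalar) — with a vector
#'   `rem_pre`, one draw per element is returned and `n` must be missing
#'   or equal to its length.
#' @param seed Optional integer seed for reproducibility.
#' @param component Set to `TRUE` to also return the sampled component.
#' @return A numeric vector of `|N|` draws in seconds, or a tibble with
#'   columns `n_total` and `component` when `component = TRUE`.
#' @export
sample_N <- function(m, rem_pre, n = length(rem_pre), seed = NULL, component = FALSE) {
  if (n < 1) {
    stop_remcycle("`n` must be at least 1.", "remcycle_parameter_error")
  }
  if (length(rem_pre) > 1L && n != length(rem_pre)) {
    stop_remcycle("With vector `rem_pre`, `n` must equal its length.", "remcycle_parameter_error")
  }
  check_domain(m, rem_pre)
  p <- eval_params_raw(m, rep_len(rem_pre, n))
  with_seed_maybe(seed, {
    long <- runif(n) < p$k_long
    mu <- ifelse(long, p$mu_long, p$mu_short)
    sig <- ifelse(long, p$sigma_long, p$sigma_short)
    val <- exp(rnorm(n, mu, sig))
    if (component) {
      tibble(n_total = val, component = ifelse(long, "long", "short"))
    } else {
      val
    }
  })
}

# closed-form intersection of the two weighted component densities on the
# ln(|N|) axis; returns NA when no root lies strictly in (mu_short, mu_long)
intersection_root <- function(k_long, mu_long, mu_short, sigma_long, sigma_short) {
  if (!is.finite(mu_short) || k_long >= 1 || k_long <= 0 || mu_short >= mu_long) {
    return(NA_real_)
  }
  k_short <- 1 - k_long
  A <- 1 / (2 * sigma_short^2) - 1 / (2 * sigma_long^2)
  B <- -mu_short / sigma_short^2 + mu_long / sigma_long^2
  C <- mu_short^2 / (2 * sigma_short^2) - mu_long^2 / (2 * sigma_long^2) -
    log((k_short * sigma_long) / (k_long * sigma_short))
  roots <- if (abs(A) < 1e-14) {
    if (abs(B) < 1e-14) numeric(0) else -C / B
  } else {
    disc <- B^2 - 4 * A * C
    if (disc < 0) numeric(0) else (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  }
  inside <- roots[roots > mu_short & roots < mu_long]
  if (length(inside) == 0L) {
    return(NA_real_)
  }
  # with two interior roots, the larger one is where dominance switches
  # from the short to the long component as ln(|N|) grows
  max(inside)
}

#' Domain minimum of the conditional model
#'
#' The smallest `rem_pre` on a `step` s grid for which the weighted short
#' and long component densities intersect strictly between their means
#' (`mu_short < x_intersect < mu_long`), so that the sequential/single
#' criterion is defined. The published light-phase model is defined from
#' 7.5 s on, the dark-phase model from 12.5 s.
#'
#' @param m A `remcycle_cgmm` model.
#' @param step Grid step in seconds (the hypnogram epoch length).
#' @return The domain minimum in seconds.
#' @export
compute_domain_min <- function(m, step = 2.5) {
  grid <- seq(step, m$rem_pre_max_fit - step, by = step)
  p <- eval_params_raw(m, grid)
  for (i in seq_along(grid)) {
    x <- intersection_root(
      p$k_long[i], p$mu_long[i], p$mu_short[i],
      p$sigma_long[i], p$sigma_short[i]
    )
    if (!is.na(x)) {
      return(grid[i])
    }
  }
  stop_remcycle(
    "No rem_pre in the fitted range has a valid component intersection; model invalid.",
    "remcycle_model_invalid_error"
  )
}

#' @export
print.remcycle_cgmm <- function(x, ...) {
  cat("Conditional Gaussian mixture model of ln(|N|) given rem_pre\n")
  cat(sprintf("  phase: %s   domain: [%g, %g) s\n", x$phase, x$domain_min, x$rem_pre_max_fit))
  for (p in names(x$curves)) {
    cv <- x$curves[[p]]
    eq <- if (cv$kind == "logarithmic") {
      sprintf("%.4g * ln(x + %.4g) + %.4g", cv$a, cv$b, cv$c)
    } else {
      sprintf("%.4g * x + %.4g", cv$a, cv$b)
    }
    cat(sprintf("  %-11s %-12s %s\n", p, paste0("(", cv$kind, ")"), eq))
  }
  invisible(x)
}

#' Serialize a conditional model to JSON and back
#'
#' @param m A `remcycle_cgmm` model.
#' @param path JSON file path.
#' @return `write_model()` invisibly returns `path`; `read_model()`
#'   returns the model.
#' @export
write_model <- function(m, path) {
  obj <- list(
    phase = m$phase,
    domain_min = m$domain_min,
    rem_pre_max_fit = m$rem_pre_max_fit,
    curves = m$curves,
    bin_fits = m$bin_fits
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  curves <- purrr::map(obj$curves, function(cv) {
    new_curve(cv$kind, a = cv$a, b = cv$b,
              c = cv$c %||% NA_real_, rss = cv$rss %||% NA_real_)
  })
  bf <- obj$bin_fits
  if (!is.null(bf)) {
    bf <- as_tibble(bf)
    class(bf) <- c("remcycle_bin_fits", class(bf))
  }
  new_cond_gmm(
    curves = curves, phase = obj$phase,
    rem_pre_max_fit = obj$rem_pre_max_fit,
    domain_min = obj$domain_min, bin_fits = bf
  )
}
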