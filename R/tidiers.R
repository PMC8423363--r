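# broom-style tidy()/glance() methods for the fitted objects.

#' Tidy a conditional mixture model
#'
#' @param x A `remcycle_cgmm` model.
#' @param ... Unused.
#' @return One row per parameter curve: `parameter`, `kind`, `a`, `b`,
#'   `c`, `rss`.
#' @export
tidy.remcycle_cgmm <- function(x, ...) {
  purrr::imap_dfr(x$curves, function(cv, name) {
    tibble(
      parameter = name, kind = cv$kind,
      a = cv$a, b = cv$b, c = cv$c, rss = cv$rss
    )
  })
}

#' @rdname tidy.remcycle_cgmm
#' @export
glance.remcycle_cgmm <- function(x, ...) {
  tibble(
    phase = x$phase,
    domain_min = x$domain_min,
    rem_pre_max_fit = x$rem_pre_max_fit,
    n_bins = if (is.null(x$bin_fits)) NA_integer_ else nrow(x$bin_fits),
    n_cycles = if (is.null(x$bin_fits)) NA_integer_ else sum(x$bin_fits$n),
    total_rss = sum(purrr::map_dbl(x$curves, "rss"))
  )
}

#' Augment cycles with model-derived columns
#'
#' Convenience alias for [classify_cycles()]: adds `label`,
#' `x_intersect`, `refractory_threshold` and `propensity` columns.
#'
#' @param x A `remcycle_cgmm` model.
#' @param data A cycle tibble.
#' @param ... Passed to [classify_cycles()].
#' @export
augment.remcycle_cgmm <- function(x, data, ...) {
  classify_cycles(data, x, ...)
}

#' Tidy a Lilliefors-corrected KS result
#'
#' @param x A `remcycle_gof` object.
#' @param ... Unused.
#' @export
tidy.remcycle_gof <- function(x, ...) {
  tibble(
    n = x$n, n_sim = x$n_sim, ks_obs = x$ks_obs,
    ks_sim_q95 = x$ks_sim_q95, p_value = x$p_value, reject = x$reject
  )
}

#' Tidy a bootstrap phase comparison
#'
#' @param x A `remcycle_boot` object.
#' @param ... Unused.
#' @export
tidy.remcycle_boot <- function(x, ...) {
  x$summary
}

#' @rdname tidy.remcycle_boot
#' @export
glance.remcycle_boot <- function(x, ...) {
  tibble(n_boot = x$n_boot, n_dropped = x$n_dropped,
         grid_lo = min(x$grid), grid_hi = max(x$grid))
}
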