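# ggplot2 views of the main result types.

#' Plot a hypnogram
#'
#' @param h A hypnogram.
#' @return A ggplot: state as a step function of time.
#' @export
plot_hypnogram <- function(h) {
  df <- tibble(
    time_min = h$time_s / 60,
    state = factor(h$state, levels = c("R", "W", "M", "N"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min, y = .data$state, group = 1)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Time (min)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of the conditional density of |N| given rem_pre
#'
#' @param object A `remcycle_cgmm` model.
#' @param n_max Upper |N| limit (s) of the heatmap.
#' @param ... Unused.
#' @return A ggplot of `P(ln|N| | rem_pre)` over the model domain.
#' @export
autoplot.remcycle_cgmm <- function(object, n_max = 2500, ...) {
  rp <- seq(object$domain_min, object$rem_pre_max_fit - 2.5, length.out = 80)
  ln_n <- seq(log(5), log(n_max), length.out = 200)
  grid <- tidyr::expand_grid(rem_pre = rp, ln_n = ln_n)
  grid$density <- mixture_pdf(object, grid$rem_pre, grid$ln_n)
  ggplot2::ggplot(grid, ggplot2::aes(.data$rem_pre, exp(.data$ln_n), fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = expression(REM[pre] ~ "(s)"), y = "|N| (s)",
      fill = "density", title = "Conditional mixture density of ln(|N|)"
    ) +
    ggplot2::theme_minimal()
}

#' Per-bin estimates with fitted parameter curves
#'
#' @param m A fitted `remcycle_cgmm` (with `bin_fits`).
#' @return A ggplot faceted by parameter: per-bin mixture estimates and
#'   the selected linear/logarithmic curve.
#' @export
plot_parameter_curves <- function(m) {
  if (is.null(m$bin_fits)) {
    stop_remcycle("Model carries no bin fits to plot.", "remcycle_parameter_error")
  }
  params <- names(m$curves)
  pts <- tidyr::pivot_longer(
    m$bin_fits[, c("x_mid", params)],
    dplyr::all_of(params),
    names_to = "parameter", values_to = "value"
  )
  x <- seq(max(m$domain_min, 2.5), m$rem_pre_max_fit - 2.5, by = 2.5)
  fitted <- purrr::imap_dfr(m$curves, function(cv, name) {
    tibble(x_mid = x, parameter = name, value = eval_curve(cv, x))
  })
  fitted$value[fitted$parameter == "k_long"] <-
    pmin(pmax(fitted$value[fitted$parameter == "k_long"], 0), 1)
  ggplot2::ggplot(pts, ggplot2::aes(.data$x_mid, .data$value)) +
    ggplot2::geom_line(data = fitted, colour = "firebrick") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = expression(REM[pre] ~ "(s)"), y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a spectral density
#'
#' @param object A [welch_psd()] tibble.
#' @param fmax Upper frequency limit (Hz) for display.
#' @param ... Unused.
#' @export
autoplot.remcycle_psd <- function(object, fmax = 25, ...) {
  df <- object[object$frequency <= fmax, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$frequency, .data$power)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)", y = expression("Power (" * unit^2 / Hz * ")")) +
    ggplot2::theme_minimal()
}

#' Plot the conditional CDF for selected rem_pre values
#'
#' @param m A `remcycle_cgmm` model.
#' @param rem_pre REM durations (s) to draw one CDF curve each.
#' @param n_max Upper |N| (s).
#' @return A ggplot of the probability of having entered REM within |N|
#'   seconds of NREM sleep.
#' @export
plot_propensity_cdf <- function(m, rem_pre = c(15, 60, 120, 180), n_max = 2000) {
  rem_pre <- rem_pre[rem_pre >= m$domain_min]
  n <- seq(0, n_max, length.out = 400)
  df <- purrr::map_dfr(rem_pre, function(r) {
    tibble(rem_pre = r, n = n, cdf = mixture_cdf(m, r, n))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$n, .data$cdf,
    colour = factor(.data$rem_pre)
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "|N| (s)", y = "P(next REM within |N|)",
      colour = expression(REM[pre] ~ "(s)")
    ) +
    ggplot2::theme_minimal()
}
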