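# Welch spectral densities, band powers and time-course utilities.

#' Frequency band definitions
#'
#' Two distinct band sets are used on purpose: the *analysis* bands for
#' spectral densities and band powers (delta 0.5-4.5, theta 5-9.5,
#' sigma 10-15 Hz), and the *scoring* bands used by the automatic sleep
#' staging (delta 0.5-4, theta 5-12, sigma 12-20, high gamma 100-150,
#' EMG 50-500 Hz). The spindle detection band is 10-16.67 Hz.
#'
#' @format Named lists of `c(lo, hi)` pairs in Hz.
#' @export
analysis_bands <- list(
  delta = c(0.5, 4.5),
  theta = c(5, 9.5),
  sigma = c(10, 15)
)

#' @rdname analysis_bands
#' @export
scoring_bands <- list(
  delta = c(0.5, 4),
  theta = c(5, 12),
  sigma = c(12, 20),
  gamma = c(100, 150),
  emg = c(50, 500)
)

#' @rdname analysis_bands
#' @export
spindle_band <- c(10, 50 / 3)

# one-sided power spectral density of a set of equal-length windows
# (rows = samples); Hann-tapered, density-normalised so that
# sum(psd) * df ~ signal variance
windowed_psd <- function(mat, fs) {
  n_win <- nrow(mat)
  w <- hann_window(n_win)
  scale <- fs * sum(w^2)
  ft <- stats::mvfft(mat * w)
  n_keep <- floor(n_win / 2) + 1L
  p <- (Mod(ft[seq_len(n_keep), , drop = FALSE])^2) / scale
  # one-sided: double everything except DC (and Nyquist for even n)
  dbl <- rep(2, n_keep)
  dbl[1] <- 1
  if (n_win %% 2 == 0) dbl[n_keep] <- 1
  p * dbl
}

# cut a signal into half-overlapping windows; returns a matrix or NULL
# when the signal is shorter than one window
window_matrix <- function(x, n_win, step) {
  n <- length(x)
  if (n < n_win) {
    return(NULL)
  }
  starts <- seq(1L, n - n_win + 1L, by = step)
  matrix(x[outer(seq_len(n_win) - 1L, starts, `+`)], nrow = n_win)
}

#' Welch power spectral density
#'
#' Averaged periodogram over 3 s, half-overlapping, Hann-windowed
#' intervals pooled across all supplied segments, yielding a 1/3 Hz
#' frequency resolution. The density is one-sided and normalised so that
#' its integral approximates the signal variance.
#'
#' @param segments A numeric vector or a list of numeric vectors (e.g.
#'   the samples of all NREM episodes); each segment must span at least
#'   one window.
#' @param fs Sampling rate in Hz.
#' @param window_sec Window length in seconds (3 s gives the 1/3 Hz grid).
#' @return A tibble of class `remcycle_psd` with columns `frequency` (Hz)
#'   and `power`, and attributes `df`, `n_segments`, `n_windows`.
#' @export
welch_psd <- function(segments, fs, window_sec = 3) {
  if (!is.list(segments)) segments <- list(segments)
  n_win <- round(window_sec * fs)
  step <- floor(n_win / 2)
  mats <- purrr::compact(purrr::map(segments, window_matrix, n_win = n_win, step = step))
  if (length(mats) == 0L) {
    stop_remcycle(sprintf("All segments are shorter than one %g s window.", window_sec),
                  "remcycle_parameter_error")
  }
  psd_cols <- purrr::map(mats, windowed_psd, fs = fs)
  n_windows <- sum(purrr::map_int(psd_cols, ncol))
  avg <- Reduce(`+`, purrr::map(psd_cols, rowSums)) / n_windows
  out <- tibble(
    frequency = seq(0, floor(n_win / 2)) * fs / n_win,
    power = avg
  )
  attr(out, "df") <- fs / n_win
  attr(out, "n_segments") <- length(mats)
  attr(out, "n_windows") <- n_windows
  class(out) <- c("remcycle_psd", class(out))
  out
}

#' Band power by midpoint Riemann sum
#'
#' Approximates the area under the spectral density over `[lo, hi)` by a
#' midpoint Riemann sum: each grid frequency is the midpoint of a cell of
#' width `df`, and cells whose midpoints fall in the half-open band are
#' summed. Half-open membership avoids double counting between adjacent
#' bands.
#'
#' @param psd A [welch_psd()] result (or any tibble with `frequency` and
#'   `power` on a uniform grid).
#' @param band `c(lo, hi)` in Hz with `lo < hi`, inside the grid range.
#' @return The band power (power units).
#' @export
band_power <- function(psd, band) {
  if (length(band) != 2L || band[1] >= band[2]) {
    stop_remcycle("`band` must be c(lo, hi) with lo < hi.", "remcycle_parameter_error")
  }
  df <- attr(psd, "df") %||% (psd$frequency[2] - psd$frequency[1])
  if (band[2] > max(psd$frequency) + df / 2) {
    stop_remcycle("Band extends beyond the frequency grid.", "remcycle_parameter_error")
  }
  sel <- psd$frequency >= band[1] & psd$frequency < band[2]
  sum(psd$power[sel]) * df
}

#' Duration-weighted average of spectral densities
#'
#' Pointwise weighted average `P_hat = sum_i w_i * P_i` of per-REM-duration-bin
#' spectral densities, used to test whether spectral differences between
#' cycle types are explained by their REM-duration composition.
#'
#' @param densities List of [welch_psd()] tibbles on a common grid.
#' @param weights Proportions summing to 1 (within 1e-9).
#' @return A tibble like the inputs with the averaged `power`.
#' @export
weighted_density_average <- function(densities, weights) {
  if (length(densities) != length(weights)) {
    stop_remcycle("Need one weight per density.", "remcycle_parameter_error")
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop_remcycle("Weights must sum to 1 (within 1e-9).", "remcycle_parameter_error")
  }
  f0 <- densities[[1]]$frequency
  for (d in densities[-1]) {
    if (length(d$frequency) != length(f0) || any(abs(d$frequency - f0) > 1e-9)) {
      stop_remcycle("Frequency grids do not match.", "remcycle_parameter_error")
    }
  }
  out <- densities[[1]]
  out$power <- Reduce(`+`, purrr::map2(densities, weights, ~ .x$power * .y))
  out
}

#' Normalized two-period time course
#'
#' Maps the refractory and permissive periods of a cycle onto unit length
#' and averages a per-epoch quantity within `n_bins` equal-duration bins
#' (quartiles by default) of each period, as used for EEG-power and event
#' rate time courses across single cycles.
#'
#' @param values Per-epoch values covering the interval (refractory
#'   epochs first, then permissive).
#' @param boundaries `c(refractory_end, period_end)`: index (into
#'   `values`) of the last refractory epoch and of the last epoch.
#' @param n_bins Bins per period.
#' @return A tibble with `period` (`"refractory"`/`"permissive"`), `bin`
#'   and `mean`; periods with fewer than `n_bins` epochs are dropped with
#'   a warning.
#' @export
normalized_timecourse <- function(values, boundaries, n_bins = 4L) {
  stopifnot(length(boundaries) == 2L, boundaries[2] <= length(values))
  periods <- list(
    refractory = seq_len(boundaries[1]),
    permissive = if (boundaries[2] > boundaries[1]) seq(boundaries[1] + 1L, boundaries[2]) else integer(0)
  )
  purrr::imap_dfr(periods, function(idx, name) {
    m <- length(idx)
    if (m < n_bins) {
      warn(sprintf("%s period has %d < %d epochs; excluded.", name, m, n_bins))
      return(NULL)
    }
    bin_of <- pmin(ceiling(seq_len(m) / m * n_bins), n_bins)
    means <- as.numeric(tapply(values[idx], bin_of, mean))
    tibble(period = name, bin = seq_len(n_bins), mean = means)
  })
}

#' Per-minute event rate within a brain state
#'
#' Number of events whose onset falls in epochs of the given state,
#' divided by the total time spent in that state in minutes. State `"N"`
#' includes microarousal (`"M"`) epochs, matching the `|N|` convention.
#'
#' @param onsets Event onset times in seconds.
#' @param h A hypnogram.
#' @param state Target state label.
#' @return Events per minute of `state`.
#' @export
event_rate <- function(onsets, h, state = "N") {
  el <- epoch_len(h)
  labels <- if (state == "N") c("N", "M") else state
  in_state <- h$state %in% labels
  minutes <- sum(in_state) * el / 60
  if (minutes == 0) {
    stop_remcycle(sprintf("Hypnogram contains no time in state %s.", dQuote(state)),
                  "remcycle_undefined_rate_error")
  }
  if (length(onsets) == 0L) {
    return(0)
  }
  epoch_idx <- pmin(floor(onsets / el) + 1L, nrow(h))
  sum(in_state[epoch_idx]) / minutes
}
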