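# Automatic brain-state classification from EEG/EMG.

#' Construct a signal recording
#'
#' Container for the raw electrophysiology: parietal and prefrontal EEG
#' plus EMG, sampled at a common rate (1000 Hz in the modelled
#' recordings).
#'
#' @param eeg_parietal,eeg_prefrontal,emg Numeric sample vectors of equal
#'   length.
#' @param fs Sampling rate in Hz.
#' @return A list of class `remcycle_recording`.
#' @export
signal_recording <- function(eeg_parietal, eeg_prefrontal, emg, fs) {
  if (length(eeg_parietal) != length(eeg_prefrontal) ||
      length(eeg_parietal) != length(emg)) {
    stop_remcycle("All channels must have the same length.", "remcycle_parameter_error")
  }
  if (!.is_scalar_num(fs) || fs <= 0) {
    stop_remcycle("`fs` must be a single positive number.", "remcycle_parameter_error")
  }
  structure(
    list(
      eeg_parietal = as.numeric(eeg_parietal),
      eeg_prefrontal = as.numeric(eeg_prefrontal),
      emg = as.numeric(emg), fs = fs
    ),
    class = "remcycle_recording"
  )
}

#' @export
print.remcycle_recording <- function(x, ...) {
  cat(sprintf(
    "Signal recording: %d samples/channel at %g Hz (%.1f min)\n",
    length(x$eeg_parietal), x$fs, length(x$eeg_parietal) / x$fs / 60
  ))
  invisible(x)
}

#' Read and write signal recordings as CSV with a JSON sidecar
#'
#' Columns `EEG1` (parietal), `EEG2` (prefrontal) and `EMG`; the sampling
#' rate lives in a JSON sidecar (`<path>.json` by default) with field
#' `sampling_rate`.
#'
#' @param path CSV file path.
#' @param sidecar JSON sidecar path.
#' @return `read_signals()` returns a [signal_recording()];
#'   `write_signals()` invisibly returns `path`.
#' @export
read_signals <- function(path, sidecar = paste0(path, ".json")) {
  meta <- jsonlite::read_json(sidecar)
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                        progress = FALSE)
  signal_recording(df$EEG1, df$EEG2, df$EMG, fs = meta$sampling_rate)
}

#' @rdname read_signals
#' @param rec A [signal_recording()].
#' @export
write_signals <- function(rec, path, sidecar = paste0(path, ".json")) {
  readr::write_csv(
    tibble(EEG1 = rec$eeg_parietal, EEG2 = rec$eeg_prefrontal, EMG = rec$emg),
    path, progress = FALSE
  )
  jsonlite::write_json(list(sampling_rate = rec$fs), sidecar, auto_unbox = TRUE)
  invisible(path)
}

#' Compute per-epoch scoring features
#'
#' EEG and EMG spectrograms from consecutive FFTs over sliding,
#' half-overlapping 5 s windows give one feature row per 2.5 s hypnogram
#' epoch: delta (0.5-4 Hz), theta (5-12 Hz), sigma (12-20 Hz) and high
#' gamma (100-150 Hz) power of the parietal EEG, the theta/delta ratio,
#' and EMG power (50-500 Hz, capped at Nyquist). The trailing epoch,
#' which has no complete window of its own, repeats the last computed
#' row so that feature rows align one-to-one with hypnogram epochs.
#'
#' @param rec A [signal_recording()].
#' @param epoch_sec Epoch length in seconds (windows span two epochs).
#' @return A tibble with one row per epoch: `delta`, `theta`, `sigma`,
#'   `gamma`, `theta_delta`, `emg`.
#' @export
compute_scoring_features <- function(rec, epoch_sec = 2.5) {
  fs <- rec$fs
  if (fs < 2 * scoring_bands$gamma[2]) {
    stop_remcycle("Sampling rate too low to resolve the 100-150 Hz gamma band.",
                  "remcycle_parameter_error")
  }
  n_win <- round(2 * epoch_sec * fs)
  step <- round(epoch_sec * fs)
  n_epochs <- floor(length(rec$eeg_parietal) / step)
  if (length(rec$eeg_parietal) < n_win) {
    stop_remcycle("Recording shorter than one 5 s scoring window.", "remcycle_parameter_error")
  }
  df <- fs / n_win
  freqs <- seq(0, floor(n_win / 2)) * df
  band_sum <- function(p, band) {
    hi <- min(band[2], fs / 2)
    colSums(p[freqs >= band[1] & freqs < hi, , drop = FALSE]) * df
  }
  eeg_mat <- window_matrix(rec$eeg_parietal, n_win, step)
  emg_mat <- window_matrix(rec$emg, n_win, step)
  p_eeg <- windowed_psd(eeg_mat, fs)
  p_emg <- windowed_psd(emg_mat, fs)
  delta <- band_sum(p_eeg, scoring_bands$delta)
  theta <- band_sum(p_eeg, scoring_bands$theta)
  sigma <- band_sum(p_eeg, scoring_bands$sigma)
  gamma <- band_sum(p_eeg, scoring_bands$gamma)
  emg <- band_sum(p_emg, scoring_bands$emg)
  out <- tibble(
    delta = delta, theta = theta, sigma = sigma, gamma = gamma,
    theta_delta = theta / delta, emg = emg
  )
  # repeat the final row so features align with the epoch grid
  if (nrow(out) < n_epochs) {
    out <- dplyr::bind_rows(out, out[rep(nrow(out), n_epochs - nrow(out)), ])
  }
  out[seq_len(n_epochs), ]
}

#' Classify brain states from scoring features
#'
#' Threshold-based staging: each feature is split at its temporal mean
#' (mean plus one standard deviation for EMG and the theta/delta ratio).
#' REM requires a high theta/delta ratio, low EMG and low delta power;
#' NREM requires high delta, a low theta/delta ratio and low EMG, or
#' alternatively low EMG, low delta and high sigma; wake covers low delta
#' with high EMG, and any high-gamma bin not already REM. When several
#' rules fire, REM takes precedence over NREM over wake; bins matching no
#' rule inherit the previous bin's label (the first such bin defaults to
#' wake). Thresholds are data-relative, so classification is invariant to
#' rescaling all channels by a positive constant.
#'
#' @param features A [compute_scoring_features()] tibble.
#' @param epoch_len Epoch length in seconds.
#' @param phase Circadian phase label for the resulting hypnogram.
#' @return A hypnogram with states `W`/`N`/`R` (no microarousal scoring).
#' @export
classify_states <- function(features, epoch_len = 2.5,
                            phase = c("unknown", "light", "dark")) {
  phase <- match.arg(phase)
  if (!all(purrr::map_lgl(features, ~ all(is.finite(.x))))) {
    stop_remcycle("Features must be finite.", "remcycle_parameter_error")
  }
  if (any(purrr::map_dbl(features, sd) == 0)) {
    warn("Zero-variance feature: thresholds degenerate to plain means.")
  }
  thr_mean <- function(x) x > mean(x)
  thr_mean_sd <- function(x) x > mean(x) + sd(x)
  delta_hi <- thr_mean(features$delta)
  sigma_hi <- thr_mean(features$sigma)
  gamma_hi <- thr_mean(features$gamma)
  emg_hi <- thr_mean_sd(features$emg)
  td_hi <- thr_mean_sd(features$theta_delta)
  is_rem <- td_hi & !emg_hi & !delta_hi
  is_nrem <- (delta_hi & !td_hi & !emg_hi) | (!emg_hi & !delta_hi & sigma_hi)
  is_wake <- (!delta_hi & emg_hi) | (gamma_hi & !is_rem)
  state <- rep(NA_character_, nrow(features))
  state[is_wake] <- "W"
  state[is_nrem] <- "N"
  state[is_rem] <- "R"
  # carry the previous label through unmatched bins
  for (i in seq_along(state)) {
    if (is.na(state[i])) state[i] <- if (i == 1L) "W" else state[i - 1L]
  }
  hypnogram(state, epoch_len = epoch_len, phase = phase)
}

#' Stage a recording end to end
#'
#' Convenience wrapper: [compute_scoring_features()] then
#' [classify_states()], optionally followed by [score_microarousals()].
#'
#' @param rec A [signal_recording()].
#' @param ma_threshold Microarousal threshold in seconds; `NULL` skips
#'   MA scoring.
#' @inheritParams classify_states
#' @return A hypnogram.
#' @export
stage_recording <- function(rec, ma_threshold = 20, epoch_len = 2.5,
                            phase = c("unknown", "light", "dark")) {
  h <- classify_states(compute_scoring_features(rec, epoch_sec = epoch_len),
                       epoch_len = epoch_len, phase = match.arg(phase))
  if (!is.null(ma_threshold)) h <- score_microarousals(h, ma_threshold)
  h
}
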