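# Sleep spindle detection on the prefrontal EEG.

# spectrogram statistics needed by the detector, computed in chunks:
# for each 600 ms window (100 ms step) the height and frequency of the
# largest local spectral maximum in the sigma band, the maximal power
# below 10 Hz, and the frequency of the global spectral peak
spindle_window_stats <- function(eeg, fs, win_sec = 0.6, step_sec = 0.1,
                                 band = spindle_band, chunk = 4096L) {
  n_win <- round(win_sec * fs)
  step <- round(step_sec * fs)
  n <- length(eeg)
  if (n < n_win) {
    stop_remcycle("Recording shorter than one 600 ms window.", "remcycle_parameter_error")
  }
  starts <- seq(1L, n - n_win + 1L, by = step)
  freqs <- seq(0, floor(n_win / 2)) * fs / n_win
  w <- hann_window(n_win)
  in_band <- freqs >= band[1] & freqs <= band[2]
  low <- freqs < 10 & freqs > 0
  sigma_peak <- sigma_freq <- low_max <- peak_freq <- numeric(length(starts))
  for (off in seq(1L, length(starts), by = chunk)) {
    idx <- off:min(off + chunk - 1L, length(starts))
    mat <- matrix(eeg[outer(seq_len(n_win) - 1L, starts[idx], `+`)], nrow = n_win)
    p <- Mod(stats::mvfft(mat * w)[seq_along(freqs), , drop = FALSE])^2
    # local maxima: strictly above the left neighbour, at least the right
    nr <- nrow(p)
    is_max <- rbind(FALSE, p[2:(nr - 1), , drop = FALSE] > p[1:(nr - 2), , drop = FALSE] &
      p[2:(nr - 1), , drop = FALSE] >= p[3:nr, , drop = FALSE], FALSE)
    p_sigma <- p
    p_sigma[!(is_max & in_band)] <- -Inf
    sigma_peak[idx] <- apply(p_sigma, 2, max)
    sigma_freq[idx] <- freqs[apply(p_sigma, 2, which.max)]
    low_max[idx] <- apply(p[low, , drop = FALSE], 2, max)
    peak_freq[idx] <- freqs[-1][apply(p[-1, , drop = FALSE], 2, which.max)]
  }
  sigma_freq[!is.finite(sigma_peak)] <- NA_real_
  tibble(
    start = (starts - 1) / fs,
    sigma_peak = sigma_peak, sigma_freq = sigma_freq,
    low_max = low_max, peak_freq = peak_freq
  )
}

#' Detect sleep spindles
#'
#' Spindles are transient sigma-band (10-16.67 Hz) oscillatory bursts in
#' the prefrontal EEG. The detector computes a spectrogram over 600 ms
#' windows with 500 ms overlap (100 ms resolution) and flags a bin as
#' spindle material when (1) the largest local spectral maximum in the
#' sigma band exceeds the 96th percentile of all such maxima over the
#' recording, and (2) that sigma peak exceeds half the peak power below
#' 10 Hz. Adjacent flagged bins form candidate events; candidates
#' separated by gaps shorter than 300 ms are fused; events lasting at
#' most 200 ms are discarded; and an event is kept only when the spectral
#' peak frequency lies in the sigma band for at least half of its bins.
#' By default, detection is restricted to NREM (incl. microarousal)
#' epochs, since spindle rates are reported per minute of NREM sleep.
#'
#' @param eeg Prefrontal EEG samples.
#' @param fs Sampling rate in Hz (>= 2 * 16.67).
#' @param h Hypnogram aligned with the signal (needed unless
#'   `restrict_nrem = FALSE`).
#' @param percentile Detection threshold percentile for the sigma peak.
#' @param sigma_ratio Required ratio of sigma peak to sub-10 Hz peak.
#' @param min_gap Gaps shorter than this (s) are fused.
#' @param min_duration Events of at most this duration (s) are discarded.
#' @param restrict_nrem Keep only events starting in `N`/`M` epochs.
#' @return A tibble with one row per spindle: `onset` (s), `duration`
#'   (s), `peak_frequency` (Hz).
#' @export
detect_spindles <- function(eeg, fs, h = NULL, percentile = 0.96,
                            sigma_ratio = 0.5, min_gap = 0.3,
                            min_duration = 0.2, restrict_nrem = TRUE) {
  if (fs < 2 * spindle_band[2]) {
    stop_remcycle("Sampling rate too low to resolve the sigma band.", "remcycle_parameter_error")
  }
  if (restrict_nrem && is.null(h)) {
    stop_remcycle("A hypnogram is required when restricting to NREM.", "remcycle_parameter_error")
  }
  st <- spindle_window_stats(eeg, fs)
  step_sec <- 0.1
  finite <- is.finite(st$sigma_peak)
  thr <- quantile(st$sigma_peak[finite], percentile, names = FALSE)
  flag <- finite & st$sigma_peak > thr & st$sigma_peak > sigma_ratio * st$low_max
  runs <- state_runs(ifelse(flag, "S", "-"))
  ev <- runs[runs$state == "S", , drop = FALSE]
  if (nrow(ev) == 0L) {
    return(tibble(onset = double(), duration = double(), peak_frequency = double()))
  }
  events <- tibble(
    start_bin = ev$start, end_bin = ev$end,
    onset = st$start[ev$start],
    end = st$start[ev$end] + step_sec
  )
  # fuse events separated by gaps shorter than min_gap
  fused <- events[1, ]
  for (i in seq_len(nrow(events))[-1]) {
    if (events$onset[i] - fused$end[nrow(fused)] < min_gap) {
      fused$end[nrow(fused)] <- events$end[i]
      fused$end_bin[nrow(fused)] <- events$end_bin[i]
    } else {
      fused <- dplyr::bind_rows(fused, events[i, ])
    }
  }
  fused$duration <- fused$end - fused$onset
  fused <- fused[fused$duration > min_duration, , drop = FALSE]
  if (nrow(fused) == 0L) {
    return(tibble(onset = double(), duration = double(), peak_frequency = double()))
  }
  # majority of bins must have their global spectral peak in the band
  keep <- logical(nrow(fused))
  peak_frequency <- numeric(nrow(fused))
  for (i in seq_len(nrow(fused))) {
    bins <- fused$start_bin[i]:fused$end_bin[i]
    pf <- st$peak_freq[bins]
    keep[i] <- mean(pf >= spindle_band[1] & pf <= spindle_band[2]) >= 0.5
    sf <- st$sigma_freq[bins]
    peak_frequency[i] <- median(sf[is.finite(sf)])
  }
  fused <- fused[keep, , drop = FALSE]
  peak_frequency <- peak_frequency[keep]
  out <- tibble(
    onset = fused$onset, duration = fused$duration,
    peak_frequency = peak_frequency
  )
  if (restrict_nrem && nrow(out) > 0L) {
    el <- epoch_len(h)
    epoch_idx <- pmin(floor(out$onset / el) + 1L, nrow(h))
    out <- out[h$state[epoch_idx] %in% c("N", "M"), , drop = FALSE]
  }
  out
}
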