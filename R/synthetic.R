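# Ground-truth generators: cycles, hypnograms and EEG/EMG signals with
# the statistical structure the analysis pipeline assumes.

#' Default ground-truth configuration for simulation
#'
#' Bundles everything the generators need: a ground-truth conditional
#' mixture model (curves shaped like the published light-phase trends:
#' `k_long` increases logarithmically and saturates at 1 at 150 s,
#' `mu_long` increases, `sigma_long` decreases logarithmically and
#' `sigma_short` decreases linearly; the resulting domain minimum is
#' 15 s on the 2.5 s grid), a REM-duration law (gamma, shape 1, scale
#' 70 s, truncated to `[7.5, 240]` s — episodes under three epochs are
#' not scored), a wake-episode law (43% of
#' inter-REM intervals uninterrupted; otherwise a geometric episode count
#' with lognormal durations above the 20 s microarousal threshold), a
#' microarousal rate, and per-state EEG/EMG band-power templates with a
#' spindle burst law. The coefficients are fixture constants chosen to
#' reproduce the qualitative published trends; they are not the (unprinted)
#' fitted mouse values.
#'
#' @param phase `"light"` (default) or `"dark"`; the dark variant has a
#'   larger long-component weight and mean and a wider long component.
#' @return A list of class `remcycle_ground_truth`.
#' @export
default_ground_truth <- function(phase = c("light", "dark")) {
  phase <- match.arg(phase)
  # k_long rises logarithmically from 0 (reached at 13 s) to 1 at 150 s,
  # placing the model domain minimum at 15 s on the 2.5 s grid;
  # mu_long/sigma_long keep the refractory threshold between one and
  # three times rem_pre through the mid-range while the mixture CDF at
  # 2000 s stays above 0.99 everywhere in the domain
  a_k <- 1 / log(150 / 13)
  model <- if (phase == "light") {
    cond_gmm(
      k_long = new_curve("logarithmic", a = a_k, b = 0, c = -a_k * log(13)),
      mu_long = new_curve("linear", a = 0.0052, b = 5.32),
      mu_short = new_curve("logarithmic", a = 0.30, b = 50, c = 2.70),
      sigma_long = new_curve("logarithmic", a = -0.10, b = 50, c = 0.868),
      sigma_short = new_curve("linear", a = -4e-4, b = 0.40),
      phase = "light"
    )
  } else {
    # dark phase: larger long-component weight and mean, wider long
    # component (k_long saturates already at 120 s)
    a_kd <- 1 / log(120 / 13)
    cond_gmm(
      k_long = new_curve("logarithmic", a = a_kd, b = 0, c = -a_kd * log(13)),
      mu_long = new_curve("linear", a = 0.0052, b = 5.57),
      mu_short = new_curve("logarithmic", a = 0.30, b = 50, c = 2.70),
      sigma_long = new_curve("logarithmic", a = -0.10, b = 50, c = 0.968),
      sigma_short = new_curve("linear", a = -4e-4, b = 0.40),
      phase = "dark"
    )
  }
  structure(
    list(
      model = model,
      # REM episodes shorter than 3 epochs (7.5 s) are not scored in
      # practice, so the duration law starts there
      rem_law = list(shape = 1, scale = 70, min = 7.5, max = 240),
      wake_law = list(p_zero = 0.43, geom_prob = 0.5,
                      dur_meanlog = 3.2, dur_sdlog = 0.7, min_dur = 22.5),
      ma_per_min = 0.6, # microarousal bouts per minute of NREM
      signal_law = list(
        fs = 1000,
        bands = list(delta = c(0.5, 4), theta = c(6, 9),
                     sigma = c(10, 15), gamma = c(100, 150)),
        # per-state amplitude gains (standard-deviation units) per band
        gains = list(
          N = c(delta = 2.0, theta = 0.7, sigma = 0.4, gamma = 0.2),
          R = c(delta = 0.5, theta = 2.2, sigma = 0.3, gamma = 0.3),
          W = c(delta = 0.8, theta = 1.0, sigma = 0.3, gamma = 1.5)
        ),
        emg_gain = c(N = 0.4, R = 0.2, W = 3.0),
        pink_gain = 0.3,
        spindle = list(rate = 3, amp = 5, freq = c(11, 15.5), dur = c(0.5, 1.5))
      )
    ),
    class = "remcycle_ground_truth"
  )
}

# truncated gamma draw for REM episode durations
draw_rem_pre <- function(law, n) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rgamma(2 * n, shape = law$shape, scale = law$scale)
    out <- c(out, x[x >= law$min & x <= law$max])
  }
  out[seq_len(n)]
}

draw_wake_episodes <- function(law) {
  if (runif(1) < law$p_zero) {
    return(numeric(0))
  }
  k <- 1L + rgeom(1, law$geom_prob)
  law$min_dur + rlnorm(k, law$dur_meanlog, law$dur_sdlog)
}

#' Generate ground-truth sleep cycles
#'
#' Draws `rem_pre` from the REM-duration law, picks the mixture component
#' with probability `(k_short(rem_pre), k_long(rem_pre))`, draws
#' `ln(n_total)` from that component and a wake-episode structure from
#' the wake law. The true component label is retained for accuracy tests.
#'
#' @param gt A [default_ground_truth()] configuration.
#' @param n Number of cycles.
#' @param seed Optional integer seed.
#' @return A tibble with `rem_pre`, `component`, `n_total`, `w_total`,
#'   `inter_rem`, `wake_episode_count`, `wake_episode_durations`.
#' @export
generate_cycles <- function(gt, n, seed = NULL) {
  if (!inherits(gt, "remcycle_ground_truth")) {
    stop_remcycle("`gt` must be a ground-truth configuration.", "remcycle_configuration_error")
  }
  if (n < 1) {
    stop_remcycle("`n` must be at least 1.", "remcycle_parameter_error")
  }
  with_seed_maybe(seed, {
    rem_pre <- draw_rem_pre(gt$rem_law, n)
    draw <- sample_N(gt$model |> strip_domain(), rem_pre, component = TRUE)
    wake <- purrr::map(seq_len(n), ~ draw_wake_episodes(gt$wake_law))
    tibble(
      rem_pre = rem_pre,
      component = draw$component,
      n_total = draw$n_total,
      w_total = purrr::map_dbl(wake, sum),
      wake_episode_count = purrr::map_int(wake, length),
      wake_episode_durations = wake
    ) |>
      dplyr::mutate(inter_rem = .data$n_total + .data$w_total, .after = "n_total")
  })
}

# the generators are defined by the raw coefficient curves over the full
# REM-duration range, so domain checks are lifted
strip_domain <- function(m) {
  m$domain_min <- 0
  m$rem_pre_max_fit <- Inf
  m
}

# one inter-REM interval as an epoch label vector: n_epochs of NREM with
# wake episodes (> MA threshold, given in epochs) and microarousal bouts
# (<= 20 s, emitted as W and relabelled M by scoring) inserted at
# distinct positions
build_interval <- function(n_epochs, w_epochs, gt, el) {
  ma_n <- rpois(1, gt$ma_per_min * n_epochs * el / 60)
  ma_epochs <- if (ma_n > 0) sample(1:8, ma_n, replace = TRUE) else integer(0)
  # the MA epochs come out of the |N| budget (they count into |N|)
  while (sum(ma_epochs) > n_epochs / 2 && length(ma_epochs) > 0) {
    ma_epochs <- ma_epochs[-length(ma_epochs)]
  }
  pure_n <- n_epochs - sum(ma_epochs)
  blocks <- c(
    purrr::map(w_epochs, ~ rep("W", .x)),
    purrr::map(ma_epochs, ~ rep("W", .x))
  )
  # each block occupies its own slot between N epochs (slot j sits before
  # the j-th N epoch, slot pure_n + 1 after the last), so distinct wake
  # runs never merge and MA bouts stay below the scoring threshold
  n_slots <- pure_n + 1L
  if (length(blocks) > n_slots) blocks <- blocks[seq_len(n_slots)]
  slots <- if (length(blocks) > 0) sample(seq_len(n_slots), length(blocks)) else integer(0)
  seq_labels <- character(0)
  for (j in seq_len(n_slots)) {
    hit <- which(slots == j)
    if (length(hit) == 1L) seq_labels <- c(seq_labels, blocks[[hit]])
    if (j <= pure_n) seq_labels <- c(seq_labels, "N")
  }
  seq_labels
}

#' Generate a hypnogram (with ground truth) from a configuration
#'
#' Concatenates generated sleep cycles into a 2.5 s epoch sequence:
#' each cycle contributes its REM episode followed by its inter-REM
#' interval (NREM with wake episodes at uniformly random positions and
#' short microarousal bouts carved out of the NREM budget), and a closing
#' REM episode terminates the final cycle. All durations are quantized to
#' the epoch grid.
#'
#' @param gt A [default_ground_truth()] configuration.
#' @param total_duration Target duration in seconds.
#' @param epoch_len Epoch length in seconds.
#' @param seed Optional integer seed.
#' @return A list with `hypnogram` (states `W`/`N`/`R`; microarousals are
#'   unlabelled wake until [score_microarousals()]) and `cycles`, the
#'   generating values (continuous, pre-quantization) of every complete
#'   cycle.
#' @export
generate_hypnogram <- function(gt, total_duration, epoch_len = 2.5, seed = NULL) {
  with_seed_maybe(seed, {
    total_epochs <- floor(total_duration / epoch_len)
    labels <- character(0)
    truth <- list()
    while (length(labels) < total_epochs) {
      cyc <- generate_cycles(gt, 1L)
      rem_epochs <- max(1L, round(cyc$rem_pre / epoch_len))
      # quantize the interval as a whole so that the recovered inter-REM
      # duration differs from the drawn one by at most half an epoch,
      # independent of the number of wake episodes
      wake_durs <- cyc$wake_episode_durations[[1]]
      w_epochs <- if (length(wake_durs) > 0) pmax(round(wake_durs / epoch_len), 9L) else integer(0)
      inter_epochs <- max(round(cyc$inter_rem / epoch_len), sum(w_epochs) + 1L)
      n_epochs <- inter_epochs - sum(w_epochs)
      interval <- build_interval(n_epochs, w_epochs, gt, epoch_len)
      start_index <- length(labels) + 1L
      labels <- c(labels, rep("R", rem_epochs), interval)
      truth[[length(truth) + 1L]] <- dplyr::mutate(
        cyc,
        start_index = start_index,
        end_epoch = length(labels) # interval end; next REM must follow
      )
    }
    labels <- labels[seq_len(total_epochs)]
    # a cycle is complete when its interval survived truncation and at
    # least one epoch of the closing REM episode fits
    cycles <- dplyr::bind_rows(truth)
    cycles <- cycles[cycles$end_epoch + 1L <= total_epochs, , drop = FALSE]
    # close the final surviving cycle if truncation removed its closing REM
    if (nrow(cycles) > 0 && labels[min(cycles$end_epoch[nrow(cycles)] + 1L, total_epochs)] != "R") {
      labels[min(cycles$end_epoch[nrow(cycles)] + 1L, total_epochs)] <- "R"
    }
    h <- hypnogram(labels, epoch_len = epoch_len, phase = gt$model$phase)
    list(hypnogram = h, cycles = dplyr::select(cycles, -"end_epoch"))
  })
}

# zero-phase band-limited unit-variance noise via FFT masking
bandlimited_noise <- function(n, fs, band) {
  x <- rnorm(n)
  ft <- fft(x)
  freq <- (seq_len(n) - 1) * fs / n
  freq <- pmin(freq, fs - freq) # fold to [0, fs/2]
  ft[freq < band[1] | freq > band[2]] <- 0
  y <- Re(fft(ft, inverse = TRUE)) / n
  y / sd(y)
}

pink_noise <- function(n, fs) {
  x <- rnorm(n)
  ft <- fft(x)
  freq <- (seq_len(n) - 1) * fs / n
  freq <- pmin(freq, fs - freq)
  scale <- ifelse(freq < 0.5, 0, 1 / sqrt(freq))
  y <- Re(fft(ft * scale, inverse = TRUE)) / n
  y / sd(y)
}

#' Generate EEG/EMG signals for a hypnogram
#'
#' Each epoch's EEG is a sum of band-limited noise components scaled by
#' the state's band-power template (NREM: high delta; REM: high theta,
#' low delta, low EMG; wake: high EMG and high gamma) over a pink-noise
#' floor; the EMG is broadband noise with state-dependent amplitude.
#' Sleep spindle bursts — Hann-enveloped sigma-band (11-15.5 Hz) wave
#' packets of 0.5-1.5 s — are injected into NREM epochs of the prefrontal
#' EEG at the configured rate, and their annotations returned.
#'
#' @param h A hypnogram (`M` epochs use the wake template).
#' @param gt A [default_ground_truth()] configuration.
#' @param seed Optional integer seed.
#' @param spindle_rate Bursts per minute of NREM; `NULL` uses the
#'   configured rate. The realised count is `round(rate * NREM minutes)`.
#' @return A list with `recording` (a [signal_recording()]) and
#'   `spindles` (tibble of true `onset`, `duration`, `frequency`).
#' @export
generate_signals <- function(h, gt, seed = NULL, spindle_rate = NULL) {
  sl <- gt$signal_law
  fs <- sl$fs
  el <- epoch_len(h)
  n <- nrow(h) * round(el * fs)
  state <- ifelse(h$state == "M", "W", h$state)
  per_sample_state <- rep(state, each = round(el * fs))
  with_seed_maybe(seed, {
    make_eeg <- function() {
      sig <- sl$pink_gain * pink_noise(n, fs)
      for (band in names(sl$bands)) {
        gains <- purrr::map_dbl(sl$gains, band)
        sig <- sig + gains[per_sample_state] * bandlimited_noise(n, fs, sl$bands[[band]])
      }
      sig
    }
    eeg_parietal <- make_eeg()
    eeg_prefrontal <- make_eeg()
    emg <- sl$emg_gain[per_sample_state] * bandlimited_noise(n, fs, c(20, fs / 2 - 1))
    # spindles: deterministic count at the configured per-minute rate,
    # placed uniformly in NREM with no overlap
    rate <- spindle_rate %||% sl$spindle$rate
    nrem_epochs <- which(state == "N")
    nrem_min <- length(nrem_epochs) * el / 60
    n_spindles <- round(rate * nrem_min)
    spindles <- tibble(onset = double(), duration = double(), frequency = double())
    if (n_spindles > 0 && length(nrem_epochs) > 2) {
      taken <- rep(FALSE, nrow(h))
      placed <- 0L
      tries <- 0L
      while (placed < n_spindles && tries < 50L * n_spindles) {
        tries <- tries + 1L
        dur <- runif(1, sl$spindle$dur[1], sl$spindle$dur[2])
        e0 <- sample(nrem_epochs, 1)
        t0 <- (e0 - 1) * el + runif(1, 0, el)
        span <- (floor(t0 / el) + 1L):min(floor((t0 + dur) / el) + 1L, nrow(h))
        if (any(state[span] != "N") || any(taken[span]) || t0 + dur > nrow(h) * el) next
        taken[span] <- TRUE
        f <- runif(1, sl$spindle$freq[1], sl$spindle$freq[2])
        i0 <- round(t0 * fs)
        len <- round(dur * fs)
        tt <- seq_len(len) / fs
        burst <- sl$spindle$amp * hann_window(len) * sin(2 * pi * f * tt + runif(1, 0, 2 * pi))
        eeg_prefrontal[i0 + seq_len(len)] <- eeg_prefrontal[i0 + seq_len(len)] + burst
        spindles <- dplyr::bind_rows(spindles, tibble(onset = t0, duration = dur, frequency = f))
        placed <- placed + 1L
      }
      spindles <- dplyr::arrange(spindles, .data$onset)
    }
    list(
      recording = signal_recording(eeg_parietal, eeg_prefrontal, emg, fs),
      spindles = spindles
    )
  })
}
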