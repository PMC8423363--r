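#' Construct a hypnogram
#'
#' A hypnogram is the epoch-by-epoch time series of brain states underlying
#' all analyses in remcycle. It is stored as a tibble with one row per epoch
#' and columns `time_s` (epoch start, seconds) and `state`, one of `"W"`
#' (wake), `"N"` (NREM), `"R"` (REM) or `"M"` (microarousal; present only
#' after [score_microarousals()]). The epoch length (default 2.5 s) and the
#' circadian phase are carried as attributes.
#'
#' @param states Character vector of epoch labels from `W`, `N`, `R`, `M`.
#' @param epoch_len Epoch duration in seconds (> 0).
#' @param phase Circadian phase of the recording: `"light"`, `"dark"` or
#'   `"unknown"`.
#' @return A tibble of class `remcycle_hypnogram`.
#' @examples
#' h <- hypnogram(c("W", "W", "N", "N", "R"))
#' epoch_len(h)
#' @export
hypnogram <- function(states, epoch_len = 2.5, phase = c("unknown", "light", "dark")) {
  phase <- match.arg(phase)
  if (!.is_scalar_num(epoch_len) || epoch_len <= 0) {
    stop_remcycle("`epoch_len` must be a single positive number.", "remcycle_parameter_error")
  }
  states <- as.character(states)
  if (length(states) == 0L) {
    stop_remcycle("A hypnogram needs at least one epoch.", "remcycle_format_error")
  }
  bad <- which(!states %in% .states)
  if (length(bad) > 0L) {
    stop_remcycle(
      sprintf(
        "Unknown state label %s at epoch %d (allowed: %s).",
        dQuote(states[bad[1]]), bad[1], paste(.states, collapse = ", ")
      ),
      "remcycle_format_error"
    )
  }
  out <- tibble(
    time_s = (seq_along(states) - 1) * epoch_len,
    state = states
  )
  attr(out, "epoch_len") <- epoch_len
  attr(out, "phase") <- phase
  class(out) <- c("remcycle_hypnogram", class(out))
  out
}

#' @rdname hypnogram
#' @param h A hypnogram.
#' @export
epoch_len <- function(h) {
  attr(h, "epoch_len") %||% 2.5
}

#' @rdname hypnogram
#' @export
hypnogram_phase <- function(h) {
  attr(h, "phase") %||% "unknown"
}

#' Read and write hypnogram CSV files
#'
#' The on-disk format is a two-column CSV with header `time_s,state`;
#' states are `W`/`N`/`R` plus `M` in files written after microarousal
#' scoring. The epoch length is inferred from the time deltas unless given
#' explicitly. Reading and writing round-trip bit-exactly.
#'
#' @param path File path.
#' @param epoch_len Epoch duration in seconds; `NULL` (default) infers it
#'   from consecutive `time_s` differences.
#' @param phase Circadian phase to attach to the result.
#' @return `read_hypnogram()` returns a hypnogram tibble;
#'   `write_hypnogram()` invisibly returns `path`.
#' @export
read_hypnogram <- function(path, epoch_len = NULL, phase = c("unknown", "light", "dark")) {
  phase <- match.arg(phase)
  if (!file.exists(path)) {
    stop_remcycle(sprintf("Hypnogram file not found: %s", path), "remcycle_io_error")
  }
  df <- readr::read_csv(path, col_types = readr::cols(
    time_s = readr::col_double(),
    state = readr::col_character()
  ), progress = FALSE)
  if (nrow(df) == 0L) {
    stop_remcycle(sprintf("Hypnogram file is empty: %s", path), "remcycle_format_error")
  }
  bad <- which(!df$state %in% .states)
  if (length(bad) > 0L) {
    stop_remcycle(
      sprintf("Unknown state label %s at row %d of %s.", dQuote(df$state[bad[1]]), bad[1], path),
      "remcycle_format_error"
    )
  }
  if (is.null(epoch_len)) {
    epoch_len <- if (nrow(df) > 1L) {
      d <- diff(df$time_s)
      if (max(d) - min(d) > 1e-9) {
        stop_remcycle("Non-uniform time grid; pass `epoch_len` explicitly.", "remcycle_format_error")
      }
      d[1]
    } else {
      2.5
    }
  }
  hypnogram(df$state, epoch_len = epoch_len, phase = phase)
}

#' @rdname read_hypnogram
#' @param h A hypnogram tibble.
#' @export
write_hypnogram <- function(h, path) {
  readr::write_csv(tibble(time_s = h$time_s, state = h$state), path, progress = FALSE)
  invisible(path)
}

#' Score microarousals
#'
#' Maximal runs of wake with a total duration of at most `ma_threshold`
#' seconds (20 s by default) are relabelled as microarousals (`M`). MAs are
#' treated as NREM in all downstream `|N|` computations. With threshold 0
#' no epochs are relabelled. The operation is idempotent: `M` runs in the
#' input are left untouched.
#'
#' @param h A hypnogram.
#' @param ma_threshold Maximal wake-bout duration (seconds) still scored as
#'   a microarousal.
#' @return The hypnogram with qualifying `W` runs relabelled `M`.
#' @export
score_microarousals <- function(h, ma_threshold = 20) {
  if (!.is_scalar_num(ma_threshold) || ma_threshold < 0) {
    stop_remcycle("`ma_threshold` must be a single non-negative number.", "remcycle_parameter_error")
  }
  el <- epoch_len(h)
  states <- h$state
  runs <- state_runs(states)
  wake <- runs[runs$state == "W" & runs$length * el <= ma_threshold, ]
  for (i in seq_len(nrow(wake))) {
    states[wake$start[i]:wake$end[i]] <- "M"
  }
  out <- hypnogram(states, epoch_len = el, phase = hypnogram_phase(h))
  out
}

#' Segment a hypnogram into sleep cycles
#'
#' A sleep cycle comprises a REM episode and the following inter-REM
#' interval, closed by the next REM episode. For each cycle the function
#' reports the leading REM duration `rem_pre`, the inter-REM interval
#' duration, the total NREM time `n_total` (`|N|`, microarousals included),
#' the total wake time `w_total` (`|W|`, microarousals excluded), the wake
#' episode structure, and the duration `rem_post` of the terminating REM
#' episode. Material before the first and after the last REM episode forms
#' no cycle.
#'
#' @param h A hypnogram, normally after [score_microarousals()].
#' @return A tibble with one row per sleep cycle and columns `start_index`
#'   (epoch index of REM onset, 1-based), `rem_pre`, `inter_rem`,
#'   `n_total`, `w_total`, `wake_episode_count`, `wake_episode_durations`
#'   (list-column), `rem_post`, `inter_start_index`, `inter_end_index`.
#'   Zero rows when the hypnogram holds fewer than two REM episodes.
#' @examples
#' h <- hypnogram(c(rep("R", 4), rep("N", 8), "M", "M", rep("N", 6), "R", "R"))
#' extract_cycles(h)
#' @export
extract_cycles <- function(h) {
  el <- epoch_len(h)
  runs <- state_runs(h$state)
  rem <- runs[runs$state == "R", ]
  empty <- tibble(
    start_index = integer(), rem_pre = double(), inter_rem = double(),
    n_total = double(), w_total = double(), wake_episode_count = integer(),
    wake_episode_durations = list(), rem_post = double(),
    inter_start_index = integer(), inter_end_index = integer()
  )
  if (nrow(rem) < 2L) {
    return(empty)
  }
  purrr::map_dfr(seq_len(nrow(rem) - 1L), function(i) {
    i0 <- rem$end[i] + 1L
    i1 <- rem$start[i + 1L] - 1L
    inter <- if (i1 >= i0) h$state[i0:i1] else character(0)
    wake_runs <- state_runs(inter)
    wake_runs <- wake_runs[wake_runs$state == "W", , drop = FALSE]
    wake_durs <- wake_runs$length * el
    tibble(
      start_index = rem$start[i],
      rem_pre = rem$length[i] * el,
      inter_rem = length(inter) * el,
      n_total = sum(inter %in% c("N", "M")) * el,
      w_total = sum(wake_durs),
      wake_episode_count = nrow(wake_runs),
      wake_episode_durations = list(wake_durs),
      rem_post = rem$length[i + 1L] * el,
      inter_start_index = if (i1 >= i0) i0 else NA_integer_,
      inter_end_index = if (i1 >= i0) i1 else NA_integer_
    )
  })
}
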