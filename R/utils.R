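# shared internal helpers

# state alphabet of the hypnogram; "M" only appears after microarousal scoring
.states <- c("W", "N", "R", "M")

.is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# run a block with a reproducible RNG state when seed is given, otherwise
# use the caller's RNG stream
with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

# run-length view of a label vector as a tibble (used by MA scoring,
# cycle extraction and the generators)
state_runs <- function(states) {
  r <- rle(as.character(states))
  ends <- cumsum(r$lengths)
  tibble(
    state = r$values,
    length = r$lengths,
    start = ends - r$lengths + 1L,
    end = ends
  )
}

# Hann window of length n (periodic form, as used for spectral averaging)
hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * seq_len(n) / n)
}

stop_remcycle <- function(msg, class) {
  abort(msg, class = c(class, "remcycle_error"))
}
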