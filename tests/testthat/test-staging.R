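test_that("scoring features separate the frequency bands", {
  fs <- 1000
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  mk <- function(x) signal_recording(x, x, x * 0.1, fs)

  f_delta <- compute_scoring_features(mk(sin(2 * pi * 2 * t)))
  expect_true(all(f_delta$delta > 10 * pmax(f_delta$theta, f_delta$sigma, f_delta$gamma)))

  f_gamma <- compute_scoring_features(mk(sin(2 * pi * 110 * t)))
  expect_true(all(f_gamma$gamma > 10 * pmax(f_gamma$delta, f_gamma$theta, f_gamma$sigma)))

  # white noise: band powers proportional to bandwidth (the grid holds
  # 17 delta and 35 theta cells of 0.2 Hz, so the expected ratio is
  # 35/17)
  withr::local_seed(31)
  f_noise <- compute_scoring_features(mk(rnorm(120 * fs)))
  ratio <- mean(f_noise$theta) / mean(f_noise$delta)
  expect_lt(abs(ratio - 35 / 17), 0.3)

  # one feature row per 2.5 s epoch
  expect_equal(nrow(f_noise), 48L)

  expect_error(compute_scoring_features(signal_recording(t, t, t, 200)),
               class = "remcycle_parameter_error")
})

test_that("state rules fire as specified on constructed features", {
  base <- tibble::tibble(
    delta = rep(1, 40), theta = rep(1, 40), sigma = rep(1, 40),
    gamma = rep(1, 40), theta_delta = rep(1, 40), emg = rep(1, 40)
  )
  # inject one clear bin per rule among neutral bins
  f <- base
  f$theta_delta[5] <- 50; f$delta[5] <- 0.01; f$emg[5] <- 0.01 # REM
  f$delta[10] <- 50; f$emg[10] <- 0.01 # NREM via high delta
  f$delta[15] <- 0.01; f$sigma[15] <- 50; f$emg[15] <- 0.01 # NREM via sigma
  f$delta[20] <- 0.01; f$emg[20] <- 50 # wake via EMG
  f$gamma[25] <- 50 # wake via gamma
  h <- suppressWarnings(classify_states(f))
  expect_equal(h$state[c(5, 10, 15, 20, 25)], c("R", "N", "N", "W", "W"))
  # every bin has exactly one label from the alphabet
  expect_true(all(h$state %in% c("W", "N", "R")))
  expect_equal(nrow(h), 40L)

  expect_error(classify_states(dplyr::mutate(f, delta = Inf)),
               class = "remcycle_parameter_error")
  expect_warning(classify_states(base), "variance")
})

test_that("classification is invariant to channel rescaling", {
  withr::local_seed(32)
  gt <- default_ground_truth()
  out <- generate_hypnogram(gt, 600)
  sig <- generate_signals(out$hypnogram, gt)
  rec <- sig$recording
  rec2 <- signal_recording(rec$eeg_parietal * 7.3, rec$eeg_prefrontal * 7.3,
                           rec$emg * 7.3, rec$fs)
  h1 <- classify_states(compute_scoring_features(rec))
  h2 <- classify_states(compute_scoring_features(rec2))
  expect_identical(h1$state, h2$state)
})

test_that("staging recovers the generating hypnogram on synthetic signals", {
  withr::local_seed(33)
  gt <- default_ground_truth()
  out <- generate_hypnogram(gt, 1200) # 20 min
  sig <- generate_signals(out$hypnogram, gt)
  h <- classify_states(compute_scoring_features(sig$recording))
  truth <- ifelse(out$hypnogram$state == "M", "W", out$hypnogram$state)
  expect_gte(mean(h$state == truth), 0.9)
  # per-state recall on states with strongly separated band content
  for (s in c("N", "R", "W")) {
    expect_gte(mean(h$state[truth == s] == s), 0.85)
  }
})

test_that("signal CSV + sidecar round-trips", {
  withr::local_seed(34)
  rec <- signal_recording(rnorm(500), rnorm(500), rnorm(500), 250)
  path <- withr::local_tempfile(fileext = ".csv")
  write_signals(rec, path)
  rec2 <- read_signals(path)
  expect_equal(rec2$fs, 250)
  expect_equal(rec2$eeg_parietal, rec$eeg_parietal, tolerance = 1e-10)
  expect_equal(rec2$emg, rec$emg, tolerance = 1e-10)
})
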