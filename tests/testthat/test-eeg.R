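test_that("Welch densities localise tones and conserve power", {
  fs <- 1000
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)

  # 10 Hz unit sinusoid: the peak sits on the 10 Hz grid point
  tone <- sin(2 * pi * 10 * t)
  psd <- welch_psd(tone, fs)
  expect_equal(psd$frequency[which.max(psd$power)], 10)
  expect_equal(psd$frequency[2] - psd$frequency[1], 1 / 3)

  # white noise: total integrated power tracks the variance within 5%
  withr::local_seed(12)
  noise <- rnorm(10 * 60 * fs)
  psd_n <- welch_psd(noise, fs)
  total <- sum(psd_n$power) * attr(psd_n, "df")
  expect_lt(abs(total / var(noise) - 1), 0.05)

  # pooling two segments of the same process matches a single segment
  psd_2 <- welch_psd(list(noise[1:300000], noise[300001:600000]), fs)
  expect_equal(attr(psd_2, "n_segments"), 2L)
  expect_lt(abs(sum(psd_2$power) / sum(psd_n$power) - 1), 0.01)

  expect_error(welch_psd(rnorm(100), fs), class = "remcycle_parameter_error")
})

test_that("band power is a midpoint Riemann sum with half-open bands", {
  # flat unit density: delta band 0.5-4.5 Hz covers 12 cells of 1/3 Hz
  psd <- tibble::tibble(frequency = seq(0, 30, by = 1 / 3), power = 1)
  attr(psd, "df") <- 1 / 3
  expect_identical(band_power(psd, c(0.5, 4.5)), 4.0)

  # additivity over adjacent bands partitioning the grid
  withr::local_seed(13)
  psd$power <- rexp(nrow(psd))
  expect_equal(
    band_power(psd, c(0, 10)) + band_power(psd, c(10, 20)),
    band_power(psd, c(0, 20))
  )

  # 1/f^2 analytic density: the midpoint rule reproduces the closed-form
  # integral over the union of the selected cells (each grid frequency
  # is the midpoint of a 1/3 Hz cell)
  f <- seq(0, 30, by = 1 / 3)
  psd2 <- tibble::tibble(frequency = f, power = ifelse(f > 0, 1 / f^2, 0))
  attr(psd2, "df") <- 1 / 3
  sel <- f[f >= 5 & f < 9.5]
  exact <- 1 / (min(sel) - 1 / 6) - 1 / (max(sel) + 1 / 6)
  expect_lt(abs(band_power(psd2, c(5, 9.5)) / exact - 1), 0.01)

  # zero-density region integrates to zero
  psd3 <- tibble::tibble(frequency = f, power = 0)
  attr(psd3, "df") <- 1 / 3
  expect_equal(band_power(psd3, c(5, 9.5)), 0)

  expect_error(band_power(psd, c(4, 4)), class = "remcycle_parameter_error")
  expect_error(band_power(psd, c(25, 40)), class = "remcycle_parameter_error")
})

test_that("weighted density averages are exact pointwise combinations", {
  withr::local_seed(14)
  make <- function() {
    p <- tibble::tibble(frequency = seq(0, 20, by = 1 / 3), power = rexp(61))
    attr(p, "df") <- 1 / 3
    p
  }
  ds <- list(make(), make(), make())

  # one-hot weights return the chosen density bit-identically
  expect_identical(weighted_density_average(ds, c(1, 0, 0))$power, ds[[1]]$power)

  # uniform weights are the arithmetic mean
  avg <- weighted_density_average(ds, rep(1 / 3, 3))
  expect_equal(avg$power, (ds[[1]]$power + ds[[2]]$power + ds[[3]]$power) / 3)

  # random weights match the brute-force recomputation
  w <- c(0.2, 0.5, 0.3)
  expect_equal(weighted_density_average(ds, w)$power,
               w[1] * ds[[1]]$power + w[2] * ds[[2]]$power + w[3] * ds[[3]]$power)

  expect_error(weighted_density_average(ds, c(0.5, 0.5, 0.5)),
               class = "remcycle_parameter_error")
  bad <- ds
  bad[[2]]$frequency <- bad[[2]]$frequency + 0.1
  expect_error(weighted_density_average(bad, c(0.5, 0.3, 0.2)),
               class = "remcycle_parameter_error")
})

test_that("normalized time courses bin the two periods into quartiles", {
  # constant signal: every quartile mean is the constant
  tc <- normalized_timecourse(rep(3, 24), boundaries = c(8, 24))
  expect_equal(tc$mean, rep(3, 8))
  expect_equal(tc$period, rep(c("refractory", "permissive"), each = 4))

  # linear ramp: quartile means equal the within-quartile midpoint averages
  vals <- 1:8
  tc2 <- normalized_timecourse(c(vals, rep(0, 8)), boundaries = c(8, 16))
  expect_equal(tc2$mean[tc2$period == "refractory"], c(1.5, 3.5, 5.5, 7.5))

  # 8 and 16 epochs: 2 and 4 epochs per quartile
  tc3 <- normalized_timecourse(rep(1, 24), boundaries = c(8, 24))
  expect_equal(nrow(tc3), 8L)

  # too few epochs: period dropped with a warning
  expect_warning(tc4 <- normalized_timecourse(rep(1, 10), boundaries = c(2, 10)),
                 "excluded")
  expect_equal(unique(tc4$period), "permissive")
})

test_that("event rates are per minute of the requested state", {
  h <- hypnogram(c(rep("N", 48), rep("M", 24), rep("W", 24)))
  # 72 epochs of N+M = 3 min; 6 events inside
  onsets <- c(10, 30, 50, 80, 100, 150)
  expect_equal(event_rate(onsets, h, "N"), 2.0)
  expect_equal(event_rate(numeric(0), h, "N"), 0)
  # events only during wake count zero toward NREM
  expect_equal(event_rate(c(190, 200), h, "N"), 0)
  expect_error(event_rate(onsets, h, "R"), class = "remcycle_undefined_rate_error")
})
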