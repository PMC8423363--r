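test_that("intersection threshold solves the weighted-density equality", {
  # equal weights and sigmas: midpoint of the means
  m <- flat_model(k_long = 0.5, mu_long = 6, mu_short = 4,
                  sigma_long = 0.4, sigma_short = 0.4)
  expect_equal(intersection_threshold(m, 50), 5, tolerance = 1e-9)

  # generic parameters: closed form equals a dense grid scan
  m2 <- flat_model(k_long = 0.65, mu_long = 6.2, mu_short = 4.1,
                   sigma_long = 0.55, sigma_short = 0.33)
  x_int <- intersection_threshold(m2, 80)
  z <- seq(4.1, 6.2, by = 1e-6)
  d <- 0.35 * dnorm(z, 4.1, 0.33) - 0.65 * dnorm(z, 6.2, 0.55)
  grid_root <- z[which.min(abs(d))]
  expect_lt(abs(x_int - grid_root), 1e-5)

  # unimodal case: no intersection point exists
  expect_error(intersection_threshold(flat_model(k_long = 1), 50),
               class = "remcycle_unimodal_error")
})

test_that("cycle classification applies the intersection criterion", {
  gt <- default_ground_truth()
  m <- gt$model

  # k_long = 1 for rem_pre >= 150 s: always single
  cyc_hi <- tibble::tibble(rem_pre = c(150, 200), n_total = c(50, 1200))
  expect_equal(classify_cycles(cyc_hi, m)$label, c("single", "single"))

  # below the domain minimum: undefined
  cyc_lo <- tibble::tibble(rem_pre = m$domain_min - 2.5, n_total = 100)
  expect_equal(classify_cycles(cyc_lo, m)$label, "undefined")

  # in-domain labels agree with the weighted-density argmax
  withr::local_seed(5)
  n <- 2000
  cyc <- tibble::tibble(
    rem_pre = runif(n, m$domain_min, 149),
    n_total = exp(runif(n, 2.5, 8.5))
  )
  ann <- classify_cycles(cyc, m)
  p <- remcycle:::eval_params_raw(m, cyc$rem_pre)
  ln_n <- log(cyc$n_total)
  d_short <- p$k_short * dnorm(ln_n, p$mu_short, p$sigma_short)
  d_long <- p$k_long * dnorm(ln_n, p$mu_long, p$sigma_long)
  oracle <- ifelse(d_short > d_long, "sequential", "single")
  ties <- d_short == d_long
  expect_equal(ann$label[!ties], oracle[!ties])

  expect_error(classify_cycles(tibble::tibble(rem_pre = 60, n_total = 0), m),
               class = "remcycle_parameter_error")
})

test_that("classification accuracy reaches the Bayes rate of the generator", {
  withr::local_seed(17)
  gt <- default_ground_truth()
  cyc <- generate_cycles(gt, 8000)
  cyc <- cyc[cyc$rem_pre >= gt$model$domain_min, ]
  ann <- classify_cycles(cyc, gt$model)
  acc <- mean((ann$label == "sequential") == (cyc$component == "short"))
  # Bayes rate of the generating mixture at each cycle's rem_pre
  p <- remcycle:::eval_params_raw(gt$model, cyc$rem_pre)
  bayes <- vapply(seq_len(nrow(cyc)), function(i) {
    integrate(function(z) pmax(
      p$k_short[i] * dnorm(z, p$mu_short[i], p$sigma_short[i]),
      p$k_long[i] * dnorm(z, p$mu_long[i], p$sigma_long[i])
    ), -5, 15, rel.tol = 1e-8)$value
  }, numeric(1))
  expect_lt(abs(acc - mean(bayes)), 0.02)
})

test_that("refractory threshold is the long component's 1st percentile", {
  m <- flat_model(k_long = 0.8, mu_long = 6, mu_short = 4,
                  sigma_long = 0.5, sigma_short = 0.4)
  thr <- refractory_threshold(m, 60)
  expect_equal(thr, exp(6 + 0.5 * qnorm(0.01)), tolerance = 1e-12)
  expect_lt(abs(thr - 126.1), 0.1)

  # bisection inversion of F_long agrees to 0.01 s
  f_long <- function(n) pnorm((log(n) - 6) / 0.5)
  lo <- 1; hi <- exp(6)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f_long(mid) < 0.01) lo <- mid else hi <- mid
  }
  expect_lt(abs(thr - (lo + hi) / 2), 0.01)

  # degenerate limit: sigma -> 0 gives exp(mu_long)
  m0 <- flat_model(k_long = 0.8, sigma_long = 1e-9)
  expect_equal(refractory_threshold(m0, 60), exp(6), tolerance = 1e-4)

  # increasing in rem_pre on trend-shaped models
  gt <- default_ground_truth()
  grid <- seq(gt$model$domain_min, 237.5, by = 2.5)
  expect_true(all(diff(refractory_threshold(gt$model, grid)) > 0))
  # mid-range: threshold between one and three times rem_pre
  mid <- grid[grid >= 30]
  ratio <- refractory_threshold(gt$model, mid) / mid
  expect_true(all(ratio > 1 & ratio < 3))
})

test_that("cycle segmentation accumulates NREM toward the threshold", {
  h <- hypnogram(c("R", "N", "N", "W", "N", "N", "N", "R"))
  cyc <- extract_cycles(h)
  seg <- segment_cycle(cyc[1, ], h, threshold = 10)
  expect_equal(seg$refractory, c(2, 3, 5, 6))
  expect_equal(seg$permissive, 7)
  expect_false(seg$flagged)

  # threshold zero: everything permissive
  seg0 <- segment_cycle(cyc[1, ], h, threshold = 0)
  expect_equal(length(seg0$refractory), 0L)
  expect_equal(seg0$permissive, c(2, 3, 5, 6, 7))

  # threshold beyond |N|: all refractory, flagged
  expect_warning(seg2 <- segment_cycle(cyc[1, ], h, threshold = 60))
  expect_length(seg2$permissive, 0)
  expect_equal(seg2$refractory, c(2, 3, 5, 6, 7))
  expect_true(seg2$flagged)
})

test_that("propensity at REM onset equals the model CDF at |N|", {
  m <- flat_model(k_long = 0.6)
  cyc <- tibble::tibble(rem_pre = c(30, 90), n_total = c(60, 400))
  expect_equal(propensity_at_rem_onset(m, cyc),
               mixture_cdf(m, cyc$rem_pre, cyc$n_total))
  long_only <- propensity_at_rem_onset(m, cyc, long_only = TRUE)
  expect_equal(long_only, pnorm((log(cyc$n_total) - 6) / 0.5))
  # limits
  expect_equal(propensity_at_rem_onset(m, tibble::tibble(rem_pre = 30, n_total = 1e9)),
               1, tolerance = 1e-6)
})

test_that("sequential run lengths tabulate consecutive sequences", {
  labels <- c("single", "sequential", "sequential", "single",
              "sequential", "single", "sequential", "sequential", "sequential")
  tab <- sequential_run_lengths(labels)
  expect_equal(tab$sequence_length, c(1L, 2L, 3L))
  expect_equal(tab$count, c(1L, 1L, 1L))
  expect_equal(nrow(sequential_run_lengths(rep("single", 5))), 0L)
})
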