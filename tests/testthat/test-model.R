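test_that("parameter evaluation clamps the weight and guards the domain", {
  gt <- default_ground_truth()
  m <- gt$model

  # the raw weight curve exceeds 1 beyond 150 s; the min(., 1) clamp applies
  p <- evaluate_parameters(m, c(150, 200, 239))
  expect_equal(p$k_long, rep(1, 3))
  expect_equal(p$k_short, rep(0, 3))

  # boundary inclusion: the domain minimum itself evaluates cleanly
  p0 <- evaluate_parameters(m, m$domain_min)
  expect_true(all(is.finite(unlist(p0))))

  # below the domain: error naming the minimum
  expect_error(evaluate_parameters(m, m$domain_min - 2.5),
               as.character(m$domain_min), class = "remcycle_domain_error")

  # evaluation equals direct curve evaluation
  expect_equal(p0$mu_long, remcycle:::eval_curve(m$curves$mu_long, m$domain_min))

  # beyond the fitted range: extrapolation warning
  expect_warning(evaluate_parameters(m, 250), "xtrapolat")
})

test_that("mixture pdf normalises and cdf matches quadrature", {
  m <- flat_model(k_long = 0.6, mu_long = 6, mu_short = 4,
                  sigma_long = 0.5, sigma_short = 0.35)
  for (rp in c(20, 60, 120)) {
    norm <- integrate(function(z) mixture_pdf(m, rp, z), -10, 20,
                      rel.tol = 1e-10)$value
    expect_lt(abs(norm - 1), 1e-6)
    for (n in c(30, 150, 600)) {
      quad <- integrate(function(z) mixture_pdf(m, rp, z), -20, log(n),
                        rel.tol = 1e-10)$value
      expect_lt(abs(mixture_cdf(m, rp, n) - quad), 1e-6)
    }
  }

  # k_long = 1 collapses to the single long Gaussian
  m1 <- flat_model(k_long = 1)
  z <- seq(3, 9, by = 0.1)
  expect_equal(mixture_pdf(m1, 50, z), dnorm(z, 6, 0.5))
  # Gaussian symmetry about the mean
  expect_equal(mixture_pdf(m1, 50, 6 + 0.7), mixture_pdf(m1, 50, 6 - 0.7))
  # median of the lognormal: cdf at exp(mu_long) is 1/2
  expect_equal(mixture_cdf(m1, 50, exp(6)), 0.5)

  # cdf contracts
  expect_equal(mixture_cdf(m, 60, 0), 0)
  nn <- seq(0, 3000, by = 10)
  expect_true(all(diff(mixture_cdf(m, 60, nn)) >= 0))
  expect_error(mixture_cdf(m, 60, -1), class = "remcycle_parameter_error")
})

test_that("sampling is reproducible and matches analytic moments", {
  m <- flat_model(k_long = 0.7, mu_long = 6, mu_short = 4,
                  sigma_long = 0.4, sigma_short = 0.3)
  a <- sample_N(m, 60, n = 50, seed = 9)
  b <- sample_N(m, 60, n = 50, seed = 9)
  expect_identical(a, b)

  x <- log(sample_N(m, 60, n = 1e5, seed = 10))
  mean_th <- 0.7 * 6 + 0.3 * 4
  var_th <- 0.7 * (0.4^2 + 6^2) + 0.3 * (0.3^2 + 4^2) - mean_th^2
  expect_lt(abs(mean(x) - mean_th), 3 * sqrt(var_th / 1e5))

  # k_long = 1: all draws from the long component
  x1 <- log(sample_N(flat_model(k_long = 1), 60, n = 2e4, seed = 11))
  expect_lt(abs(sd(x1) - 0.5), 0.01)
  expect_lt(abs(mean(x1) - 6), 0.01)
})

test_that("domain minimum scanning follows the intersection rule", {
  # weight curve crosses zero at 4: valid from the first grid point >= 5
  k_from5 <- remcycle:::new_curve("logarithmic", a = 0.3, b = 0, c = -0.3 * log(4.9))
  m <- cond_gmm(
    k_long = k_from5,
    mu_long = remcycle:::new_curve("linear", a = 0, b = 6),
    mu_short = remcycle:::new_curve("linear", a = 0, b = 4),
    sigma_long = remcycle:::new_curve("linear", a = 0, b = 0.5),
    sigma_short = remcycle:::new_curve("linear", a = 0, b = 0.4)
  )
  expect_equal(m$domain_min, 5)

  # mu_short above mu_long at small rem_pre: domain starts strictly later
  m2 <- cond_gmm(
    k_long = remcycle:::new_curve("linear", a = 0, b = 0.5),
    mu_long = remcycle:::new_curve("linear", a = 0, b = 6),
    mu_short = remcycle:::new_curve("logarithmic", a = -1.2, b = 0, c = 9),
    sigma_long = remcycle:::new_curve("linear", a = 0, b = 0.5),
    sigma_short = remcycle:::new_curve("linear", a = 0, b = 0.4)
  )
  expect_gt(m2$domain_min, 2.5)

  # identical components everywhere: no valid intersection, model invalid
  expect_error(
    cond_gmm(
      k_long = remcycle:::new_curve("linear", a = 0, b = 0.5),
      mu_long = remcycle:::new_curve("linear", a = 0, b = 5),
      mu_short = remcycle:::new_curve("linear", a = 0, b = 5),
      sigma_long = remcycle:::new_curve("linear", a = 0, b = 0.5),
      sigma_short = remcycle:::new_curve("linear", a = 0, b = 0.5)
    ),
    class = "remcycle_model_invalid_error"
  )
})

test_that("model JSON serialization round-trips", {
  withr::local_seed(3)
  gt <- default_ground_truth()
  cyc <- generate_cycles(gt, 3000)
  bins <- suppressWarnings(fit_bin_mixtures(cyc))
  m <- fit_parameter_curves(bins, phase = "light")
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(m2$domain_min, m$domain_min)
  expect_equal(m2$curves, m$curves, tolerance = 1e-12)
  grid <- seq(m$domain_min, 237.5, by = 7.5)
  expect_equal(evaluate_parameters(m2, grid), evaluate_parameters(m, grid))
})
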