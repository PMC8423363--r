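# shared fixtures: tiny models with known parameters, built in code

# conditional model with constant parameter curves (flat in rem_pre),
# handy when a test needs exact hand-computable mixture parameters
flat_model <- function(k_long = 0.5, mu_long = 6, mu_short = 4,
                       sigma_long = 0.5, sigma_short = 0.4) {
  cond_gmm(
    k_long = remcycle:::new_curve("linear", a = 0, b = k_long),
    mu_long = remcycle:::new_curve("linear", a = 0, b = mu_long),
    mu_short = remcycle:::new_curve("linear", a = 0, b = mu_short),
    sigma_long = remcycle:::new_curve("linear", a = 0, b = sigma_long),
    sigma_short = remcycle:::new_curve("linear", a = 0, b = sigma_short),
    # a unimodal flat model has no intersection; pin the domain directly
    domain_min = if (k_long >= 1) 2.5 else NULL
  )
}

# random hypnogram over the full alphabet (pre-MA states only)
random_hypnogram <- function(n, seed = 1) {
  withr::with_seed(seed, {
    hypnogram(sample(c("W", "N", "R"), n, replace = TRUE,
                     prob = c(0.3, 0.55, 0.15)))
  })
}

# brute-force mixture log-likelihood maximisation over a coarse grid;
# independent oracle for the EM fitter
grid_mle_loglik <- function(x, k_grid = seq(0.1, 0.9, by = 0.1),
                            n_mu = 12L, n_sigma = 8L) {
  mu_grid <- seq(min(x), max(x), length.out = n_mu)
  sd_lo <- max(sd(x) / 8, 0.02)
  sigma_grid <- seq(sd_lo, sd(x) * 1.5, length.out = n_sigma)
  comb <- expand.grid(mu = mu_grid, sigma = sigma_grid)
  dens <- sapply(seq_len(nrow(comb)),
                 function(i) dnorm(x, comb$mu[i], comb$sigma[i]))
  best <- -Inf
  for (k in k_grid) {
    for (i in seq_len(nrow(comb))) {
      m <- k * dens[, i]
      ll <- colSums(log(pmax(m + (1 - k) * dens, 1e-300)))
      best <- max(best, max(ll))
    }
  }
  best
}

# overlap matching between detected and annotated events
match_events <- function(detected, truth) {
  recall <- if (nrow(truth) == 0) NA_real_ else {
    mean(vapply(seq_len(nrow(truth)), function(i) {
      any(detected$onset < truth$onset[i] + truth$duration[i] &
            detected$onset + detected$duration > truth$onset[i])
    }, logical(1)))
  }
  false_frac <- if (nrow(detected) == 0) 0 else {
    mean(vapply(seq_len(nrow(detected)), function(j) {
      !any(truth$onset < detected$onset[j] + detected$duration[j] &
             truth$onset + truth$duration > detected$onset[j])
    }, logical(1)))
  }
  list(recall = recall, false_frac = false_frac)
}
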