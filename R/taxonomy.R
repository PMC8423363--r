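# Sequential vs single cycle taxonomy, refractory/permissive segmentation
# and REM-propensity evaluation.

#' Intersection threshold between the short and long components
#'
#' Solves `k_short * f_short(x) = k_long * f_long(x)` on the `ln(|N|)`
#' axis in closed form (the equality reduces to a quadratic) and returns
#' the root lying strictly between `mu_short` and `mu_long`. Cycles with
#' `ln(n_total)` below this point are more likely to come from the short
#' component and are labelled sequential.
#'
#' @param m A `remcycle_cgmm` model.
#' @param rem_pre Preceding REM duration (s), in the model domain, with
#'   `k_long < 1` so that both components exist.
#' @return The intersection point in ln-seconds.
#' @export
intersection_threshold <- function(m, rem_pre) {
  check_domain(m, rem_pre)
  p <- eval_params_raw(m, rem_pre)
  out <- purrr::map_dbl(seq_len(nrow(p)), function(i) {
    if (p$k_long[i] >= 1) {
      stop_remcycle(
        "k_long = 1 at this rem_pre: the mixture is unimodal and has no intersection point.",
        "remcycle_unimodal_error"
      )
    }
    x <- intersection_root(
      p$k_long[i], p$mu_long[i], p$mu_short[i],
      p$sigma_long[i], p$sigma_short[i]
    )
    if (is.na(x)) {
      stop_remcycle(
        "No intersection of the weighted component densities lies between the component means.",
        "remcycle_no_intersection_error"
      )
    }
    x
  })
  out
}

# single/sequential decision for one (rem_pre, ln_n) pair given evaluated
# parameters; falls back to the posterior-comparison rule when the
# quadratic has no interior root
classify_one <- function(k_long, mu_long, mu_short, sigma_long, sigma_short, ln_n) {
  if (k_long >= 1) {
    return("single")
  }
  x_int <- intersection_root(k_long, mu_long, mu_short, sigma_long, sigma_short)
  if (!is.na(x_int)) {
    if (ln_n < x_int) "sequential" else "single"
  } else {
    d_short <- (1 - k_long) * dnorm(ln_n, mu_short, sigma_short)
    d_long <- k_long * dnorm(ln_n, mu_long, sigma_long)
    if (d_short > d_long) "sequential" else "single"
  }
}

#' Classify sleep cycles as sequential or single
#'
#' Applies the intersection criterion: a cycle is sequential when
#' `ln(n_total)` lies below the intersection point of the weighted short
#' and long component densities at its `rem_pre`, single otherwise.
#' Cycles with `rem_pre` below the model's domain minimum are labelled
#' `"undefined"`; cycles at `rem_pre` where `k_long = 1` are always
#' single. The annotated tibble also carries the intersection point, the
#' refractory threshold and the REM propensity at REM onset.
#'
#' @param cycles Cycle tibble (needs `rem_pre` and `n_total`).
#' @param m A `remcycle_cgmm` model.
#' @param long_only Use only the long-component CDF for the propensity
#'   column (all-mixture CDF by default).
#' @return `cycles` with added columns `label`, `x_intersect`,
#'   `refractory_threshold` and `propensity`.
#' @export
classify_cycles <- function(cycles, m, long_only = FALSE) {
  stopifnot(is.data.frame(cycles), all(c("rem_pre", "n_total") %in% names(cycles)))
  if (any(cycles$n_total <= 0)) {
    stop_remcycle("Cycles with n_total = 0 cannot be classified (ln undefined).",
                  "remcycle_parameter_error")
  }
  in_dom <- cycles$rem_pre >= m$domain_min
  p <- eval_params_raw(m, cycles$rem_pre)
  ln_n <- log(cycles$n_total)
  label <- rep("undefined", nrow(cycles))
  x_int <- rep(NA_real_, nrow(cycles))
  for (i in which(in_dom)) {
    label[i] <- classify_one(
      p$k_long[i], p$mu_long[i], p$mu_short[i],
      p$sigma_long[i], p$sigma_short[i], ln_n[i]
    )
    if (p$k_long[i] < 1) {
      x_int[i] <- intersection_root(
        p$k_long[i], p$mu_long[i], p$mu_short[i],
        p$sigma_long[i], p$sigma_short[i]
      )
    }
  }
  refr <- rep(NA_real_, nrow(cycles))
  refr[in_dom] <- exp(p$mu_long[in_dom] + p$sigma_long[in_dom] * qnorm(0.01))
  prop <- rep(NA_real_, nrow(cycles))
  if (any(in_dom)) {
    prop[in_dom] <- if (long_only) {
      pnorm((ln_n[in_dom] - p$mu_long[in_dom]) / p$sigma_long[in_dom])
    } else {
      mixture_cdf(m, cycles$rem_pre[in_dom], cycles$n_total[in_dom])
    }
  }
  dplyr::mutate(cycles,
    label = label, x_intersect = x_int,
    refractory_threshold = refr, propensity = prop
  )
}

#' Refractory-period threshold
#'
#' The NREM amount separating the refractory from the permissive period
#' of a single cycle: the 1st percentile of the long component,
#' `exp(mu_long(rem_pre) + sigma_long(rem_pre) * z_0.01)` seconds, where
#' `z_0.01` is the standard-normal 1% quantile. Transitions to REM before
#' this much NREM has accumulated are extremely unlikely.
#'
#' @param m A `remcycle_cgmm` model.
#' @param rem_pre Preceding REM durations (s), in the model domain.
#' @return Thresholds in seconds, one per `rem_pre`.
#' @export
refractory_threshold <- function(m, rem_pre) {
  check_domain(m, rem_pre)
  p <- eval_params_raw(m, rem_pre)
  exp(p$mu_long + p$sigma_long * qnorm(0.01))
}

#' Split a cycle's NREM epochs into refractory and permissive periods
#'
#' Walks the inter-REM interval of a cycle: NREM epochs (microarousals
#' included) accumulate towards `threshold` seconds; epochs up to the one
#' at which the cumulative NREM time first reaches the threshold are
#' refractory, the remaining NREM epochs permissive. Wake epochs belong
#' to neither period but do not reset the accumulator.
#'
#' @param cycle One row of an [extract_cycles()] tibble (needs
#'   `inter_start_index`, `inter_end_index`).
#' @param h The hypnogram the cycle was extracted from.
#' @param threshold Refractory threshold in seconds (>= 0).
#' @return A list with epoch indices `refractory` and `permissive` (into
#'   `h`), and `flagged = TRUE` when the interval holds less NREM than
#'   the threshold (whole interval refractory).
#' @export
segment_cycle <- function(cycle, h, threshold) {
  if (!.is_scalar_num(threshold) || threshold < 0) {
    stop_remcycle("`threshold` must be a single non-negative number.", "remcycle_parameter_error")
  }
  el <- epoch_len(h)
  idx <- seq(cycle$inter_start_index, cycle$inter_end_index)
  is_nrem <- h$state[idx] %in% c("N", "M")
  nrem_idx <- idx[is_nrem]
  # refractory while the NREM time accumulated before the epoch is still
  # below the threshold (so the epoch in which it is first reached counts)
  cum <- cumsum(rep(el, length(nrem_idx)))
  before <- cum - el
  refr <- nrem_idx[before < threshold]
  perm <- setdiff(nrem_idx, refr)
  flagged <- sum(is_nrem) * el < threshold
  if (flagged) {
    warn("Cycle holds less NREM than the refractory threshold; whole interval refractory.")
  }
  list(refractory = refr, permissive = perm, flagged = flagged)
}

#' REM propensity at REM onset
#'
#' The conditional CDF evaluated at the cycle's own `|N|`: the modelled
#' probability of having entered REM sleep within the NREM amount the
#' animal actually accumulated, i.e. the REM propensity at the moment the
#' next REM episode begins.
#'
#' @param m A `remcycle_cgmm` model.
#' @param cycles Cycle tibble (needs `rem_pre`, `n_total`), all in domain.
#' @param long_only Use the long-component CDF instead of the mixture CDF.
#' @return Probabilities in `[0, 1]`, one per cycle.
#' @export
propensity_at_rem_onset <- function(m, cycles, long_only = FALSE) {
  if (long_only) {
    check_domain(m, cycles$rem_pre)
    p <- eval_params_raw(m, cycles$rem_pre)
    pnorm((log(cycles$n_total) - p$mu_long) / p$sigma_long)
  } else {
    mixture_cdf(m, cycles$rem_pre, cycles$n_total)
  }
}

#' Tabulate run lengths of consecutive sequential cycles
#'
#' Summary utility for REM-sequence statistics: counts how many
#' consecutive sequential cycles form each REM sleep sequence.
#'
#' @param labels Character vector of cycle labels in temporal order.
#' @return A tibble with `sequence_length` (number of consecutive
#'   sequential cycles) and `count`.
#' @export
sequential_run_lengths <- function(labels) {
  r <- rle(labels == "sequential")
  lens <- r$lengths[r$values]
  if (length(lens) == 0L) {
    return(tibble(sequence_length = integer(), count = integer()))
  }
  tab <- table(lens)
  tibble(
    sequence_length = as.integer(names(tab)),
    count = as.integer(tab)
  )
}
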