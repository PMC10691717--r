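# Kick samplers. Durations, peak speeds and (in groups) kick lengths are all
# drawn from the same two-exponential family m * (-0.5) * log(r1 r2) with r1,
# r2 uniform in (0,1): a Gamma(shape 2, scale m/2) variable with mean m,
# matching the bell-shaped experimental distributions. Draws are independent
# across kicks and across fish.

.sample_gamma2 <- function(n, mean_value, lower = 0) {
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 16L)
    x <- -0.5 * mean_value * log(stats::runif(m) * stats::runif(m))
    out <- c(out, x[x >= lower])
  }
  out[seq_len(n)]
}

#' Sample kick durations
#'
#' Durations are drawn as `-0.5 * tau_bar * log(r1 r2)` (mean `tau_bar`);
#' draws below `tau_min` are rejected and resampled, reproducing the
#' short-kick deficit seen in the data.
#'
#' @param p a [light_params()] object.
#' @param n number of draws.
#' @param truncate if `FALSE`, the rejection rule is disabled (the raw
#'   two-exponential distribution, mean exactly `tau_bar`).
#' @return kick durations, s.
#' @export
sample_kick_duration <- function(p, n = 1, truncate = TRUE) {
  .sample_gamma2(n, p$tau_bar, if (truncate) p$tau_min else 0)
}

#' Sample peak speeds
#'
#' Same two-exponential family as the duration sampler, with mean `v_bar`
#' and optional lower truncation `v_min`.
#'
#' @inheritParams sample_kick_duration
#' @return peak speeds, mm/s.
#' @export
sample_peak_speed <- function(p, n = 1, truncate = TRUE) {
  .sample_gamma2(n, p$v_bar, if (truncate) p$v_min else 0)
}

#' Kick length from peak speed and duration
#'
#' During the glide the speed decays exponentially with time constant
#' `tau0`, so peak speed, duration and length are linked by
#' `l = v * tau0 * (1 - exp(-tau / tau0))`.
#'
#' @param v_peak peak speed(s), mm/s.
#' @param tau kick duration(s), s.
#' @param tau0 glide decay time, s.
#' @return kick length(s), mm. Always below `v_peak * tau0`.
#' @export
kick_length_from_speed <- function(v_peak, tau, tau0) {
  v_peak * tau0 * (1 - exp(-tau / tau0))
}

#' Sample a complete kick (duration, length, peak speed)
#'
#' The sampling mode depends on group size:
#' * `n_fish == 1`: duration and peak speed are sampled independently and the
#'   length follows from the glide relation.
#' * `n_fish == 2`: the length is sampled from the two-exponential family
#'   whose mean is the distance-modulated mean kick length
#'   [modulated_mean_length()] evaluated at the distance `d` to the
#'   most influential neighbor.
#' * `n_fish >= 3`: the modulation is neglected and the mean is the fixed
#'   mean kick length `l_bar`.
#'
#' In the last two modes the peak speed is derived from the sampled length
#' and duration through the glide relation.
#'
#' @param p a [light_params()] object.
#' @param n_fish group size.
#' @param d distance to the most influential neighbor, mm; required when
#'   `n_fish == 2`.
#' @param n number of kicks to sample.
#' @return a list with numeric components `tau` (s), `l` (mm), `v_peak`
#'   (mm/s), each of length `n`.
#' @export
sample_kick <- function(p, n_fish, d = NULL, n = 1) {
  tau <- sample_kick_duration(p, n)
  if (n_fish <= 1) {
    v <- sample_peak_speed(p, n)
    l <- kick_length_from_speed(v, tau, p$tau0)
  } else {
    mean_l <- if (n_fish == 2) {
      if (is.null(d)) stop("pair mode needs the distance to the neighbor")
      modulated_mean_length(d, p)
    } else {
      p$l_bar
    }
    l <- .sample_gamma2(n, mean_l)
    v <- l / (p$tau0 * (1 - exp(-tau / p$tau0)))
  }
  list(tau = tau, l = l, v_peak = v)
}

#' @rdname sample_kick
#' @return `sample_kick_length()`: kick lengths only, mm.
#' @export
sample_kick_length <- function(p, n_fish, d = NULL, n = 1) {
  sample_kick(p, n_fish, d = d, n = n)$l
}
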