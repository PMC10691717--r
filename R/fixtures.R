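# Synthetic-data generation. Every pipeline stage is testable without any
# external download: cohorts come from the simulator itself, tracker files
# are simulated tracker output (pixels, quantization, label swaps, stops),
# and kick tables can be sampled directly from the model's heading-change
# law at prescribed state distributions, which makes reconstruction tests
# fast and gives exact ground truth.

#' Specification of a synthetic fixture
#'
#' @param scenario one of `"single"`, `"pair"`, `"group5"`, `"group25"`.
#' @param light light condition, lx (see [light_conditions()]); the packaged
#'   defaults for that condition are used unless `params` is given.
#' @param params optional [light_params()] overriding `light`.
#' @param duration simulated duration, s.
#' @param seed integer seed; regeneration is bit-identical.
#' @param swap_prob per-frame probability of a random label permutation when
#'   exporting tracker files.
#' @param stop_windows list of `c(start, end)` times (s) replaced by a full
#'   stop when exporting tracker files.
#' @return object of class `"fixture_spec"`.
#' @export
fixture_spec <- function(scenario = c("single", "pair", "group5", "group25"),
                         light = 50, params = NULL, duration = 120,
                         seed = 1, swap_prob = 0, stop_windows = list()) {
  scenario <- match.arg(scenario)
  n <- c(single = 1L, pair = 2L, group5 = 5L, group25 = 25L)[[scenario]]
  structure(list(scenario = scenario, n_fish = n, light = light,
                 params = params, duration = duration, seed = as.integer(seed),
                 swap_prob = swap_prob, stop_windows = stop_windows),
            class = "fixture_spec")
}

.spec_params <- function(spec) {
  spec$params %||% default_light_params(spec$light, n_fish = spec$n_fish)
}

#' Simulated cohort fixture
#'
#' Runs the simulator for the scenario and returns the trajectory together
#' with its ground-truth kick log and parameters.
#'
#' @param spec a [fixture_spec()].
#' @return a `"school_sim"` object (see [simulate_school()]).
#' @export
make_simulated_cohort <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  simulate_school(.spec_params(spec), n_fish = spec$n_fish,
                  duration = spec$duration, seed = spec$seed)
}

#' Tracker-style raw fixture
#'
#' Converts a simulated cohort to tracker output: pixel coordinates around a
#' tank-center pixel, quantized to whole pixels, optionally corrupted with
#' random per-frame label permutations and full-stop windows (positions
#' frozen at the window start).
#'
#' @param spec a [fixture_spec()].
#' @param center_px pixel coordinates of the tank center.
#' @param scale mm per pixel.
#' @return list with `raw` (data frame `frame`, `id`, `x_px`, `y_px`),
#'   `truth` (the uncorrupted metric trajectory), `center_px`, `scale`.
#' @export
make_tracker_file <- function(spec, center_px = c(540, 540), scale = 0.478) {
  sim <- make_simulated_cohort(spec)
  traj <- sim$trajectory
  # stop windows: freeze positions at the window start
  for (w in spec$stop_windows) {
    inw <- traj$time_s >= w[1L] & traj$time_s <= w[2L]
    for (i in unique(traj$fish_id)) {
      sel <- inw & traj$fish_id == i
      if (any(sel)) {
        traj$x_mm[sel] <- traj$x_mm[sel][1L]
        traj$y_mm[sel] <- traj$y_mm[sel][1L]
      }
    }
  }
  raw <- data.frame(frame = traj$frame, id = traj$fish_id,
                    x_px = round(traj$x_mm / scale + center_px[1L]),
                    y_px = round(traj$y_mm / scale + center_px[2L]))
  if (spec$swap_prob > 0 && spec$n_fish > 1L) {
    set.seed(spec$seed + 1L)
    for (fr in unique(raw$frame)) {
      if (stats::runif(1L) < spec$swap_prob) {
        sel <- which(raw$frame == fr)
        raw$id[sel] <- raw$id[sel][sample(length(sel))]
      }
    }
  }
  list(raw = raw, truth = sim$trajectory, center_px = center_px,
       scale = scale)
}

#' Kick-table fixture sampled directly from the heading-change law
#'
#' Draws kick-level records with known interaction parameters, bypassing the
#' full simulation: state variables are sampled from prescribed marginals
#' (uniform by default) and the per-kick heading change follows the model
#' exactly (spontaneous Gaussian noise plus wall or social terms). This
#' gives reconstruction tests a fast, exact ground truth.
#'
#' @param p a [light_params()] object: the ground truth.
#' @param n_kicks number of kicks.
#' @param mode `"wall"` (single fish: states `(r_w, theta_w)`, heading
#'   change = noise + wall term) or `"pair"` (states `(d, psi, delta_phi)`
#'   far from the wall, heading change = noise + social term, kick lengths
#'   drawn with the distance-modulated mean).
#' @param seed integer seed.
#' @param r_max upper bound of the uniform `r_w` marginal (wall mode), mm.
#' @param d_max upper bound of the uniform `d` marginal (pair mode), mm.
#' @return a kick table data frame matching the [kick_table()] layout.
#' @export
make_kick_table <- function(p, n_kicks, mode = c("wall", "pair"), seed = 1,
                            r_max = 120, d_max = 200) {
  mode <- match.arg(mode)
  set.seed(seed)
  n <- n_kicks
  tau <- sample_kick_duration(p, n)
  if (mode == "wall") {
    r_w <- stats::runif(n, 0, r_max)
    theta_w <- stats::runif(n, -pi, pi)
    dphi <- spontaneous_dphi(r_w, p) + wall_dphi(r_w, theta_w, p)
    v <- sample_peak_speed(p, n)
    data.frame(fish_id = 1L, t_start = cumsum(tau) - tau, tau = tau,
               length = kick_length_from_speed(v, tau, p$tau0), v_peak = v,
               r_w = r_w, theta_w = theta_w, dphi = dphi)
  } else {
    d <- stats::runif(n, 0, d_max)
    psi <- stats::runif(n, -pi, pi)
    delta_phi <- stats::runif(n, -pi, pi)
    r_w <- stats::runif(n, 80, 200)    # far from the wall by construction
    s <- list(d = d, psi = psi, delta_phi = delta_phi)
    dphi <- p$gamma_R * stats::rnorm(n) + social_dphi(s, p)
    len <- .sample_gamma2_mean(modulated_mean_length(d, p))
    data.frame(fish_id = 1L, t_start = cumsum(tau) - tau, tau = tau,
               length = len,
               v_peak = len / (p$tau0 * (1 - exp(-tau / p$tau0))),
               r_w = r_w, theta_w = stats::runif(n, -pi, pi),
               dphi = dphi, d = d, psi = psi, delta_phi = delta_phi)
  }
}

# one two-exponential draw per element, with element-wise means
.sample_gamma2_mean <- function(mean_values) {
  n <- length(mean_values)
  -0.5 * mean_values * log(stats::runif(n) * stats::runif(n))
}
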