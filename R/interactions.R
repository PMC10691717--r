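# Analytic interaction functions of the burst-and-coast model.
#
# Each heading-change term factorizes into a radial intensity times angular
# profiles; angular profiles carry unit mean square (see normalize_angular),
# the radial factor carries the intensity. The universal angular shapes below
# (coefficients 0.8, 0.33, 0.6/0.4, 1.18/0.49) were found to be common to all
# light conditions; only the radial intensities and ranges vary with light.

# cache of the four normalization constants; filled lazily
.norm_cache <- new.env(parent = emptyenv())

.norm_const <- function(key, profile) {
  if (is.null(.norm_cache[[key]])) {
    .norm_cache[[key]] <- normalize_angular(profile)
  }
  .norm_cache[[key]]
}

.ow_raw  <- function(th)  sin(th) * (1 + 0.8 * cos(2 * th))
.oatt_raw <- function(ps) sin(ps) * (1 - 0.33 * cos(ps))
.eatt_raw <- function(dp) 1 - 0.6 * cos(dp) - 0.4 * cos(2 * dp)
.oali_raw <- function(dp) sin(dp) * (1 + 0.33 * cos(dp))
.eali_raw <- function(ps) 1 + 1.18 * cos(ps) - 0.49 * cos(2 * ps)

#' Pairwise state of two fish
#'
#' The relative state of a focal fish and one neighbor is given by the
#' distance `d` between them, the viewing angle `psi` under which the focal
#' fish sees the neighbor (angle from the focal heading to the focal-to-
#' neighbor direction, positive counter-clockwise), and their relative
#' orientation `delta_phi` (neighbor heading minus focal heading). Both
#' angles are wrapped to (-pi, pi].
#'
#' @param d inter-fish distance(s), mm (>= 0).
#' @param psi viewing angle(s), rad.
#' @param delta_phi relative orientation(s), rad.
#' @return a data frame of class `"pair_state"` with columns `d`, `psi`,
#'   `delta_phi`.
#' @export
pair_state <- function(d, psi, delta_phi) {
  if (any(d < 0)) stop("pair distances must be >= 0")
  structure(
    data.frame(d = d, psi = wrap_angle(psi), delta_phi = wrap_angle(delta_phi)),
    class = c("pair_state", "data.frame")
  )
}

#' Radial intensity of the wall repulsion
#'
#' `f_w(r_w) = gamma_w * exp(-(r_w / l_w)^2)`: a Gaussian fall-off with the
#' distance to the wall, of intensity `gamma_w` and range `l_w`.
#'
#' @param r_w distance(s) to the wall, mm (>= 0).
#' @param p a [light_params()] object.
#' @return dimensionless intensity, strictly decreasing in `r_w`.
#' @export
wall_force <- function(r_w, p) {
  if (any(r_w < 0)) stop("wall distance r_w must be >= 0")
  p$gamma_w * exp(-(r_w / p$l_w)^2)
}

#' Angular profile of the wall repulsion
#'
#' `O_w(theta_w)` is proportional to `sin(theta_w) * (1 + 0.8 cos(2 theta_w))`,
#' normalized to unit mean square over a period. It is odd: the fish turns
#' with the same intensity but opposite sign depending on which side the wall
#' is on (`theta_w > 0`: wall on the right, positive = counter-clockwise turn
#' away from it).
#'
#' @param theta_w relative orientation(s) to the wall, rad.
#' @return dimensionless profile value(s).
#' @export
wall_angular <- function(theta_w) {
  .norm_const("ow", .ow_raw) * .ow_raw(theta_w)
}

#' Wall contribution to the heading change
#'
#' @param r_w distance(s) to the wall, mm.
#' @param theta_w relative orientation(s) to the wall, rad.
#' @param p a [light_params()] object.
#' @return heading change contribution, rad.
#' @export
wall_dphi <- function(r_w, theta_w, p) {
  wall_force(r_w, p) * wall_angular(theta_w)
}

#' Attraction contribution to the heading change
#'
#' `delta_phi_Att = f_Att(d) O_Att(psi) E_Att(delta_phi)` with
#' `f_Att(d) = gamma_att (d/d_att - 1) / (1 + (d/l_att)^2)` (repulsive below
#' `d_att`), `O_Att(psi) ~ sin(psi)(1 - 0.33 cos psi)` (odd), and
#' `E_Att(delta_phi) ~ 1 - 0.6 cos(delta_phi) - 0.4 cos(2 delta_phi)` (even).
#'
#' @param s a [pair_state()] (or data frame with columns `d`, `psi`,
#'   `delta_phi`).
#' @param p a [light_params()] object.
#' @return heading change contribution(s), rad.
#' @export
attraction_dphi <- function(s, p) {
  f <- p$gamma_att * (s$d / p$d_att - 1) / (1 + (s$d / p$l_att)^2)
  f * .norm_const("oatt", .oatt_raw) * .oatt_raw(s$psi) *
    .norm_const("eatt", .eatt_raw) * .eatt_raw(s$delta_phi)
}

#' Alignment contribution to the heading change
#'
#' `delta_phi_Ali = f_Ali(d) O_Ali(delta_phi) E_Ali(psi)` with
#' `f_Ali(d) = gamma_ali (d/d_ali) exp(-(d/l_ali)^2)` (vanishing at contact,
#' maximal at `l_ali/sqrt(2)`), `O_Ali(delta_phi) ~ sin(delta_phi)(1 + 0.33
#' cos delta_phi)` (odd), and `E_Ali(psi) ~ 1 + 1.18 cos psi - 0.49 cos(2
#' psi)` (even: alignment does not depend on the side the neighbor is on).
#'
#' @inheritParams attraction_dphi
#' @return heading change contribution(s), rad.
#' @export
alignment_dphi <- function(s, p) {
  f <- p$gamma_ali * (s$d / p$d_ali) * exp(-(s$d / p$l_ali)^2)
  f * .norm_const("oali", .oali_raw) * .oali_raw(s$delta_phi) *
    .norm_const("eali", .eali_raw) * .eali_raw(s$psi)
}

#' Social (attraction + alignment) contribution to the heading change
#'
#' The pairwise social term is the sum of the attraction and alignment
#' contributions.
#'
#' @inheritParams attraction_dphi
#' @return heading change contribution(s), rad.
#' @export
social_dphi <- function(s, p) {
  attraction_dphi(s, p) + alignment_dphi(s, p)
}

#' Influence of a neighbor on the focal fish
#'
#' The influence of neighbor j on fish i is the absolute value of j's
#' pairwise social contribution to i's instantaneous heading change. In
#' groups, each fish attends only to its `k` most influential neighbors.
#'
#' @inheritParams attraction_dphi
#' @return nonnegative influence value(s).
#' @export
influence <- function(s, p) {
  abs(social_dphi(s, p))
}

#' Spontaneous (random) heading change
#'
#' Gaussian heading noise whose standard deviation is reduced near the wall:
#' `delta_phi_R = gamma_R (1 - alpha exp(-(r_w / l_w_noise)^2)) g`, `g` a
#' standard Gaussian draw. Far from the wall the sd tends to `gamma_R`; at
#' the wall it is `gamma_R (1 - alpha)`.
#'
#' @param r_w distance(s) to the wall, mm (>= 0).
#' @param p a [light_params()] object.
#' @param n number of draws; defaults to `length(r_w)`.
#' @return `n` heading-change draws, rad. Uses R's global RNG stream.
#' @export
spontaneous_dphi <- function(r_w, p, n = length(r_w)) {
  spontaneous_sd(r_w, p) * stats::rnorm(n)
}

#' @rdname spontaneous_dphi
#' @return `spontaneous_sd()`: the closed-form standard deviation, rad.
#' @export
spontaneous_sd <- function(r_w, p) {
  if (any(r_w < 0)) stop("wall distance r_w must be >= 0")
  p$gamma_R * (1 - p$alpha * exp(-(r_w / p$l_w_noise)^2))
}

#' Distance-modulated mean kick length
#'
#' When two fish swim together the mean kick length depends on the distance
#' to the neighbor: `F_m(d) = l_m - gamma_m (d + d_m) exp(-d / l_m)`. It
#' saturates at `l_m` for large distance and is smallest (kicks shortest) at
#' `d = l_m - d_m`.
#'
#' @param d distance(s) to the most influential neighbor, mm (>= 0).
#' @param p a [light_params()] object.
#' @return mean kick length(s), mm.
#' @export
modulated_mean_length <- function(d, p) {
  if (any(d < 0)) stop("distance d must be >= 0")
  p$l_m - p$gamma_m * (d + p$d_m) * exp(-d / p$l_m)
}
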