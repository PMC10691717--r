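#' Wrap angles into (-pi, pi]
#'
#' All angular state variables in the package (headings, wall angles, viewing
#' angles, relative orientations) live on the half-open interval (-pi, pi].
#' `wrap_angle()` maps any finite angle onto that interval, modulo 2*pi.
#'
#' @param a numeric vector of angles, radians.
#' @return numeric vector of the same length, each element in (-pi, pi] and
#'   congruent to the input modulo 2*pi.
#' @examples
#' wrap_angle(c(0, 3 * pi, -pi))
#' @export
wrap_angle <- function(a) {
  if (!is.numeric(a) || any(!is.finite(a))) {
    stop("wrap_angle() requires finite numeric input")
  }
  w <- a - 2 * pi * floor(a / (2 * pi) + 0.5)
  # floor-based wrap yields [-pi, pi); move -pi to +pi for the (-pi, pi] convention
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w
}

#' Normalization constant for an angular interaction profile
#'
#' Angular factors of the interaction functions are normalized so that the
#' mean of the squared function over a full period equals one:
#' (1/2pi) * integral of (A f)^2 over (-pi, pi] = 1. This fixes the scale
#' convention: angular profiles are dimensionless with unit mean square, and
#' the radial factor carries the intensity of the interaction.
#'
#' @param f a vectorized function of one angle (radians).
#' @return the positive scalar A such that `A * f` has unit mean square.
#' @details The integral is computed by adaptive quadrature
#'   ([stats::integrate()]) with absolute tolerance 1e-10. An identically
#'   zero (or numerically zero) profile is an error: it cannot be normalized.
#' @examples
#' normalize_angular(function(th) sin(th))          # sqrt(2)
#' normalize_angular(function(th) sin(th) * (1 + 0.8 * cos(2 * th)))
#' @export
normalize_angular <- function(f) {
  stopifnot(is.function(f))
  msq <- stats::integrate(function(th) f(th)^2, -pi, pi,
                          abs.tol = 1e-10, rel.tol = 1e-10,
                          subdivisions = 500L)$value / (2 * pi)
  if (msq < 1e-14) {
    stop("cannot normalize an (almost) identically zero angular function")
  }
  1 / sqrt(msq)
}
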