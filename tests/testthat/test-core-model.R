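test_that("wrap_angle maps onto (-pi, pi] and preserves the angle mod 2pi", {
  expect_identical(wrap_angle(0), 0)
  expect_equal(wrap_angle(3 * pi), pi)          # boundary maps to +pi
  # brute-force oracle: repeated +/- 2pi shifts
  shift_oracle <- function(a) {
    while (a > pi) a <- a - 2 * pi
    while (a <= -pi) a <- a + 2 * pi
    a
  }
  expect_equal(wrap_angle(-7.5 * pi / 2), shift_oracle(-7.5 * pi / 2))
  set.seed(42)
  a <- runif(200, -50, 50)
  w <- wrap_angle(a)
  expect_true(all(w > -pi & w <= pi))
  expect_equal(sin(w), sin(a))
  expect_equal(cos(w), cos(a))
  expect_error(wrap_angle(Inf), "finite")
})

test_that("normalize_angular reproduces printed and derived constants", {
  # printed constant of the combined wall angular profile
  expect_equal(normalize_angular(function(th) sin(th) * (1 + 0.8 * cos(2 * th))),
               1.9612, tolerance = 5e-5)
  expect_equal(normalize_angular(sin), sqrt(2), tolerance = 1e-8)
  # derived via an independent Riemann-sum oracle
  f <- function(th) sin(th) * (1 - 0.33 * cos(th))
  expect_equal(normalize_angular(f), riemann_norm_const(f), tolerance = 1e-4)
  expect_error(normalize_angular(function(th) 0 * th), "zero")
})

test_that("all four angular profiles have unit mean square and the stated parity", {
  th <- seq(-pi, pi, length.out = 1001)[-1L]
  profs <- list(
    odd1 = wall_angular,
    odd2 = function(a) attraction_dphi(pair_state(100, a, 0.7), quick_params()),
    odd3 = function(a) alignment_dphi(pair_state(100, 0.7, a), quick_params())
  )
  for (f in profs) expect_equal(f(-th), -f(th))            # strictly odd
  # even factors: even in the complementary angle
  p <- quick_params()
  expect_equal(attraction_dphi(pair_state(100, 0.7, th), p),
               attraction_dphi(pair_state(100, 0.7, -th), p))
  expect_equal(alignment_dphi(pair_state(100, th, 0.7), p),
               alignment_dphi(pair_state(100, -th, 0.7), p))
  # unit mean square of each normalized profile (Riemann assertion)
  raw <- list(
    function(a) sin(a) * (1 + 0.8 * cos(2 * a)),
    function(a) sin(a) * (1 - 0.33 * cos(a)),
    function(a) 1 - 0.6 * cos(a) - 0.4 * cos(2 * a),
    function(a) sin(a) * (1 + 0.33 * cos(a)),
    function(a) 1 + 1.18 * cos(a) - 0.49 * cos(2 * a)
  )
  for (f in raw) {
    A <- normalize_angular(f)
    expect_equal(mean((A * f(th))^2), 1, tolerance = 1e-5)
  }
})

test_that("wall interaction has the closed-form values and monotone decay", {
  p <- quick_params(gamma_w = 2, l_w = 60)
  expect_equal(wall_force(0, p), 2)
  expect_equal(wall_force(60, p), 2 * exp(-1))
  expect_equal(wall_force(120, p), 2 * exp(-4))
  r <- seq(0, 200, by = 1)
  expect_true(all(diff(wall_force(r, p)) < 0))
  expect_error(wall_force(-1, p), ">= 0")
  # angular profile: odd, printed value at pi/2
  expect_equal(wall_angular(0), 0)
  expect_equal(wall_angular(pi / 2), 1.9612 * (1 - 0.8), tolerance = 1e-4)
  expect_equal(wall_angular(-pi / 4), -wall_angular(pi / 4))
})

test_that("attraction vanishes at its sign-change distance and at psi = 0", {
  p <- quick_params()
  expect_equal(attraction_dphi(pair_state(p$d_att, 1.1, 0.4), p), 0)
  expect_equal(attraction_dphi(pair_state(120, 0, 0.4), p), 0)
  # factor-by-factor oracle at d = 2 d_att, psi = pi/2, delta_phi = 0
  f <- p$gamma_att * (2 - 1) / (1 + (2 * p$d_att / p$l_att)^2)
  o <- riemann_norm_const(function(a) sin(a) * (1 - 0.33 * cos(a))) * 1
  e <- riemann_norm_const(function(a) 1 - 0.6 * cos(a) - 0.4 * cos(2 * a)) *
    (1 - 0.6 - 0.4)
  expect_equal(attraction_dphi(pair_state(2 * p$d_att, pi / 2, 0), p),
               f * o * e, tolerance = 1e-3)
  # sign change across d_att
  lo <- attraction_dphi(pair_state(p$d_att - 5, pi / 2, 1), p)
  hi <- attraction_dphi(pair_state(p$d_att + 5, pi / 2, 1), p)
  expect_lt(lo, 0)
  expect_gt(hi, 0)
})

test_that("alignment vanishes at contact and peaks at l_ali/sqrt(2)", {
  p <- quick_params()
  expect_equal(alignment_dphi(pair_state(0, 0.5, 0.8), p), 0)
  expect_equal(alignment_dphi(pair_state(80, 0.5, 0), p), 0)
  f_ali <- function(d) p$gamma_ali * (d / p$d_ali) * exp(-(d / p$l_ali)^2)
  d_star <- stats::optimize(f_ali, c(1, 500), maximum = TRUE)$maximum
  expect_equal(d_star, p$l_ali / sqrt(2), tolerance = 1e-4)
})

test_that("social term is additive and its parity algebra isolates attraction", {
  p <- quick_params()
  s <- grid_pair_states()
  expect_equal(social_dphi(s, p),
               attraction_dphi(s, p) + alignment_dphi(s, p))
  expect_equal(social_dphi(pair_state(100, 0, 0), p), 0)
  # four-term symmetrization recovers the attraction component exactly
  Fpp <- social_dphi(s, p)
  Fmp <- social_dphi(pair_state(s$d, -s$psi, s$delta_phi), p)
  Fpm <- social_dphi(pair_state(s$d, s$psi, -s$delta_phi), p)
  Fmm <- social_dphi(pair_state(s$d, -s$psi, -s$delta_phi), p)
  expect_equal((Fpp - Fmp + Fpm - Fmm) / 4, attraction_dphi(s, p))
  expect_equal((Fpp + Fmp - Fpm - Fmm) / 4, alignment_dphi(s, p))
  # influence: absolute social contribution, symmetric under full mirror
  expect_equal(influence(s, p), abs(Fpp))
  expect_equal(influence(pair_state(s$d, -s$psi, -s$delta_phi), p),
               influence(s, p))
})

test_that("spontaneous heading noise has the closed-form wall-reduced sd", {
  p <- quick_params(gamma_R = 0.4, alpha = 0.6, l_w = 50, l_w_noise = 50)
  expect_equal(spontaneous_sd(1e6, p), 0.4, tolerance = 1e-6)
  expect_equal(spontaneous_sd(0, p), 0.4 * (1 - 0.6))
  set.seed(1)
  draws <- spontaneous_dphi(rep(50, 1e6), p)
  sd_expect <- 0.4 * (1 - 0.6 * exp(-1))
  # 3 Monte-Carlo sigmas for an sd estimate: sd/sqrt(2n)
  expect_lt(abs(sd(draws) - sd_expect), 3 * sd_expect / sqrt(2e6))
  expect_lt(abs(mean(draws)), 3 * sd_expect / sqrt(1e6))
})

test_that("kick-length modulation saturates and dips at l_m - d_m", {
  p <- quick_params(gamma_m = 1.2, l_m = 60, d_m = 10)
  expect_equal(modulated_mean_length(1e6, p), 60)
  expect_equal(modulated_mean_length(0, p), 60 - 1.2 * 10)
  d_star <- stats::optimize(function(d) modulated_mean_length(d, p),
                            c(0, 400))$minimum
  expect_equal(d_star, p$l_m - p$d_m, tolerance = 1e-3)
  expect_error(modulated_mean_length(-5, p), ">= 0")
})

test_that("parameter containers validate and round-trip through flat files", {
  expect_error(light_params(alpha = 1.2), "alpha")
  expect_error(light_params(tau_bar = 0.1, tau_min = 0.2), "tau_bar")
  expect_error(light_params(l_att = -5), "positive")
  expect_error(arena(-1))
  expect_error(default_light_params(7), "unknown light")
  p <- default_light_params(1.5, 5)
  f <- tempfile(fileext = ".conf")
  write_light_params(p, f)
  q <- read_light_params(f)
  expect_equal(unclass(q), unclass(p))
  writeLines("nonsense = 1", f)
  expect_error(read_light_params(f), "unknown parameter")
  # packaged parameter files agree with the in-code defaults
  pkg <- system.file("extdata/params/N5_1.5lx.conf", package = "fishschool")
  expect_equal(unclass(read_light_params(pkg)), unclass(p))
})
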