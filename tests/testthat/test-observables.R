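test_that("dispersion matches closed forms and a direct-summation oracle", {
  expect_equal(dispersion(5, -3), 0)
  expect_equal(dispersion(c(0, 10), c(0, 0)), 5)   # two fish: s/2
  set.seed(4)
  x <- rnorm(40, sd = 30); y <- rnorm(40, sd = 30)
  oracle <- sqrt(sum((x - mean(x))^2 + (y - mean(y))^2) / 40)
  expect_equal(dispersion(x, y), oracle)
})

test_that("polarization is 1 for aligned, 0 for opposed, ~sqrt(pi)/(2 sqrt(N)) for random", {
  expect_equal(polarization(rep(0.7, 8)), 1)
  expect_equal(polarization(c(1, 1 + pi)), 0, tolerance = 1e-12)
  set.seed(8)
  N <- 5
  P <- replicate(1e5, polarization(runif(N, -pi, pi)))
  # Rayleigh: E|sum of N unit steps| ~ sqrt(pi N)/2 for large N; Monte-Carlo
  # value asserted with a generous band since N = 5 is far from asymptopia
  expect_equal(mean(P), sqrt(pi) / (2 * sqrt(N)), tolerance = 0.06)
  expect_true(all(P >= 0 & P <= 1))
})

test_that("milling detects coherent rotation independent of direction", {
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  x <- 100 * cos(th); y <- 100 * sin(th)
  # tangential counter-clockwise: velocity perpendicular to radius
  expect_equal(milling(x, y, -sin(th), cos(th)), 1, tolerance = 1e-12)
  expect_equal(milling(x, y, sin(th), -cos(th)), 1, tolerance = 1e-12)  # cw
  expect_equal(milling(x, y, cos(th), sin(th)), 0, tolerance = 1e-12)  # radial
  set.seed(2)
  vx <- rnorm(8); vy <- rnorm(8)
  phi_bar <- atan2(vy - mean(vy), vx - mean(vx))
  theta_bar <- atan2(y - mean(y), x - mean(x))
  expect_equal(milling(x, y, vx, vy), abs(mean(sin(phi_bar - theta_bar))))
})

test_that("wall state follows the package angle conventions", {
  ws <- wall_state(0, 0, 1.3)
  expect_equal(ws$r_w, 250)
  # fish on +x axis heading +y: tangential counter-clockwise
  ws <- wall_state(125, 0, pi / 2)
  expect_equal(ws$r_w, 125)
  expect_equal(ws$theta_w, pi / 2)
  # mirror y -> -y flips theta_w
  set.seed(6)
  x <- runif(50, -150, 150); y <- runif(50, -150, 150); h <- runif(50, -pi, pi)
  a <- wall_state(x, y, h)
  b <- wall_state(x, -y, -h)
  expect_equal(b$theta_w, -a$theta_w)
  expect_equal(b$r_w, a$r_w)
  expect_error(wall_state(300, 0, 0), "outside")
})

test_that("pair state and nearest-neighbor distances match brute force", {
  # collinear pair: neighbor straight ahead
  s <- pair_state_of(list(x = 0, y = 0, heading = 0),
                     list(x = 50, y = 0, heading = 0))
  expect_equal(s$psi, 0)
  expect_equal(s$delta_phi, 0)
  expect_equal(s$d, 50)
  set.seed(5)
  x <- runif(5, -100, 100); y <- runif(5, -100, 100)
  nnd <- nearest_neighbor_distances(x, y)
  for (i in 1:5) {
    dd <- sqrt((x[i] - x[-i])^2 + (y[i] - y[-i])^2)
    expect_equal(nnd[[i]], min(dd))
  }
})

test_that("the geometrical leader is the fish with the larger viewing angle", {
  # one fish directly ahead of the other: the front fish leads
  front <- list(x = 100, y = 0, heading = 0, id = 1)
  back <- list(x = 0, y = 0, heading = 0, id = 2)
  lf <- leader_follower(list(front, back))
  expect_equal(lf$leader, 1)
  expect_false(lf$tie)
  # symmetric side-by-side: tie, flagged, lower id wins
  a <- list(x = 0, y = 25, heading = 0, id = 3)
  b <- list(x = 0, y = -25, heading = 0, id = 4)
  lf <- leader_follower(list(a, b))
  expect_true(lf$tie)
  expect_equal(lf$leader, 3)
  # random states against the definition
  set.seed(9)
  for (q in 1:20) {
    s1 <- list(x = runif(1, -99, 99), y = runif(1, -99, 99),
               heading = runif(1, -pi, pi), id = 1)
    s2 <- list(x = runif(1, -99, 99), y = runif(1, -99, 99),
               heading = runif(1, -pi, pi), id = 2)
    lf <- leader_follower(list(s1, s2))
    psi1 <- abs(pair_state_of(s1, s2)$psi)
    psi2 <- abs(pair_state_of(s2, s1)$psi)
    expect_equal(lf$leader, if (psi1 >= psi2) 1 else 2)
  }
})

test_that("observables are invariant under rotation, translation and mirror", {
  set.seed(12)
  n <- 7
  x <- runif(n, -120, 120); y <- runif(n, -120, 120); h <- runif(n, -pi, pi)
  vx <- cos(h) * 80; vy <- sin(h) * 80
  rot <- 1.1
  xr <- x * cos(rot) - y * sin(rot); yr <- x * sin(rot) + y * cos(rot)
  vxr <- vx * cos(rot) - vy * sin(rot); vyr <- vx * sin(rot) + vy * cos(rot)
  expect_equal(dispersion(xr, yr), dispersion(x, y))
  expect_equal(dispersion(x + 31, y - 12), dispersion(x, y))
  expect_equal(polarization(h + rot), polarization(h))
  expect_equal(milling(xr, yr, vxr, vyr), milling(x, y, vx, vy))
  # mirror preserves D, P, M
  expect_equal(milling(x, -y, vx, -vy), milling(x, y, vx, vy))
  expect_equal(polarization(-h), polarization(h))
  # NND translation invariance
  expect_equal(nearest_neighbor_distances(x + 5, y - 9),
               nearest_neighbor_distances(x, y))
  # bounds on arbitrary input
  expect_true(polarization(runif(100, -10, 10)) <= 1)
  expect_true(milling(x, y, vx, vy) <= 1)
})

test_that("per-frame observables agree with direct per-frame computation", {
  p <- default_light_params(50, 5)
  sim <- simulate_school(p, 5, 30, seed = 4)
  obs <- school_observables(sim$trajectory)
  expect_true(all(obs$D >= 0 & obs$D <= 250))
  expect_true(all(obs$P >= 0 & obs$P <= 1))
  expect_true(all(obs$M >= 0 & obs$M <= 1))
  # spot-check one frame against direct formulas
  fr <- 400
  z <- sim$trajectory[sim$trajectory$frame == fr, ]
  expect_equal(obs$D[obs$frame == fr], dispersion(z$x_mm, z$y_mm))
  expect_equal(obs$P[obs$frame == fr], polarization(z$heading_rad))
  expect_equal(obs$nnd[obs$frame == fr],
               mean(nearest_neighbor_distances(z$x_mm, z$y_mm)))
  s <- summarize_observables(list(obs, obs))
  expect_identical(s$observable, c("r_w", "nnd", "D", "P", "M"))
  expect_equal(s$se, rep(0, 5))    # identical runs: zero spread
})
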