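test_that("pixel conversion centers and scales, and round-trips within half a pixel", {
  raw <- data.frame(frame = 1, id = 1,
                    x_px = c(540, 640, 540), y_px = c(540, 540, 440))
  mm <- pixels_to_mm(raw, center_px = c(540, 540))
  expect_equal(mm$x_mm, c(0, 47.8, 0))
  expect_equal(mm$y_mm, c(0, 0, -47.8))
  # round trip mm -> px (quantized) -> mm
  set.seed(1)
  x <- runif(100, -200, 200)
  px <- round(x / 0.478 + 540)
  back <- 0.478 * (px - 540)
  expect_true(all(abs(back - x) <= 0.478 / 2 + 1e-9))
})

test_that("the assignment solver matches exhaustive permutation search", {
  set.seed(3)
  for (n in c(2, 3, 5)) {
    for (rep in 1:10) {
      cost <- matrix(runif(n * n), n, n)
      a <- lap_solve(cost)
      expect_equal(sum(cost[cbind(seq_len(n), a)]),
                   brute_assignment(cost)$cost)
      expect_setequal(a, seq_len(n))
    }
  }
})

test_that("identity resolution repairs label swaps for well-separated fish", {
  # 5 fish on smooth non-crossing paths, labels permuted at random each frame
  set.seed(10)
  nf <- 120
  t <- seq(0, (nf - 1) * 0.04, by = 0.04)
  truth <- do.call(rbind, lapply(1:5, function(i) {
    data.frame(frame = seq_len(nf), fish_id = i,
               x_mm = 150 * cos(0.4 * t + 2 * pi * i / 5),
               y_mm = 150 * sin(0.4 * t + 2 * pi * i / 5))
  }))
  shuffled <- truth
  for (fr in 2:nf) {
    sel <- which(shuffled$frame == fr)
    perm <- sample(5)
    shuffled$fish_id[sel] <- perm[shuffled$fish_id[sel]]
  }
  res <- resolve_identities(shuffled)
  got <- res$tracks[order(res$tracks$frame, res$tracks$fish_id), ]
  want <- truth[order(truth$frame, truth$fish_id), ]
  expect_equal(got$x_mm, want$x_mm)
  expect_equal(got$y_mm, want$y_mm)
  # never increases total displacement relative to the input labeling
  disp <- function(tr) {
    tr <- tr[order(tr$fish_id, tr$frame), ]
    sum(abs(diff(tr$x_mm))) + sum(abs(diff(tr$y_mm)))
  }
  expect_lte(disp(res$tracks), disp(shuffled))
  # a single swapped frame in a pair is repaired
  pair <- data.frame(frame = rep(1:3, each = 2), fish_id = c(1, 2, 2, 1, 1, 2),
                     x_mm = c(0, 100, 0, 100, 0, 100), y_mm = 0)
  fixed <- resolve_identities(pair)$tracks
  expect_equal(fixed$x_mm[fixed$fish_id == 1], rep(0, 3))
})

test_that("incomplete frames split the data into logged segments", {
  tr <- data.frame(frame = rep(1:5, each = 2), fish_id = rep(1:2, 5),
                   x_mm = rnorm(10), y_mm = rnorm(10))
  tr <- tr[!(tr$frame == 3 & tr$fish_id == 2), ]   # fish 2 missing at frame 3
  expect_message(res <- resolve_identities(tr), "incomplete")
  expect_equal(nrow(res$segments), 2)
  expect_false(3 %in% res$tracks$frame)
})

test_that("activity filter removes long stops but keeps short lulls", {
  t <- seq(0, 40, by = 0.04)
  mk <- function(speed_profile) {
    x <- cumsum(speed_profile * 0.04)
    data.frame(frame = seq_along(t), time_s = t, fish_id = 1, x_mm = x, y_mm = 0)
  }
  # constant 100 mm/s: one full active segment
  seg <- activity_filter(mk(rep(100, length(t))))
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start_frame, 1)
  expect_equal(seg$end_frame, length(t))
  # 3 s full stop in the middle: split into two segments
  v <- rep(100, length(t)); v[t >= 20 & t < 23] <- 0
  seg <- activity_filter(mk(v))
  expect_equal(nrow(seg), 2)
  expect_lt(seg$end_time[1], 21)
  expect_gt(seg$start_time[2], 22)
  # 1.5 s lull: below the duration threshold, kept
  v <- rep(100, length(t)); v[t >= 20 & t < 21.5] <- 0
  seg <- activity_filter(mk(v))
  expect_equal(nrow(seg), 1)
})

test_that("kick detection recovers simulator onsets and is deterministic", {
  p <- default_light_params(0.5, 1)     # fast glide decay: sharp onsets
  sim <- simulate_school(p, 1, 300, seed = 3)
  tr <- sim$trajectory[, c("frame", "time_s", "x_mm", "y_mm")]
  kk <- detect_kicks(tr)
  expect_identical(kk, detect_kicks(tr))
  err <- vapply(sim$kicks$t_start,
                function(t) min(abs(kk$t_start - t)), numeric(1))
  expect_gt(mean(err <= 0.04 + 1e-9), 0.8)   # onsets within +/- 1 frame
  expect_lt(median(err), 0.04 + 1e-9)
  # false-positive rate
  fp <- vapply(kk$t_start,
               function(t) min(abs(sim$kicks$t_start - t)), numeric(1))
  expect_lt(mean(fp > 0.06), 0.05)
  # all phases respect the merge rule after segmentation
  expect_true(all(kk$tau >= 0.08))
  # per-kick summaries: lengths bounded by the within-kick path length
  path_len <- function(q) {
    i <- which(tr$time_s >= kk$t_start[q] - 1e-9 &
                 tr$time_s <= kk$t_start[q] + kk$tau[q] + 1e-9)
    sum(sqrt(diff(tr$x_mm[i])^2 + diff(tr$y_mm[i])^2))
  }
  for (q in sample(nrow(kk), 20)) {
    expect_lte(kk$length[q], path_len(q) + 1e-6)
  }
})

test_that("constant-speed input yields no kicks and short dips are merged", {
  t <- seq(0, 20, by = 0.04)
  traj <- data.frame(frame = seq_along(t), time_s = t,
                     x_mm = 100 * t, y_mm = 0)
  expect_equal(nrow(detect_kicks(traj)), 0)
  expect_error(detect_kicks(traj[1:5, ]), "shorter than")
})

test_that("mirror augmentation doubles the data and enforces odd symmetry", {
  p <- quick_params()
  kk <- make_kick_table(p, 2000, "wall", seed = 13)
  aug <- mirror_augment(kk)
  expect_equal(nrow(aug), 2 * nrow(kk))
  expect_equal(sum(aug$mirrored), nrow(kk))
  # the augmented set is exactly symmetric: odd moments vanish
  expect_equal(mean(aug$theta_w), 0, tolerance = 1e-12)
  expect_equal(mean(aug$dphi), 0, tolerance = 1e-12)
  # trajectory mirroring flips y and heading
  tr <- data.frame(frame = 1:3, time_s = 0:2, fish_id = 1,
                   x_mm = 1:3, y_mm = c(1, -2, 3), heading_rad = c(0.5, 1, -1))
  m <- mirror_augment(tr)
  expect_equal(m$y_mm[4:6], -tr$y_mm)
  expect_equal(m$heading_rad[4:6], -tr$heading_rad)
})
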