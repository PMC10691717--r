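# Collective and pairwise descriptors of trajectories: dispersion (radius of
# gyration), polarization, milling, nearest-neighbor distances, wall state,
# and the geometrical leader/follower classification for pairs.

#' Group dispersion (radius of gyration)
#'
#' Root-mean-square distance of the fish to their barycenter: a measure of
#' the total space occupied by the group.
#'
#' @param x,y positions of the N fish, mm.
#' @return dispersion, mm.
#' @export
dispersion <- function(x, y) {
  sqrt(mean((x - mean(x))^2 + (y - mean(y))^2))
}

#' Group polarization
#'
#' Norm of the mean heading unit vector, in `[0, 1]`: 1 when all fish point
#' the same way, near 0 for uncorrelated or mutually cancelling headings.
#'
#' @param heading headings of the N fish, rad.
#' @return polarization, dimensionless.
#' @export
polarization <- function(heading) {
  sqrt(mean(cos(heading))^2 + mean(sin(heading))^2)
}

#' Group milling index
#'
#' Measures coherent rotation of the group, independently of its direction:
#' `M = |mean(sin(phi_bar - theta_bar))|` where `phi_bar` and `theta_bar`
#' are each fish's heading and position angles in the barycenter frame
#' (positions relative to the barycenter, velocities relative to the
#' barycenter velocity).
#'
#' @param x,y positions of the N fish, mm.
#' @param vx,vy velocities of the N fish, mm/s.
#' @return milling index in `[0, 1]`.
#' @export
milling <- function(x, y, vx, vy) {
  xb <- x - mean(x)
  yb <- y - mean(y)
  vxb <- vx - mean(vx)
  vyb <- vy - mean(vy)
  theta_bar <- atan2(yb, xb)
  phi_bar <- atan2(vyb, vxb)
  abs(mean(sin(phi_bar - theta_bar)))
}

#' Wall state of a fish
#'
#' Distance to the wall `r_w = R - |u|` and relative orientation
#' `theta_w = wrap(heading - position angle)`: `theta_w = 0` means heading
#' radially outward, `+/- pi/2` tangential (positive = counter-clockwise
#' motion, wall on the right).
#'
#' @param x,y position(s), mm.
#' @param heading heading(s), rad.
#' @param arena an [arena()] object.
#' @return data frame with columns `r_w` (mm) and `theta_w` (rad).
#' @export
wall_state <- function(x, y, heading, arena = fishschool::arena()) {
  r <- sqrt(x^2 + y^2)
  if (any(r > arena$R + 1e-9)) stop("position outside the arena")
  data.frame(r_w = arena$R - r, theta_w = wrap_angle(heading - atan2(y, x)))
}

#' Pairwise state of a focal fish and a neighbor
#'
#' @param focal,neighbor lists (or one-row data frames) with fields `x`,
#'   `y`, `heading`; fields may be vectors of equal length.
#' @return a [pair_state()] data frame (`d`, `psi`, `delta_phi`).
#' @export
pair_state_of <- function(focal, neighbor) {
  dx <- neighbor$x - focal$x
  dy <- neighbor$y - focal$y
  pair_state(d = sqrt(dx^2 + dy^2),
             psi = atan2(dy, dx) - focal$heading,
             delta_phi = neighbor$heading - focal$heading)
}

#' Nearest-neighbor distances
#'
#' @param x,y positions of the N fish (N >= 2), mm.
#' @return for each fish, the distance to its nearest neighbor, mm.
#' @export
nearest_neighbor_distances <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 2L)
  dm <- as.matrix(stats::dist(cbind(x, y)))
  diag(dm) <- Inf
  apply(dm, 1L, min)
}

#' Geometrical leader and follower of a pair
#'
#' The geometrical leader of a pair is the fish with the larger absolute
#' viewing angle of the other: it would have to turn the most to face its
#' partner, i.e. it swims in front. Exact ties are resolved in favor of the
#' lower id and flagged.
#'
#' @param states a list of two lists, each with fields `x`, `y`, `heading`
#'   (and optionally `id`; defaults to 1 and 2).
#' @return a list with `leader`, `follower` (ids) and logical `tie`.
#' @export
leader_follower <- function(states) {
  stopifnot(length(states) == 2L)
  ids <- vapply(seq_along(states),
                function(i) states[[i]]$id %||% i, numeric(1))
  psi1 <- abs(pair_state_of(states[[1L]], states[[2L]])$psi)
  psi2 <- abs(pair_state_of(states[[2L]], states[[1L]])$psi)
  tie <- isTRUE(all.equal(psi1, psi2))
  lead <- if (tie) which.min(ids) else which.max(c(psi1, psi2))
  list(leader = ids[lead], follower = ids[3L - lead], tie = tie)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-frame collective observables of a trajectory
#'
#' Computes, for every frame of a trajectory sampled on a regular clock, the
#' group dispersion, polarization, milling index, mean nearest-neighbor
#' distance, and per-frame means of the wall distance, plus the barycenter
#' position, velocity, heading, wall distance and incidence. Velocities are
#' estimated by centered finite differences on the sampling grid (one-sided
#' at the ends).
#'
#' @param traj trajectory data frame with columns `frame`, `time_s`,
#'   `fish_id`, `x_mm`, `y_mm` and optionally `heading_rad` (if absent,
#'   headings are taken from the velocity direction).
#' @param arena an [arena()] object.
#' @return data frame with one row per frame: `frame`, `time_s`, `D`, `P`,
#'   `M`, `nnd`, `r_w`, `x_B`, `y_B`, `vx_B`, `vy_B`, `phi_B`, `r_w_B`,
#'   `theta_w_B`. For a single fish `D = 0`, `P = 1` and `M` and `nnd` are
#'   `NA`.
#' @export
school_observables <- function(traj, arena = fishschool::arena()) {
  ids <- sort(unique(traj$fish_id))
  n <- length(ids)
  traj <- traj[order(traj$fish_id, traj$frame), ]
  frames <- sort(unique(traj$frame))
  nf <- length(frames)
  if (nrow(traj) != n * nf) stop("trajectory must have one row per fish per frame")
  X <- matrix(traj$x_mm, nrow = nf, ncol = n)
  Y <- matrix(traj$y_mm, nrow = nf, ncol = n)
  t_s <- traj$time_s[seq_len(nf)]
  VX <- apply(X, 2L, .fd_velocity, t = t_s)
  VY <- apply(Y, 2L, .fd_velocity, t = t_s)
  H <- if ("heading_rad" %in% names(traj)) {
    matrix(traj$heading_rad, nrow = nf, ncol = n)
  } else {
    atan2(VY, VX)
  }

  xb <- rowMeans(X); yb <- rowMeans(Y)
  vxb <- rowMeans(VX); vyb <- rowMeans(VY)
  D <- sqrt(rowMeans((X - xb)^2 + (Y - yb)^2))
  P <- sqrt(rowMeans(cos(H))^2 + rowMeans(sin(H))^2)
  r_w <- rowMeans(arena$R - sqrt(X^2 + Y^2))
  if (n >= 2L) {
    M <- vapply(seq_len(nf), function(i) milling(X[i, ], Y[i, ], VX[i, ], VY[i, ]),
                numeric(1))
    nnd <- vapply(seq_len(nf), function(i) {
      mean(nearest_neighbor_distances(X[i, ], Y[i, ]))
    }, numeric(1))
  } else {
    M <- rep(NA_real_, nf)
    nnd <- rep(NA_real_, nf)
  }
  data.frame(frame = frames, time_s = t_s, D = D, P = P, M = M, nnd = nnd,
             r_w = r_w, x_B = xb, y_B = yb, vx_B = vxb, vy_B = vyb,
             phi_B = atan2(vyb, vxb),
             r_w_B = arena$R - sqrt(xb^2 + yb^2),
             theta_w_B = wrap_angle(atan2(vyb, vxb) - atan2(yb, xb)))
}

# centered finite differences on a (regular) time grid, one-sided ends
.fd_velocity <- function(z, t) {
  nf <- length(z)
  if (nf < 2L) return(rep(NA_real_, nf))
  v <- numeric(nf)
  v[1L] <- (z[2L] - z[1L]) / (t[2L] - t[1L])
  v[nf] <- (z[nf] - z[nf - 1L]) / (t[nf] - t[nf - 1L])
  if (nf > 2L) {
    v[2:(nf - 1L)] <- (z[3:nf] - z[1:(nf - 2L)]) / (t[3:nf] - t[1:(nf - 2L)])
  }
  v
}

#' Time-averaged summary of collective observables
#'
#' @param obs a per-frame observable data frame from [school_observables()],
#'   or a list of them (one per run); with several runs the standard error
#'   over runs is reported.
#' @return data frame with one row per observable (`r_w`, `nnd`, `D`, `P`,
#'   `M`): `mean` and `se`.
#' @export
summarize_observables <- function(obs) {
  if (is.data.frame(obs)) obs <- list(obs)
  vars <- c("r_w", "nnd", "D", "P", "M")
  per_run <- vapply(obs, function(o) {
    vapply(vars, function(v) mean(o[[v]], na.rm = TRUE), numeric(1))
  }, numeric(length(vars)))
  per_run <- matrix(per_run, nrow = length(vars),
                    dimnames = list(vars, NULL))
  m <- rowMeans(per_run)
  se <- if (ncol(per_run) > 1L) {
    apply(per_run, 1L, stats::sd) / sqrt(ncol(per_run))
  } else {
    rep(NA_real_, length(vars))
  }
  data.frame(observable = vars, mean = m, se = se, row.names = NULL)
}
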