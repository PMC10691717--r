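# Asynchronous kick-event simulator. Each fish moves in discrete kicks:
# at a kick onset it picks a new heading (spontaneous noise + wall avoidance
# + social terms from its k most influential neighbors), then glides along a
# straight segment with exponentially decaying speed. Kicks of different
# fish are asynchronous; the event loop always advances the fish whose
# current kick ends first (ties broken by fish id).

#' Position during the glide
#'
#' A time `dt` after a kick onset the fish has covered
#' `l * (1 - exp(-dt/tau0)) / (1 - exp(-tau/tau0))` of its kick segment
#' (exponential speed decay, normalized so the full length `l` is covered at
#' `dt = tau`).
#'
#' @param kick a list with fields `x0`, `y0` (origin, mm), `heading` (rad),
#'   `l` (length, mm), `tau` (duration, s). Fields may be vectors.
#' @param dt time(s) since kick onset, s; must lie in `[0, tau]`.
#' @param tau0 glide decay time, s.
#' @return a two-column matrix of positions (mm).
#' @export
glide_position <- function(kick, dt, tau0) {
  if (any(dt < -1e-12) || any(dt > kick$tau + 1e-12)) {
    stop("dt outside the kick: need 0 <= dt <= tau")
  }
  frac <- (1 - exp(-dt / tau0)) / (1 - exp(-kick$tau / tau0))
  cbind(x = kick$x0 + kick$l * frac * cos(kick$heading),
        y = kick$y0 + kick$l * frac * sin(kick$heading))
}

# social contributions of all neighbors on a focal fish; returns the summed
# k-best contribution and the distance to the most influential neighbor
.social_term <- function(xi, yi, phii, xo, yo, phio, ids, p) {
  dx <- xo - xi
  dy <- yo - yi
  d <- sqrt(dx^2 + dy^2)
  s <- list(d = d,
            psi = wrap_angle(atan2(dy, dx) - phii),
            delta_phi = wrap_angle(phio - phii))
  contrib <- social_dphi(s, p)
  infl <- abs(contrib)
  ord <- order(-infl, ids)          # ties -> smaller fish id
  best <- ord[seq_len(min(p$k, length(ord)))]
  list(dphi = sum(contrib[best]),
       d_influential = d[ord[1L]],
       selected = ids[best])
}

#' Select the most influential neighbors
#'
#' Ranks neighbors by the influence (absolute pairwise social contribution)
#' they exert on the focal fish and returns the ids of the `k` strongest;
#' ties are broken in favor of the smaller fish id. Fewer than `k` ids are
#' returned when fewer neighbors exist.
#'
#' @param focal list with fields `x`, `y`, `heading` for the focal fish.
#' @param others data frame (or list) with fields `x`, `y`, `heading`, `id`
#'   for the interpolated states of the other fish.
#' @param p a [light_params()] object.
#' @param k number of neighbors to keep (defaults to `p$k`).
#' @return integer vector of selected fish ids, strongest first.
#' @export
select_neighbors <- function(focal, others, p, k = p$k) {
  stopifnot(length(others$id) >= 1L)
  p2 <- p
  p2$k <- k
  .social_term(focal$x, focal$y, focal$heading,
               others$x, others$y, others$heading, others$id, p2)$selected
}

#' Kick acceptance rule
#'
#' A candidate kick of length `l` in direction `heading` from position
#' `(x, y)` is accepted iff the point a distance `l + l_c` along the heading
#' is still inside the arena, i.e. the fish keeps a comfort distance `l_c`
#' to the wall.
#'
#' @param x,y current position, mm.
#' @param heading candidate absolute heading, rad.
#' @param l candidate kick length, mm.
#' @param arena an [arena()] object.
#' @param l_c comfort distance to the wall, mm.
#' @return logical, vectorized over `heading` / `l`.
#' @export
kick_accepted <- function(x, y, heading, l, arena, l_c) {
  ex <- x + (l + l_c) * cos(heading)
  ey <- y + (l + l_c) * sin(heading)
  sqrt(ex^2 + ey^2) < arena$R
}

# one heading/length decision with the rejection rule: up to `max_tries`
# joint resamples of (dphi_R, tau, l) with the wall and social terms fixed;
# then uniform dphi_R (resampling tau, l every 100 further tries) until the
# comfort condition holds
.decide_kick <- function(x, y, phi, dphi_w, dphi_s, d_inf, n_fish, p, arena,
                         max_tries = 1000L) {
  r_w <- max(arena$R - sqrt(x^2 + y^2), 0)
  for (try in seq_len(max_tries)) {
    dphi_r <- spontaneous_dphi(r_w, p, 1L)
    kk <- sample_kick(p, n_fish, d = d_inf, n = 1L)
    dphi <- dphi_r + dphi_w + dphi_s
    if (kick_accepted(x, y, phi + dphi, kk$l, arena, p$l_c)) {
      return(list(dphi_r = dphi_r, dphi = dphi, tau = kk$tau, l = kk$l,
                  v_peak = kk$v_peak, fallback = FALSE))
    }
  }
  # fallback: uniform spontaneous term; guaranteed to terminate because a
  # heading towards the center works whenever l + l_c < R + |u|
  repeat {
    for (try in seq_len(100L)) {
      dphi_r <- stats::runif(1L, -pi, pi)
      dphi <- dphi_r + dphi_w + dphi_s
      if (kick_accepted(x, y, phi + dphi, kk$l, arena, p$l_c)) {
        return(list(dphi_r = dphi_r, dphi = dphi, tau = kk$tau, l = kk$l,
                    v_peak = kk$v_peak, fallback = TRUE))
      }
    }
    kk <- sample_kick(p, n_fish, d = d_inf, n = 1L)
  }
}

#' Simulate a school of burst-and-coast swimmers
#'
#' Runs the asynchronous kick-event model for `n_fish` fish in a circular
#' arena and returns the trajectory sampled on a regular clock together with
#' the full kick log.
#'
#' Initial conditions: positions uniform in the disk of radius
#' `R - 2 l_c`, headings uniform, first kicks decided at time 0 with the
#' full decision rule. The output clock is independent of the kick events;
#' at the final sample the last kick is clamped at its endpoint.
#'
#' @param p a [light_params()] object (see [default_light_params()]).
#' @param n_fish number of fish.
#' @param duration simulated time, s.
#' @param seed integer seed; the run is fully reproducible given
#'   `(seed, p, n_fish, duration)`.
#' @param arena an [arena()] object.
#' @param dt_out output sampling step, s (default 0.04, i.e. 25 Hz).
#' @return an object of class `"school_sim"` with components
#'   \describe{
#'     \item{trajectory}{data frame `frame`, `time_s`, `fish_id`, `x_mm`,
#'       `y_mm`, `heading_rad`.}
#'     \item{kicks}{data frame of kick events: `fish_id`, `t_start`, `tau`,
#'       `length`, `v_peak`, `x0`, `y0`, `heading_new`, `dphi`, `dphi_r`,
#'       `dphi_w`, `dphi_s`, `fallback`.}
#'     \item{params, arena, n_fish, duration, seed, dt_out}{the inputs.}
#'   }
#' @examples
#' sim <- simulate_school(default_light_params(50), n_fish = 1,
#'                        duration = 20, seed = 1)
#' print(sim)
#' @export
simulate_school <- function(p, n_fish, duration, seed = NULL,
                            arena = fishschool::arena(), dt_out = 0.04) {
  stopifnot(inherits(p, "light_params"), n_fish >= 1, duration > 0)
  if (!is.null(seed)) set.seed(seed)
  R <- arena$R
  n <- as.integer(n_fish)

  # initial positions uniform in the disk of radius R - 2 l_c
  r0 <- (R - 2 * p$l_c) * sqrt(stats::runif(n))
  th0 <- stats::runif(n, -pi, pi)
  x <- r0 * cos(th0)
  y <- r0 * sin(th0)
  phi <- stats::runif(n, -pi, pi)

  # per-fish current kick state; the pre-first "kick" is a zero-length
  # placeholder with an infinitesimal duration so interpolation is defined
  t_start <- numeric(n)
  tau <- rep(1e-9, n)
  l <- numeric(n)
  v <- numeric(n)
  x0 <- x
  y0 <- y
  heading <- phi

  # kick log accumulators
  acc <- vector("list", 2048L)
  n_acc <- 0L
  push <- function(rec) {
    n_acc <<- n_acc + 1L
    if (n_acc > length(acc)) length(acc) <<- 2L * length(acc)
    acc[[n_acc]] <<- rec
  }

  decide <- function(i, t_now) {
    # instantaneous state of fish i at its kick onset
    xi <- x0[i] + l[i] * cos(heading[i])
    yi <- y0[i] + l[i] * sin(heading[i])
    # numerical safety: the comfort rule keeps |u| < R, clamp tiny overshoot
    rr <- sqrt(xi^2 + yi^2)
    if (rr >= R) {
      xi <- xi * (R - 1e-9) / rr
      yi <- yi * (R - 1e-9) / rr
      rr <- R - 1e-9
    }
    phii <- heading[i]
    r_w <- R - rr
    theta_w <- wrap_angle(phii - atan2(yi, xi))
    dphi_w <- wall_dphi(r_w, theta_w, p)
    dphi_s <- 0
    d_inf <- NULL
    if (n > 1L) {
      j <- setdiff(seq_len(n), i)
      dtj <- pmin(pmax(t_now - t_start[j], 0), tau[j])
      pos <- glide_position(list(x0 = x0[j], y0 = y0[j], heading = heading[j],
                                 l = l[j], tau = tau[j]), dtj, p$tau0)
      st <- .social_term(xi, yi, phii, pos[, 1L], pos[, 2L], heading[j], j, p)
      dphi_s <- st$dphi
      d_inf <- st$d_influential
    }
    dec <- .decide_kick(xi, yi, phii, dphi_w, dphi_s, d_inf, n, p, arena)
    new_heading <- wrap_angle(phii + dec$dphi)
    x0[i] <<- xi
    y0[i] <<- yi
    heading[i] <<- new_heading
    t_start[i] <<- t_now
    tau[i] <<- dec$tau
    l[i] <<- dec$l
    v[i] <<- dec$v_peak
    push(c(i, t_now, dec$tau, dec$l, dec$v_peak, xi, yi, new_heading,
           dec$dphi, dec$dphi_r, dphi_w, dphi_s, as.numeric(dec$fallback)))
  }

  # first kicks at t = 0, in fish-id order
  for (i in seq_len(n)) decide(i, 0)

  t_end <- t_start + tau
  repeat {
    i <- which.min(t_end)           # which.min takes the first (smallest id)
    t_now <- t_end[i]
    if (t_now >= duration) break
    decide(i, t_now)
    t_end[i] <- t_start[i] + tau[i]
  }

  kicks <- do.call(rbind, acc[seq_len(n_acc)])
  kicks <- data.frame(
    fish_id = as.integer(kicks[, 1L]), t_start = kicks[, 2L],
    tau = kicks[, 3L], length = kicks[, 4L], v_peak = kicks[, 5L],
    x0 = kicks[, 6L], y0 = kicks[, 7L], heading_new = kicks[, 8L],
    dphi = kicks[, 9L], dphi_r = kicks[, 10L], dphi_w = kicks[, 11L],
    dphi_s = kicks[, 12L], fallback = kicks[, 13L] > 0
  )
  kicks <- kicks[order(kicks$t_start, kicks$fish_id), ]
  rownames(kicks) <- NULL

  traj <- sample_trajectory(kicks, p$tau0, duration, dt_out)
  structure(list(trajectory = traj, kicks = kicks, params = p, arena = arena,
                 n_fish = n, duration = duration, seed = seed,
                 dt_out = dt_out),
            class = "school_sim")
}

#' Sample a kick log onto a regular clock
#'
#' Interpolates each fish's kick sequence onto the output clock using the
#' glide formula; after a fish's last logged kick the position is clamped at
#' the kick endpoint.
#'
#' @param kicks a kick-event data frame as produced by [simulate_school()].
#' @param tau0 glide decay time, s.
#' @param duration length of the clock, s.
#' @param dt_out sampling step, s.
#' @return trajectory data frame (`frame`, `time_s`, `fish_id`, `x_mm`,
#'   `y_mm`, `heading_rad`), ordered by frame then fish id.
#' @export
sample_trajectory <- function(kicks, tau0, duration, dt_out = 0.04) {
  t_grid <- seq(0, duration, by = dt_out)
  out <- vector("list", length(unique(kicks$fish_id)))
  ids <- sort(unique(kicks$fish_id))
  for (m in seq_along(ids)) {
    ki <- kicks[kicks$fish_id == ids[m], ]
    ki <- ki[order(ki$t_start), ]
    idx <- findInterval(t_grid, ki$t_start)
    idx[idx < 1L] <- 1L
    dt <- pmin(pmax(t_grid - ki$t_start[idx], 0), ki$tau[idx])
    pos <- glide_position(list(x0 = ki$x0[idx], y0 = ki$y0[idx],
                               heading = ki$heading_new[idx],
                               l = ki$length[idx], tau = ki$tau[idx]),
                          dt, tau0)
    out[[m]] <- data.frame(frame = seq_along(t_grid), time_s = t_grid,
                           fish_id = ids[m], x_mm = pos[, 1L],
                           y_mm = pos[, 2L],
                           heading_rad = ki$heading_new[idx])
  }
  traj <- do.call(rbind, out)
  traj <- traj[order(traj$frame, traj$fish_id), ]
  rownames(traj) <- NULL
  traj
}

#' @export
print.school_sim <- function(x, ...) {
  cat(sprintf("Burst-and-coast simulation: %d fish, %g s at %g Hz%s\n",
              x$n_fish, x$duration, 1 / x$dt_out,
              if (!is.na(x$params$label)) sprintf(" (%g lx)", x$params$label)
              else ""))
  cat(sprintf("  %d kicks logged, %d trajectory samples, arena R = %g mm\n",
              nrow(x$kicks), nrow(x$trajectory), x$arena$R))
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' @export
summary.school_sim <- function(object, ...) {
  obs <- school_observables(object$trajectory, object$arena)
  s <- summarize_observables(obs)
  k <- object$kicks
  cat(sprintf("Kicks: mean tau = %.3f s, mean length = %.1f mm, mean peak speed = %.0f mm/s\n",
              mean(k$tau), mean(k$length), mean(k$v_peak)))
  print(s)
  invisible(s)
}

#' @export
plot.school_sim <- function(x, n_last = Inf, ...) {
  tr <- x$trajectory
  if (is.finite(n_last)) tr <- tr[tr$frame > max(tr$frame) - n_last, ]
  R <- x$arena$R
  plot(NA, xlim = c(-R, R), ylim = c(-R, R), asp = 1,
       xlab = "x (mm)", ylab = "y (mm)",
       main = sprintf("%d fish, %s lx", x$n_fish, format(x$params$label)))
  th <- seq(0, 2 * pi, length.out = 361)
  graphics::lines(R * cos(th), R * sin(th), col = "grey40")
  cols <- grDevices::hcl.colors(max(tr$fish_id), "Dark 3")
  for (i in unique(tr$fish_id)) {
    ti <- tr[tr$fish_id == i, ]
    graphics::lines(ti$x_mm, ti$y_mm, col = cols[i])
  }
  invisible(x)
}
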