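# Preprocessing of tracker output: pixel-to-metric conversion, identity
# resolution across frames, activity filtering, burst-and-coast kick
# segmentation, and left/right mirror symmetrization.

#' Convert tracker pixel coordinates to centered metric coordinates
#'
#' `(x, y) = scale * (x_px - x0_px, y_px - y0_px)`: coordinates are centered
#' on the tank center and converted with a single scale factor in both
#' directions (default 0.478 mm/pixel, the calibration of the recording
#' setup).
#'
#' @param raw data frame with columns `frame`, `id`, `x_px`, `y_px`.
#' @param center_px numeric length-2: pixel coordinates of the tank center.
#' @param scale mm per pixel.
#' @return data frame `frame`, `fish_id`, `x_mm`, `y_mm`.
#' @export
pixels_to_mm <- function(raw, center_px = c(0, 0), scale = 0.478) {
  stopifnot(all(c("frame", "id", "x_px", "y_px") %in% names(raw)))
  data.frame(frame = raw$frame, fish_id = raw$id,
             x_mm = scale * (raw$x_px - center_px[1L]),
             y_mm = scale * (raw$y_px - center_px[2L]))
}

#' Solve a linear assignment problem
#'
#' Minimum-cost perfect matching of rows to columns of a square cost matrix,
#' by the shortest-augmenting-path (Jonker-Volgenant) algorithm, O(n^3).
#'
#' @param cost square numeric cost matrix.
#' @return integer vector `a` with `a[i]` the column assigned to row `i`.
#' @export
lap_solve <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  if (n == 1L) return(1L)
  # columns indexed 1..n; index n+1 is the virtual start column
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)      # p[j] = row matched to column j (0 = free)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[n + 1L] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  a <- integer(n)
  a[p[seq_len(n)]] <- seq_len(n)
  a
}

#' Resolve fish identities across frames
#'
#' Tracker labels can swap between frames. Identities are re-assigned
#' sequentially so that the total distance covered by the group between
#' consecutive frames is minimized (optimal assignment between the positions
#' at frame t and t+1). Exact ties are broken in favor of keeping the
#' incoming labels. Frames where any fish is missing split the data into
#' independently relabeled segments.
#'
#' @param tracks data frame `frame`, `fish_id`, `x_mm`, `y_mm` (one row per
#'   fish per complete frame; incomplete frames are dropped).
#' @return a list with `tracks` (relabeled data frame, extra column
#'   `segment`) and `segments` (data frame `segment`, `start_frame`,
#'   `end_frame`, `n_frames`).
#' @export
resolve_identities <- function(tracks) {
  stopifnot(all(c("frame", "fish_id", "x_mm", "y_mm") %in% names(tracks)))
  n <- length(unique(tracks$fish_id))
  cnt <- table(tracks$frame)
  complete <- as.numeric(names(cnt))[cnt == n]
  dropped <- setdiff(unique(tracks$frame), complete)
  if (length(dropped)) {
    message("dropping ", length(dropped), " incomplete frame(s)")
  }
  tracks <- tracks[tracks$frame %in% complete, ]
  tracks <- tracks[order(tracks$frame, tracks$fish_id), ]
  frames <- sort(complete)
  # segment breaks at frame-number gaps
  seg_id <- cumsum(c(1, diff(frames) != 1))
  X <- matrix(tracks$x_mm, nrow = n)
  Y <- matrix(tracks$y_mm, nrow = n)
  new_id <- matrix(NA_integer_, nrow = n, ncol = length(frames))
  for (s in unique(seg_id)) {
    cols <- which(seg_id == s)
    new_id[, cols[1L]] <- seq_len(n)
    if (length(cols) > 1L) {
      for (kk in cols[-1L]) {
        d <- sqrt(outer(X[, kk - 1L], X[, kk], `-`)^2 +
                  outer(Y[, kk - 1L], Y[, kk], `-`)^2)
        # favor label continuity on exact ties
        d <- d + 1e-9 * (outer(seq_len(n), seq_len(n), `!=`))
        a <- lap_solve(d)              # a[i]: column matched to prev row i
        prev <- new_id[, kk - 1L]
        nid <- integer(n)
        nid[a] <- prev
        new_id[, kk] <- nid
      }
    }
  }
  tracks$fish_id <- as.vector(new_id)
  tracks$segment <- rep(seg_id, each = n)
  tracks <- tracks[order(tracks$frame, tracks$fish_id), ]
  rownames(tracks) <- NULL
  seg <- data.frame(
    segment = unique(seg_id),
    start_frame = tapply(rep(frames, each = 1), seg_id, min),
    end_frame = tapply(frames, seg_id, max),
    row.names = NULL
  )
  seg$n_frames <- seg$end_frame - seg$start_frame + 1
  list(tracks = tracks, segments = seg)
}

#' Select sustained-activity windows
#'
#' Frames where the fastest fish of the group swims below `speed_floor` for
#' longer than `max_lull` are classified as stopping behavior and removed;
#' shorter lulls are retained. Returns the active windows.
#'
#' @param traj data frame `frame`, `time_s`, `fish_id`, `x_mm`, `y_mm`
#'   sampled on a regular clock.
#' @param speed_floor mm/s (default 40).
#' @param max_lull s (default 2).
#' @return data frame of active segments: `start_frame`, `end_frame`,
#'   `start_time`, `end_time`.
#' @export
activity_filter <- function(traj, speed_floor = 40, max_lull = 2) {
  traj <- traj[order(traj$fish_id, traj$frame), ]
  frames <- sort(unique(traj$frame))
  nf <- length(frames)
  n <- length(unique(traj$fish_id))
  t_s <- traj$time_s[seq_len(nf)]
  dt <- stats::median(diff(t_s))
  spd <- matrix(NA_real_, nf, n)
  for (m in seq_len(n)) {
    idx <- ((m - 1L) * nf + 1L):(m * nf)
    vx <- .fd_velocity(traj$x_mm[idx], t_s)
    vy <- .fd_velocity(traj$y_mm[idx], t_s)
    spd[, m] <- sqrt(vx^2 + vy^2)
  }
  fastest <- apply(spd, 1L, max)
  slow <- fastest < speed_floor
  r <- rle(slow)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  stopped <- rep(FALSE, nf)
  for (q in seq_along(r$values)) {
    if (r$values[q] && r$lengths[q] * dt > max_lull) {
      stopped[starts[q]:ends[q]] <- TRUE
    }
  }
  active <- !stopped
  ra <- rle(active)
  ea <- cumsum(ra$lengths)
  sa <- ea - ra$lengths + 1L
  keep <- which(ra$values)
  data.frame(start_frame = frames[sa[keep]], end_frame = frames[ea[keep]],
             start_time = t_s[sa[keep]], end_time = t_s[ea[keep]])
}

#' Segment a single-fish trajectory into kicks
#'
#' The speed time series (centered finite differences at the sampling rate)
#' is smoothed with a degree-3 Savitzky-Golay filter over a 0.36 s window
#' and split into accelerating and decelerating phases; phases shorter than
#' 0.08 s are merged into their neighbors to limit noise. Kick onsets are
#' the starts of the acceleration phases (the speed minima).
#'
#' For each kick the table reports the onset time, duration (onset to next
#' onset), length (straight-line displacement between onsets), peak speed,
#' onset position, the glide heading (direction of the net displacement),
#' and the heading change `dphi` relative to the previous kick's glide
#' heading, i.e. the turn decided at this onset.
#'
#' In addition to the smoothed-minima rule, phases are split at speed
#' discontinuities: during a glide the speed decays quasi-exponentially, so
#' the frame-to-frame speed ratio is bounded; a jump up or a drop beyond
#' any plausible glide decay marks a kick onset even when the new peak speed
#' is below the previous glide's tail (the burst is treated as
#' instantaneous, so such silent onsets occur). On continuous speed
#' profiles this rule never fires and the procedure reduces to the
#' minima rule.
#'
#' @param traj single-fish trajectory data frame (`frame`, `time_s`,
#'   `x_mm`, `y_mm`), regular clock.
#' @param sg_window Savitzky-Golay window, s.
#' @param min_phase minimum phase duration, s; shorter phases are merged.
#' @param jump_ratio frame-to-frame raw-speed ratios outside
#'   `[1/jump_ratio, jump_ratio]` (at speeds above `speed_eps`) are treated
#'   as kick onsets; `NULL` disables discontinuity splitting.
#' @param speed_eps minimum speed (mm/s) for the discontinuity rule.
#' @return data frame, one row per kick: `t_start`, `tau`, `length`,
#'   `v_peak`, `x0`, `y0`, `heading`, `dphi` (NA for the first kick).
#' @export
detect_kicks <- function(traj, sg_window = 0.36, min_phase = 0.08,
                         jump_ratio = 1.25, speed_eps = 10) {
  traj <- traj[order(traj$frame), ]
  t_s <- traj$time_s
  dt <- stats::median(diff(t_s))
  nwin <- round(sg_window / dt)
  if (nwin %% 2 == 0) nwin <- nwin + 1L     # sgolay needs an odd window
  if (nrow(traj) <= nwin) {
    stop("trajectory segment shorter than the smoothing window")
  }
  vx <- .fd_velocity(traj$x_mm, t_s)
  vy <- .fd_velocity(traj$y_mm, t_s)
  raw <- sqrt(vx^2 + vy^2)
  spd <- signal::sgolayfilt(raw, p = 3, n = nwin)

  ds <- diff(spd)
  ds[abs(ds) < 1e-9] <- 0                    # numerically flat is not accel
  accel <- ds > 0                            # phase of frame i -> i+1
  if (!any(accel) || all(accel)) {
    return(.empty_kick_table())
  }
  r <- rle(accel)
  min_frames <- ceiling(min_phase / dt)
  # merge phases shorter than min_phase into their neighbors, shortest first
  while (length(r$lengths) > 1L && min(r$lengths) < min_frames) {
    q <- which.min(r$lengths)
    r$values[q] <- !r$values[q]              # absorb into neighbors
    r <- rle(inverse.rle(r))
  }
  if (length(r$lengths) < 2L) return(.empty_kick_table())
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  onset_idx <- starts[r$values]              # first frame of each accel phase

  if (!is.null(jump_ratio)) {
    # discontinuity onsets from the forward-difference speed (sharper at a
    # jump than the centered estimate); a one-frame dip or spike produces
    # two adjacent flags, keep the first of each run
    fwd <- c(NA_real_, sqrt(diff(traj$x_mm)^2 + diff(traj$y_mm)^2) / dt)
    i <- 2:(length(fwd) - 1L)
    ratio <- fwd[i + 1L] / pmax(fwd[i], 1e-12)
    disc <- i[(ratio > jump_ratio | ratio < 1 / jump_ratio) &
                pmax(fwd[i], fwd[i + 1L]) > speed_eps]
    if (length(disc)) {
      disc <- disc[c(TRUE, diff(disc) > 2L)]
      # a discontinuity is sharper evidence than a smoothed minimum: drop
      # smoothed onsets ringing around it
      keep_sg <- vapply(onset_idx, function(j) all(abs(disc - j) > 4L),
                        logical(1))
      onset_idx <- sort(c(onset_idx[keep_sg], disc))
    }
  }
  # enforce a minimum kick separation (well below the shortest duration)
  if (length(onset_idx) > 1L) {
    kept <- onset_idx[1L]
    for (j in onset_idx[-1L]) {
      if (j - kept[length(kept)] > 3L) kept <- c(kept, j)
    }
    onset_idx <- kept
  }
  if (length(onset_idx) < 2L) return(.empty_kick_table())

  n_k <- length(onset_idx) - 1L
  i0 <- onset_idx[seq_len(n_k)]
  i1 <- onset_idx[-1L]
  dx <- traj$x_mm[i1] - traj$x_mm[i0]
  dy <- traj$y_mm[i1] - traj$y_mm[i0]
  heading <- atan2(dy, dx)
  v_peak <- vapply(seq_len(n_k), function(q) max(spd[i0[q]:i1[q]]), numeric(1))
  data.frame(
    t_start = t_s[i0], tau = t_s[i1] - t_s[i0],
    length = sqrt(dx^2 + dy^2), v_peak = v_peak,
    x0 = traj$x_mm[i0], y0 = traj$y_mm[i0],
    heading = heading,
    dphi = c(NA_real_, wrap_angle(diff(heading)))
  )
}

.empty_kick_table <- function() {
  data.frame(t_start = numeric(0), tau = numeric(0), length = numeric(0),
             v_peak = numeric(0), x0 = numeric(0), y0 = numeric(0),
             heading = numeric(0), dphi = numeric(0))
}

#' Build a kick table with state variables from a trajectory
#'
#' Runs [detect_kicks()] for every fish and attaches, at each kick onset,
#' the state variables the model's decision depends on: the wall state
#' (`r_w`, `theta_w`, computed with the pre-decision heading, i.e. the
#' previous kick's glide direction) and, for pairs, the neighbor state
#' (`d`, `psi`, `delta_phi`) with the neighbor's position interpolated at
#' the onset frame. The first kick of each fish carries no decision and is
#' dropped.
#'
#' @param traj trajectory data frame (`frame`, `time_s`, `fish_id`, `x_mm`,
#'   `y_mm`), regular clock, N = 1 or 2 fish.
#' @param arena an [arena()] object.
#' @param ... passed to [detect_kicks()].
#' @return a kick table: `fish_id`, `t_start`, `tau`, `length`, `v_peak`,
#'   `r_w`, `theta_w`, `dphi`, and for pairs `d`, `psi`, `delta_phi`.
#' @export
kick_table <- function(traj, arena = fishschool::arena(), ...) {
  ids <- sort(unique(traj$fish_id))
  if (length(ids) > 2L) {
    stop("kick tables are built for single fish or pairs")
  }
  out <- list()
  for (i in ids) {
    ti <- traj[traj$fish_id == i, ]
    kk <- detect_kicks(ti, ...)
    if (nrow(kk) < 2L) next
    kk0 <- kk[-1L, ]                         # first kick has no pre-heading
    pre_heading <- kk$heading[-nrow(kk)]
    tab <- data.frame(
      fish_id = i, t_start = kk0$t_start, tau = kk0$tau, length = kk0$length,
      v_peak = kk0$v_peak,
      r_w = arena$R - sqrt(kk0$x0^2 + kk0$y0^2),
      theta_w = wrap_angle(pre_heading - atan2(kk0$y0, kk0$x0)),
      dphi = kk0$dphi
    )
    if (length(ids) == 2L) {
      j <- setdiff(ids, i)
      tj <- traj[traj$fish_id == j, ]
      # neighbor position and glide heading at the onset times
      xj <- stats::approx(tj$time_s, tj$x_mm, xout = kk0$t_start, rule = 2)$y
      yj <- stats::approx(tj$time_s, tj$y_mm, xout = kk0$t_start, rule = 2)$y
      vxj <- .fd_velocity(tj$x_mm, tj$time_s)
      vyj <- .fd_velocity(tj$y_mm, tj$time_s)
      hj <- atan2(stats::approx(tj$time_s, vyj, xout = kk0$t_start, rule = 2)$y,
                  stats::approx(tj$time_s, vxj, xout = kk0$t_start, rule = 2)$y)
      dxx <- xj - kk0$x0
      dyy <- yj - kk0$y0
      tab$d <- sqrt(dxx^2 + dyy^2)
      tab$psi <- wrap_angle(atan2(dyy, dxx) - pre_heading)
      tab$delta_phi <- wrap_angle(hj - pre_heading)
    }
    out[[length(out) + 1L]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mirror-symmetrize a data set
#'
#' Swimming statistics show an almost perfect left/right symmetry: a
#' trajectory and its mirror image (y -> -y) are equally likely. Adding the
#' mirrored copy of every record doubles the data and enforces exact
#' symmetry in reconstructed angular profiles. Mirroring negates y
#' coordinates, headings, and all signed angles (`theta_w`, `psi`,
#' `delta_phi`, `dphi`).
#'
#' @param x a trajectory data frame (with `y_mm` and optionally
#'   `heading_rad`) or a kick table (with angle columns).
#' @return the input with mirrored copies appended and a logical `mirrored`
#'   column.
#' @export
mirror_augment <- function(x) {
  m <- x
  for (col in intersect(c("y_mm", "y0", "heading_rad", "heading",
                          "theta_w", "psi", "delta_phi", "dphi"),
                        names(m))) {
    m[[col]] <- -m[[col]]
  }
  x$mirrored <- FALSE
  m$mirrored <- TRUE
  rbind(x, m)
}
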