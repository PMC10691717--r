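# Reconstruction of the interaction functions from kick-level data: binned
# conditional means of the per-kick heading change, parity decomposition,
# rank-1 factorization into radial and angular profiles, and least-squares
# fits of the analytic forms. The closed loop (simulate -> segment ->
# reconstruct -> recover the generating parameters) is the package's main
# validation surface.

#' Fit result container
#'
#' Lightweight S3 container for reconstruction fits: fitted parameters,
#' residual norm, convergence flag and bookkeeping.
#'
#' @param params named numeric vector of fitted parameters.
#' @param residual_norm root-mean-square residual of the fit.
#' @param converged logical.
#' @param method short description string.
#' @param n number of data points (or kicks) used.
#' @param extra optional list of extra fields (e.g. data weight outside the
#'   fitted range).
#' @return object of class `"fs_fit"`.
#' @export
fs_fit <- function(params, residual_norm = NA_real_, converged = TRUE,
                   method = "", n = NA_integer_, extra = list()) {
  structure(c(list(params = params, residual_norm = residual_norm,
                   converged = converged, method = method, n = n), extra),
            class = "fs_fit")
}

#' @export
print.fs_fit <- function(x, ...) {
  cat("Reconstruction fit", if (nzchar(x$method)) paste0("(", x$method, ")"),
      if (!x$converged) "[NOT CONVERGED]", "\n")
  print(round(x$params, 4))
  if (is.finite(x$residual_norm)) {
    cat(sprintf("  rms residual %.4g on n = %s\n", x$residual_norm,
                format(x$n)))
  }
  invisible(x)
}

#' @export
coef.fs_fit <- function(object, ...) object$params

# weighted least squares with multi-start Nelder-Mead over a coarse grid of
# starting points; model(par, x) must be vectorized in x
.fit_ls <- function(model, starts, x, y, w = rep(1, length(y))) {
  ok <- is.finite(y) & is.finite(x) & w > 0
  x <- x[ok]; y <- y[ok]; w <- w[ok]
  obj <- function(par) {
    r <- y - model(par, x)
    sum(w * r^2)
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), obj, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("all least-squares starts failed")
  list(par = best$par,
       rms = sqrt(best$value / sum(w)),
       converged = best$convergence == 0L,
       n = length(y))
}

#' Spontaneous heading-noise intensity from kicks far from the wall
#'
#' Far from the wall the heading change at a kick reduces to the Gaussian
#' spontaneous term, so its standard deviation estimates `gamma_R`.
#'
#' @param kicks kick table with columns `r_w` and `dphi`.
#' @param r_min wall-exclusion threshold, mm (default 60: beyond it the wall
#'   influence is negligible).
#' @return an [fs_fit()] with parameter `gamma_R` (rad).
#' @export
fit_gamma_R <- function(kicks, r_min = 60) {
  d <- kicks$dphi[kicks$r_w > r_min & is.finite(kicks$dphi)]
  if (length(d) < 10L) stop("too few kicks beyond r_min")
  g <- sqrt(mean(d^2))                 # zero-mean by symmetry
  fs_fit(c(gamma_R = g), residual_norm = g / sqrt(2 * length(d)),
         method = "sd of far-from-wall heading changes", n = length(d))
}

#' Glide decay time from within-kick speed profiles
#'
#' Fits `exp(-t / tau0)` to speed profiles normalized by the speed at the
#' kick onset, by least squares over all profile points.
#'
#' @param profiles a list of data frames with columns `t` (s since the kick
#'   onset/speed peak) and `v` (speed, mm/s), or a single such data frame.
#' @return an [fs_fit()] with parameter `tau0` (s).
#' @export
fit_tau0 <- function(profiles) {
  if (is.data.frame(profiles)) profiles <- list(profiles)
  pts <- do.call(rbind, lapply(profiles, function(pr) {
    if (any(pr$v <= 0)) stop("speed profiles must be positive")
    data.frame(t = pr$t, vn = pr$v / pr$v[1L])
  }))
  obj <- function(tau0) sum((pts$vn - exp(-pts$t / tau0))^2)
  opt <- stats::optimize(obj, c(0.01, 10))
  fs_fit(c(tau0 = opt$minimum),
         residual_norm = sqrt(opt$objective / nrow(pts)),
         method = "ls fit of exponential speed decay", n = nrow(pts))
}

#' Bin the wall interaction
#'
#' Bins the per-kick heading change on a `(r_w, theta_w)` grid after
#' antisymmetrization in `theta_w` (each kick contributes also its mirror
#' image with `theta_w` and `dphi` negated), which cancels the even-in-angle
#' spontaneous component and enforces the odd symmetry of the wall term.
#'
#' @param kicks single-fish kick table with `r_w`, `theta_w`, `dphi`.
#' @param r_edges distance bin edges, mm (default 10 mm bins to 120 mm).
#' @param n_theta number of angular bins over (-pi, pi] (default 16).
#' @param min_count bins with fewer (symmetrized) kicks are flagged `NA`.
#' @return object of class `"binned_interaction"`: list with `r_mid`,
#'   `theta_mid`, matrices `mean`, `count`, `se`, and the total kick count.
#' @export
bin_wall_interaction <- function(kicks, r_edges = seq(0, 120, by = 10),
                                 n_theta = 16, min_count = 50) {
  ok <- is.finite(kicks$dphi) & is.finite(kicks$theta_w)
  kk <- kicks[ok, ]
  # antisymmetrize: append the mirror image
  r <- c(kk$r_w, kk$r_w)
  th <- c(kk$theta_w, -kk$theta_w)
  dp <- c(kk$dphi, -kk$dphi)
  th_edges <- seq(-pi, pi, length.out = n_theta + 1L)
  ri <- findInterval(r, r_edges, rightmost.closed = TRUE)
  ti <- findInterval(th, th_edges, rightmost.closed = TRUE)
  keep <- ri >= 1L & ri <= length(r_edges) - 1L & ti >= 1L & ti <= n_theta
  ri <- ri[keep]; ti <- ti[keep]; dp <- dp[keep]
  nr <- length(r_edges) - 1L
  idx <- (ti - 1L) * nr + ri
  cnt <- tabulate(idx, nbins = nr * n_theta)
  S1 <- S2 <- numeric(nr * n_theta)
  rs1 <- rowsum(dp, idx)
  rs2 <- rowsum(dp^2, idx)
  S1[as.integer(rownames(rs1))] <- rs1[, 1L]
  S2[as.integer(rownames(rs2))] <- rs2[, 1L]
  m <- ifelse(cnt > 0, S1 / cnt, NA_real_)
  v <- ifelse(cnt > 1, pmax(S2 / cnt - m^2, 0), NA_real_)
  se <- sqrt(v / pmax(cnt, 1))
  m[cnt < min_count] <- NA_real_
  structure(list(
    r_mid = (r_edges[-1L] + r_edges[-length(r_edges)]) / 2,
    theta_mid = (th_edges[-1L] + th_edges[-length(th_edges)]) / 2,
    mean = matrix(m, nr, n_theta),
    count = matrix(cnt, nr, n_theta),
    se = matrix(se, nr, n_theta),
    n_kicks = nrow(kk)
  ), class = "binned_interaction")
}

# weighted rank-1 factorization M ~ f %o% O by alternating projection
.rank1 <- function(M, W, tol = 1e-8, max_iter = 500L) {
  W[is.na(M)] <- 0
  M[is.na(M)] <- 0
  O <- colSums(W * M) / pmax(colSums(W), 1)   # init from column means
  if (all(O == 0)) O <- rep(1, ncol(M))
  f <- rep(0, nrow(M))
  for (it in seq_len(max_iter)) {
    f_new <- as.numeric((W * M) %*% O) / pmax(as.numeric(W %*% O^2), 1e-300)
    O_new <- as.numeric(t(W * M) %*% f_new) /
      pmax(as.numeric(t(W) %*% f_new^2), 1e-300)
    delta <- max(abs(f_new - f), abs(O_new - O))
    f <- f_new
    O <- O_new
    if (delta < tol) return(list(f = f, O = O, iterations = it, converged = TRUE))
  }
  list(f = f, O = O, iterations = max_iter, converged = FALSE)
}

#' Factor a binned wall interaction into radial and angular profiles
#'
#' Decomposes the binned mean heading change as a product
#' `f_w(r_w) * O_w(theta_w)` by count-weighted alternating projection to a
#' rank-1 fixed point. The angular profile is normalized to unit mean square
#' with its sign chosen to correlate positively with `sin(theta_w)`; the
#' scale (and sign) is absorbed into the radial factor.
#'
#' @param bins a `"binned_interaction"` from [bin_wall_interaction()].
#' @param tol fixed-point tolerance on the factor change.
#' @return list with `r_mid`, `f_w`, `theta_mid`, `O_w`, `iterations`,
#'   `converged`.
#' @export
extract_wall_product <- function(bins, tol = 1e-8) {
  dec <- .rank1(bins$mean, bins$count, tol = tol)
  f <- dec$f
  O <- dec$O
  if (sum(O * sin(bins$theta_mid)) < 0) {
    O <- -O
    f <- -f
  }
  A <- 1 / sqrt(mean(O^2))
  list(r_mid = bins$r_mid, f_w = f / A, theta_mid = bins$theta_mid,
       O_w = O * A, iterations = dec$iterations, converged = dec$converged)
}

#' Fit the analytic wall-repulsion form to a reconstructed radial profile
#'
#' Fits `gamma_w * exp(-(r_w / l_w)^2)` to the discrete radial factor by
#' multi-start least squares. The fit is restricted to `r_w <= r_max`
#' (default 80 mm): beyond it the occupancy is low and the reconstruction
#' fluctuates. The residual probability weight of the data beyond `r_max` is
#' reported.
#'
#' @param ext output of [extract_wall_product()].
#' @param bins the `"binned_interaction"` the profile came from (used for
#'   occupancy weights).
#' @param r_max fitting range, mm.
#' @return an [fs_fit()] with parameters `gamma_w`, `l_w` and extra field
#'   `weight_outside` (fraction of kicks with `r_w > r_max`).
#' @export
fit_wall_params <- function(ext, bins = NULL, r_max = 80) {
  use <- ext$r_mid <= r_max & is.finite(ext$f_w)
  w <- if (is.null(bins)) rep(1, sum(use)) else rowSums(bins$count)[use]
  starts <- expand.grid(gamma = c(0.5, 1, 2, 4, 8),
                        l = c(20, 40, 60, 90))
  fit <- .fit_ls(function(par, r) par[1L] * exp(-(r / par[2L])^2),
                 starts, ext$r_mid[use], ext$f_w[use], w)
  wo <- if (is.null(bins)) NA_real_ else {
    cr <- rowSums(bins$count)
    sum(cr[bins$r_mid > r_max]) / sum(cr)
  }
  fs_fit(c(gamma_w = fit$par[1L], l_w = abs(fit$par[2L])),
         residual_norm = fit$rms, converged = fit$converged,
         method = "multi-start ls, Gaussian wall repulsion", n = fit$n,
         extra = list(weight_outside = wo, r_max = r_max))
}

# 3-way binned mean with parity symmetrization; parity = c(sign under
# psi -> -psi, sign under delta_phi -> -delta_phi) of the target component
.bin3_parity <- function(kk, parity, d_edges, n_ang, min_count) {
  a_edges <- seq(-pi, pi, length.out = n_ang + 1L)
  # four-term symmetrization as data augmentation
  d <- rep(kk$d, 4L)
  psi <- c(kk$psi, -kk$psi, kk$psi, -kk$psi)
  dp <- c(kk$delta_phi, kk$delta_phi, -kk$delta_phi, -kk$delta_phi)
  sgn <- c(rep(1, nrow(kk)), rep(parity[1L], nrow(kk)),
           rep(parity[2L], nrow(kk)), rep(parity[1L] * parity[2L], nrow(kk)))
  y <- rep(kk$dphi, 4L) * sgn
  di <- findInterval(d, d_edges, rightmost.closed = TRUE)
  pi_ <- findInterval(psi, a_edges, rightmost.closed = TRUE)
  qi <- findInterval(dp, a_edges, rightmost.closed = TRUE)
  nd <- length(d_edges) - 1L
  keep <- di >= 1L & di <= nd & pi_ >= 1L & pi_ <= n_ang & qi >= 1L & qi <= n_ang
  idx <- ((qi - 1L) * n_ang + (pi_ - 1L)) * nd + di
  idx <- idx[keep]; y <- y[keep]
  ncell <- nd * n_ang * n_ang
  cnt <- tabulate(idx, nbins = ncell)
  S <- numeric(ncell)
  rs <- rowsum(y, idx)
  S[as.integer(rownames(rs))] <- rs[, 1L]
  m <- ifelse(cnt >= min_count, S / pmax(cnt, 1), NA_real_)
  list(mean = array(m, dim = c(nd, n_ang, n_ang)),
       count = array(cnt, dim = c(nd, n_ang, n_ang)),
       d_mid = (d_edges[-1L] + d_edges[-length(d_edges)]) / 2,
       ang_mid = (a_edges[-1L] + a_edges[-length(a_edges)]) / 2)
}

# weighted rank-1 factorization of a 3-way array M ~ f %o% O %o% E
.rank1_3 <- function(M, W, tol = 1e-8, max_iter = 500L) {
  W[is.na(M)] <- 0
  M[is.na(M)] <- 0
  d1 <- dim(M)[1L]; d2 <- dim(M)[2L]; d3 <- dim(M)[3L]
  O <- rep(1, d2); E <- rep(1, d3)
  f <- rep(0, d1)
  outer3 <- function(a, b, c) outer(a, outer(b, c))
  for (it in seq_len(max_iter)) {
    G <- outer3(rep(1, d1), O, E)
    f_new <- apply(W * M * G, 1L, sum) / pmax(apply(W * G^2, 1L, sum), 1e-300)
    G <- outer3(f_new, rep(1, d2), E)
    O_new <- apply(W * M * G, 2L, sum) / pmax(apply(W * G^2, 2L, sum), 1e-300)
    G <- outer3(f_new, O_new, rep(1, d3))
    E_new <- apply(W * M * G, 3L, sum) / pmax(apply(W * G^2, 3L, sum), 1e-300)
    delta <- max(abs(f_new - f), abs(O_new - O), abs(E_new - E))
    f <- f_new; O <- O_new; E <- E_new
    if (delta < tol) {
      return(list(f = f, O = O, E = E, iterations = it, converged = TRUE))
    }
  }
  list(f = f, O = O, E = E, iterations = max_iter, converged = FALSE)
}

#' Extract the social interaction factors from a pair kick table
#'
#' Separates attraction from alignment by their parities -- attraction is
#' odd in the viewing angle `psi` and even in the relative orientation
#' `delta_phi`, alignment the reverse -- via the four-term symmetrization
#' over `(+/-psi, +/-delta_phi)`, then factorizes each component on a
#' `(d, psi, delta_phi)` grid into radial x odd x even profiles by weighted
#' alternating projection. Kicks closer to the wall than `r_min` are
#' excluded so the wall term does not contaminate the social estimate.
#' Angular profiles carry unit mean square; the odd profile's sign is set by
#' positive correlation with the sine, the even profile's by a positive
#' mean; intensity (and any residual sign) lives in the radial factor.
#'
#' @param kicks pair kick table with `r_w`, `d`, `psi`, `delta_phi`, `dphi`.
#' @param r_min wall-exclusion threshold, mm.
#' @param d_edges distance bin edges, mm.
#' @param n_ang angular bins over (-pi, pi].
#' @param min_count minimum (symmetrized) kicks per used 3-D cell.
#' @return list with components `attraction` and `alignment`, each a list
#'   `d_mid`, `f`, `odd_mid`, `O`, `even_mid`, `E`, `converged`; plus
#'   `n_kicks`.
#' @export
extract_social <- function(kicks, r_min = 60, d_edges = seq(0, 200, by = 10),
                           n_ang = 16, min_count = 20) {
  kk <- kicks[kicks$r_w > r_min &
                is.finite(kicks$dphi) & is.finite(kicks$psi) &
                is.finite(kicks$delta_phi), ]
  if (nrow(kk) < 100L) stop("too few far-from-wall pair kicks")
  # array axes are (d, psi, delta_phi); the attraction component is odd in
  # psi (axis 2) and even in delta_phi, alignment the reverse
  att <- local({
    b <- .bin3_parity(kk, c(-1, 1), d_edges, n_ang, min_count)
    dec <- .rank1_3(b$mean, b$count)
    .finish_social(dec$f, dec$O, dec$E, b, odd_is_axis2 = TRUE,
                   converged = dec$converged)
  })
  ali <- local({
    b <- .bin3_parity(kk, c(1, -1), d_edges, n_ang, min_count)
    dec <- .rank1_3(b$mean, b$count)
    .finish_social(dec$f, dec$O, dec$E, b, odd_is_axis2 = FALSE,
                   converged = dec$converged)
  })
  list(attraction = att, alignment = ali, n_kicks = nrow(kk))
}

.finish_social <- function(f, ax2, ax3, b, odd_is_axis2, converged) {
  odd <- if (odd_is_axis2) ax2 else ax3
  even <- if (odd_is_axis2) ax3 else ax2
  if (sum(odd * sin(b$ang_mid)) < 0) { odd <- -odd; f <- -f }
  if (mean(even) < 0) { even <- -even; f <- -f }
  Ao <- 1 / sqrt(mean(odd^2))
  Ae <- 1 / sqrt(mean(even^2))
  list(d_mid = b$d_mid, f = f / (Ao * Ae),
       odd_mid = b$ang_mid, O = odd * Ao,
       even_mid = b$ang_mid, E = even * Ae,
       converged = converged,
       count_d = apply(b$count, 1L, sum))
}

#' Fit the analytic attraction and alignment forms
#'
#' Fits `f_att(d) = gamma_att (d/d_att - 1) / (1 + (d/l_att)^2)` (3 free
#' parameters) and `f_ali(d) = gamma_ali (d/d_ali) exp(-(d/l_ali)^2)`
#' (`d_ali` is a fixed scale; 2 free parameters) to the reconstructed radial
#' factors, by multi-start least squares weighted by bin occupancy.
#'
#' @param ext output of [extract_social()].
#' @param d_ali fixed alignment distance scale, mm.
#' @return an [fs_fit()] with parameters `gamma_att`, `l_att`, `d_att`,
#'   `gamma_ali`, `l_ali`.
#' @export
fit_social_params <- function(ext, d_ali = 50) {
  att <- ext$attraction
  starts_a <- expand.grid(gamma = c(0.1, 0.3, 0.6, 1.2),
                          l = c(60, 120, 200), d0 = c(15, 30, 60))
  fa <- .fit_ls(function(par, d) {
    par[1L] * (d / par[3L] - 1) / (1 + (d / par[2L])^2)
  }, starts_a, att$d_mid, att$f, att$count_d)
  ali <- ext$alignment
  starts_l <- expand.grid(gamma = c(0.2, 0.6, 1.2, 2.5),
                          l = c(50, 100, 160, 250))
  fl <- .fit_ls(function(par, d) {
    par[1L] * (d / d_ali) * exp(-(d / par[2L])^2)
  }, starts_l, ali$d_mid, ali$f, ali$count_d)
  fs_fit(c(gamma_att = fa$par[1L], l_att = abs(fa$par[2L]),
           d_att = fa$par[3L],
           gamma_ali = fl$par[1L], l_ali = abs(fl$par[2L])),
         residual_norm = sqrt(mean(c(fa$rms, fl$rms)^2)),
         converged = fa$converged && fl$converged,
         method = "multi-start ls, social radial profiles",
         n = fa$n + fl$n,
         extra = list(d_ali = d_ali))
}

#' Fit the kick-length modulation from a pair kick table
#'
#' The mean kick length as a function of the distance to the neighbor is
#' estimated by binning the observed kick lengths in `d`, then fitting the
#' saturating form `F_m(d) = l_m - gamma_m (d + d_m) exp(-d / l_m)` by
#' multi-start least squares weighted by bin occupancy.
#'
#' @param kicks pair kick table with `d` and `length`.
#' @param d_edges distance bin edges, mm.
#' @param min_count minimum kicks per used bin.
#' @return an [fs_fit()] with parameters `gamma_m`, `l_m`, `d_m`.
#' @export
fit_modulation <- function(kicks, d_edges = seq(0, 200, by = 10),
                           min_count = 50) {
  di <- findInterval(kicks$d, d_edges, rightmost.closed = TRUE)
  nd <- length(d_edges) - 1L
  keep <- di >= 1L & di <= nd & is.finite(kicks$length)
  di <- di[keep]
  len <- kicks$length[keep]
  cnt <- tabulate(di, nbins = nd)
  S <- numeric(nd)
  rs <- rowsum(len, di)
  S[as.integer(rownames(rs))] <- rs[, 1L]
  mean_l <- ifelse(cnt >= min_count, S / pmax(cnt, 1), NA_real_)
  d_mid <- (d_edges[-1L] + d_edges[-length(d_edges)]) / 2
  starts <- expand.grid(gamma = c(0.3, 1, 2), l = c(30, 50, 80),
                        dm = c(5, 15, 40))
  fit <- .fit_ls(function(par, d) {
    par[2L] - par[1L] * (d + par[3L]) * exp(-d / par[2L])
  }, starts, d_mid, mean_l, cnt)
  fs_fit(c(gamma_m = fit$par[1L], l_m = fit$par[2L], d_m = fit$par[3L]),
         residual_norm = fit$rms, converged = fit$converged,
         method = "multi-start ls, binned mean kick length", n = fit$n)
}
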