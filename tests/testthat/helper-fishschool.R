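# Shared helpers: independent oracles kept deliberately naive so they do not
# share code paths with the implementation they check.

# Riemann-sum mean square of f over (-pi, pi], independent of
# stats::integrate used by normalize_angular()
riemann_norm_const <- function(f, n = 2e5) {
  th <- seq(-pi, pi, length.out = n + 1L)[-1L]
  1 / sqrt(mean(f(th)^2))
}

# brute-force assignment by exhaustive permutation search (n <= 7)
brute_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  best <- NULL
  best_cost <- Inf
  for (p in perms(seq_len(n))) {
    cc <- sum(cost[cbind(seq_len(n), p)])
    if (cc < best_cost) {
      best_cost <- cc
      best <- p
    }
  }
  list(assignment = best, cost = best_cost)
}

# small pair-state sample on a fixed grid, for parity checks
grid_pair_states <- function(n_d = 5, n_a = 9) {
  g <- expand.grid(d = seq(20, 180, length.out = n_d),
                   psi = seq(-pi + 0.1, pi - 0.1, length.out = n_a),
                   delta_phi = seq(-pi + 0.1, pi - 0.1, length.out = n_a))
  pair_state(g$d, g$psi, g$delta_phi)
}

quick_params <- function(...) {
  p <- default_light_params(50, 1)
  over <- list(...)
  for (nm in names(over)) p[[nm]] <- over[[nm]]
  p
}
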