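# Brute-force oracles kept deliberately independent of the package's
# vectorized implementations.

# mean resultant length via an explicit complex sum
vs_oracle <- function(angles) {
  z <- sum(complex(modulus = 1, argument = angles)) / length(angles)
  Mod(z)
}

# causal-window accuracy by direct per-frame loops
acc_oracle <- function(theta, bump, window_frames) {
  off <- wrap_angle(bump - theta)
  vapply(seq_along(off), function(i) {
    w <- off[max(1, i - window_frames + 1):i]
    vs_oracle(w)
  }, numeric(1))
}

# dense-grid posterior for the conflict regression, aggregated onto 5x5x5
# coarse bins over a in [-3,3], b in [-pi,pi), log kappa in [log .05, log 100]
bin5 <- function(x, lo, hi) pmin(5L, pmax(1L, 1L + floor(5 * (x - lo) / (hi - lo))))

grid_conflict_bins <- function(data, priors = conflict_priors(),
                               n_a = 61, n_b = 60, n_k = 60) {
  a_grid <- seq(-3, 3, length.out = n_a)
  b_grid <- -pi + (seq_len(n_b) - 1) * 2 * pi / n_b
  lk_grid <- seq(log(0.05), log(100), length.out = n_k)
  lp <- array(NA_real_, c(n_a, n_b, n_k))
  for (ik in seq_len(n_k)) {
    kap <- exp(lk_grid[ik])
    log_i0 <- log(besselI(kap, 0, expon.scaled = TRUE)) + kap
    lprior_k <- priors$kappa_shape * log(priors$kappa_scale) -
      lgamma(priors$kappa_shape) - (priors$kappa_shape + 1) * log(kap) -
      priors$kappa_scale / kap + log(kap)
    for (ib in seq_len(n_b)) {
      for (ia in seq_len(n_a)) {
        mu <- a_grid[ia] * data$theta + b_grid[ib]
        ll <- sum(kap * cos(data$phi - mu)) -
          nrow(data) * (log(2 * pi) + log_i0)
        lp[ia, ib, ik] <- ll +
          dnorm(a_grid[ia], 0, priors$a_sd, log = TRUE) + lprior_k
      }
    }
  }
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  ab <- bin5(a_grid, -3, 3)
  bb <- bin5(b_grid, -pi, pi)
  kb <- bin5(lk_grid, log(0.05), log(100))
  coarse <- array(0, c(5, 5, 5))
  for (ia in seq_len(n_a)) for (ib in seq_len(n_b)) for (ik in seq_len(n_k)) {
    coarse[ab[ia], bb[ib], kb[ik]] <- coarse[ab[ia], bb[ib], kb[ik]] + w[ia, ib, ik]
  }
  coarse
}

bin_draws5 <- function(draws) {
  h <- array(0, c(5, 5, 5))
  ia <- bin5(draws$a, -3, 3)
  ib <- bin5(draws$b, -pi, pi)
  ik <- bin5(log(draws$kappa), log(0.05), log(100))
  for (j in seq_along(ia)) h[ia[j], ib[j], ik[j]] <- h[ia[j], ib[j], ik[j]] + 1
  h / sum(h)
}

# short trajectory for quick simulations
quick_trace <- function(duration, seed, ...) {
  generate_trajectory(trajectory_params(duration = duration, ...), seed)
}
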