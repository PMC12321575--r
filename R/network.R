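#' EPG ring-network parameters
#'
#' Rate dynamics of the `N` EPG (compass) neurons arranged on a ring:
#' `tau df_n/dt = -f_n + [alpha f_n + D (f_{n-1} + f_{n+1})
#'   + (v / v_rel) (f_{n+1} - f_{n-1}) / 2 - beta sum_l f_l + I_n1 + I_n2 + 1]_+`
#' with circular neighbor indexing, global inhibition `beta`, angular-velocity
#' advection scaled by `v_rel`, inhibitory cue inputs `I_k = -W_k g_k`, and a
#' tonic drive of 1 inside the rectification.
#'
#' @param N Number of EPG neurons. Default 32.
#' @param tau Time constant (s). Default 0.05.
#' @param alpha Self-interaction. Default -8.93.
#' @param D Nearest-neighbor excitation. Default 5.19.
#' @param beta Global inhibition. Default 0.11.
#' @param v_rel Velocity scaling (rad/s). Default 3.64.
#' @param const_drive Tonic input. Default 1.
#' @param dt Euler step (s). Default 0.0025.
#' @return A list of class `network_params`.
#' @export
network_params <- function(N = 32L, tau = 0.05, alpha = -8.93, D = 5.19,
                           beta = 0.11, v_rel = 3.64, const_drive = 1,
                           dt = 0.0025) {
  stopifnot(N >= 3, tau > 0, dt > 0, dt < tau)
  p <- list(N = as.integer(N), tau = tau, alpha = alpha, D = D, beta = beta,
            v_rel = v_rel, const_drive = const_drive, dt = dt)
  class(p) <- "network_params"
  p
}

#' Plasticity parameters of the ER-to-EPG synapses
#'
#' The inhibitory weights evolve by the postsynaptically gated rule
#' `dW_nm/dt = eta |v| f_n (w_max (1 - g_m / g0) - W_nm)`: non-associative
#' potentiation toward `w_max` gated by postsynaptic rate, and associative
#' depression where pre- and postsynaptic activity coincide. Learning is
#' velocity gated (`|v|`). Weights are clipped at zero after each Euler step,
#' reconciling the rule's negative fixed point for `g > g0` with the
#' constraint that inhibitory weights are non-negative.
#'
#' @param eta Base learning rate. Default 0.34.
#' @param w_max Weight scale. Default 1/17.
#' @param g0 Presynaptic normalization. Default 1.
#' @param init_frobenius_norm Frobenius norm of each initial weight matrix.
#'   Default 1.5.
#' @param clip_nonnegative Clip weights at zero each step? Default `TRUE`.
#' @return A list of class `plasticity_params`.
#' @export
plasticity_params <- function(eta = 0.34, w_max = 1 / 17, g0 = 1,
                              init_frobenius_norm = 1.5,
                              clip_nonnegative = TRUE) {
  stopifnot(eta >= 0, w_max > 0, g0 > 0, init_frobenius_norm >= 0)
  p <- list(eta = eta, w_max = w_max, g0 = g0,
            init_frobenius_norm = init_frobenius_norm,
            clip_nonnegative = clip_nonnegative)
  class(p) <- "plasticity_params"
  p
}

# Angle carried by each EPG neuron. Positive angular velocity advects the
# bump toward lower indices under the advection term, so the ring is read
# out with a negative index-to-angle slope; the bump then follows
# +theta_true in closed loop (validated by the tracking tests).
epg_angles <- function(N) wrap_angle(-2 * pi * (seq_len(N) - 1) / N)

#' Initialize the network state
#'
#' The EPG rates start from a raised-cosine profile and relax for 20 s with
#' zero velocity and zero cue input, defining the steady-state bump `f_ss`
#' (its amplitude, peak minus trough, is ~1.062 with default parameters).
#' Each ER-to-EPG weight matrix is drawn elementwise from uniform `[0, 1)`
#' and rescaled to Frobenius norm `init_frobenius_norm`.
#'
#' @param net A [network_params()] object.
#' @param plast A [plasticity_params()] object.
#' @param n_cues Number of cue pathways (1 or 2).
#' @param seed Integer seed for the weight draw.
#' @param M Number of ER neurons per cue. Default 32.
#' @param relax_duration Relaxation time (s). Default 20.
#' @return A list of class `network_state` with fields `f`, `W` (list of
#'   `N x M` matrices), `t`, `f_ss_profile`, `f_ss_amplitude`, `f_ss_sum`.
#' @export
initialize_network <- function(net, plast, n_cues = 1L, seed = 1, M = 32L,
                               relax_duration = 20) {
  stopifnot(inherits(net, "network_params"), inherits(plast, "plasticity_params"),
            n_cues %in% c(1L, 2L))
  f_ss <- relax_to_steady_state(net, relax_duration)
  seeds <- derive_seeds(seed, paste0("weights", seq_len(n_cues)))
  W <- lapply(seq_len(n_cues), function(k) {
    Wk <- withr::with_seed(seeds[[k]],
                           matrix(stats::runif(net$N * M), net$N, M))
    Wk * (plast$init_frobenius_norm / sqrt(sum(Wk^2)))
  })
  state <- list(f = f_ss$f, W = W, t = 0,
                f_ss_profile = f_ss$f,
                f_ss_amplitude = f_ss$amplitude,
                f_ss_sum = f_ss$sum)
  class(state) <- "network_state"
  state
}

# Relax the rate equation from a raised-cosine start with v = 0, I = 0.
relax_to_steady_state <- function(net, relax_duration = 20, tol = 1e-7) {
  n_steps <- as.integer(round(relax_duration / net$dt))
  f0 <- 0.5 * (1 + cos(2 * pi * (seq_len(net$N) - 1) / net$N))
  res <- sim_core(v = numeric(n_steps),
                  theta_in = matrix(0, n_steps, 1),
                  A = matrix(0, n_steps, 1),
                  kappa_cue = 1, theta_pref = matrix(0, 1, 1),
                  noise_bound = 0,
                  tau = net$tau, alpha = net$alpha, D = net$D, beta = net$beta,
                  v_rel = net$v_rel, drive = net$const_drive, dt = net$dt,
                  eta = 0, w_max = 1, g0 = 1, clip = TRUE,
                  f0 = f0, W0 = list(matrix(0, net$N, 1)),
                  record_every = 0L, w_record_every = 0L)
  f1 <- res$f_final
  # one more step to confirm settling
  res2 <- sim_core(v = numeric(1), theta_in = matrix(0, 1, 1),
                   A = matrix(0, 1, 1), kappa_cue = 1,
                   theta_pref = matrix(0, 1, 1), noise_bound = 0,
                   tau = net$tau, alpha = net$alpha, D = net$D, beta = net$beta,
                   v_rel = net$v_rel, drive = net$const_drive, dt = net$dt,
                   eta = 0, w_max = 1, g0 = 1, clip = TRUE,
                   f0 = f1, W0 = list(matrix(0, net$N, 1)),
                   record_every = 0L, w_record_every = 0L)
  if (max(abs(res2$f_final - f1)) > tol) {
    stop("network failed to settle during initialization; check parameters")
  }
  list(f = f1, amplitude = max(f1) - min(f1), sum = sum(f1))
}

# Circularly wrapped Gaussian smoothing kernel, truncated at 4 sigma.
gauss_kernel <- function(n, sigma) {
  h <- min(ceiling(4 * sigma), floor((n - 1) / 2))
  k <- exp(-((-h):h)^2 / (2 * sigma^2))
  k <- k / sum(k)
  Kmat <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- ((i - 1 + (-h):h) %% n) + 1
    Kmat[i, idx] <- Kmat[i, idx] + k
  }
  Kmat
}

# Smooth an N x M matrix with a Gaussian filter wrapped on both axes.
smooth_weight_matrix <- function(W, sigma = 2) {
  gauss_kernel(nrow(W), sigma) %*% W %*% t(gauss_kernel(ncol(W), sigma))
}

#' Notch depth of a weight matrix
#'
#' Learning etches a band of weakened inhibitory weights (the "notch") into
#' the ER-to-EPG matrix. Its depth is measured as max minus min of the matrix
#' after smoothing with a Gaussian filter (s.d. `sigma_smooth` matrix
#' elements) wrapped on both axes, since both index circular variables.
#'
#' @param W An `N x M` weight matrix.
#' @param sigma_smooth Gaussian s.d. in matrix elements. Default 2.
#' @return Max minus min of the smoothed matrix.
#' @export
notch_depth <- function(W, sigma_smooth = 2) {
  S <- smooth_weight_matrix(W, sigma_smooth)
  max(S) - min(S)
}

#' Advance the network state by one Euler step
#'
#' One synchronous explicit-Euler step of the rate equation and the plasticity
#' rule, given the instantaneous ER activity vectors. The weight update uses
#' the pre-step rates and is gated by both postsynaptic rate and `|v|`;
#' weights are clipped at zero afterwards.
#'
#' @param state A `network_state` from [initialize_network()].
#' @param v_t Angular velocity at this step (rad/s).
#' @param g List of ER activity vectors, one per cue (length `M` each).
#' @param net A [network_params()] object.
#' @param plast A [plasticity_params()] object.
#' @return The updated `network_state` (time advanced by `dt`).
#' @export
step_network <- function(state, v_t, g, net, plast) {
  stopifnot(inherits(state, "network_state"), length(g) == length(state$W))
  f <- state$f
  N <- length(f)
  fp <- f[c(2:N, 1)]
  fm <- f[c(N, 1:(N - 1))]
  I <- 0
  for (k in seq_along(g)) I <- I - as.numeric(state$W[[k]] %*% g[[k]])
  inp <- net$alpha * f + net$D * (fm + fp) + 0.5 * (v_t / net$v_rel) * (fp - fm) -
    net$beta * sum(f) + I + net$const_drive
  f_new <- f + net$dt / net$tau * (-f + pmax(inp, 0))
  if (any(!is.finite(f_new))) stop("EPG rates became non-finite (blow-up)")
  coef <- plast$eta * abs(v_t) * net$dt
  if (coef > 0) {
    state$W <- lapply(seq_along(g), function(k) {
      target <- outer(f, plast$w_max * (1 - g[[k]] / plast$g0),
                      function(fn, tg) tg)
      Wk <- state$W[[k]] + coef * f * (target - state$W[[k]])
      if (plast$clip_nonnegative) Wk[Wk < 0] <- 0
      if (any(!is.finite(Wk))) stop("weights became non-finite (blow-up)")
      Wk
    })
  }
  state$f <- f_new
  state$t <- state$t + net$dt
  state
}

# Bump position of one activity profile: angle of the circular argmax
# (lowest index on ties).
bump_position <- function(f, angles) angles[which.max(f)]

#' Full width at half maximum of a circular activity profile
#'
#' Model-convention bump width: starting from the circular argmax, the
#' profile is walked in both directions to the first crossings of
#' `trough + (peak - trough)/2`, with linear interpolation between samples.
#' Returns `NA` for a flat profile and `2*pi` when the profile never falls
#' below half maximum.
#'
#' @param f Activity values on an evenly spaced circular grid.
#' @param d_angle Angular spacing of the grid (radians). Default `2*pi/length(f)`.
#' @return Width in radians.
#' @export
fwhm_circular <- function(f, d_angle = 2 * pi / length(f)) {
  n <- length(f)
  pk <- which.max(f)
  lo <- min(f)
  amp <- f[pk] - lo
  if (amp <= 0) return(NA_real_)
  half <- lo + amp / 2
  cross <- function(dir) {
    prev <- f[pk]
    for (s in seq_len(n - 1)) {
      i <- ((pk - 1 + dir * s) %% n) + 1
      if (f[i] < half) {
        return((s - 1) + (prev - half) / (prev - f[i]))
      }
      prev <- f[i]
    }
    NA_real_
  }
  r <- cross(1L); l <- cross(-1L)
  if (is.na(r) || is.na(l)) return(2 * pi)
  (r + l) * d_angle
}
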