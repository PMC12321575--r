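#' Parameters of the simulated heading trajectory
#'
#' The simulated fly's head direction (HD) is a smoothed Gaussian random walk:
#' per-step displacements `du ~ N(0, sigma_u^2 dt)` are converted to raw
#' angular velocities `du/dt`, smoothed with a centered running average to give
#' the true velocity, and integrated to give the HD sequence. The network is
#' driven by a noisy copy of the velocity (white noise of s.d. `sigma_AV`,
#' smoothed over a short window).
#'
#' @param sigma_u Motion-noise scale (rad s^-1/2); s.d. of per-step HD
#'   displacements is `sigma_u * sqrt(dt)`. Default 8.
#' @param sigma_AV S.d. of the velocity white noise (rad/s). Default 1.
#' @param smooth_window_v Centered window for the true velocity (s). Default 2.5.
#' @param smooth_window_noise Centered window for the velocity noise (s).
#'   Default 0.04.
#' @param dt Integration step (s). Default 0.0025.
#' @param duration Trial length (s, simulation time).
#' @return A list of class `trajectory_params`.
#' @export
trajectory_params <- function(sigma_u = 8, sigma_AV = 1,
                              smooth_window_v = 2.5,
                              smooth_window_noise = 0.04,
                              dt = 0.0025, duration = 100) {
  stopifnot(sigma_u >= 0, sigma_AV >= 0, dt > 0, duration > 0,
            smooth_window_v > 0, smooth_window_noise > 0)
  p <- list(sigma_u = sigma_u, sigma_AV = sigma_AV,
            smooth_window_v = smooth_window_v,
            smooth_window_noise = smooth_window_noise,
            dt = dt, duration = duration)
  class(p) <- "trajectory_params"
  p
}

window_span <- function(window, dt) max(1L, as.integer(round(window / dt)))

#' Generate a simulated heading trace
#'
#' Draws HD displacements, smooths the implied raw velocity with a centered
#' running average (truncated symmetrically at the sequence ends), and
#' integrates it into the ground-truth HD, wrapped to `[-pi, pi)`. The
#' `v_noisy` column is initialised equal to `v_true`; add the driving noise
#' with [add_velocity_noise()].
#'
#' @param params A [trajectory_params()] object.
#' @param seed Integer seed; the draw is deterministic given it.
#' @return A tibble of class `heading_trace` with columns `t`, `theta_true`,
#'   `v_true`, `v_noisy`, plus the raw velocity in attribute `v_raw`.
#' @export
#' @examples
#' tr <- generate_heading(trajectory_params(duration = 10), seed = 1)
#' head(tr)
generate_heading <- function(params, seed) {
  stopifnot(inherits(params, "trajectory_params"))
  n <- as.integer(round(params$duration / params$dt))
  span <- window_span(params$smooth_window_v, params$dt)
  if (n < span) {
    stop("duration is shorter than the velocity smoothing window")
  }
  seeds <- derive_seeds(seed, c("heading"))
  v_raw <- withr::with_seed(seeds[["heading"]], {
    stats::rnorm(n, 0, params$sigma_u * sqrt(params$dt)) / params$dt
  })
  v_true <- running_mean(v_raw, span)
  theta <- wrap_angle(cumsum(v_true) * params$dt)
  out <- tibble::tibble(
    t = seq_len(n) * params$dt,
    theta_true = theta,
    v_true = v_true,
    v_noisy = v_true
  )
  attr(out, "params") <- params
  attr(out, "v_raw") <- v_raw
  class(out) <- c("heading_trace", class(out))
  out
}

#' Add smoothed Gaussian noise to the driving velocity
#'
#' `v_noisy = v_true + eps`, where `eps` is Gaussian white noise of s.d.
#' `sigma_AV` smoothed with a short centered running average. The ground-truth
#' columns are unchanged.
#'
#' @param trace A `heading_trace` from [generate_heading()].
#' @param params The same [trajectory_params()] used to build `trace`.
#' @param seed Integer seed for the noise sub-stream.
#' @return The trace with `v_noisy` replaced.
#' @export
add_velocity_noise <- function(trace, params, seed) {
  stopifnot(inherits(trace, "heading_trace"), inherits(params, "trajectory_params"))
  n <- nrow(trace)
  if (n != as.integer(round(params$duration / params$dt))) {
    stop("trace length does not match params time grid")
  }
  if (params$sigma_AV == 0) {
    trace$v_noisy <- trace$v_true
    return(trace)
  }
  seeds <- derive_seeds(seed, c("heading", "av_noise"))
  span <- window_span(params$smooth_window_noise, params$dt)
  # raw white noise scaled so the smoothed process has s.d. sigma_AV
  eps <- withr::with_seed(seeds[["av_noise"]],
                          stats::rnorm(n, 0, params$sigma_AV * sqrt(span)))
  trace$v_noisy <- trace$v_true + running_mean(eps, span)
  trace
}

#' Generate a heading trace with driving noise in one call
#'
#' Convenience wrapper running [generate_heading()] then
#' [add_velocity_noise()] with sub-streams derived from one root seed.
#'
#' @inheritParams generate_heading
#' @return A `heading_trace` tibble.
#' @export
generate_trajectory <- function(params, seed) {
  add_velocity_noise(generate_heading(params, seed), params, seed)
}
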