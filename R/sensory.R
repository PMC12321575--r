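#' Convert an ER tuning width to a von Mises precision
#'
#' The ER activity profile `A exp[kappa (cos(d) - 1)]` falls to half its peak
#' at angular distance `width/2` exactly when
#' `kappa = log(2) / (1 - cos(width / 2))`; this function returns that value.
#'
#' @param width Full tuning width (radians), in `(0, 2*pi)`.
#' @return The precision `kappa`.
#' @export
#' @examples
#' kappa_from_width(0.8)  # ~8.781
kappa_from_width <- function(width) {
  if (any(width <= 0 | width >= 2 * pi)) {
    stop("width must lie strictly between 0 and 2*pi")
  }
  log(2) / (1 - cos(width / 2))
}

#' Parameters of one ER (ring neuron) population
#'
#' Each cue is carried by `M` inhibitory ring neurons with von Mises-shaped
#' tuning to cue direction. The population amplitude is specified as a
#' dimensionless scale `A_scale`; the absolute amplitude is
#' `A_scale * f_ss_amplitude`, the steady-state EPG bump amplitude, and is
#' filled in at simulation time. Baseline noise per neuron and step is
#' uniform on `[0, b_ER * mean(f_ss))`, the steady-state mean EPG rate
#' scaled by `b_ER`.
#'
#' @param M Number of ER neurons for this cue. Default 32.
#' @param A_scale Dimensionless amplitude scale. Default 1.
#' @param width Full tuning width (radians). Default 0.8.
#' @param b_ER Baseline-noise factor. Default 0.45.
#' @return A list of class `er_params` with fields `M`, `A_scale`, `width`,
#'   `kappa`, `b_ER`, `preferred_dirs` (evenly spaced on `[-pi, pi)`).
#' @export
er_params <- function(M = 32L, A_scale = 1, width = 0.8, b_ER = 0.45) {
  stopifnot(M >= 2, A_scale >= 0, b_ER >= 0)
  p <- list(M = as.integer(M), A_scale = A_scale, width = width,
            kappa = kappa_from_width(width), b_ER = b_ER,
            preferred_dirs = wrap_angle(2 * pi * (seq_len(M) - 1) / M - pi))
  class(p) <- "er_params"
  p
}

#' ER population activity for one time step
#'
#' Element `m` is `eps_m + A * exp[kappa (cos(theta_input - theta_m) - 1)]`
#' with `eps_m ~ uniform(0, b_ER * f_ss_mean)` drawn independently per neuron.
#' Used directly in tests and small analyses; the simulator core evaluates the
#' same expression in compiled code.
#'
#' @param theta_input Tuning argument (radians): the cue-defined direction,
#'   already gain- and shift-transformed via [input_angle()].
#' @param params An [er_params()] object.
#' @param A Absolute population amplitude (`A_scale * f_ss_amplitude`).
#' @param f_ss_mean Mean steady-state EPG rate (sets the noise bound).
#' @param noise Draw baseline noise? Default `TRUE`.
#' @return Numeric vector of length `M`.
#' @export
er_activity <- function(theta_input, params, A, f_ss_mean, noise = TRUE) {
  stopifnot(inherits(params, "er_params"))
  if (f_ss_mean < 0) stop("f_ss_mean must be non-negative")
  act <- A * exp(params$kappa * (cos(theta_input - params$preferred_dirs) - 1))
  if (noise && params$b_ER > 0 && f_ss_mean > 0) {
    act <- act + stats::runif(params$M, 0, params$b_ER * f_ss_mean)
  }
  act
}

#' Tuning argument of a cue under closed-loop gain and shift
#'
#' Returns `wrap(gain * theta_true + shift)`. With gain +1 and zero shift this
#' is the identity used in all normal-gain protocols; gain -1 realizes the
#' inverted-gain manipulation in which the cue rotates opposite to the fly's
#' turns.
#'
#' @param theta_true True heading (radians), vectorised.
#' @param gain Closed-loop gain, +1 or -1.
#' @param shift Cumulative cue shift (radians).
#' @return Wrapped angles on `[-pi, pi)`.
#' @export
input_angle <- function(theta_true, gain = 1, shift = 0) {
  wrap_angle(gain * theta_true + shift)
}
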