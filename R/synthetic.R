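#' Parameters of a synthetic imaging-like recording
#'
#' Emulates the statistical structure of a population recording of the
#' compass bump: per-frame activity over 25-40 regions of interest (ROIs) at
#' ~9.18 frames/s, a von Mises bump whose position follows
#' `wrap(-hd + offset)` (imaging convention), i.i.d. Gaussian ROI noise, and
#' optional immobile epochs during which heading freezes and speed is zero.
#'
#' @param n_rois Number of ROIs (25-40). Default 32.
#' @param frame_rate Frames per second. Default 9.18.
#' @param duration Recording length (s). Default 120.
#' @param amp_coeff,kappa,baseline Truth von Mises parameters of each frame's
#'   profile `a exp(kappa cos(x - mu)) + c`. Defaults 1, 4, 0.1.
#' @param offset Constant bump-to-heading offset (radians). Default 0.
#' @param noise_sd Additive per-ROI Gaussian noise s.d. Default 0.
#' @param immobile_epochs List of `c(start, end)` intervals (s). Default none.
#' @param traj A [trajectory_params()] object used to draw the heading.
#' @return A list of class `synthetic_recording_params`.
#' @export
synthetic_recording_params <- function(n_rois = 32L, frame_rate = 9.18,
                                       duration = 120, amp_coeff = 1,
                                       kappa = 4, baseline = 0.1,
                                       offset = 0, noise_sd = 0,
                                       immobile_epochs = list(),
                                       traj = NULL) {
  stopifnot(n_rois >= 25, n_rois <= 40, frame_rate > 0, noise_sd >= 0,
            kappa >= 0)
  if (is.null(traj)) traj <- trajectory_params(duration = duration)
  p <- list(n_rois = as.integer(n_rois), frame_rate = frame_rate,
            duration = duration, amp_coeff = amp_coeff, kappa = kappa,
            baseline = baseline, offset = offset, noise_sd = noise_sd,
            immobile_epochs = immobile_epochs, traj = traj)
  class(p) <- "synthetic_recording_params"
  p
}

# downsample a heading trace to the frame grid, freezing hd (and zeroing
# speed) inside immobile epochs
frame_behavior <- function(params, seed) {
  trace <- generate_trajectory(params$traj, seed)
  tf <- seq(1 / params$frame_rate, params$duration, by = 1 / params$frame_rate)
  idx <- pmin(nrow(trace), pmax(1L, as.integer(round(tf / params$traj$dt))))
  hd <- trace$theta_true[idx]
  speed <- abs(trace$v_true[idx])
  for (ep in params$immobile_epochs) {
    sel <- tf >= ep[1] & tf < ep[2]
    if (any(sel)) {
      first <- which(sel)[1]
      frozen <- if (first > 1) hd[first - 1] else hd[first]
      hd[sel] <- frozen
      speed[sel] <- 0
    }
  }
  tibble::tibble(t = tf, hd = hd, speed = speed)
}

#' Generate a synthetic imaging-like recording
#'
#' Each frame's ROI profile is a truth von Mises bump
#' `a exp(kappa cos(x - mu(t))) + c` with `mu(t) = wrap(-hd(t) + offset)`,
#' plus i.i.d. Gaussian noise. The generating parameters are attached as the
#' `truth` attribute for recovery tests only; no analysis function reads
#' them.
#'
#' @param params A [synthetic_recording_params()] object.
#' @param seed Integer seed.
#' @return A list of class `synthetic_recording` with `dff` (frames x ROIs),
#'   `roi_angles`, `behavior` (tibble: `t`, `hd`, `speed`), `cue_pos`
#'   (tibble: `t`, `cue`, `ref`), and attribute `truth`.
#' @export
generate_recording <- function(params, seed = 1) {
  stopifnot(inherits(params, "synthetic_recording_params"))
  seeds <- derive_seeds(seed, c("behavior", "noise"))
  beh <- frame_behavior(params, seeds[["behavior"]])
  roi_angles <- wrap_angle(2 * pi * (seq_len(params$n_rois) - 1) / params$n_rois - pi)
  mu <- wrap_angle(-beh$hd + params$offset)
  dff <- params$amp_coeff *
    exp(params$kappa * cos(outer(mu, roi_angles, "-"))) + params$baseline
  if (params$noise_sd > 0) {
    dff <- dff + withr::with_seed(
      seeds[["noise"]],
      matrix(stats::rnorm(length(dff), 0, params$noise_sd), nrow(dff)))
  }
  out <- list(dff = dff, roi_angles = roi_angles, behavior = beh,
              cue_pos = tibble::tibble(t = beh$t, cue = 1L, ref = 0))
  attr(out, "truth") <- list(mu = mu, amp_coeff = params$amp_coeff,
                             kappa = params$kappa, baseline = params$baseline,
                             offset = params$offset)
  class(out) <- "synthetic_recording"
  out
}

#' Generate a synthetic two-cue shift experiment
#'
#' Builds a recording in which the bump keeps a fixed offset to one cue (the
#' `follow` cue) across alternating ±120° shifts of the visual (cue 1) and
#' wind (cue 2) cues. At each shift of the followed cue the bump jumps with
#' it, so the offset to the other cue changes by the shift; shifts of the
#' other cue leave the bump in place. Bump preference indices computed from
#' this fixture are -1 (follow = visual) or +1 (follow = wind) by
#' construction.
#'
#' @param params A [synthetic_recording_params()] object.
#' @param follow `"visual"` or `"wind"`.
#' @param shift_interval Seconds between shifts. Default 12.5.
#' @param n_shifts Number of shifts (alternating, visual first). Default 8.
#' @param seed Integer seed.
#' @return A `synthetic_recording` whose `cue_pos` table holds each cue's
#'   cumulative reference angle per frame, with the shift events in
#'   attribute `shift_events`.
#' @export
generate_shift_experiment <- function(params, follow = c("visual", "wind"),
                                      shift_interval = 12.5, n_shifts = 8,
                                      seed = 1) {
  follow <- match.arg(follow)
  stopifnot(inherits(params, "synthetic_recording_params"))
  seeds <- derive_seeds(seed, c("behavior", "noise", "shifts"))
  beh <- frame_behavior(params, seeds[["behavior"]])
  n_shifts <- as.integer(n_shifts)
  events <- tibble::tibble(
    time = shift_interval * seq_len(n_shifts),
    cue = rep(c(1L, 2L), length.out = n_shifts),
    shift = withr::with_seed(seeds[["shifts"]],
                             sample(c(-1, 1), n_shifts, replace = TRUE)) * 2 * pi / 3)
  if (n_shifts > 0 && max(events$time) + shift_interval > params$duration) {
    stop("duration too short for the requested shifts")
  }
  ref <- matrix(0, nrow(beh), 2)
  for (i in seq_len(nrow(events))) {
    sel <- beh$t > events$time[i]
    ref[sel, events$cue[i]] <- ref[sel, events$cue[i]] + events$shift[i]
  }
  follow_k <- if (follow == "visual") 1L else 2L
  # bump keeps params$offset to the followed cue's reference
  mu <- wrap_angle(-beh$hd + ref[, follow_k] + params$offset)
  roi_angles <- wrap_angle(2 * pi * (seq_len(params$n_rois) - 1) / params$n_rois - pi)
  dff <- params$amp_coeff *
    exp(params$kappa * cos(outer(mu, roi_angles, "-"))) + params$baseline
  if (params$noise_sd > 0) {
    dff <- dff + withr::with_seed(
      seeds[["noise"]],
      matrix(stats::rnorm(length(dff), 0, params$noise_sd), nrow(dff)))
  }
  out <- list(dff = dff, roi_angles = roi_angles, behavior = beh,
              cue_pos = tibble::tibble(
                t = rep(beh$t, 2), cue = rep(1:2, each = nrow(beh)),
                ref = c(ref[, 1], ref[, 2])))
  attr(out, "truth") <- list(mu = mu, follow = follow, offset = params$offset)
  attr(out, "shift_events") <- events
  class(out) <- "synthetic_recording"
  out
}

#' Generate a synthetic conflict dataset
#'
#' Conflicts `theta_n` are uniform on `[-pi, pi)`; offset changes are
#' `phi_n = wrap(a theta_n + b + e_n)` with `e_n ~ vonMises(0, kappa)`.
#'
#' @param a Slope.
#' @param b Offset (radians).
#' @param kappa Noise concentration (> 0).
#' @param n Number of pairs.
#' @param seed Integer seed.
#' @return A tibble with columns `theta`, `phi`.
#' @export
generate_conflict_dataset <- function(a, b, kappa, n, seed = 1) {
  stopifnot(kappa > 0, n >= 1)
  withr::with_seed(seed, {
    theta <- stats::runif(n, -pi, pi)
    phi <- wrap_angle(a * theta + b + rvonmises(n, 0, kappa))
    tibble::tibble(theta = theta, phi = phi)
  })
}
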