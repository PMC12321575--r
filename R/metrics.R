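#' Configuration of the bump/behavior metrics
#'
#' @param accuracy_window Causal window for HD encoding accuracy (s).
#'   Default 8.
#' @param r2_threshold Adjusted-R^2 gate below which a von Mises frame fit is
#'   flagged invalid. Default 0.5.
#' @param movement_threshold Rotational speed below which a frame counts as
#'   immobile (rad/s). Not printed in the source experiments; default 0.05,
#'   configurable.
#' @param notch_sigma Gaussian s.d. for weight-matrix smoothing (elements).
#'   Default 2.
#' @param pre_window,post_window Lengths (s) of the windows before/after a cue
#'   shift over which offsets are averaged. Model default 5 and 5; imaging
#'   analyses use 120 and 120.
#' @param post_delay Delay (s) between the shift and the start of the post
#'   window. Model default 0; imaging analyses use 30 (offsets take ~30 s to
#'   stabilize after a shift).
#' @return A list of class `metrics_config`.
#' @export
metrics_config <- function(accuracy_window = 8, r2_threshold = 0.5,
                           movement_threshold = 0.05, notch_sigma = 2,
                           pre_window = 5, post_window = 5, post_delay = 0) {
  stopifnot(accuracy_window > 0, r2_threshold >= 0, r2_threshold <= 1,
            movement_threshold >= 0, pre_window > 0, post_window > 0,
            post_delay >= 0)
  cfg <- list(accuracy_window = accuracy_window, r2_threshold = r2_threshold,
              movement_threshold = movement_threshold,
              notch_sigma = notch_sigma, pre_window = pre_window,
              post_window = post_window, post_delay = post_delay)
  class(cfg) <- "metrics_config"
  cfg
}

# log(cosh(k)) computed without overflow
log_cosh <- function(k) k + log1p(exp(-2 * k)) - log(2)

# Derived width/amplitude of a von Mises profile fit f(x) = a exp(k cos(x-mu)) + c
vm_fit_width <- function(kappa) {
  if (kappa <= 0) return(pi)
  2 * abs(acos(pmin(1, log_cosh(kappa) / kappa)))
}
vm_fit_amplitude <- function(amp_coeff, kappa) {
  amp_coeff * (exp(kappa) - exp(-kappa))
}

#' Fit a von Mises profile to one activity frame
#'
#' Least-squares fit of `f(x) = a exp(kappa cos(x - mu)) + c` to a population
#' activity profile sampled on a circular grid, with `a >= 0` and
#' `kappa >= 0`. For fixed `(kappa, mu)` the model is linear in `(a, c)`, so
#' the outer optimization runs over `(kappa, mu)` only, started from the
#' activity-weighted circular mean of the angles and from its antipode (the
#' residual landscape is bimodal in `mu`); the lower-residual solution wins.
#' The derived bump width is
#' `2 |acos(log(0.5 (e^kappa + e^-kappa)) / kappa)|` and the derived amplitude
#' `a (e^kappa - e^-kappa)`. Fits with adjusted R^2 (4 parameters) below
#' `config$r2_threshold` are flagged invalid.
#'
#' @param profile Activity values (length >= 8).
#' @param angles Angles of the samples (radians), spanning the circle.
#' @param config A [metrics_config()] object.
#' @return A one-row tibble of class `bump_fit`: `mu`, `kappa`, `amp_coeff`,
#'   `baseline`, `adj_r2`, `width`, `amplitude`, `valid`.
#' @export
fit_bump_profile <- function(profile, angles, config = metrics_config()) {
  n <- length(profile)
  if (n < 8 || length(angles) != n) {
    stop("need at least 8 samples with one angle each")
  }
  w <- pmax(profile - min(profile), 0)
  mu0 <- if (sum(w) > 0) atan2(sum(w * sin(angles)), sum(w * cos(angles))) else 0

  # linear (a, c) solve for fixed (kappa, mu); returns residual sum of squares
  solve_ac <- function(kappa, mu) {
    b <- exp(kappa * (cos(angles - mu) - 1))  # scaled basis, max 1
    X <- cbind(b, 1)
    fit <- tryCatch(stats::lm.fit(X, profile), error = function(e) NULL)
    if (is.null(fit)) return(list(rss = Inf))
    a_s <- unname(fit$coefficients[1]); c0 <- unname(fit$coefficients[2])
    if (is.na(a_s) || a_s < 0) {  # constrained: flat fit
      c0 <- mean(profile); a_s <- 0
    }
    r <- profile - (a_s * b + c0)
    list(rss = sum(r^2), a = a_s * exp(-kappa), c = c0)
  }
  obj <- function(p) solve_ac(exp(p[1]), p[2])$rss
  best <- NULL
  for (mu_start in c(mu0, wrap_angle(mu0 + pi))) {
    for (lk in log(c(0.5, 2, 8))) {
      o <- tryCatch(
        stats::optim(c(lk, mu_start), obj, method = "L-BFGS-B",
                     lower = c(log(1e-4), mu_start - pi),
                     upper = c(log(500), mu_start + pi)),
        error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
  }
  kappa <- exp(best$par[1]); mu <- wrap_angle(best$par[2])
  ac <- solve_ac(kappa, mu)
  rss <- ac$rss
  tss <- sum((profile - mean(profile))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  adj_r2 <- if (n > 4) 1 - (1 - r2) * (n - 1) / (n - 4) else NA_real_
  out <- tibble::tibble(
    mu = mu, kappa = kappa, amp_coeff = ac$a, baseline = ac$c,
    adj_r2 = adj_r2,
    width = vm_fit_width(kappa),
    amplitude = vm_fit_amplitude(ac$a, kappa),
    valid = !is.na(adj_r2) && adj_r2 >= config$r2_threshold)
  class(out) <- c("bump_fit", class(out))
  out
}

#' Fit every frame of a recording
#'
#' @param dff Frames x ROIs activity matrix.
#' @param roi_angles Angle of each ROI (radians).
#' @param config A [metrics_config()] object.
#' @return A tibble with one [fit_bump_profile()] row per frame plus a
#'   `frame` column.
#' @export
fit_bump_frames <- function(dff, roi_angles, config = metrics_config()) {
  fits <- purrr::map_dfr(seq_len(nrow(dff)), function(i) {
    fit_bump_profile(dff[i, ], roi_angles, config)
  })
  dplyr::mutate(fits, frame = dplyr::row_number(), .before = 1)
}

#' Bump-to-heading offset series
#'
#' `offset = bump position - (-HD)`, i.e. `wrap(bump_pos + hd)` in the
#' imaging convention (the bump rotates opposite to HD in the ellipsoid
#' body). Frames with rotational speed below `config$movement_threshold` are
#' flagged immobile.
#'
#' @param bump_pos Bump positions (radians).
#' @param hd Heading (radians).
#' @param speed Rotational speed (rad/s).
#' @param config A [metrics_config()] object.
#' @param t Optional time grid; row index is used if omitted.
#' @return A tibble with columns `t`, `offset`, `moving`.
#' @export
offset_series <- function(bump_pos, hd, speed, config = metrics_config(),
                          t = NULL) {
  n <- length(bump_pos)
  if (length(hd) != n || length(speed) != n) {
    stop("bump_pos, hd and speed must have equal lengths")
  }
  tibble::tibble(
    t = if (is.null(t)) seq_len(n) else t,
    offset = wrap_angle(bump_pos + hd),
    moving = speed >= config$movement_threshold)
}

#' Causal-window HD encoding accuracy for model traces
#'
#' Per-frame vector strength of the bump-to-heading offsets
#' `wrap(bump_pos - theta_true)` over the causal window `(t - 8 s, t]`
#' (model convention: the simulated bump co-rotates with heading). Early
#' frames use the partial window.
#'
#' @param theta_true True heading per frame (radians).
#' @param bump_pos Bump position per frame (radians).
#' @param config A [metrics_config()] object.
#' @param frame_dt Frame spacing (s).
#' @return Numeric vector of per-frame accuracies in `[0, 1]`.
#' @export
encoding_accuracy_model <- function(theta_true, bump_pos,
                                    config = metrics_config(),
                                    frame_dt) {
  n <- length(theta_true)
  stopifnot(length(bump_pos) == n, frame_dt > 0)
  off <- wrap_angle(bump_pos - theta_true)
  w <- max(1L, as.integer(round(config$accuracy_window / frame_dt)))
  cs <- cumsum(c(0, cos(off))); ss <- cumsum(c(0, sin(off)))
  i <- seq_len(n)
  lo <- pmax(0L, i - w)
  cnt <- i - lo
  sqrt(((cs[i + 1] - cs[lo + 1]) / cnt)^2 + ((ss[i + 1] - ss[lo + 1]) / cnt)^2)
}

#' Preference index of one cue shift
#'
#' Circular-mean offsets are taken in a window before the shift and a
#' (possibly delayed) window after it, for each of two offset series; the
#' index contrasts the absolute offset changes:
#' `(|change A| - |change B|) / (|change A| + |change B|)`, in `[-1, 1]`.
#' With A = visual-cue offsets and B = wind offsets this is the bump
#' preference index (-1: the bump follows the visual cue; +1: it follows the
#' wind). `kind = "stickiness"` names the shifted/nonshifted-cue variant and
#' `kind = "behavioral"` the HD-relative-to-cue variant; the arithmetic is
#' identical, only the offset series supplied differ.
#'
#' @param offsets_cueA,offsets_cueB Tibbles with columns `t` and `offset`
#'   (e.g. from [offset_series()]).
#' @param shift_event Time of the shift (s).
#' @param config A [metrics_config()] object (fields `pre_window`,
#'   `post_window`, `post_delay`).
#' @param kind One of `"bump"`, `"stickiness"`, `"behavioral"`
#'   (documentation only).
#' @return The index, or `NA` when both offset changes are zero.
#' @export
shift_indices <- function(offsets_cueA, offsets_cueB, shift_event,
                          config = metrics_config(),
                          kind = c("bump", "stickiness", "behavioral")) {
  kind <- match.arg(kind)
  delta <- function(series) {
    pre <- series$offset[series$t >= shift_event - config$pre_window &
                           series$t < shift_event]
    post_start <- shift_event + config$post_delay
    post <- series$offset[series$t >= post_start &
                            series$t < post_start + config$post_window]
    if (!length(pre) || !length(post)) {
      stop("pre/post windows extend outside the trace")
    }
    abs(circ_diff(circ_mean(post), circ_mean(pre)))
  }
  dA <- delta(offsets_cueA); dB <- delta(offsets_cueB)
  if (dA + dB == 0) return(NA_real_)
  (dA - dB) / (dA + dB)
}

#' Remapping index
#'
#' Difference between the bump's coherence with self-motion-derived heading
#' and its coherence with the cue:
#' `vector_strength(wrap(bump - hd)) - vector_strength(wrap(bump - cue_pos))`,
#' over moving frames only. Positive values mean the bump follows heading
#' rather than the (remapped) cue. Use the sign convention of the traces
#' supplied: for imaging-convention data pass `-HD`.
#'
#' @param bump_pos,hd,cue_pos Equal-length angle series (radians).
#' @param moving Logical per-frame movement flags.
#' @param config A [metrics_config()] object.
#' @return A value in `[-1, 1]`.
#' @export
remapping_index <- function(bump_pos, hd, cue_pos, moving,
                            config = metrics_config()) {
  n <- length(bump_pos)
  stopifnot(length(hd) == n, length(cue_pos) == n, length(moving) == n)
  if (!any(moving)) stop("remapping index undefined: all frames immobile")
  b <- bump_pos[moving]; h <- hd[moving]; cp <- cue_pos[moving]
  vector_strength(wrap_angle(b - h)) - vector_strength(wrap_angle(b - cp))
}

#' Conflict / offset-change pairs for the cue-combination analysis
#'
#' The conflict is the wrapped difference between the offset with both cues
#' and the initial single-cue offset; the offset change (amount of remapping)
#' is the wrapped difference between the final and initial single-cue
#' offsets.
#'
#' @param initial_offset,both_cue_offset,final_offset Circular-mean offsets
#'   (radians), vectorised over trials/flies.
#' @return A tibble with columns `theta` (conflict) and `phi` (offset
#'   change), both on `[-pi, pi)`.
#' @export
conflict_pairs <- function(initial_offset, both_cue_offset, final_offset) {
  tibble::tibble(
    theta = circ_diff(both_cue_offset, initial_offset),
    phi = circ_diff(final_offset, initial_offset))
}
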