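#' Simulate the ring network over a heading trace and cue schedule
#'
#' Runs the full trial: initializes the network (20-s relaxation to the
#' steady-state bump, random weight matrices at Frobenius norm 1.5), expands
#' the schedule onto the time grid, and Euler-integrates the coupled
#' rate/weight dynamics at `dt = 2.5` ms driven by the noisy angular velocity.
#' ER amplitudes are `A_scale * f_ss_amplitude`; ER baseline noise is uniform
#' on `[0, b_ER * mean(f_ss))` per neuron and step (the steady-state mean
#' EPG rate sets the noise scale).
#'
#' @param trace A `heading_trace` from [generate_trajectory()].
#' @param schedule A [build_schedule()] object of matching duration.
#' @param net A [network_params()] object (its `dt` must match the trace).
#' @param plast A [plasticity_params()] object.
#' @param er An [er_params()] object, or a list of one per cue.
#' @param seed Root seed for the trial; weight-initialization and ER-noise
#'   sub-streams are derived from it.
#' @param record_every Record the EPG profile every this many steps.
#'   Default 20 (50 ms).
#' @param w_record_every Snapshot the weight matrices every this many steps.
#'   Default 200 (0.5 s).
#' @return A list of class `ring_sim` with elements `frames` (tibble: `t`,
#'   `theta_true`, `speed`, `bump_pos`, `width`, `amplitude`, and one
#'   `cue<k>_heading` column per cue), `notch` (tibble: `t`, `cue`, `notch`),
#'   `f_ss_amplitude`, `f_ss_sum`, `final_f`, `final_W`, `init_W`,
#'   `schedule`, `net`, `plast`, `seed`.
#' @export
simulate_trial <- function(trace, schedule, net = network_params(),
                           plast = plasticity_params(), er = er_params(),
                           seed = 1, record_every = 20L,
                           w_record_every = 200L) {
  stopifnot(inherits(trace, "heading_trace"), inherits(schedule, "cue_schedule"))
  K <- schedule$n_cues
  if (inherits(er, "er_params")) er <- rep(list(er), K)
  stopifnot(length(er) == K)
  n <- nrow(trace)
  tp <- attr(trace, "params")
  if (!isTRUE(all.equal(tp$dt, net$dt))) {
    stop("trace and network must share one dt")
  }
  if (abs(tp$duration - schedule$duration) > net$dt / 2) {
    stop("schedule duration does not match the trace")
  }

  seeds <- derive_seeds(seed, c("weights", "er_noise"))
  state <- initialize_network(net, plast, n_cues = K, seed = seeds[["weights"]],
                              M = er[[1]]$M)
  arr <- schedule_arrays(schedule, trace$t)
  A_abs <- arr$A_scale * state$f_ss_amplitude
  theta_in <- wrap_angle(arr$gain * trace$theta_true + arr$shift)
  theta_pref <- vapply(er, function(e) e$preferred_dirs, numeric(er[[1]]$M))
  noise_bound <- er[[1]]$b_ER * state$f_ss_sum / length(state$f)

  res <- withr::with_seed(seeds[["er_noise"]], sim_core(
    v = trace$v_noisy, theta_in = theta_in, A = A_abs,
    kappa_cue = vapply(er, `[[`, numeric(1), "kappa"),
    theta_pref = theta_pref, noise_bound = noise_bound,
    tau = net$tau, alpha = net$alpha, D = net$D, beta = net$beta,
    v_rel = net$v_rel, drive = net$const_drive, dt = net$dt,
    eta = plast$eta, w_max = plast$w_max, g0 = plast$g0,
    clip = plast$clip_nonnegative,
    f0 = state$f, W0 = state$W,
    record_every = as.integer(record_every),
    w_record_every = as.integer(w_record_every)))

  N <- net$N
  angles <- epg_angles(N)
  rec_idx <- seq_len(nrow(res$f_rec)) * record_every
  d_angle <- 2 * pi / N
  frames <- tibble::tibble(
    t = res$t_rec,
    theta_true = trace$theta_true[rec_idx],
    speed = abs(trace$v_true[rec_idx]),
    bump_pos = angles[max.col(res$f_rec, ties.method = "first")],
    width = apply(res$f_rec, 1, fwhm_circular, d_angle = d_angle),
    amplitude = apply(res$f_rec, 1, function(f) max(f) - min(f))
  )
  for (k in seq_len(K)) {
    frames[[paste0("cue", k, "_heading")]] <- theta_in[rec_idx, k]
  }

  notch <- NULL
  if (length(res$t_wrec)) {
    notch <- purrr::map_dfr(seq_len(K), function(k) {
      Wk <- res$W_rec[[k]]
      nw <- dim(Wk)[3]
      tibble::tibble(
        t = res$t_wrec,
        cue = k,
        notch = vapply(seq_len(nw), function(i) notch_depth(Wk[, , i]),
                       numeric(1)))
    })
  }

  out <- list(frames = frames, notch = notch,
              f_ss_amplitude = state$f_ss_amplitude,
              f_ss_sum = state$f_ss_sum,
              f_rec = res$f_rec,
              final_f = res$f_final, final_W = res$W_final,
              init_W = state$W,
              schedule = schedule, net = net, plast = plast,
              record_every = record_every, seed = seed)
  class(out) <- "ring_sim"
  out
}

#' @export
print.ring_sim <- function(x, ...) {
  cat("<ring_sim> protocol:", x$schedule$protocol,
      "| duration:", x$schedule$duration, "s |",
      nrow(x$frames), "recorded frames\n")
  cat("steady-state bump amplitude:", signif(x$f_ss_amplitude, 5), "\n")
  invisible(x)
}

#' Per-frame metric table of a simulated trial
#'
#' Adds the bump-to-heading offset and the causal-window HD encoding accuracy
#' to the frame table of a [simulate_trial()] result.
#'
#' @param sim A `ring_sim` object.
#' @param config A [metrics_config()] object.
#' @return A tibble: the frame table plus `offset` (wrapped
#'   `bump_pos - theta_true`) and `accuracy`.
#' @export
sim_metrics <- function(sim, config = metrics_config()) {
  stopifnot(inherits(sim, "ring_sim"))
  fr <- sim$frames
  fr$offset <- wrap_angle(fr$bump_pos - fr$theta_true)
  fr$accuracy <- encoding_accuracy_model(fr$theta_true, fr$bump_pos,
                                         config = config,
                                         frame_dt = fr$t[2] - fr$t[1])
  fr
}
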