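#' Convert simulation time to experiment time
#'
#' Learning in the model runs faster than in the experiments it mirrors:
#' 24 s of experiment time correspond to 1 s of simulation time.
#'
#' @param t_sim Time (s, simulation).
#' @return Time (s, experiment): `24 * t_sim`.
#' @export
to_experiment_time <- function(t_sim) 24 * t_sim

new_protocol_result <- function(protocol, trials, conditions, config, ...) {
  out <- c(list(protocol = protocol, trials = trials, conditions = conditions,
                config = config), list(...))
  class(out) <- "protocol_result"
  out
}

#' @export
print.protocol_result <- function(x, ...) {
  cat("<protocol_result>", x$protocol, "|", nrow(x$trials), "trials\n")
  print(x$conditions)
  invisible(x)
}

trial_seeds <- function(seed, n) derive_seeds(seed, paste0("trial", seq_len(n)))

# vector strength of model bump-to-heading offsets over a time window
window_accuracy <- function(frames, window) {
  sel <- frames$t > window[1] & frames$t <= window[2]
  vector_strength(wrap_angle(frames$bump_pos[sel] - frames$theta_true[sel]))
}

window_mean <- function(frames, col, window) {
  sel <- frames$t > window[1] & frames$t <= window[2]
  mean(frames[[col]][sel], na.rm = TRUE)
}

#' Run the cue-intensity sweep
#'
#' One cue at each amplitude scale, 120-s burn-in, bump parameters assessed
#' over the following 30 s, averaged over trials. The full grid is 41 scales
#' from 0 to 2 in steps of 0.05 with 100 trials per scale; both are
#' configurable for reduced-scale runs.
#'
#' @param config Named list: `levels` (amplitude scales; default
#'   `seq(0, 2, 0.05)`), `trials` (default 100), `seed` (default 1),
#'   `record_every` (default 20).
#' @return A `protocol_result` with per-trial metrics (`trials`) and
#'   per-level averages (`conditions`: `A_scale`, `accuracy`, `width`,
#'   `amplitude`, `notch`, plus the untrained-matrix notch floor
#'   `notch_init`).
#' @export
run_intensity_sweep <- function(config = list()) {
  levels <- config$levels %||% seq(0, 2, by = 0.05)
  trials <- config$trials %||% 100L
  seed <- config$seed %||% 1L
  record_every <- config$record_every %||% 20L
  burn_in <- config$burn_in %||% 120
  assess <- config$assess %||% 30
  dur <- burn_in + assess
  grid <- tidyr::expand_grid(A_scale = levels, trial = seq_len(trials))
  seeds <- trial_seeds(seed, nrow(grid))
  tp <- trajectory_params(duration = dur)
  rows <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    s <- seeds[[i]]
    sched <- build_schedule("intensity_sweep",
                            list(A_scale = grid$A_scale[i],
                                 burn_in = burn_in, assess = assess),
                            seed = s)
    sim <- simulate_trial(generate_trajectory(tp, s), sched,
                          seed = s, record_every = record_every,
                          w_record_every = 0L)
    win <- sched$windows$assess
    fr <- sim$frames
    fr$accuracy <- encoding_accuracy_model(fr$theta_true, fr$bump_pos,
                                           frame_dt = fr$t[2] - fr$t[1])
    tibble::tibble(
      A_scale = grid$A_scale[i], trial = grid$trial[i], seed = s,
      accuracy = window_mean(fr, "accuracy", win),
      width = window_mean(fr, "width", win),
      amplitude = window_mean(fr, "amplitude", win),
      notch = notch_depth(sim$final_W[[1]]),
      notch_init = notch_depth(sim$init_W[[1]]))
  })
  conditions <- rows |>
    dplyr::group_by(.data$A_scale) |>
    dplyr::summarise(dplyr::across(c("accuracy", "width", "amplitude",
                                     "notch", "notch_init"), mean),
                     .groups = "drop")
  new_protocol_result("intensity_sweep", rows, conditions,
                      list(levels = levels, trials = trials, seed = seed))
}

#' Enumerate the two-cue shift trials
#'
#' 11 amplitude scales (0 to 1 in steps of 0.1) for one cue with the partner
#' fixed at 0.75, and vice versa (22 pairs), crossed with which cue is
#' presented (and shifts) first and `trials_per` repeats: 132 trials with the
#' defaults.
#'
#' @param trials_per Repeats per pair and cue order. Default 3.
#' @param values Amplitude scales for the varied cue. Default
#'   `seq(0, 1, 0.1)`.
#' @param fixed Amplitude scale of the partner cue. Default 0.75.
#' @return A tibble with columns `trial_id`, `pair_id`, `A1`, `A2`,
#'   `first_cue`, `rep`.
#' @export
enumerate_two_cue_trials <- function(trials_per = 3, values = seq(0, 1, by = 0.1),
                                     fixed = 0.75) {
  pairs <- dplyr::bind_rows(
    tibble::tibble(A1 = values, A2 = fixed),
    tibble::tibble(A1 = fixed, A2 = values))
  pairs$pair_id <- seq_len(nrow(pairs))
  grid <- tidyr::expand_grid(pairs, first_cue = 1:2,
                             rep = seq_len(trials_per))
  grid$trial_id <- seq_len(nrow(grid))
  dplyr::relocate(grid, "trial_id")
}

#' Run the two-cue shift protocol
#'
#' Each trial: 30-s burn-in (cues off), two 25-s single-cue blocks, then both
#' cues on for 262.5 s with 20 alternating ±120° shifts (10 per modality).
#' Single-cue accuracy, width, and amplitude are assessed over the second
#' half of each single-cue block; a bump preference index is computed for
#' every shift from 5-s windows before and after it, and averaged per
#' modality.
#'
#' @param config Named list: `trials` (tibble from
#'   [enumerate_two_cue_trials()]; default the full 132), `seed`,
#'   `record_every` (default 20).
#' @return A `protocol_result`. `trials` has one row per trial with
#'   single-cue metrics (`acc_cue1`, `acc_cue2`, ...), modality-mean
#'   preference indices (`index_visual_shifts`, `index_wind_shifts`), and the
#'   per-shift table is in `$shifts`. `conditions` averages over repeats and
#'   cue order per amplitude pair.
#' @export
run_two_cue_shift <- function(config = list()) {
  plan <- config$trials %||% enumerate_two_cue_trials()
  seed <- config$seed %||% 1L
  record_every <- config$record_every %||% 20L
  mcfg <- config$metrics %||% metrics_config()
  seeds <- trial_seeds(seed, max(plan$trial_id))
  res <- purrr::map(seq_len(nrow(plan)), function(i) {
    row <- plan[i, ]
    s <- seeds[[row$trial_id]]
    sched <- build_schedule("two_cue_shift",
                            list(A1 = row$A1, A2 = row$A2,
                                 first_cue = row$first_cue), seed = s)
    tp <- trajectory_params(duration = sched$duration)
    sim <- simulate_trial(generate_trajectory(tp, s), sched,
                          seed = s, record_every = record_every,
                          w_record_every = 0L)
    fr <- sim$frames
    # offsets of the bump relative to each cue's current reference
    off1 <- tibble::tibble(t = fr$t,
                           offset = wrap_angle(fr$bump_pos - fr$cue1_heading))
    off2 <- tibble::tibble(t = fr$t,
                           offset = wrap_angle(fr$bump_pos - fr$cue2_heading))
    ev <- sched$shift_events
    idx <- vapply(seq_len(nrow(ev)), function(j) {
      shift_indices(off1, off2, ev$time[j], mcfg, kind = "bump")
    }, numeric(1))
    shifts <- dplyr::mutate(ev, trial_id = row$trial_id, index = idx)
    w_first <- sched$windows$single_first
    w_second <- sched$windows$single_second
    half <- function(w) c(mean(w), w[2])
    win_by_cue <- if (row$first_cue == 1L) {
      list(half(w_first), half(w_second))
    } else {
      list(half(w_second), half(w_first))
    }
    trial <- tibble::tibble(
      trial_id = row$trial_id, pair_id = row$pair_id,
      A1 = row$A1, A2 = row$A2, first_cue = row$first_cue, rep = row$rep,
      seed = s,
      acc_cue1 = window_accuracy(fr, win_by_cue[[1]]),
      acc_cue2 = window_accuracy(fr, win_by_cue[[2]]),
      width_cue1 = window_mean(fr, "width", win_by_cue[[1]]),
      width_cue2 = window_mean(fr, "width", win_by_cue[[2]]),
      index_visual_shifts = mean(idx[ev$cue == 1L], na.rm = TRUE),
      index_wind_shifts = mean(idx[ev$cue == 2L], na.rm = TRUE),
      index_all = mean(idx, na.rm = TRUE))
    list(trial = trial, shifts = shifts)
  })
  trials_tbl <- purrr::map_dfr(res, "trial")
  conditions <- trials_tbl |>
    dplyr::group_by(.data$A1, .data$A2) |>
    dplyr::summarise(dplyr::across(c("acc_cue1", "acc_cue2", "index_all",
                                     "index_visual_shifts", "index_wind_shifts"),
                                   mean), .groups = "drop")
  new_protocol_result("two_cue_shift", trials_tbl, conditions,
                      list(seed = seed),
                      shifts = purrr::map_dfr(res, "shifts"))
}

#' Run the cue-combination protocol
#'
#' Both cues at amplitude scale 2. Blocks: 30-s burn-in (off), 25 s cue 1,
#' 25 s cue 2, 32.5 s both, 12.5 s cue 1, 12.5 s cue 2. Full time courses of
#' accuracy, width, amplitude, and each cue's weight-notch depth are
#' trial-averaged; per-trial block summaries support the
#' combination/recency/priming comparisons.
#'
#' @param config Named list: `trials` (default 100), `seed`, `A_scale`
#'   (default 2), `record_every` (default 20), `w_record_every` (default 200,
#'   i.e. 0.5-s weight snapshots).
#' @return A `protocol_result` with `timecourse` (t, t_exp, trial-mean
#'   accuracy/width/amplitude), `notch` (t, cue, trial-mean depth), and
#'   per-trial block summaries in `trials`.
#' @export
run_cue_combination <- function(config = list()) {
  trials <- config$trials %||% 100L
  seed <- config$seed %||% 1L
  A <- config$A_scale %||% 2
  record_every <- config$record_every %||% 20L
  w_record_every <- config$w_record_every %||% 200L
  seeds <- trial_seeds(seed, trials)
  sched <- build_schedule("cue_combination", list(A_scale = A))
  tp <- trajectory_params(duration = sched$duration)
  win <- sched$windows
  res <- purrr::map(seq_len(trials), function(i) {
    s <- seeds[[i]]
    sim <- simulate_trial(generate_trajectory(tp, s), sched, seed = s,
                          record_every = record_every,
                          w_record_every = w_record_every)
    fr <- sim$frames
    fr$accuracy <- encoding_accuracy_model(fr$theta_true, fr$bump_pos,
                                           frame_dt = fr$t[2] - fr$t[1])
    both_on <- win$both[1]
    first_notch_t <- min(sim$notch$t[sim$notch$t >= both_on])
    notch_at_onset <- sim$notch[sim$notch$t == first_notch_t, ]
    block_len <- win$cue1_final[2] - win$cue1_final[1]
    summary <- tibble::tibble(
      trial = i, seed = s,
      acc_single_plateau = window_accuracy(fr, c(mean(win$cue2_first), win$cue2_first[2])),
      acc_both = window_accuracy(fr, c(mean(win$both), win$both[2])),
      notch_cue1_at_both_onset = notch_at_onset$notch[notch_at_onset$cue == 1L],
      notch_cue2_at_both_onset = notch_at_onset$notch[notch_at_onset$cue == 2L],
      acc_cue1_first_matched = window_accuracy(fr, c(win$cue1_first[1],
                                                     win$cue1_first[1] + block_len)),
      acc_cue1_final = window_accuracy(fr, win$cue1_final))
    list(frames = fr, notch = sim$notch, summary = summary)
  })
  timecourse <- purrr::map_dfr(res, "frames") |>
    dplyr::group_by(.data$t) |>
    dplyr::summarise(dplyr::across(c("accuracy", "width", "amplitude"), mean),
                     .groups = "drop") |>
    dplyr::mutate(t_exp = to_experiment_time(.data$t))
  notch <- purrr::map_dfr(res, "notch") |>
    dplyr::group_by(.data$t, .data$cue) |>
    dplyr::summarise(notch = mean(.data$notch), .groups = "drop") |>
    dplyr::mutate(t_exp = to_experiment_time(.data$t))
  trials_tbl <- purrr::map_dfr(res, "summary")
  conditions <- dplyr::summarise(
    trials_tbl,
    dplyr::across(c("acc_single_plateau", "acc_both",
                    "notch_cue1_at_both_onset", "notch_cue2_at_both_onset",
                    "acc_cue1_first_matched", "acc_cue1_final"), mean))
  new_protocol_result("cue_combination", trials_tbl, conditions,
                      list(trials = trials, seed = seed, A_scale = A),
                      timecourse = timecourse, notch = notch,
                      windows = win)
}

#' Run the gain-inversion protocol
#'
#' One cue on throughout; 60-s burn-in and 8 s more at normal gain (+1), then
#' 32 s at inverted gain (-1). Per amplitude scale (default 1 to 2 in steps
#' of 0.25) the accuracy time course is trial-averaged and normalized to its
#' value at the end of the normal-gain epoch; the recovery latency is the
#' time after inversion at which the mean normalized accuracy, having dipped,
#' again reaches `recovery_threshold`.
#'
#' @param config Named list: `levels` (default `seq(1, 2, 0.25)`), `trials`
#'   (default 100), `seed`, `recovery_threshold` (default 0.8),
#'   `record_every` (default 20).
#' @return A `protocol_result` with `timecourse` (t, A_scale, mean
#'   normalized accuracy) and `conditions` (per-level recovery latency, s;
#'   `NA` if the mean curve never recovers).
#' @export
run_gain_inversion <- function(config = list()) {
  levels <- config$levels %||% seq(1, 2, by = 0.25)
  trials <- config$trials %||% 100L
  seed <- config$seed %||% 1L
  thr <- config$recovery_threshold %||% 0.8
  record_every <- config$record_every %||% 20L
  grid <- tidyr::expand_grid(A_scale = levels, trial = seq_len(trials))
  seeds <- trial_seeds(seed, nrow(grid))
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    s <- seeds[[i]]
    sched <- build_schedule("gain_inversion", list(A_scale = grid$A_scale[i]),
                            seed = s)
    tp <- trajectory_params(duration = sched$duration)
    sim <- simulate_trial(generate_trajectory(tp, s), sched, seed = s,
                          record_every = record_every, w_record_every = 0L)
    fr <- sim$frames
    acc <- encoding_accuracy_model(fr$theta_true, fr$bump_pos,
                                   frame_dt = fr$t[2] - fr$t[1])
    t_inv <- sched$windows$inverted[1]
    norm_val <- acc[max(which(fr$t <= t_inv))]
    tibble::tibble(A_scale = grid$A_scale[i], trial = grid$trial[i],
                   t = fr$t, accuracy = acc,
                   norm_accuracy = acc / norm_val)
  })
  timecourse <- dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$A_scale, .data$t) |>
    dplyr::summarise(norm_accuracy = mean(.data$norm_accuracy),
                     accuracy = mean(.data$accuracy), .groups = "drop") |>
    dplyr::mutate(t_exp = to_experiment_time(.data$t))
  t_inv <- build_schedule("gain_inversion")$windows$inverted[1]
  conditions <- timecourse |>
    dplyr::group_by(.data$A_scale) |>
    dplyr::group_modify(function(df, key) {
      post <- df[df$t > t_inv, ]
      i_min <- which.min(post$norm_accuracy)
      rec <- post$t[post$t >= post$t[i_min] & post$norm_accuracy >= thr]
      tibble::tibble(
        min_norm_accuracy = post$norm_accuracy[i_min],
        recovery_latency = if (length(rec)) min(rec) - t_inv else NA_real_)
    }) |>
    dplyr::ungroup()
  trials_tbl <- dplyr::bind_rows(rows) |>
    dplyr::distinct(.data$A_scale, .data$trial)
  new_protocol_result("gain_inversion", trials_tbl, conditions,
                      list(levels = levels, trials = trials, seed = seed,
                           recovery_threshold = thr),
                      timecourse = timecourse)
}
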