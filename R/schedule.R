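#' Build the cue schedule for one of the simulation protocols
#'
#' A cue schedule is the piecewise-constant description of each cue's
#' amplitude scale, the cumulative angular shift applied to each cue, and the
#' closed-loop gain over a trial. By convention cue 1 is the visual cue and
#' cue 2 the wind cue. Protocols:
#'
#' * `intensity_sweep` — one cue, on at `A_scale` throughout a 120-s burn-in
#'   plus a 30-s assessment window.
#' * `two_cue_shift` — 30-s burn-in (both cues off), two 25-s single-cue
#'   blocks (the `first_cue` first), then both cues on for 262.5 s with a
#'   ±120° shift every 12.5 s, alternating modality starting with
#'   `first_cue`; 20 shifts, 10 per modality, directions drawn with equal
#'   probability from the trial's RNG stream.
#' * `cue_combination` — 30-s burn-in (off), 25 s cue 1, 25 s cue 2, 32.5 s
#'   both, 12.5 s cue 1, 12.5 s cue 2; both cues at `A_scale` 2 by default.
#' * `gain_inversion` — one cue on throughout: 60-s burn-in and another 8 s at
#'   gain +1, then 32 s at gain -1.
#'
#' @param protocol One of `"intensity_sweep"`, `"two_cue_shift"`,
#'   `"cue_combination"`, `"gain_inversion"`.
#' @param config Named list of overrides. Common fields: `A_scale` (single-cue
#'   protocols), `A1`, `A2` (two-cue shift), `first_cue` (1 or 2).
#' @param seed Integer seed governing random shift directions.
#' @return A list of class `cue_schedule` with fields `protocol`, `n_cues`,
#'   `duration`, `amp` (tibble: cue, t_start, t_end, A_scale), `gain`
#'   (tibble: t_start, t_end, gain), `shift_events` (tibble: time, cue,
#'   shift), and `windows` (protocol-specific analysis windows).
#' @export
build_schedule <- function(protocol, config = list(), seed = 1) {
  cfg <- function(name, default) if (!is.null(config[[name]])) config[[name]] else default
  seg <- function(cue, t0, t1, a) tibble::tibble(cue = cue, t_start = t0, t_end = t1, A_scale = a)
  no_shifts <- tibble::tibble(time = numeric(), cue = integer(), shift = numeric())

  if (protocol == "intensity_sweep") {
    burn <- cfg("burn_in", 120); assess <- cfg("assess", 30)
    A <- cfg("A_scale", 1)
    dur <- burn + assess
    sched <- list(protocol = protocol, n_cues = 1L, duration = dur,
                  amp = seg(1L, 0, dur, A),
                  gain = tibble::tibble(t_start = 0, t_end = dur, gain = 1),
                  shift_events = no_shifts,
                  windows = list(assess = c(burn, dur)))
  } else if (protocol == "two_cue_shift") {
    burn <- cfg("burn_in", 30); single <- cfg("single_block", 25)
    two <- cfg("two_cue_block", 262.5); ival <- cfg("shift_interval", 12.5)
    n_shift <- cfg("n_shifts", 20L)
    A1 <- cfg("A1", 0.75); A2 <- cfg("A2", 0.75)
    first <- as.integer(cfg("first_cue", 1L))
    stopifnot(first %in% c(1L, 2L))
    second <- 3L - first
    t1 <- burn; t2 <- t1 + single; t3 <- t2 + single; dur <- t3 + two
    amp_first <- if (first == 1L) A1 else A2
    amp_second <- if (first == 1L) A2 else A1
    amp <- dplyr::bind_rows(
      seg(first, 0, t1, 0), seg(second, 0, t1, 0),
      seg(first, t1, t2, amp_first), seg(second, t1, t2, 0),
      seg(first, t2, t3, 0), seg(second, t2, t3, amp_second),
      seg(1L, t3, dur, A1), seg(2L, t3, dur, A2))
    shift_times <- t3 + ival * seq_len(n_shift)
    stopifnot(max(shift_times) <= dur)
    shift_cues <- rep(c(first, second), length.out = n_shift)
    signs <- withr::with_seed(derive_seeds(seed, "shifts")[["shifts"]],
                              sample(c(-1, 1), n_shift, replace = TRUE))
    sched <- list(protocol = protocol, n_cues = 2L, duration = dur,
                  amp = amp,
                  gain = tibble::tibble(t_start = 0, t_end = dur, gain = 1),
                  shift_events = tibble::tibble(time = shift_times,
                                                cue = shift_cues,
                                                shift = signs * 2 * pi / 3),
                  windows = list(single_first = c(t1, t2),
                                 single_second = c(t2, t3),
                                 two_cue = c(t3, dur)))
    sched$first_cue <- first
  } else if (protocol == "cue_combination") {
    burn <- cfg("burn_in", 30); single <- cfg("single_block", 25)
    both <- cfg("two_cue_block", 32.5); post <- cfg("post_block", 12.5)
    A <- cfg("A_scale", 2)
    t1 <- burn; t2 <- t1 + single; t3 <- t2 + single
    t4 <- t3 + both; t5 <- t4 + post; dur <- t5 + post
    amp <- dplyr::bind_rows(
      seg(1L, 0, t1, 0), seg(2L, 0, t1, 0),
      seg(1L, t1, t2, A), seg(2L, t1, t2, 0),
      seg(1L, t2, t3, 0), seg(2L, t2, t3, A),
      seg(1L, t3, t4, A), seg(2L, t3, t4, A),
      seg(1L, t4, t5, A), seg(2L, t4, t5, 0),
      seg(1L, t5, dur, 0), seg(2L, t5, dur, A))
    sched <- list(protocol = protocol, n_cues = 2L, duration = dur,
                  amp = amp,
                  gain = tibble::tibble(t_start = 0, t_end = dur, gain = 1),
                  shift_events = no_shifts,
                  windows = list(cue1_first = c(t1, t2), cue2_first = c(t2, t3),
                                 both = c(t3, t4), cue1_final = c(t4, t5),
                                 cue2_final = c(t5, dur)))
  } else if (protocol == "gain_inversion") {
    burn <- cfg("burn_in", 60); normal <- cfg("normal_block", 8)
    inv <- cfg("inverted_block", 32)
    A <- cfg("A_scale", 1)
    t_inv <- burn + normal; dur <- t_inv + inv
    sched <- list(protocol = protocol, n_cues = 1L, duration = dur,
                  amp = seg(1L, 0, dur, A),
                  gain = tibble::tibble(t_start = c(0, t_inv),
                                        t_end = c(t_inv, dur),
                                        gain = c(1, -1)),
                  shift_events = no_shifts,
                  windows = list(normal = c(burn, t_inv), inverted = c(t_inv, dur)))
  } else {
    stop("unknown protocol: ", protocol)
  }
  class(sched) <- "cue_schedule"
  sched
}

# Expand a schedule into per-step arrays on the trace's time grid.
# A step at time t belongs to the segment with t_start < t <= t_end; a shift
# applies from the first step strictly after its event time.
schedule_arrays <- function(schedule, t) {
  K <- schedule$n_cues
  T_ <- length(t)
  A <- matrix(0, T_, K)
  shift <- matrix(0, T_, K)
  for (i in seq_len(nrow(schedule$amp))) {
    r <- schedule$amp[i, ]
    idx <- t > r$t_start & t <= r$t_end
    A[idx, r$cue] <- r$A_scale
  }
  g <- numeric(T_)
  for (i in seq_len(nrow(schedule$gain))) {
    r <- schedule$gain[i, ]
    g[t > r$t_start & t <= r$t_end] <- r$gain
  }
  if (nrow(schedule$shift_events)) {
    for (i in seq_len(nrow(schedule$shift_events))) {
      e <- schedule$shift_events[i, ]
      shift[t > e$time, e$cue] <- shift[t > e$time, e$cue] + e$shift
    }
  }
  list(A_scale = A, shift = shift, gain = g)
}

#' Cue schedule event table
#'
#' Flattens a schedule into a tidy event table (amplitude segments, gain
#' segments, shift events) suitable for CSV export.
#'
#' @param schedule A [build_schedule()] object.
#' @return A tibble with columns `time`, `cue`, `event`, `value`.
#' @export
schedule_events <- function(schedule) {
  stopifnot(inherits(schedule, "cue_schedule"))
  dplyr::bind_rows(
    dplyr::transmute(schedule$amp, time = .data$t_start, cue = .data$cue,
                     event = "amplitude", value = .data$A_scale),
    dplyr::transmute(schedule$gain, time = .data$t_start, cue = NA_integer_,
                     event = "gain", value = .data$gain),
    dplyr::transmute(schedule$shift_events, time = .data$time, cue = .data$cue,
                     event = "shift", value = .data$shift)
  ) |> dplyr::arrange(.data$time)
}
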