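test_that("tuning width converts to precision by the half-maximum relation", {
  expect_equal(kappa_from_width(0.8), 8.780794, tolerance = 1e-6)
  expect_equal(kappa_from_width(pi), log(2), tolerance = 1e-12)
  expect_error(kappa_from_width(0))
  expect_error(kappa_from_width(2 * pi))
  # the deterministic profile is at half its peak at angular distance width/2
  er <- er_params(width = 1.3)
  act <- er_activity(er$preferred_dirs[5] + 1.3 / 2, er, A = 2, f_ss_mean = 0,
                     noise = FALSE)
  expect_equal(act[5], 1, tolerance = 1e-12)
})

test_that("ER activity peaks at the preferred direction and bounds its noise", {
  er <- er_params()
  expect_equal(er_activity(0.3, er, A = 0, f_ss_mean = 0, noise = FALSE),
               rep(0, er$M))
  act <- er_activity(er$preferred_dirs[9], er, A = 1.5, f_ss_mean = 0,
                     noise = FALSE)
  expect_equal(act[9], 1.5, tolerance = 1e-12)
  expect_equal(which.max(act), 9L)
  # 2*pi periodicity
  act2 <- er_activity(er$preferred_dirs[9] + 2 * pi, er, A = 1.5,
                      f_ss_mean = 0, noise = FALSE)
  expect_equal(act, act2, tolerance = 1e-12)
  withr::with_seed(4, {
    noisy <- replicate(50, er_activity(0, er, A = 0, f_ss_mean = 0.35))
    expect_true(all(noisy >= 0 & noisy < er$b_ER * 0.35))
  })
  expect_error(er_activity(0, er, A = 1, f_ss_mean = -1))
})

test_that("the cue tuning argument composes gain and shift then wraps", {
  th <- seq(-3, 3, by = 0.5)
  expect_equal(input_angle(th, 1, 0), wrap_angle(th))
  expect_equal(input_angle(th, -1, 0), wrap_angle(-th))
  expect_equal(input_angle(pi / 2, 1, 2 * pi / 3), -5 * pi / 6,
               tolerance = 1e-12)
})

test_that("the two-cue shift schedule has 20 alternating shifts, 10 per cue", {
  sch <- build_schedule("two_cue_shift", list(first_cue = 2), seed = 3)
  ev <- sch$shift_events
  expect_identical(nrow(ev), 20L)
  expect_identical(as.integer(table(ev$cue)), c(10L, 10L))
  expect_identical(ev$cue[1], 2L)                   # first-presented cue shifts first
  expect_identical(unique(diff(ev$time)), 12.5)
  expect_true(all(abs(ev$shift) == 2 * pi / 3))
  expect_true(all(ev$time > 80 & ev$time <= sch$duration))
  expect_equal(sch$duration, 30 + 25 + 25 + 262.5)
  # reproducible for a fixed seed
  expect_identical(build_schedule("two_cue_shift", list(first_cue = 2), seed = 3),
                   sch)
})

test_that("the cue-combination schedule tiles its five blocks", {
  sch <- build_schedule("cue_combination")
  w <- sch$windows
  expect_equal(w$cue1_first, c(30, 55))
  expect_equal(w$cue2_first, c(55, 80))
  expect_equal(w$both, c(80, 112.5))
  expect_equal(w$cue1_final, c(112.5, 125))
  expect_equal(w$cue2_final, c(125, 137.5))
  # amplitude segments tile the trial without overlap, per cue
  for (k in 1:2) {
    segs <- sch$amp[sch$amp$cue == k, ]
    segs <- segs[order(segs$t_start), ]
    expect_equal(segs$t_start[-1], segs$t_end[-nrow(segs)])
    expect_equal(segs$t_start[1], 0)
    expect_equal(segs$t_end[nrow(segs)], sch$duration)
  }
})

test_that("the gain-inversion schedule flips the gain after 68 s", {
  sch <- build_schedule("gain_inversion", list(A_scale = 1.25))
  expect_equal(sch$gain$gain, c(1, -1))
  expect_equal(sch$gain$t_end[1], 68)
  expect_equal(sch$duration, 100)
  expect_error(build_schedule("not_a_protocol"), "unknown")
})

test_that("schedules flatten to a tidy event table", {
  sch <- build_schedule("two_cue_shift", seed = 1)
  ev <- schedule_events(sch)
  expect_true(all(c("time", "cue", "event", "value") %in% names(ev)))
  expect_identical(sum(ev$event == "shift"), 20L)
  expect_false(is.unsorted(ev$time))
})
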