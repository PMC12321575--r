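angles32 <- seq(-pi, pi - 2 * pi / 32, length.out = 32)

test_that("the von Mises frame fit round-trips noiseless parameters", {
  truth <- list(a = 1, kappa = 2, mu = 30 * pi / 180, c = 0.1)
  prof <- truth$a * exp(truth$kappa * cos(angles32 - truth$mu)) + truth$c
  fit <- fit_bump_profile(prof, angles32)
  expect_equal(fit$mu, truth$mu, tolerance = 1e-4)
  expect_equal(fit$kappa, truth$kappa, tolerance = 1e-4)
  expect_equal(fit$amp_coeff, truth$a, tolerance = 1e-4)
  expect_equal(fit$baseline, truth$c, tolerance = 1e-4)
  expect_true(fit$valid)
  expect_error(fit_bump_profile(prof[1:5], angles32[1:5]), "8 samples")
})

test_that("small kappa drives the derived width to 180 degrees, amplitude to 0", {
  expect_equal(ringcompass:::vm_fit_width(1e-8), pi, tolerance = 1e-6)
  expect_equal(ringcompass:::vm_fit_amplitude(1, 1e-8), 0, tolerance = 1e-6)
  # and the derived width decreases in kappa
  ks <- c(0.5, 1, 2, 4, 8)
  ws <- vapply(ks, ringcompass:::vm_fit_width, numeric(1))
  expect_true(all(diff(ws) < 0))
})

test_that("the adjusted-R2 gate flags pure-noise profiles invalid", {
  prof <- withr::with_seed(8, stats::runif(32))
  fit <- fit_bump_profile(prof, angles32)
  expect_lt(fit$adj_r2, 0.5)
  expect_false(fit$valid)
})

test_that("fit-derived width and amplitude agree with the model convention", {
  for (kap in c(1, 2, 5)) {
    prof <- 0.8 * exp(kap * cos(angles32 - 0.7)) + 0.05
    fit <- fit_bump_profile(prof, angles32)
    expect_equal(fit$width, fwhm_circular(prof), tolerance = 2 * pi / 32)
    expect_equal(fit$amplitude, max(prof) - min(prof), tolerance = 0.08)
  }
})

test_that("offset series implement bump - (-HD) with a movement flag", {
  n <- 50
  hd <- seq(-pi, pi, length.out = n)
  expect_equal(offset_series(-hd, hd, rep(1, n))$offset, rep(0, n))
  expect_equal(offset_series(rep(0, n), rep(pi / 2, n), rep(1, n))$offset,
               rep(pi / 2, n))
  # common rotation leaves the offset constant
  lag <- 0.3
  os <- offset_series(wrap_angle(-hd + lag), hd, rep(1, n))
  expect_equal(os$offset, rep(lag, n), tolerance = 1e-12)
  cfg <- metrics_config(movement_threshold = 0.5)
  expect_identical(offset_series(hd, hd, c(rep(0, 25), rep(1, 25)), cfg)$moving,
                   c(rep(FALSE, 25), rep(TRUE, 25)))
  expect_error(offset_series(1:3, 1:2, 1:3), "equal lengths")
})

test_that("vector strength matches its definition and the brute-force oracle", {
  expect_equal(vector_strength(rep(0.7, 5)), 1)
  expect_equal(vector_strength(c(0, pi)), 0, tolerance = 1e-12)
  expect_equal(vector_strength(c(0, pi / 2)), sqrt(2) / 2, tolerance = 1e-12)
  expect_error(vector_strength(numeric(0)))
  withr::with_seed(13, {
    for (i in 1:25) {
      x <- stats::runif(sample(1:40, 1), -pi, pi)
      expect_equal(vector_strength(x), vs_oracle(x), tolerance = 1e-12)
      rot <- stats::runif(1, -pi, pi)
      expect_equal(vector_strength(wrap_angle(x + rot)), vector_strength(x),
                   tolerance = 1e-12)
    }
  })
})

test_that("causal-window accuracy matches the brute-force oracle", {
  withr::with_seed(17, {
    n <- 400
    theta <- wrap_angle(cumsum(stats::rnorm(n, 0, 0.1)))
    bump <- wrap_angle(theta + stats::rnorm(n, 0, 0.4))
    cfg <- metrics_config(accuracy_window = 2)
    acc <- encoding_accuracy_model(theta, bump, cfg, frame_dt = 0.1)
    expect_equal(acc, acc_oracle(theta, bump, 20), tolerance = 1e-12)
  })
})

test_that("accuracy is 1 under perfect tracking and decays for random bumps", {
  n <- 2000
  theta <- wrap_angle(cumsum(rep(0.01, n)))
  acc <- encoding_accuracy_model(theta, wrap_angle(theta + 1), frame_dt = 0.05)
  expect_equal(acc, rep(1, n), tolerance = 1e-12)
  withr::with_seed(19, {
    bump <- stats::runif(n, -pi, pi)
    acc_r <- encoding_accuracy_model(theta, bump, frame_dt = 0.05)
    w <- 160  # frames per 8-s window at 50 ms
    expect_lt(mean(acc_r[w:n]), 3 / sqrt(w))
  })
})

test_that("a single offset jump dents accuracy and is forgotten within 8 s", {
  n <- 1200; dt <- 0.05
  theta <- rep(0, n)
  bump <- c(rep(0.5, 600), rep(1.8, 600))  # jump at t = 30 s
  acc <- encoding_accuracy_model(theta, bump, frame_dt = dt)
  expect_equal(acc[599], 1, tolerance = 1e-12)
  expect_lt(min(acc[600:760]), 0.95)
  expect_equal(acc[920], 1, tolerance = 1e-9)  # window fully past the jump
})

test_that("shift preference indices hit their worked endpoints", {
  t <- seq(0.1, 20, by = 0.1)
  ev <- 10
  flat <- tibble::tibble(t = t, offset = rep(0.4, length(t)))
  jump <- tibble::tibble(t = t, offset = ifelse(t < ev, 0.4,
                                                wrap_angle(0.4 + 2 * pi / 3)))
  # visual offset unchanged, wind offset changes by 120 deg -> follows visual
  expect_equal(shift_indices(flat, jump, ev), -1, tolerance = 1e-9)
  expect_equal(shift_indices(jump, flat, ev), 1, tolerance = 1e-9)
  # equal absolute changes -> 0; swapping the cue roles flips the sign
  jump2 <- tibble::tibble(t = t, offset = ifelse(t < ev, 0, -2 * pi / 3))
  expect_equal(shift_indices(jump, jump2, ev), 0, tolerance = 1e-9)
  x <- shift_indices(jump, flat, ev)
  expect_equal(shift_indices(flat, jump, ev), -x, tolerance = 1e-12)
  expect_error(shift_indices(flat, jump, 24), "windows")
  expect_true(is.na(shift_indices(flat, flat, ev)))
})

test_that("the remapping index separates heading-locked from cue-locked bumps", {
  n <- 720
  mv <- rep(TRUE, n)
  expect_equal(remapping_index(rep(1, n), rep(0.2, n), rep(-0.5, n), mv), 0)
  withr::with_seed(23, {
    hd <- wrap_angle(cumsum(stats::rnorm(n, 0, 0.3)))
    cue <- stats::runif(n, -pi, pi)
    # bump locked to heading, uniform relative to the cue
    ri <- remapping_index(wrap_angle(hd + 0.3), hd, cue, mv)
    expect_gt(ri, 0.8)
    # mirror: bump locked to the cue
    ri2 <- remapping_index(wrap_angle(cue + 0.3), hd, cue, mv)
    expect_lt(ri2, -0.8)
  })
  expect_error(remapping_index(1:3, 1:3, 1:3, rep(FALSE, 3)), "immobile")
})

test_that("conflict/offset-change pairs wrap their differences", {
  cp <- conflict_pairs(0.2, 0.2, 0.2)
  expect_equal(cp$theta, 0)
  expect_equal(cp$phi, 0)
  deg <- pi / 180
  cp2 <- conflict_pairs(170 * deg, -170 * deg, 170 * deg)
  expect_equal(cp2$theta, 20 * deg, tolerance = 1e-12)
})
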