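net <- network_params()
plast <- plasticity_params()

test_that("relaxation reaches the documented steady-state bump", {
  st <- initialize_network(net, plast, n_cues = 1, seed = 1)
  expect_equal(st$f_ss_amplitude, 1.062, tolerance = 0.02)
  expect_true(all(st$f >= 0))
  # with global inhibition the trough sits at zero, so amplitude ~ peak
  expect_equal(min(st$f_ss_profile), 0, tolerance = 1e-6)
})

test_that("initial weight matrices hit the target Frobenius norm exactly", {
  for (s in c(1, 99, 123456)) {
    st <- initialize_network(net, plast, n_cues = 2, seed = s)
    for (W in st$W) {
      expect_equal(sqrt(sum(W^2)), 1.5, tolerance = 1e-12)
      expect_true(all(W >= 0))
    }
  }
  # different seeds give different matrices
  a <- initialize_network(net, plast, seed = 1)$W[[1]]
  b <- initialize_network(net, plast, seed = 2)$W[[1]]
  expect_false(identical(a, b))
})

test_that("the relaxed profile is rotation-equivariant in its starting phase", {
  relax_from <- function(f0) {
    n_steps <- 8000L
    ringcompass:::sim_core(
      v = numeric(n_steps), theta_in = matrix(0, n_steps, 1),
      A = matrix(0, n_steps, 1), kappa_cue = 1,
      theta_pref = matrix(0, 1, 1), noise_bound = 0,
      tau = net$tau, alpha = net$alpha, D = net$D, beta = net$beta,
      v_rel = net$v_rel, drive = net$const_drive, dt = net$dt,
      eta = 0, w_max = 1, g0 = 1, clip = TRUE,
      f0 = f0, W0 = list(matrix(0, net$N, 1)),
      record_every = 0L, w_record_every = 0L)$f_final
  }
  base <- 0.5 * (1 + cos(2 * pi * (0:31) / 32))
  f_a <- relax_from(base)
  shift <- 9L
  f_b <- relax_from(base[((0:31 + shift) %% 32) + 1])
  expect_equal(f_b, f_a[((0:31 + shift) %% 32) + 1], tolerance = 1e-8)
})

test_that("one Euler step respects its fixed point and gating structure", {
  st <- initialize_network(net, plast, n_cues = 1, seed = 5)
  g0 <- list(rep(0, 32))
  stepped <- step_network(st, v_t = 0, g = g0, net, plast)
  expect_lt(max(abs(stepped$f - st$f)), 1e-9)          # steady state is fixed
  expect_identical(stepped$W, st$W)                    # no |v|, no learning
  # postsynaptic gating: silent EPG population freezes the weights
  st0 <- st; st0$f <- rep(0, 32)
  g_big <- list(runif(32, 0, 3))
  expect_identical(step_network(st0, v_t = 2, g = g_big, net, plast)$W, st0$W)
  # velocity gating: v = 0 freezes the weights whatever f and g are
  expect_identical(step_network(st, v_t = 0, g = g_big, net, plast)$W, st$W)
  expect_equal(stepped$t, st$t + net$dt)
})

test_that("the R step and the compiled core advance the state identically", {
  st <- initialize_network(net, plast, n_cues = 1, seed = 8)
  er <- er_params()
  theta <- 0.7
  A <- 1.3
  n_steps <- 5L
  res <- ringcompass:::sim_core(
    v = rep(2.2, n_steps), theta_in = matrix(theta, n_steps, 1),
    A = matrix(A, n_steps, 1), kappa_cue = er$kappa,
    theta_pref = matrix(er$preferred_dirs, ncol = 1), noise_bound = 0,
    tau = net$tau, alpha = net$alpha, D = net$D, beta = net$beta,
    v_rel = net$v_rel, drive = net$const_drive, dt = net$dt,
    eta = plast$eta, w_max = plast$w_max, g0 = plast$g0, clip = TRUE,
    f0 = st$f, W0 = st$W, record_every = 0L, w_record_every = 0L)
  g <- list(er_activity(theta, er, A = A, f_ss_mean = 0, noise = FALSE))
  st_r <- st
  for (i in seq_len(n_steps)) st_r <- step_network(st_r, 2.2, g, net, plast)
  expect_equal(st_r$f, res$f_final, tolerance = 1e-12)
  expect_equal(st_r$W[[1]], res$W_final[[1]], tolerance = 1e-12)
})

test_that("notch depth is zero for flat input, shrunk by smoothing, wrap-invariant", {
  expect_equal(notch_depth(matrix(0.3, 32, 32)), 0, tolerance = 1e-12)
  W <- matrix(0, 32, 32); W[5, 20] <- 1
  expect_lt(notch_depth(W), max(W) - min(W))
  W2 <- W[c(15:32, 1:14), c(30:32, 1:29)]   # circular shifts on both axes
  expect_equal(notch_depth(W2), notch_depth(W), tolerance = 1e-12)
})

test_that("rates stay non-negative and weights stay within their bounds", {
  tr <- quick_trace(20, seed = 21)
  sch <- build_schedule("intensity_sweep",
                        list(A_scale = 2, burn_in = 15, assess = 5))
  sim <- simulate_trial(tr, sch, seed = 21)
  expect_true(all(sim$f_rec >= 0))
  w_cap <- max(max(sim$init_W[[1]]), plasticity_params()$w_max) + 1e-9
  expect_true(all(sim$final_W[[1]] >= 0))
  expect_true(all(sim$final_W[[1]] <= w_cap))
})

test_that("after learning with a bright cue the notch is a diagonal band", {
  tr <- quick_trace(80, seed = 31)
  sch <- build_schedule("intensity_sweep",
                        list(A_scale = 2, burn_in = 70, assess = 10))
  sim <- simulate_trial(tr, sch, seed = 31)
  S <- ringcompass:::smooth_weight_matrix(sim$final_W[[1]], 2)
  mins <- apply(S, 2, which.min)
  # column-wise argmin positions advance monotonically around the ring:
  # signed circular steps wind exactly once, with almost no back-steps
  wd <- ((diff(c(mins, mins[1])) + 16) %% 32) - 16   # closed cycle
  expect_equal(abs(sum(wd)), 32)
  expect_gt(mean(sign(wd) == sign(sum(wd)) | wd == 0), 0.9)
  expect_gt(notch_depth(sim$final_W[[1]]), 2 * notch_depth(sim$init_W[[1]]))
})

test_that("halving dt barely moves the bump on a deterministic input", {
  run_det <- function(dt) {
    n <- as.integer(30 / dt)
    tt <- seq_len(n) * dt
    v <- 2 * sin(2 * pi * tt / 7)
    theta <- wrap_angle(cumsum(v) * dt)
    er <- er_params()
    f0 <- ringcompass:::relax_to_steady_state(network_params(dt = dt))$f
    res <- ringcompass:::sim_core(
      v = v, theta_in = matrix(theta, ncol = 1),
      A = matrix(1.062, n, 1), kappa_cue = er$kappa,
      theta_pref = matrix(er$preferred_dirs, ncol = 1), noise_bound = 0,
      tau = net$tau, alpha = net$alpha, D = net$D, beta = net$beta,
      v_rel = net$v_rel, drive = net$const_drive, dt = dt,
      eta = plast$eta, w_max = plast$w_max, g0 = plast$g0, clip = TRUE,
      f0 = f0, W0 = list(matrix(0.04, 32, 32)),
      record_every = 0L, w_record_every = 0L)
    ringcompass:::epg_angles(32)[which.max(res$f_final)]
  }
  d <- abs(wrap_angle(run_det(0.0025) - run_det(0.00125)))
  expect_lt(d, 2 * pi / 32)
})

test_that("the circular FWHM matches the closed-form von Mises width", {
  angles <- ringcompass:::epg_angles(32)
  for (kap in c(1, 2, 5)) {
    prof <- exp(kap * (cos(angles - 0.4) - 1))
    closed <- 2 * acos(1 + log(0.5 + 0.5 * exp(-2 * kap)) / kap)
    expect_equal(fwhm_circular(prof), closed, tolerance = 2 * pi / 32)
  }
  expect_true(is.na(fwhm_circular(rep(1, 32))))
})
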