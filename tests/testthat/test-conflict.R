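test_that("the von Mises log-likelihood matches its closed forms", {
  d1 <- tibble::tibble(theta = 0.4, phi = wrap_angle(1 * 0.4 + 0.5))
  expect_equal(vm_loglik(d1, a = 1, b = 0.5, kappa = 1),
               1 - log(2 * pi * besselI(1, 0)), tolerance = 1e-12)
  d <- generate_conflict_dataset(0.5, 1, 4, 20, seed = 2)
  # kappa -> 0 degenerates to the circular uniform
  expect_equal(vm_loglik(d, 0.5, 1, 1e-12), 20 * log(1 / (2 * pi)),
               tolerance = 1e-6)
  # periodicity in phi
  d2 <- d; d2$phi[3] <- d2$phi[3] + 2 * pi
  expect_equal(vm_loglik(d2, 0.5, 1, 4), vm_loglik(d, 0.5, 1, 4),
               tolerance = 1e-9)
  # numerically stable for large concentration
  expect_true(is.finite(vm_loglik(d, 0.5, 1, 500)))
  expect_error(vm_loglik(d, 0.5, 1, 0), "positive")
})

test_that("inverse-gamma tail masses match a sampling oracle", {
  m <- prior_tail_mass(1.91, 6.47, 1, 50)
  draws <- withr::with_seed(3, 1 / stats::rgamma(1e5, 1.91, rate = 6.47))
  emp <- mean(draws < 1 | draws > 50)
  se <- sqrt(m * (1 - m) / 1e5)
  expect_lt(abs(emp - m), 3 * se)
  expect_equal(prior_tail_mass(1.91, 6.47, 0, 50),
               stats::pgamma(1 / 50, 1.91, rate = 6.47))
  expect_error(prior_tail_mass(-1, 6.47, 1, 50))
  expect_error(prior_tail_mass(1.91, 6.47, 5, 2))
})

test_that("rotating all offset changes shifts only the circular intercept", {
  d <- generate_conflict_dataset(0.8, 0.5, 8, 36, seed = 6)
  delta <- 1.2
  d_rot <- d; d_rot$phi <- wrap_angle(d$phi + delta)
  f1 <- fit_conflict_model(d, seed = 10)
  f2 <- fit_conflict_model(d_rot, seed = 10)
  t1 <- tidy(f1); t2 <- tidy(f2)
  expect_equal(wrap_angle(t2$estimate[t2$term == "b"] -
                            t1$estimate[t1$term == "b"]),
               delta, tolerance = 0.1)
  expect_equal(t2$estimate[t2$term == "a"], t1$estimate[t1$term == "a"],
               tolerance = 0.1)
  expect_equal(t2$estimate[t2$term == "kappa"], t1$estimate[t1$term == "kappa"],
               tolerance = 0.15 * t1$estimate[t1$term == "kappa"])
})

test_that("a flat relationship concentrates the slope posterior at zero", {
  withr::with_seed(4, {
    d <- tibble::tibble(theta = stats::runif(36, -pi, pi), phi = 0.5)
  })
  fit <- suppressWarnings(fit_conflict_model(d, seed = 11))
  td <- tidy(fit)
  expect_lt(abs(td$estimate[td$term == "a"]), 0.05)
  expect_equal(td$estimate[td$term == "b"], 0.5, tolerance = 0.05)
})

test_that("fits carry convergence diagnostics and broom-style summaries", {
  d <- generate_conflict_dataset(0.8, 0.5, 8, 36, seed = 7)
  fit <- fit_conflict_model(d, seed = 12)
  expect_identical(fit$diagnostics$param, c("a", "b", "kappa"))
  expect_true(all(is.finite(fit$diagnostics$rhat)))
  expect_true(all(fit$diagnostics$ess > 50))
  expect_true(fit$reliable)
  expect_identical(nrow(fit$draws), 4000L)
  expect_true(all(fit$draws$kappa > 0))
  g <- glance(fit)
  expect_identical(g$n, 36L)
  expect_true(g$reliable)
})

test_that("prior draws of the concentration respect the design tails", {
  draws <- withr::with_seed(9, 1 / stats::rgamma(1e5, 1.91, rate = 6.47))
  expect_lt(mean(draws < 1), 0.02)
  expect_lt(mean(draws > 50), 0.02)
})

test_that("retrodictive bands cover model-generated data and flag outliers", {
  d <- generate_conflict_dataset(0.8, 0.5, 8, 36, seed = 15)
  fit <- fit_conflict_model(d, seed = 16)
  rd <- posterior_retrodictive(d, fit, seed = 17)
  expect_gte(attr(rd, "coverage"), 0.85)
  # gross outlier: flip one observation to the antipode of its prediction
  d_out <- d
  d_out$phi[5] <- wrap_angle(0.8 * d_out$theta[5] + 0.5 + pi)
  rd2 <- posterior_retrodictive(d_out, fit, seed = 18)
  expect_false(rd2$covered[5])
  expect_true(all(rd2$band_lo >= -pi & rd2$band_lo < pi))
  expect_true(all(rd2$band_hi >= -pi & rd2$band_hi < pi))
})

test_that("the von Mises sampler is calibrated", {
  x <- withr::with_seed(21, rvonmises(4000, mu = 1.2, kappa = 5))
  expect_true(all(x >= -pi & x < pi))
  expect_equal(circ_mean(x), 1.2, tolerance = 0.05)
  # mean resultant length ~ A1(kappa) = I1/I0
  expect_equal(vector_strength(wrap_angle(x - 1.2)),
               besselI(5, 1) / besselI(5, 0), tolerance = 0.02)
  u <- withr::with_seed(22, rvonmises(4000, 0, 0))
  expect_gt(stats::ks.test(u, "punif", -pi, pi)$p.value, 0.01)
})
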