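test_that("kinetic rates vanish without biomass, substrate or growth headroom", {
  p <- ferm_sim_params()
  expect_equal(kinetic_rhs(c(0, 100, 10), 0, p), c(0, 0, 0))
  p0 <- ferm_sim_params(m = 0)
  expect_equal(kinetic_rhs(c(20, 0, 10), 0, p0), c(0, 0, 0))
  expect_equal(kinetic_rhs(c(20, 100, p0$P_max), 0, p0), c(0, 0, 0))
  expect_error(kinetic_rhs(c(-1, 100, 0), 0, p), "negative")
})

test_that("noise-free default run hits the study's endpoint conditions", {
  e <- simulate_experiment(noise_free_params(n_points = 500L), seed = 1L)
  P <- e$data[, "ethanol"]
  expect_lt(abs(P[length(P)] - 108), 5)
  expect_equal(unname(e$data[nrow(e$data), "temperature"]), 28)
  ## cascade: temperature only takes setpoint values and never rises
  temps <- e$data[, "temperature"]
  expect_true(all(temps %in% c(34, 32, 30, 28)))
  expect_true(all(diff(temps) <= 0))
})

test_that("noise-free trajectories are monotone and conserve the ethanol yield", {
  p <- noise_free_params(m = 0)
  e <- simulate_experiment(p, seed = 3L)
  expect_true(all(diff(e$data[, "ethanol"]) >= -1e-9))
  expect_true(all(diff(e$data[, "substrate"]) <= 1e-9))
  ## Y_ps * (S0 - S) - (P - P0) = 0 within integration tolerance
  resid <- p$Y_ps * (p$S0 - e$data[, "substrate"]) -
    (e$data[, "ethanol"] - p$P0)
  expect_lt(max(abs(resid)), 1e-6 * p$S0)
})

test_that("dead start and zero inoculum leave the state unchanged", {
  p <- noise_free_params(X0 = 0)
  e <- simulate_experiment(p, seed = 2L)
  expect_equal(unname(e$data[, "ethanol"]), rep(0, 60))
  expect_equal(unname(e$data[, "substrate"]), rep(p$S0, 60))
})

test_that("uninhibited growth matches an independent fine-step integrator", {
  ## No product inhibition, no maintenance: cells should follow pure
  ## Monod-limited growth. Oracle: 4th-order Runge-Kutta at 100x finer step.
  p <- noise_free_params(P_max = 1e9, m = 0)
  e <- simulate_experiment(p, seed = 5L)

  rk4 <- function(p, n_grid, refine) {
    h <- p$duration_h / ((n_grid - 1) * refine)
    f <- function(s) {
      X <- s[1]; S <- max(s[2], 0)
      dX <- p$mu_max * S / (p$K_s + S) * X
      c(dX, -dX / p$Y_xs, p$Y_ps * dX / p$Y_xs)
    }
    s <- c(p$X0, p$S0, p$P0)
    out <- matrix(NA_real_, n_grid, 3)
    out[1, ] <- s
    for (i in seq_len((n_grid - 1) * refine)) {
      k1 <- f(s); k2 <- f(s + h / 2 * k1)
      k3 <- f(s + h / 2 * k2); k4 <- f(s + h * k3)
      s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (i %% refine == 0) out[i / refine + 1, ] <- s
    }
    out
  }
  oracle <- rk4(p, 60L, 100L)
  expect_lt(max(abs(e$data[, "cells"] - oracle[, 1]) / oracle[, 1]), 0.01)
})

test_that("fault injection masks or offsets exactly one channel", {
  e <- simulate_experiment(small_params(), seed = 9L)
  miss <- inject_fault(e, fault_spec("missing_channel", "redox"))
  expect_true(all(is.na(miss$data[, "redox"])))
  expect_identical(miss$data[, "pH"], e$data[, "pH"])
  expect_identical(miss$data[, "capacitance"], e$data[, "capacitance"])

  up <- inject_fault(e, fault_spec("offset_channel", "capacitance",
                                   offset = 7.5))
  expect_equal(mean(up$data[, "capacitance"]) - mean(e$data[, "capacitance"]),
               7.5)
  down <- inject_fault(up, fault_spec("offset_channel", "capacitance",
                                      offset = -7.5))
  expect_equal(down$data[, "capacitance"], e$data[, "capacitance"])

  expect_error(fault_spec("missing_channel", "ethanol"), "channel")
  expect_error(fault_spec("offset_channel", "capacitance", offset = Inf),
               "finite")
})

test_that("a simulated study reproduces the two probe faults and is deterministic", {
  study <- small_study()
  expect_length(study, 11L)
  all_missing_redox <- vapply(seq_len(11), function(i) {
    all(is.na(study[[i]]$data[, "redox"]))
  }, logical(1))
  expect_equal(sum(all_missing_redox), 1L)
  offset_flag <- vapply(seq_len(11), function(i) {
    any(startsWith(study[[i]]$faults, "offset_channel:capacitance"))
  }, logical(1))
  expect_equal(sum(offset_flag), 1L)
  expect_false(all_missing_redox[which(offset_flag)])

  again <- simulate_study(small_params(), n_experiments = 11L, seed = 42L)
  expect_identical(again$experiments, study$experiments)

  clean <- simulate_study(small_params(), n_experiments = 2L,
                          fault_plan = list(), seed = 1L)
  expect_length(clean, 2L)
  expect_false(any(vapply(clean$experiments,
                          function(e) anyNA(e$data), logical(1))))
  expect_error(simulate_study(small_params(), n_experiments = 3L,
                              fault_plan = default_fault_plan(), seed = 1L),
               "out of range")
})

test_that("between-experiment variability propagates to the final titer", {
  p <- noise_free_params()
  p$between_experiment_cv <- 0.1
  finals <- vapply(seq_len(20), function(i) {
    e <- simulate_experiment(p, seed = 1000L + i)
    e$data[nrow(e$data), "ethanol"]
  }, numeric(1))
  cv <- sd(finals) / mean(finals)
  expect_gt(cv, 0.1 / 3)
  expect_lt(cv, 0.1 * 3)
})
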