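test_that("logistic closed form: limits and independent RK4 oracle", {
  expect_equal(logistic_closed_form(1000, 0, 5e4, c(0, 10, 500)),
               rep(1000, 3))
  expect_equal(logistic_closed_form(5e4, 0.03, 5e4, c(0, 100)), rep(5e4, 2))
  # independent fixed-step RK4 integration of dN/dt = gN(1 - N/theta)
  cf <- logistic_closed_form(1000, 0.03, 53873, 120)
  expect_lt(abs(rk4_logistic(1000, 0.03, 53873, 120) - cf) / cf, 1e-6)
})

test_that("damaged_rate limits", {
  expect_equal(damaged_rate(100, 100, gd = 0.02, kd = -0.04, gamma_d = 0.05),
               0.02)                                   # exp(0) = 1
  expect_equal(damaged_rate(1e6, 0, 0.02, -0.04, 0.05), -0.04)  # asymptote
  expect_equal(damaged_rate(c(0, 50, 500), 0, 0.02, -0.04, 0),
               rep(0.02, 3))                           # gamma_d = 0
  # monotone decreasing iff gd > kd
  tt <- seq(0, 300, 10)
  expect_true(all(diff(damaged_rate(tt, 0, 0.02, -0.04, 0.03)) < 0))
  expect_true(all(diff(damaged_rate(tt, 0, -0.05, 0.01, 0.03)) > 0))
})

test_that("dose partition conserves cells exactly", {
  expect_equal(apply_dose_partition(1e4, 1), list(S_plus = 1e4, D_plus = 0))
  expect_equal(apply_dose_partition(1e4, 0), list(S_plus = 0, D_plus = 1e4))
  ps <- apply_dose_partition(1e4, 0.3)
  expect_equal(ps$S_plus, 3000)
  expect_equal(ps$D_plus, 7000)
  expect_identical(ps$S_plus + ps$D_plus, 1e4)
})

test_that("simulate: untreated and fs = 1 limits match the closed form", {
  tg <- seq(0, 600, 2)
  # n_d = 0: pure logistic with (g0, theta_u)
  tr <- simulate_treatment(untreated_params(0.03, 53873, 1500),
                           treatment_schedule(), tg)
  cf <- logistic_closed_form(1500, 0.03, 53873, tg)
  expect_lt(max(abs(tr$N - cf) / cf), 1e-6)
  expect_equal(nrow(tr$D), 0)
  # fs = 1: D stays 0, N follows (gs, theta_dox) logistic from the dose on
  p <- multi_dose_params(0.03, 0.018, 0.02, -0.04, 45000, fs = 1,
                         gamma_d = 0.02, mode = "constant", N0 = 2000)
  s <- treatment_schedule(48, 75)
  tr2 <- simulate_treatment(p, s, tg)
  expect_true(all(tr2$D == 0))
  n48 <- logistic_closed_form(2000, 0.03, 53873, 48)
  cf2 <- ifelse(tg < 48, logistic_closed_form(2000, 0.03, 53873, tg),
                logistic_closed_form(n48, 0.018, 45000, tg - 48))
  expect_lt(max(abs(tr2$N - cf2) / cf2), 1e-6)
})

test_that("total count is continuous across every dose time", {
  p <- multi_dose_params(0.03, 0.018, 0.02, -0.04, 45000,
                         fs = c(0.2, 0.5, 0.7), gamma_d = c(0.05, 0.02, 0.01),
                         mode = "adaptive", N0 = 2000)
  doses <- c(48, 96, 384)
  s <- treatment_schedule(doses, 75)
  eps <- 1e-6
  tg <- sort(unique(c(seq(0, 800, 2), doses - eps, doses)))
  tr <- simulate_treatment(p, s, tg)
  for (td in doses) {
    n_minus <- tr$N[abs(tr$times - (td - eps)) < 1e-9]
    n_plus <- tr$N[tr$times == td]
    expect_lt(abs(n_plus - n_minus) / n_minus, 1e-6)
    # but S jumps down by the dose partition
  }
  expect_true(all(tr$S >= 0), info = "nonnegativity")
  expect_true(all(tr$D >= 0))
  expect_true(all(tr$N <= max(53873, 45000) * (1 + 1e-6)))
})

test_that("constant mode is bit-identical to expanded adaptive mode", {
  s <- treatment_schedule(c(48, 96), 75)
  tg <- seq(0, 500, 2)
  pc <- multi_dose_params(0.03, 0.018, 0.02, -0.04, 45000, fs = 0.3,
                          gamma_d = 0.02, mode = "constant", N0 = 2000)
  pa <- multi_dose_params(0.03, 0.018, 0.02, -0.04, 45000, fs = c(0.3, 0.3),
                          gamma_d = c(0.02, 0.02), mode = "adaptive",
                          N0 = 2000)
  expect_identical(simulate_treatment(pc, s, tg)$N,
                   simulate_treatment(pa, s, tg)$N)
})

test_that("kd = gd collapses damaged dynamics to plain logistic growth", {
  # with gs = gd = kd = g every compartment grows at rate g, so the total
  # follows a single logistic with capacity theta_dox after the dose
  g <- 0.02
  p <- multi_dose_params(0.03, g, g, g, 45000, fs = 0.4, gamma_d = 0.07,
                         mode = "constant", N0 = 2000)
  tg <- seq(0, 600, 2)
  tr <- simulate_treatment(p, treatment_schedule(48, 75), tg)
  n48 <- logistic_closed_form(2000, 0.03, 53873, 48)
  cf <- ifelse(tg < 48, logistic_closed_form(2000, 0.03, 53873, tg),
               logistic_closed_form(n48, g, 45000, tg - 48))
  expect_lt(max(abs(tr$N - cf) / cf), 1e-6)
})

test_that("simultaneous doses partition sequentially", {
  # two doses at the same instant with equal gamma_d are equivalent to a
  # single partition with fs1 * fs2
  s2 <- treatment_schedule(c(48, 48), 75)
  s1 <- treatment_schedule(48, 75)
  tg <- seq(0, 500, 2)
  p2 <- multi_dose_params(0.03, 0.018, 0.02, -0.04, 45000, fs = c(0.6, 0.5),
                          gamma_d = c(0.02, 0.02), mode = "adaptive",
                          N0 = 2000)
  p1 <- multi_dose_params(0.03, 0.018, 0.02, -0.04, 45000, fs = 0.3,
                          gamma_d = 0.02, mode = "constant", N0 = 2000)
  tr2 <- simulate_treatment(p2, s2, tg)
  tr1 <- simulate_treatment(p1, s1, tg)
  expect_lt(max(abs(tr2$N - tr1$N) / tr1$N), 1e-8)
  expect_equal(tr2$S, tr1$S, tolerance = 1e-8)
})

test_that("grid-refinement convergence of the integrator", {
  p <- multi_dose_params(0.03, 0.018, 0.02, -0.04, 45000, fs = 0.2,
                         gamma_d = 0.05, mode = "constant", N0 = 2000)
  s <- treatment_schedule(48, 75)
  tg <- seq(0, 600, 4)
  n1 <- simulate_treatment(p, s, tg, rtol = 1e-8)$N
  n2 <- simulate_treatment(p, s, tg, rtol = 5e-9)$N
  expect_lt(max(abs(n1 - n2) / n2), 1e-6)
})

test_that("simulate validates inputs", {
  p <- multi_dose_params(0.03, 0.018, 0.02, -0.04, 45000, fs = 0.2,
                         gamma_d = 0.05, mode = "constant", N0 = 2000)
  expect_error(simulate_treatment(p, treatment_schedule(700, 75),
                                  seq(0, 600, 2)),
               "within the simulation window")
})
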