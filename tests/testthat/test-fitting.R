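test_that("fit_untreated recovers noiseless logistic parameters", {
  tc <- make_logistic_tc(N0 = 1800, g = 0.028, theta = 48000,
                         times = seq(0, 500, 3))
  f <- fit_untreated(tc)
  true <- c(g0 = 0.028, theta_u = 48000, N0 = 1800)
  expect_lt(max(abs(f$estimate[names(true)] - true) / true), 1e-3)
  expect_lt(f$gof$nrmse, 0.01)
  # degenerate constant data: the effective growth rate g0(1 - N0/theta)
  # vanishes (either root: g0 at its lower bound or theta_u = N0)
  flat <- time_course(seq(0, 100, 10), rep(2000, 11))
  ff <- fit_untreated(flat)
  eff <- ff$estimate[["g0"]] *
    (1 - ff$estimate[["N0"]] / ff$estimate[["theta_u"]])
  expect_lt(abs(eff), 1e-4)
  expect_lt(ff$convergence$final_cost, 1)
  expect_error(fit_untreated(time_course(0:3, 1:4)), "at least 6")
})

test_that("fit_model recovers noiseless single-dose parameters", {
  w <- default_world()
  g <- generate_replicate(w$params, w$schedule, w$cadence, w$horizon,
                          noise_model(multiplicative_cv = 0))
  f <- fit_model(g$tc, w$schedule, "constant")
  true <- as_named_truth(w$params)
  expect_lt(max(abs(f$estimate[names(true)] - true) / true), 1e-2)
  # objective at the solution never exceeds the objective at the start
  r0 <- f$pred_fun(doxpop:::default_param_table(
    1, g$tc$counts[1], 53873, TRUE)$init) - g$tc$counts
  expect_lte(f$convergence$final_cost, sum(r0^2))
})

test_that("fs = 1 data are fit to sub-1% NRMSE despite weak identifiability", {
  p <- multi_dose_params(0.025, 0.018, 0.02, -0.04, 45000, fs = 1,
                         gamma_d = 0.02, mode = "constant", N0 = 2000)
  s <- treatment_schedule(48, 75)
  g <- generate_replicate(p, s, 3, 504, noise_model(multiplicative_cv = 0))
  f <- fit_model(g$tc, s, "constant")
  expect_lt(f$gof$nrmse, 1)
})

test_that("n_d = 1 adaptive fit equals the constant (single-dose) fit", {
  w <- default_world()
  g <- generate_replicate(w$params, w$schedule, w$cadence, w$horizon,
                          noise_model(multiplicative_cv = 0.03, seed = 5))
  fc <- fit_model(g$tc, w$schedule, "constant")
  fa <- fit_model(g$tc, w$schedule, "adaptive")
  expect_equal(fa$estimate, fc$estimate, tolerance = 1e-6)
})

test_that("adaptive fit of constant-generated 2-dose data: per-dose
           estimates agree within CI overlap", {
  p <- true_params_at(75, mode = "constant", n_doses = 2)
  s <- treatment_schedule(c(48, 96), 75)
  g <- generate_replicate(p, s, 3, 600,
                          noise_model(multiplicative_cv = 0.02, seed = 9))
  f <- fit_model(g$tc, s, "adaptive", spec = fit_spec(n_starts = 3))
  ci <- param_confidence_intervals(f)
  for (par in c("fs", "gamma_d")) {
    i1 <- ci[ci$param == paste0(par, "1"), ]
    i2 <- ci[ci$param == paste0(par, "2"), ]
    if (any(is.na(c(i1$lower, i2$lower)))) next  # unidentified direction
    expect_lt(max(i1$lower, i2$lower), min(i1$upper, i2$upper) + 1e-12)
  }
})

test_that("refitting from the optimum is stationary", {
  w <- default_world()
  g <- generate_replicate(w$params, w$schedule, w$cadence, w$horizon,
                          noise_model(multiplicative_cv = 0.05, seed = 3))
  f1 <- fit_model(g$tc, w$schedule, "constant")
  f2 <- fit_model(g$tc, w$schedule, "constant",
                  spec = fit_spec(init = f1$estimate))
  expect_lt(abs(f1$convergence$final_cost - f2$convergence$final_cost) /
              f1$convergence$final_cost, 1e-8 + 1e-6)
})

test_that("theta_dox policy: thresholds and group-mean fixing", {
  set.seed(17)
  s <- treatment_schedule(48, 75)
  mk <- function(fs, gs, id) {
    p <- multi_dose_params(0.025, gs, 0.015, -0.05, 44000, fs = fs,
                           gamma_d = 0.05, mode = "constant", N0 = 2000)
    g <- generate_replicate(p, s, 3, 700,
                            noise_model(multiplicative_cv = 0.02),
                            replicate_id = id,
                            condition = list(experiment = 1,
                                             concentration_nM = 75,
                                             interval_d = NA, n_doses = 1))
    fit_model(g$tc, s, "constant")
  }
  # three recovering replicates (high last count) + one suppressed
  # (tiny surviving fraction and slow regrowth keep its final count low)
  fits <- list(mk(0.45, 0.018, "r1"), mk(0.5, 0.018, "r2"),
               mk(0.55, 0.018, "r3"), mk(0.01, 0.003, "r4"))
  last <- vapply(fits, function(f) f$tc$counts[length(f$tc$counts)],
                 numeric(1))
  expect_true(all(last[1:3] > 0.3 * 53873) && last[4] < 0.3 * 53873)
  out <- apply_theta_dox_policy(fits, theta_u = 53873, threshold = 0.3)
  # pass-1 fits untouched
  for (i in 1:3) expect_identical(out[[i]], fits[[i]])
  # the suppressed replicate is refit with theta_dox fixed to the mean
  expect_equal(unname(out[[4]]$fixed["theta_dox"]),
               mean(vapply(fits[1:3], function(f)
                 f$estimate[["theta_dox"]], numeric(1))))
  expect_false("theta_dox" %in% names(out[[4]]$estimate))
  # threshold 0: everyone keeps a free theta_dox
  out0 <- apply_theta_dox_policy(fits, theta_u = 53873, threshold = 0)
  for (i in 1:4) expect_identical(out0[[i]], fits[[i]])
  # no replicate above threshold: instructive error
  expect_error(apply_theta_dox_policy(fits[4], theta_u = 53873),
               "manually")
})

test_that("parameter CIs match closed-form OLS on a linear model", {
  set.seed(31)
  x <- seq(0, 10, length.out = 25)
  beta <- c(2, 1.5)
  y <- beta[1] + beta[2] * x + rnorm(25, 0, 0.4)
  X <- cbind(1, x)
  bhat <- unname(solve(crossprod(X), crossprod(X, y))[, 1])
  fake <- structure(list(
    estimate = c(a = bhat[1], b = bhat[2]),
    pred_fun = function(p, times = x) p[["a"]] + p[["b"]] * times,
    residuals = X %*% bhat - y,
    lower = c(a = -Inf, b = -Inf), upper = c(a = Inf, b = Inf)),
    class = "fit_result")
  ci <- param_confidence_intervals(fake)
  # textbook OLS intervals
  s2 <- sum((y - X %*% bhat)^2) / (25 - 2)
  se <- sqrt(diag(solve(crossprod(X)) * s2))
  tq <- qt(0.975, 23)
  expect_equal(ci$se, unname(se), tolerance = 1e-6)
  expect_equal(ci$lower, unname(bhat - tq * se), tolerance = 1e-6)
  expect_equal(ci$upper, unname(bhat + tq * se), tolerance = 1e-6)
  # prediction band equals the textbook confidence band
  pb <- prediction_intervals(fake, x)
  half <- tq * sqrt(rowSums((X %*% solve(crossprod(X))) * X) * s2)
  expect_equal(pb$upper - pb$fit, half, tolerance = 1e-6)
  expect_true(all(pb$lower <= pb$fit & pb$fit <= pb$upper))
})

test_that("zero-residual fits give near-zero intervals and bands", {
  tc <- make_logistic_tc(times = seq(0, 400, 4))
  f <- fit_untreated(tc)
  ci <- param_confidence_intervals(f)
  expect_true(all(ci$se / abs(ci$estimate) < 1e-3, na.rm = TRUE))
  pb <- prediction_intervals(f, seq(0, 400, 40))
  expect_true(all((pb$upper - pb$lower) / pb$fit < 1e-2))
})

test_that("CI coverage over repeated noisy fits is near nominal", {
  # 200 seeds, noise at 5% of the typical count, untreated logistic model.
  # Homoscedastic additive noise so the asymptotic intervals are tested
  # under their own assumptions (the lognormal generator is
  # heteroscedastic, which the vignette discusses as a known mismatch).
  true <- c(g0 = 0.025, theta_u = 53873, N0 = 20000)
  tg <- seq(0, 504, 4)
  truth_n <- logistic_closed_form(true[["N0"]], true[["g0"]],
                                  true[["theta_u"]], tg)
  sdev <- 0.05 * mean(truth_n)
  hits <- matrix(FALSE, 200, 3, dimnames = list(NULL, names(true)))
  set.seed(5000)
  for (i in 1:200) {
    tc <- time_course(tg, pmax(truth_n + rnorm(length(tg), 0, sdev), 0))
    f <- fit_untreated(tc)
    ci <- param_confidence_intervals(f)
    rownames(ci) <- ci$param
    hits[i, ] <- ci[names(true), "lower"] <= true &
      true <= ci[names(true), "upper"]
  }
  cov <- colMeans(hits)
  for (p in names(true)) {
    expect_gte(cov[[p]], 0.88)
    expect_lte(cov[[p]], 0.99)
  }
})
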