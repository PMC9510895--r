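#' Closed-form logistic growth
#'
#' Analytic solution of `dN/dt = g N (1 - N / theta)`, used both for the
#' pre-treatment growth segment oracle and as an independent check on the
#' numerical integrator.
#'
#' @param N0 initial count (cells), positive.
#' @param g growth rate (1/h).
#' @param theta carrying capacity (cells), positive.
#' @param t time (h), scalar or vector.
#' @return `theta * N0 * exp(g t) / (theta + N0 * (exp(g t) - 1))`.
#' @export
logistic_closed_form <- function(N0, g, theta, t) {
  stopifnot(N0 > 0, theta > 0)
  egt <- exp(g * t)
  theta * N0 * egt / (theta + N0 * (egt - 1))
}

#' Net growth rate of an irreversibly damaged subpopulation
#'
#' Damaged cells proliferate at `gd` immediately after their dose and
#' transition exponentially (rate `gamma_d`) towards the asymptotic net
#' rate `kd`; a negative `kd` denotes drug-induced death.
#'
#' @param t time (h), at or after `t_dose`.
#' @param t_dose dose time (h).
#' @param gd initial proliferation rate (1/h).
#' @param kd asymptotic net rate (1/h).
#' @param gamma_d death-delay rate (1/h), nonnegative.
#' @return `kd + (gd - kd) * exp(-gamma_d * (t - t_dose))`.
#' @export
damaged_rate <- function(t, t_dose, gd, kd, gamma_d) {
  stopifnot(all(gamma_d >= 0))
  kd + (gd - kd) * exp(-gamma_d * (t - t_dose))
}

#' Partition a population at a dose time
#'
#' At each dose a fraction `fs_i` of the exposed population survives and
#' keeps proliferating; the complement becomes a new irreversibly damaged
#' subpopulation. The split conserves the total exactly, which is what
#' makes the simulated total count continuous across dose times.
#'
#' @param S_minus population immediately before the dose (for dose 1 this
#'   is the total `N`; for later doses the surviving compartment only).
#' @param fs_i surviving fraction in `[0, 1]`.
#' @return A list with `S_plus` and `D_plus`; `S_plus + D_plus == S_minus`.
#' @export
apply_dose_partition <- function(S_minus, fs_i) {
  stopifnot(S_minus >= 0, fs_i >= 0, fs_i <= 1)
  list(S_plus = fs_i * S_minus, D_plus = (1 - fs_i) * S_minus)
}

#' Simulate the multi-dose treatment-response model
#'
#' Piecewise integration with dose events. Before the first dose the total
#' population follows logistic growth with rate `g0` and capacity
#' `theta_u`. Each dose `i` partitions the exposed population (the total
#' for dose 1, the surviving compartment thereafter) by the surviving
#' fraction `fs_i` and spawns damaged subpopulation `D_i`; existing
#' damaged subpopulations are not re-partitioned. Between events the
#' surviving cells follow logistic growth with rate `gs` and the damaged
#' cells the exponentially decaying net rate of [damaged_rate()], all
#' sharing the treated capacity `theta_dox` and coupled through the total
#' `N`. Integration uses an adaptive Dormand-Prince Runge-Kutta 5(4)
#' scheme.
#'
#' @param params a [multi_dose_params()] (or [untreated_params()] for pure
#'   logistic growth).
#' @param schedule a [treatment_schedule()]; `n_doses = 0` simulates the
#'   untreated model.
#' @param t_grid strictly increasing output times (h) covering the
#'   schedule.
#' @param rtol,atol integrator tolerances (relative; absolute in cells).
#' @return A `state_trajectory`: list with `times`, `S`, `D` (matrix with
#'   one row per damaged subpopulation, zero before its dose), and total
#'   `N`.
#' @export
simulate_treatment <- function(params, schedule = treatment_schedule(),
                               t_grid, rtol = 1e-8, atol = 1e-2) {
  if (inherits(params, "untreated_params")) {
    params <- multi_dose_params(g0 = params$g0, gs = params$g0, gd = 0,
                                kd = 0, theta_dox = params$theta_u,
                                fs = 1, gamma_d = 0, mode = "constant",
                                N0 = params$N0, theta_u = params$theta_u)
    schedule <- treatment_schedule()
  }
  nd <- schedule$n_doses
  if (nd > 0 && (min(schedule$dose_times) < min(t_grid) ||
                 max(schedule$dose_times) > max(t_grid)))
    stop("dose times must lie within the simulation window")
  pd <- expand_dose_params(params, nd)
  m <- .sim_multidose_cpp(as.numeric(t_grid), schedule$dose_times,
                          pd$fs, pd$gamma_d,
                          params$g0, params$gs, params$gd, params$kd,
                          params$theta_u, params$theta_dox, params$N0,
                          rtol, atol)
  D <- if (nd > 0) t(m[, 2 + seq_len(nd), drop = FALSE]) else
    matrix(0, 0, length(t_grid))
  structure(list(times = m[, 1], S = m[, 2], D = D, N = m[, 2 + nd + 1]),
            class = "state_trajectory")
}

#' @export
print.state_trajectory <- function(x, ...) {
  cat(sprintf("<state_trajectory> %d points, %d damaged subpopulation(s)\n",
              length(x$times), nrow(x$D)))
  cat(sprintf("  N: %.1f -> %.1f cells\n", x$N[1], x$N[length(x$N)]))
  invisible(x)
}
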