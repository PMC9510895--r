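#' Registry of empirical concentration-parameter functional forms
#'
#' Four shapes describe how the single-dose model parameters vary with
#' doxorubicin concentration `C` (nM):
#' * `exp_decay`: `a1 * exp(-a2 C)` -- surviving/damaged proliferation
#'   rates decay with dose.
#' * `exp_decay_offset`: `a1 * exp(-a2 C) + a3` -- the surviving fraction
#'   decays but stays at a small nonzero floor at high concentrations.
#' * `morse`: `a1 * (1 - exp(-a2 (C - a3)))^2 + a4` -- a well-shaped
#'   (Morse-potential-like) relationship for the asymptotic net death
#'   rate, with minimum `a4` at `C = a3` and a plateau at high `C`.
#' * `saturating_exp`: `a1 - a2 * exp(-a3 C)` -- a flipped decaying
#'   exponential for the death-delay rate, which rises and plateaus.
#'
#' @format A named list; each entry has `fun(coef, C)`, `n_coef`, and
#'   default `lower`, `upper`, `init` coefficient vectors.
#' @export
formula_forms <- list(
  exp_decay = list(
    fun = function(coef, C) coef[1] * exp(-coef[2] * C),
    n_coef = 2L,
    lower = c(0, 0), upper = c(1, 1), init = c(0.05, 0.01)),
  exp_decay_offset = list(
    fun = function(coef, C) coef[1] * exp(-coef[2] * C) + coef[3],
    n_coef = 3L,
    lower = c(0, 0, 0), upper = c(2, 1, 1), init = c(0.5, 0.01, 0.01)),
  morse = list(
    fun = function(coef, C) coef[1] * (1 - exp(-coef[2] * (C - coef[3])))^2 +
      coef[4],
    n_coef = 4L,
    lower = c(0, 0, 0, -0.5), upper = c(1, 1, 300, 0),
    init = c(0.05, 0.01, 50, -0.05)),
  saturating_exp = list(
    fun = function(coef, C) coef[1] - coef[2] * exp(-coef[3] * C),
    n_coef = 3L,
    lower = c(0, 0, 0), upper = c(1, 1, 1), init = c(0.05, 0.04, 0.01))
)

default_form_for <- c(fs = "exp_decay_offset", gs = "exp_decay",
                      gd = "exp_decay", kd = "morse",
                      gamma_d = "saturating_exp")

#' Evaluate an empirical parameter formula
#'
#' @param f an `empirical_formula` from [fit_formula()], or a list with
#'   elements `form` and `coef`.
#' @param C concentration(s) in nM, nonnegative.
#' @return The parameter value(s); `fs` values are clamped to `[0, 1]`.
#' @export
eval_formula <- function(f, C) {
  form <- formula_forms[[f$form]]
  if (is.null(form)) stop("unknown form: ", f$form)
  v <- form$fun(f$coef, C)
  if (identical(f$target_param, "fs")) v <- pmin(1, pmax(0, v))
  v
}

#' Fit an empirical formula to per-concentration parameter medians
#'
#' Bounded least squares of the target parameter's functional form to the
#' medians of its fitted per-replicate distribution at each concentration,
#' with delta-method coefficient confidence intervals and per-
#' concentration 95% bands, plus quality-of-fit metrics against the
#' medians.
#'
#' @param target one of `"fs"`, `"gs"`, `"gd"`, `"kd"`, `"gamma_d"`.
#' @param concentrations distinct concentrations (nM).
#' @param medians observed per-concentration medians.
#' @param form functional form name; defaults to the target's canonical
#'   shape (see [formula_forms]).
#' @param spec a [fit_spec()] (bounds/inits override coefficients named
#'   `a1`, `a2`, ...).
#' @param level confidence level for bands.
#' @return An object of class `empirical_formula` with `target_param`,
#'   `form`, `coef`, `coef_ci`, `band` (data.frame over
#'   `concentrations`), `gof`, `convergence`.
#' @export
fit_formula <- function(target, concentrations, medians, form = NULL,
                        spec = fit_spec(), level = 0.95) {
  form <- form %||% default_form_for[[target]]
  fdef <- formula_forms[[form]]
  if (is.null(fdef)) stop("unknown form: ", form)
  if (anyDuplicated(concentrations)) stop("concentrations must be distinct")
  if (length(concentrations) < fdef$n_coef)
    stop("need at least as many points as coefficients")
  nm <- paste0("a", seq_len(fdef$n_coef))
  tab <- list(names = nm, lower = setNames(fdef$lower, nm),
              upper = setNames(fdef$upper, nm),
              init = setNames(fdef$init, nm))
  tab <- apply_spec_overrides(tab, spec)
  pred_fun <- function(p, x = concentrations) fdef$fun(unname(p), x)
  ans <- bounded_nls(pred_fun, medians, tab, spec)
  # reuse the fitting machinery for CIs/bands via a lightweight fit_result
  fake <- structure(list(estimate = ans$par, pred_fun = pred_fun,
                         residuals = pred_fun(ans$par) - medians,
                         lower = tab$lower, upper = tab$upper),
                    class = "fit_result")
  ci <- tryCatch(param_confidence_intervals(fake, level),
                 error = function(e) NULL)
  band <- tryCatch(prediction_intervals(fake, concentrations, level),
                   error = function(e)
                     data.frame(time = concentrations,
                                fit = pred_fun(ans$par),
                                lower = pred_fun(ans$par),
                                upper = pred_fun(ans$par)))
  names(band)[1] <- "concentration_nM"
  structure(list(target_param = target, form = form, coef = unname(ans$par),
                 coef_ci = ci, band = band,
                 pred_fun = pred_fun, fit = fake,
                 gof = gof_report(medians, pred_fun(ans$par)),
                 convergence = ans$convergence,
                 level = level),
            class = "empirical_formula")
}

#' @export
print.empirical_formula <- function(x, ...) {
  cat(sprintf("<empirical_formula> %s ~ %s(C), coef = (%s)\n",
              x$target_param, x$form,
              paste(signif(x$coef, 4), collapse = ", ")))
  invisible(x)
}

#' 95% band of an empirical formula at arbitrary concentrations
#'
#' Delta-method confidence band of the fitted formula value.
#'
#' @param f an `empirical_formula`.
#' @param C concentration(s) in nM.
#' @return A data.frame with `concentration_nM`, `fit`, `lower`, `upper`.
#' @export
formula_band <- function(f, C) {
  hit <- match(C, f$band$concentration_nM)
  if (!anyNA(hit)) {
    b <- f$band[hit, , drop = FALSE]
    rownames(b) <- NULL
    return(b)
  }
  b <- tryCatch(prediction_intervals(f$fit, C, f$level),
                error = function(e) {
                  v <- f$pred_fun(f$coef, C)
                  data.frame(time = C, fit = v, lower = v, upper = v)
                })
  names(b)[1] <- "concentration_nM"
  b
}

#' Latin hypercube sample over the formulas' 95% bands
#'
#' Draws `n` five-dimensional parameter combinations
#' `(fs, gs, gd, kd, gamma_d)` at concentration `C`, each dimension
#' uniform over that parameter's 95% band with exactly one sample per
#' `1/n` stratum (marginal stratification). `fs` draws are clamped to
#' `[0, 1]`; a zero-width band degenerates to the midpoint.
#'
#' @param formulas named list of `empirical_formula` objects for `fs`,
#'   `gs`, `gd`, `kd`, `gamma_d`.
#' @param C concentration (nM) at which to sample.
#' @param n number of combinations.
#' @param seed integer seed; fixed seed gives identical output.
#' @return An `n x 5` matrix with columns `fs, gs, gd, kd, gamma_d`.
#' @export
lhs_sample <- function(formulas, C, n = 200, seed = NULL) {
  pars <- c("fs", "gs", "gd", "kd", "gamma_d")
  if (!all(pars %in% names(formulas)))
    stop("formulas must be named fs, gs, gd, kd, gamma_d")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  out <- matrix(NA_real_, n, length(pars), dimnames = list(NULL, pars))
  for (p in pars) {
    b <- formula_band(formulas[[p]], C)
    lo <- b$lower[1]; hi <- b$upper[1]
    if (p == "fs") { lo <- max(0, lo); hi <- min(1, hi) }
    if (hi <= lo) {
      out[, p] <- rep((lo + hi) / 2, n)
    } else {
      strata <- sample.int(n) - runif(n)  # one draw per 1/n stratum
      out[, p] <- lo + (hi - lo) * strata / n
    }
  }
  out
}

#' Simulation envelope from sampled parameter combinations
#'
#' Runs one forward simulation per parameter combination and returns the
#' pointwise median and range of the total cell count, emulating the
#' uncertainty envelope of the formula-driven model.
#'
#' @param combinations matrix from [lhs_sample()].
#' @param schedule a [treatment_schedule()].
#' @param t_grid output times (h).
#' @param theta_dox treated carrying capacity (cells), shared.
#' @param g0 pre-treatment growth rate (1/h), shared.
#' @param N0 initial count (cells).
#' @param theta_u untreated capacity (cells).
#' @param max_fail_frac simulations are skipped on failure; more than this
#'   fraction failing is an error.
#' @return A list with `times`, `median`, `min`, `max`, `n_ok`.
#' @export
simulate_band <- function(combinations, schedule, t_grid, theta_dox,
                          g0, N0 = 2000, theta_u = 53873,
                          max_fail_frac = 0.05) {
  n <- nrow(combinations)
  traj <- matrix(NA_real_, n, length(t_grid))
  for (i in seq_len(n)) {
    co <- combinations[i, ]
    traj[i, ] <- tryCatch({
      p <- multi_dose_params(g0 = g0, gs = co[["gs"]], gd = co[["gd"]],
                             kd = min(co[["kd"]], 0),
                             theta_dox = theta_dox,
                             fs = min(1, max(0, co[["fs"]])),
                             gamma_d = max(0, co[["gamma_d"]]),
                             mode = "constant", N0 = N0, theta_u = theta_u)
      simulate_treatment(p, schedule, t_grid)$N
    }, error = function(e) rep(NA_real_, length(t_grid)))
  }
  ok <- stats::complete.cases(traj)
  if (mean(!ok) > max_fail_frac)
    stop("more than ", 100 * max_fail_frac, "% of simulations failed")
  traj <- traj[ok, , drop = FALSE]
  list(times = t_grid,
       median = apply(traj, 2, median),
       min = apply(traj, 2, min),
       max = apply(traj, 2, max),
       n_ok = sum(ok))
}
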