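#' Specification of a bounded nonlinear least-squares fit
#'
#' Collects bounds, initial guesses, optimizer tolerances and evaluation
#' caps. Defaults follow the study's calibration settings: function and
#' step tolerances of 1e-6 with at most 20,000 function evaluations and
#' iterations, a bounded trust-region least-squares solver, and
#' physiologically motivated bounds (proliferation rates at most 0.1/h,
#' i.e. doubling times of about 7 h or slower; treated capacity within
#' 0.1-3 times the untreated capacity).
#'
#' @param lower,upper,init named numeric vectors overriding the default
#'   bound or initial guess of individual parameters (per-dose parameters
#'   are named `fs1`, `gamma_d1`, ...).
#' @param ftol,xtol function (relative objective) and step tolerances.
#' @param max_eval,max_iter evaluation and iteration caps.
#' @param theta_dox_threshold fraction of `theta_u` the last observed
#'   count must exceed for `theta_dox` to be identifiable (see
#'   [apply_theta_dox_policy()]).
#' @param n_starts number of optimizer starts (jittered within bounds;
#'   best final objective kept). Default 1, matching the study.
#' @return An object of class `fit_spec`.
#' @export
fit_spec <- function(lower = NULL, upper = NULL, init = NULL,
                     ftol = 1e-6, xtol = 1e-6,
                     max_eval = 20000, max_iter = 20000,
                     theta_dox_threshold = 0.3, n_starts = 1) {
  stopifnot(ftol > 0, xtol > 0, max_eval >= 1, max_iter >= 1)
  structure(list(lower = lower, upper = upper, init = init,
                 ftol = ftol, xtol = xtol,
                 max_eval = max_eval, max_iter = max_iter,
                 theta_dox_threshold = theta_dox_threshold,
                 n_starts = n_starts),
            class = "fit_spec")
}

# default bound/init table for the treated model
default_param_table <- function(n_doses, first_count, theta_u,
                                theta_dox_free) {
  nm <- c("g0", "gs", "gd", "kd",
          paste0("fs", seq_len(n_doses)),
          paste0("gamma_d", seq_len(n_doses)), "N0")
  lower <- c(0, 0, 0, -0.5, rep(0, n_doses), rep(0, n_doses),
             0.5 * first_count)
  upper <- c(0.1, 0.1, 0.1, 0, rep(1, n_doses), rep(1, n_doses),
             2 * first_count)
  init <- c(0.02, 0.02, 0.02, -0.01, rep(0.3, n_doses),
            rep(0.01, n_doses), first_count)
  if (theta_dox_free) {
    nm <- c(nm, "theta_dox")
    lower <- c(lower, 0.1 * theta_u)
    upper <- c(upper, 3 * theta_u)
    init <- c(init, theta_u)
  }
  list(names = nm, lower = setNames(lower, nm),
       upper = setNames(upper, nm), init = setNames(init, nm))
}

apply_spec_overrides <- function(tab, spec) {
  for (field in c("lower", "upper", "init")) {
    ov <- spec[[field]]
    if (!is.null(ov)) {
      keep <- intersect(names(ov), tab$names)
      tab[[field]][keep] <- ov[keep]
    }
  }
  bad <- tab$init < tab$lower | tab$init > tab$upper
  if (any(bad))
    stop("initial guess outside bounds for: ",
         paste(tab$names[bad], collapse = ", "))
  tab
}

# Levenberg-Marquardt with diagonal damping (a trust-region method) and
# bound projection; residual Jacobian by forward finite differences.
lm_bounded <- function(resid_fun, p0, lower, upper, ftol, xtol,
                       max_eval, max_iter) {
  p <- pmin(pmax(p0, lower), upper)
  k <- length(p)
  typ <- pmax(abs(p0), 1e-4)  # typical magnitude for steps/convergence
  r <- resid_fun(p); nev <- 1L
  if (is.null(r)) stop("initial parameters yield an invalid model")
  rss <- sum(r * r)
  lambda <- 1e-3
  status <- 1L; msg <- "iteration limit reached"; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    J <- matrix(0, length(r), k)
    for (j in seq_len(k)) {
      h <- 1e-6 * max(abs(p[j]), 0.01 * typ[j])
      if (p[j] + h > upper[j]) h <- -h
      pj <- p; pj[j] <- p[j] + h
      rj <- resid_fun(pj); nev <- nev + 1L
      if (!is.null(rj)) J[, j] <- (rj - r) / h
    }
    A <- crossprod(J)
    g <- crossprod(J, r)[, 1]
    # active-set reduction: a parameter pinned at a bound with the
    # gradient pointing outward cannot move; drop it from the solve
    beps <- 1e-10 * pmax(abs(upper - lower), 1)
    free <- !((p <= lower + beps & g > 0) | (p >= upper - beps & g < 0))
    if (!any(free)) { status <- 0L; msg <- "all parameters at bounds"; break }
    Af <- A[free, free, drop = FALSE]
    gf <- g[free]
    # floor relative to the largest curvature so structurally-inert
    # parameters (zero Jacobian column) stay put instead of blowing up
    dscale <- pmax(diag(Af), 1e-8 * max(diag(Af), 1), 1e-12)
    improved <- FALSE; step <- rep(0, k); relchange <- Inf; full_step <- TRUE
    for (tries in 1:60) {
      deltaf <- tryCatch(
        as.numeric(solve(Af + lambda * diag(dscale, sum(free)), -gf)),
        error = function(e) NULL)
      if (!is.null(deltaf) && all(is.finite(deltaf))) {
        delta <- rep(0, k); delta[free] <- deltaf
        # backtrack along the projected direction if the full step fails
        for (tfac in 2^-(0:6)) {
          pn <- pmin(pmax(p + tfac * delta, lower), upper)
          if (all(pn == p)) break
          rn <- resid_fun(pn); nev <- nev + 1L
          if (!is.null(rn)) {
            rssn <- sum(rn * rn)
            if (is.finite(rssn) && rssn < rss) {
              step <- pn - p
              relchange <- (rss - rssn) / max(rss, .Machine$double.xmin)
              p <- pn; r <- rn; rss <- rssn
              full_step <- tfac == 1
              # a backtracked step means the local model is poor: damp more
              lambda <- if (full_step) max(lambda / 3, 1e-12) else lambda * 2
              improved <- TRUE
              break
            }
          }
        }
        if (improved) break
      }
      lambda <- lambda * 5
      if (lambda > 1e13) break
    }
    if (!improved) { status <- 0L; msg <- "no further decrease (stationary)"; break }
    # convergence judged on full trust-region steps only; a backtracked
    # step says nothing about stationarity
    if (full_step && relchange < ftol) {
      status <- 0L; msg <- "function tolerance reached"; break
    }
    if (full_step && max(abs(step) / pmax(abs(p), typ)) < xtol) {
      status <- 0L; msg <- "step tolerance reached"; break
    }
    if (nev >= max_eval) { status <- 1L; msg <- "evaluation limit reached"; break }
  }
  list(par = p, rss = rss, status = status, message = msg,
       iterations = it, evaluations = nev)
}

# bounded least squares on a prediction function
bounded_nls <- function(pred_fun, obs, tab, spec) {
  resid_fun <- function(p) {
    r <- tryCatch(pred_fun(setNames(p, tab$names)) - obs,
                  error = function(e) NULL)
    if (is.null(r) || any(!is.finite(r))) NULL else r
  }
  run_one <- function(p0)
    lm_bounded(p0, lower = tab$lower, upper = tab$upper,
               resid_fun = resid_fun, ftol = spec$ftol, xtol = spec$xtol,
               max_eval = spec$max_eval, max_iter = spec$max_iter)
  best <- run_one(tab$init)
  if (spec$n_starts > 1) {
    for (s in seq_len(spec$n_starts - 1)) {
      p0 <- tab$lower + runif(length(tab$init)) * (tab$upper - tab$lower)
      p0[!is.finite(p0)] <- tab$init[!is.finite(p0)]
      cand <- tryCatch(run_one(p0), error = function(e) NULL)
      if (!is.null(cand) && cand$rss < best$rss) best <- cand
    }
  }
  list(par = setNames(best$par, tab$names), rss = best$rss,
       convergence = list(status = best$status,
                          message = best$message,
                          iterations = best$iterations,
                          evaluations = best$evaluations,
                          final_cost = best$rss))
}

new_fit_result <- function(par, fixed, pred_fun, tc, schedule, mode,
                           theta_u, conv, tab, spec) {
  pred <- pred_fun(par)
  res <- pred - tc$counts
  structure(list(estimate = par, fixed = fixed, pred_fun = pred_fun,
                 tc = tc, schedule = schedule, mode = mode,
                 theta_u = theta_u, residuals = res,
                 gof = gof_report(tc$counts, pred),
                 convergence = conv,
                 lower = tab$lower, upper = tab$upper, spec = spec),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s, %d free parameter(s), RSS = %.4g\n",
              if (is.null(x$mode)) "untreated" else x$mode,
              length(x$estimate), x$convergence$final_cost))
  print(signif(x$estimate, 4))
  cat(sprintf("  NRMSE %.2f%%  R2 %.4f  PCC %.4f  CCC %.4f\n",
              x$gof$nrmse, x$gof$r2, x$gof$pcc, x$gof$ccc))
  invisible(x)
}

#' Predicted total cell count of a fitted model
#'
#' @param object a `fit_result`.
#' @param times times (h) at which to predict; defaults to the observed
#'   times.
#' @param ... unused.
#' @return Numeric vector of predicted counts.
#' @export
predict.fit_result <- function(object, times = NULL, ...) {
  object$pred_fun(object$estimate, times %||% object$tc$times)
}

#' Fit the untreated logistic model to a 0 nM trajectory
#'
#' Estimates `(g0, theta_u, N0)` by bounded least squares on the closed
#' form logistic solution.
#'
#' @param tc an untreated [time_course()] with at least 6 points.
#' @param spec a [fit_spec()].
#' @return A `fit_result`.
#' @export
fit_untreated <- function(tc, spec = fit_spec()) {
  if (length(tc$times) < 6) stop("need at least 6 points to fit")
  first <- tc$counts[1]
  mx <- max(tc$counts)
  nm <- c("g0", "theta_u", "N0")
  tab <- list(names = nm,
              lower = setNames(c(0, 0.5 * mx, 0.5 * first), nm),
              upper = setNames(c(0.1, 10 * mx, 2 * first), nm),
              init = setNames(c(0.02, 1.2 * mx, first), nm))
  tab <- apply_spec_overrides(tab, spec)
  t0 <- tc$times[1]
  pred_fun <- function(p, times = tc$times)
    logistic_closed_form(p[["N0"]], p[["g0"]], p[["theta_u"]], times - t0)
  ans <- bounded_nls(pred_fun, tc$counts, tab, spec)
  new_fit_result(ans$par, numeric(), pred_fun, tc, treatment_schedule(),
                 NULL, NA_real_, ans$convergence, tab, spec)
}

#' Fit the treatment-response model to one trajectory
#'
#' Calibrates `g0`, `gs`, `gd`, `kd`, the per-dose surviving fractions and
#' death-delay rates (one shared value in `constant` mode, one per dose in
#' `adaptive` mode), `N0`, and optionally `theta_dox`, by bounded
#' nonlinear least squares on the unweighted residuals of the total count.
#'
#' @param tc a [time_course()] spanning pre- and post-treatment times.
#' @param schedule a [treatment_schedule()] with at least one dose.
#' @param mode `"constant"` or `"adaptive"` per-dose parameterization.
#' @param spec a [fit_spec()].
#' @param theta_u untreated carrying capacity (cells), held fixed.
#' @param theta_dox if `NULL` (default) the treated capacity is a free
#'   parameter; a numeric value fixes it (see [apply_theta_dox_policy()]).
#' @return A `fit_result`.
#' @export
fit_model <- function(tc, schedule, mode = c("constant", "adaptive"),
                      spec = fit_spec(), theta_u = 53873,
                      theta_dox = NULL) {
  mode <- match.arg(mode)
  if (schedule$n_doses < 1) stop("schedule must contain at least one dose")
  if (length(tc$times) < 6) stop("need at least 6 points to fit")
  if (min(tc$times) > min(schedule$dose_times) ||
      max(tc$times) <= max(schedule$dose_times))
    stop("trajectory must span pre- and post-treatment times")
  n_par_doses <- if (mode == "adaptive") schedule$n_doses else 1L
  theta_free <- is.null(theta_dox)
  tab <- default_param_table(n_par_doses, tc$counts[1], theta_u, theta_free)
  tab <- apply_spec_overrides(tab, spec)
  pred_fun <- function(p, times = tc$times) {
    fs <- p[paste0("fs", seq_len(n_par_doses))]
    gd_i <- p[paste0("gamma_d", seq_len(n_par_doses))]
    params <- multi_dose_params(
      g0 = p[["g0"]], gs = p[["gs"]], gd = p[["gd"]], kd = p[["kd"]],
      theta_dox = if (theta_free) p[["theta_dox"]] else theta_dox,
      fs = unname(fs), gamma_d = unname(gd_i), mode = mode,
      N0 = p[["N0"]], theta_u = theta_u)
    simulate_treatment(params, schedule, times)$N
  }
  ans <- bounded_nls(pred_fun, tc$counts, tab, spec)
  fixed <- if (theta_free) numeric() else c(theta_dox = theta_dox)
  new_fit_result(ans$par, fixed, pred_fun, tc, schedule, mode, theta_u,
                 ans$convergence, tab, spec)
}

#' Two-pass policy for the treated carrying capacity
#'
#' Trajectories whose final observed count exceeds
#' `threshold * theta_u` identify `theta_dox` well and keep their free
#' estimates (pass 1). The remaining trajectories are refit with
#' `theta_dox` fixed to the mean of the pass-1 estimates within the same
#' experiment group, because low final counts leave the capacity
#' unidentifiable and inflate fitting error.
#'
#' @param fits list of `fit_result` from [fit_model()] with `theta_dox`
#'   free.
#' @param theta_u untreated carrying capacity (cells).
#' @param threshold identifiability threshold as a fraction of `theta_u`.
#' @return The list of fits with below-threshold members refit;
#'   each refit fit carries `fixed["theta_dox"]`.
#' @export
apply_theta_dox_policy <- function(fits, theta_u = 53873, threshold = 0.3) {
  last_counts <- vapply(fits, function(f) f$tc$counts[length(f$tc$counts)],
                        numeric(1))
  groups <- vapply(fits, function(f)
    as.character(f$tc$condition$experiment %||% NA), character(1))
  out <- fits
  for (g in unique(groups)) {
    idx <- which(groups == g)
    above <- idx[last_counts[idx] > threshold * theta_u]
    below <- setdiff(idx, above)
    if (!length(below)) next
    if (!length(above))
      stop("no replicate in group '", g, "' exceeds the threshold; ",
           "supply theta_dox manually")
    est <- vapply(fits[above], function(f) f$estimate[["theta_dox"]],
                  numeric(1))
    theta_fix <- mean(est)
    for (i in below) {
      f <- fits[[i]]
      out[[i]] <- fit_model(f$tc, f$schedule, f$mode, f$spec,
                            theta_u = theta_u, theta_dox = theta_fix)
    }
  }
  out
}

# central finite-difference Jacobian of pred_fun at p
fd_jacobian <- function(pred_fun, p, times = NULL, rel_step = 1e-6) {
  f0 <- if (is.null(times)) pred_fun(p) else pred_fun(p, times)
  J <- matrix(0, length(f0), length(p),
              dimnames = list(NULL, names(p)))
  for (j in seq_along(p)) {
    h <- rel_step * max(abs(p[j]), 1e-4)
    pp <- p; pp[j] <- p[j] + h
    pm <- p; pm[j] <- p[j] - h
    fp <- if (is.null(times)) pred_fun(pp) else pred_fun(pp, times)
    fm <- if (is.null(times)) pred_fun(pm) else pred_fun(pm, times)
    J[, j] <- (fp - fm) / (2 * h)
  }
  J
}

# covariance of the estimates from the residual Jacobian; singular
# directions are flagged so dependent parameters report NA intervals
fit_covariance <- function(fit) {
  J <- fd_jacobian(fit$pred_fun, fit$estimate)
  n <- length(fit$residuals)
  k <- length(fit$estimate)
  dof <- n - k
  if (dof < 1) stop("not enough points for confidence intervals")
  s2 <- sum(fit$residuals^2) / dof
  sv <- svd(J)
  tol <- max(sv$d) * 1e-10
  good <- sv$d > tol
  dinv2 <- ifelse(good, 1 / sv$d^2, 0)
  covm <- sv$v %*% (dinv2 * t(sv$v)) * s2
  unident <- if (all(good)) rep(FALSE, k) else
    rowSums(abs(sv$v[, !good, drop = FALSE])) > 1e-6
  list(cov = covm, dof = dof, s2 = s2, unidentified = unident)
}

#' Asymptotic 95% confidence intervals for fitted parameters
#'
#' Intervals are `estimate +/- t(0.975, dof) * se`, with standard errors
#' from the inverse Gauss-Newton Hessian `(J'J)^-1 s^2`,
#' `s^2 = RSS / dof`, and the Jacobian evaluated by central finite
#' differences at the estimate. Parameters lying in a numerically singular
#' direction of `J'J` are reported as unidentified (`NA` interval) rather
#' than raising an error; intervals extending past a bound are flagged,
#' not clipped.
#'
#' @param fit a `fit_result`.
#' @param level confidence level.
#' @return A data.frame with columns `param`, `estimate`, `se`, `lower`,
#'   `upper`, `at_bound`, `unidentified`.
#' @export
param_confidence_intervals <- function(fit, level = 0.95) {
  fc <- fit_covariance(fit)
  se <- sqrt(pmax(diag(fc$cov), 0))
  se[fc$unidentified] <- NA_real_
  tq <- qt(1 - (1 - level) / 2, fc$dof)
  est <- fit$estimate
  lower <- est - tq * se
  upper <- est + tq * se
  data.frame(param = names(est), estimate = unname(est), se = unname(se),
             lower = unname(lower), upper = unname(upper),
             at_bound = unname(lower < fit$lower[names(est)] |
                                 upper > fit$upper[names(est)]),
             unidentified = fc$unidentified,
             row.names = NULL)
}

#' Delta-method 95% confidence band for the fitted curve
#'
#' Pointwise band `Nhat(t) +/- t(0.975, dof) * sqrt(g' (J'J)^-1 g s^2)`
#' with `g = dN(t)/dparams` at the estimate (confidence band for the mean
#' curve; observation-level bands are out of scope).
#'
#' @param fit a `fit_result`.
#' @param t_grid times (h) at which to evaluate the band.
#' @param level confidence level.
#' @return A data.frame with columns `time`, `fit`, `lower`, `upper`.
#' @export
prediction_intervals <- function(fit, t_grid = NULL, level = 0.95) {
  t_grid <- t_grid %||% fit$tc$times
  fc <- fit_covariance(fit)
  G <- fd_jacobian(fit$pred_fun, fit$estimate, times = t_grid)
  half <- qt(1 - (1 - level) / 2, fc$dof) *
    sqrt(pmax(rowSums((G %*% fc$cov) * G), 0))
  yhat <- fit$pred_fun(fit$estimate, t_grid)
  data.frame(time = t_grid, fit = yhat,
             lower = yhat - half, upper = yhat + half)
}
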