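#' Construct a time course of observed tumor cell counts
#'
#' A `time_course` holds one replicate's observed trajectory: strictly
#' increasing observation times (hours), nonnegative cell counts (reals --
#' fluorescence-derived estimates need not be integers), a replicate label,
#' and the experimental condition the well was subjected to.
#'
#' @param times numeric, observation times in hours, strictly increasing.
#' @param counts numeric, total cell counts, nonnegative, same length.
#' @param replicate_id character or integer label for the replicate.
#' @param condition named list with elements `experiment`,
#'   `concentration_nM`, `interval_d`, `n_doses` (missing entries filled
#'   with `NA`).
#' @param provenance character vector of per-point flags (default "raw").
#' @return An object of class `time_course`.
#' @export
time_course <- function(times, counts, replicate_id = "r1",
                        condition = list(), provenance = NULL) {
  times <- as.numeric(times)
  counts <- as.numeric(counts)
  if (length(times) != length(counts))
    stop("times and counts must have equal length")
  if (length(times) && any(diff(times) <= 0))
    stop("times must be strictly increasing in replicate ", replicate_id)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and nonnegative in replicate ", replicate_id)
  cond <- list(experiment = NA, concentration_nM = NA,
               interval_d = NA, n_doses = NA)
  cond[names(condition)] <- condition
  if (is.null(provenance)) provenance <- rep("raw", length(times))
  structure(list(times = times, counts = counts,
                 replicate_id = as.character(replicate_id),
                 condition = cond, provenance = provenance,
                 flags = character()),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("<time_course> replicate %s: %d points over [%.1f, %.1f] h\n",
              x$replicate_id, length(x$times),
              if (length(x$times)) min(x$times) else NA,
              if (length(x$times)) max(x$times) else NA))
  cond <- x$condition
  cat(sprintf("  condition: experiment=%s, %s nM, interval %s d, %s dose(s)\n",
              cond$experiment, cond$concentration_nM, cond$interval_d,
              cond$n_doses))
  invisible(x)
}

#' @export
length.time_course <- function(x) length(x$times)

#' Construct a treatment schedule
#'
#' Ordered doxorubicin dose times (hours) with per-dose concentrations (nM).
#' An empty schedule (`n_doses = 0`) denotes an untreated well.
#'
#' @param dose_times numeric, nondecreasing dose times in hours.
#' @param concentrations numeric, one concentration (nM) per dose; a scalar
#'   is recycled.
#' @return An object of class `treatment_schedule`.
#' @export
treatment_schedule <- function(dose_times = numeric(), concentrations = numeric()) {
  dose_times <- as.numeric(dose_times)
  if (length(dose_times) && any(diff(dose_times) < 0))
    stop("dose_times must be nondecreasing")
  if (length(concentrations) == 1L && length(dose_times) > 1L)
    concentrations <- rep(concentrations, length(dose_times))
  if (length(concentrations) != length(dose_times))
    stop("dose_times and concentrations must have equal length")
  structure(list(dose_times = dose_times,
                 concentrations = as.numeric(concentrations),
                 n_doses = length(dose_times)),
            class = "treatment_schedule")
}

#' @export
print.treatment_schedule <- function(x, ...) {
  cat(sprintf("<treatment_schedule> %d dose(s)\n", x$n_doses))
  if (x$n_doses)
    cat(paste0("  t = ", x$dose_times, " h @ ", x$concentrations, " nM",
               collapse = "\n"), "\n")
  invisible(x)
}

#' Parameters of the untreated logistic growth model
#'
#' @param g0 untreated proliferation rate (1/h), nonnegative.
#' @param theta_u untreated carrying capacity (cells), positive.
#' @param N0 initial cell count, positive.
#' @return An object of class `untreated_params`.
#' @export
untreated_params <- function(g0, theta_u, N0) {
  if (g0 < 0) stop("g0 must be nonnegative")
  if (theta_u <= 0) stop("theta_u must be positive")
  if (N0 <= 0) stop("N0 must be positive")
  structure(list(g0 = g0, theta_u = theta_u, N0 = N0),
            class = "untreated_params")
}

#' Parameters of the multi-dose treatment-response model
#'
#' Shared rates plus per-dose surviving fractions `fs` and death-delay
#' rates `gamma_d`. The single-dose model is the `n_d = 1` case. In
#' `constant` mode a single `fs` and a single `gamma_d` apply to every
#' dose; in `adaptive` mode one value per dose is required.
#'
#' @param g0 pre-treatment proliferation rate (1/h).
#' @param gs proliferation rate of surviving cells (1/h).
#' @param gd proliferation rate of damaged cells (1/h).
#' @param kd asymptotic net rate of damaged cells (1/h); `kd <= 0` denotes
#'   net drug-induced death.
#' @param theta_dox treated carrying capacity (cells), positive.
#' @param fs surviving fraction(s) in `[0, 1]`; scalar in constant mode.
#' @param gamma_d death-delay rate(s) (1/h), nonnegative.
#' @param mode `"constant"` or `"adaptive"`.
#' @param N0 initial cell count (cells).
#' @param theta_u untreated carrying capacity used before the first dose
#'   (cells); defaults to the study-level value of 53873.
#' @return An object of class `multi_dose_params`.
#' @export
multi_dose_params <- function(g0, gs, gd, kd, theta_dox, fs, gamma_d,
                              mode = c("constant", "adaptive"),
                              N0, theta_u = 53873) {
  mode <- match.arg(mode)
  if (any(fs < 0 | fs > 1)) stop("each fs must lie in [0, 1]")
  if (any(gamma_d < 0)) stop("each gamma_d must be nonnegative")
  if (theta_dox <= 0) stop("theta_dox must be positive")
  if (theta_u <= 0) stop("theta_u must be positive")
  if (N0 <= 0) stop("N0 must be positive")
  if (mode == "constant") {
    if (length(unique(fs)) > 1L || length(unique(gamma_d)) > 1L)
      stop("constant mode requires a single fs and a single gamma_d value")
  } else if (length(fs) != length(gamma_d)) {
    stop("adaptive mode requires fs and gamma_d of equal length")
  }
  structure(list(g0 = as.numeric(g0), gs = as.numeric(gs),
                 gd = as.numeric(gd), kd = as.numeric(kd),
                 theta_dox = as.numeric(theta_dox), fs = as.numeric(fs),
                 gamma_d = as.numeric(gamma_d), mode = mode,
                 N0 = as.numeric(N0), theta_u = as.numeric(theta_u)),
            class = "multi_dose_params")
}

# expand per-dose parameter lists to the schedule length
expand_dose_params <- function(params, n_doses) {
  fs <- params$fs
  gamma_d <- params$gamma_d
  if (params$mode == "constant") {
    fs <- rep(fs[1], n_doses)
    gamma_d <- rep(gamma_d[1], n_doses)
  }
  if (n_doses > 0 && (length(fs) != n_doses || length(gamma_d) != n_doses))
    stop("adaptive parameters must supply one fs and gamma_d per dose (",
         n_doses, " required)")
  list(fs = fs, gamma_d = gamma_d)
}

#' Enumerate the replicate design of one of the three experiments
#'
#' Experiment 1 varies doxorubicin concentration (10 concentrations
#' including the untreated 0 nM control, 1 dose, 6 replicates each).
#' Experiment 2 varies the inter-treatment interval (9 intervals, 2 doses
#' of 75 nM, 12 replicates each). Experiment 3 varies the number of doses
#' (1-5 doses of 75 nM at 2-day or 14-day intervals, 12 replicates each).
#'
#' @param experiment_id integer, 1, 2 or 3.
#' @return A data.frame with one row per (condition, replicate) and columns
#'   `experiment`, `concentration_nM`, `interval_d`, `n_doses`,
#'   `replicate_id`.
#' @export
enumerate_design <- function(experiment_id) {
  if (!experiment_id %in% 1:3) stop("unknown experiment id: ", experiment_id)
  if (experiment_id == 1) {
    conds <- data.frame(concentration_nM = c(0, 10, 20, 35, 50, 75,
                                             100, 125, 150, 300),
                        interval_d = NA_real_, n_doses = 1L)
    n_rep <- 6L
  } else if (experiment_id == 2) {
    conds <- data.frame(concentration_nM = 75,
                        interval_d = c(0, 2, 4, 6, 8, 10, 12, 14, 16),
                        n_doses = 2L)
    n_rep <- 12L
  } else {
    conds <- expand.grid(concentration_nM = 75, interval_d = c(2, 14),
                         n_doses = 1:5)
    n_rep <- 12L
  }
  out <- conds[rep(seq_len(nrow(conds)), each = n_rep), , drop = FALSE]
  out$experiment <- experiment_id
  out$replicate_id <- paste0("r", rep(seq_len(n_rep), times = nrow(conds)))
  rownames(out) <- NULL
  out[, c("experiment", "concentration_nM", "interval_d", "n_doses",
          "replicate_id")]
}

#' Build the treatment schedule implied by a design condition
#'
#' The first dose is delivered after the pre-treatment growth period
#' (default 48 h); subsequent doses follow at the condition's
#' inter-treatment interval.
#'
#' @param condition one row of [enumerate_design()] output, or an
#'   equivalent list.
#' @param first_dose_h time of the first dose in hours.
#' @return A [treatment_schedule()].
#' @export
schedule_from_condition <- function(condition, first_dose_h = 48) {
  nd <- condition$n_doses
  if (is.na(nd) || nd == 0) return(treatment_schedule())
  interval_h <- if (nd > 1) condition$interval_d * 24 else 0
  times <- first_dose_h + (seq_len(nd) - 1) * interval_h
  treatment_schedule(times, rep(condition$concentration_nM, nd))
}

#' Read time courses from a CSV file
#'
#' The canonical layout has columns
#' `time,count,replicate,experiment,concentration_nM,interval_d,n_doses`.
#' A `schema` list maps nonstandard column names and declares the unit of
#' the time column (`"hours"` or `"days"`); days are converted to hours.
#'
#' @param path path to a CSV file.
#' @param schema list with optional entries `time`, `count`, `replicate`
#'   (column names) and `time_unit`.
#' @return A list of [time_course()] objects, one per replicate-condition.
#' @export
read_time_courses <- function(path, schema = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  sc <- modifyList(list(time = "time", count = "count",
                        replicate = "replicate", time_unit = "hours"),
                   schema)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c(sc$time, sc$count, sc$replicate)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  mult <- switch(sc$time_unit, hours = 1, days = 24,
                 stop("unknown time unit: ", sc$time_unit))
  cond_cols <- intersect(c("experiment", "concentration_nM", "interval_d",
                           "n_doses"), names(df))
  key <- do.call(paste, c(df[c(sc$replicate, cond_cols)], sep = "\r"))
  lapply(split(df, factor(key, levels = unique(key))), function(g) {
    g <- g[order(g[[sc$time]]), , drop = FALSE]
    cond <- lapply(g[1, cond_cols, drop = FALSE], identity)
    time_course(g[[sc$time]] * mult, g[[sc$count]],
                replicate_id = g[[sc$replicate]][1], condition = cond)
  })
}

#' Write time courses to a CSV file in the canonical layout
#'
#' @param tcs list of [time_course()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_time_courses <- function(tcs, path) {
  if (inherits(tcs, "time_course")) tcs <- list(tcs)
  rows <- lapply(tcs, function(tc) {
    data.frame(time = tc$times, count = tc$counts,
               replicate = tc$replicate_id,
               experiment = tc$condition$experiment,
               concentration_nM = tc$condition$concentration_nM,
               interval_d = tc$condition$interval_d,
               n_doses = tc$condition$n_doses)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
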