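#' Configuration of an end-to-end pipeline run
#'
#' @param outdir output directory (created if missing).
#' @param design experiment design id (1, 2 or 3) for synthetic input.
#' @param input_csv optional path to observed data in the canonical CSV
#'   layout; when given, the synthesis stage is skipped.
#' @param seed root seed; every stochastic stage draws from a stream
#'   seeded deterministically from it.
#' @param theta_u untreated carrying capacity (cells).
#' @param noise a [noise_model()] for the synthesis stage.
#' @param cadence imaging cadence (h) for synthesis.
#' @param adaptive_threshold_d intervals at or above this many days are
#'   fit with the adaptive per-dose parameterization (model-selection rule
#'   established by [compare_model_versions()]).
#' @param spec a [fit_spec()].
#' @param confluence_frac,window,n_mad preprocessing settings.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, design = 1, input_csv = NULL, seed = 1,
                            theta_u = 53873, noise = noise_model(),
                            cadence = 3, adaptive_threshold_d = 8,
                            spec = fit_spec(n_starts = 5),
                            confluence_frac = 0.95,
                            window = 5, n_mad = 3) {
  if (!is.null(input_csv) && !file.exists(input_csv))
    stop("input_csv does not exist: ", input_csv)
  structure(list(outdir = outdir, design = design, input_csv = input_csv,
                 seed = seed, theta_u = theta_u, noise = noise,
                 cadence = cadence,
                 adaptive_threshold_d = adaptive_threshold_d, spec = spec,
                 confluence_frac = confluence_frac, window = window,
                 n_mad = n_mad),
            class = "pipeline_config")
}

fit_summary_row <- function(fit) {
  est <- as.list(fit$estimate)
  data.frame(replicate = fit$tc$replicate_id,
             experiment = fit$tc$condition$experiment %||% NA,
             concentration_nM = fit$tc$condition$concentration_nM %||% NA,
             interval_d = fit$tc$condition$interval_d %||% NA,
             n_doses = fit$tc$condition$n_doses %||% NA,
             mode = fit$mode %||% "untreated",
             nrmse = fit$gof$nrmse, r2 = fit$gof$r2, pcc = fit$gof$pcc,
             ccc = fit$gof$ccc,
             status = fit$convergence$status,
             iterations = fit$convergence$iterations,
             final_cost = fit$convergence$final_cost,
             params = I(list(est)))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: synthesize (or load) trajectories, preprocess, fit
#' (untreated wells with the logistic model; treated wells with the
#' multi-dose model, constant or adaptive per the interval rule, then the
#' treated-capacity policy), compute quality-of-fit, and -- for the
#' varying-concentration design -- fit the empirical parameter formulas.
#' Per-stage artifacts (CSV/JSON) and a manifest are written under
#' `config$outdir`; stages whose artifact already exists are re-used when
#' `resume = TRUE`.
#'
#' @param config a [pipeline_config()].
#' @param resume reuse existing stage artifacts where possible.
#' @return The run manifest (also written to `manifest.json`),
#'   invisibly a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(config$outdir, f)
  manifest <- list(package_version = as.character(utils::packageVersion("doxpop")),
                   seed = config$seed, design = config$design,
                   stages = list())

  # stage 1: input
  raw_path <- pth("raw.csv")
  if (!is.null(config$input_csv)) {
    tcs <- read_time_courses(config$input_csv)
    truth <- NULL
  } else if (resume && file.exists(raw_path)) {
    tcs <- read_time_courses(raw_path)
    truth <- NULL
  } else {
    synth <- generate_experiment(config$design, seed = config$seed,
                                 noise = config$noise,
                                 cadence = config$cadence)
    tcs <- synth$time_courses
    truth <- synth$truth
    write_time_courses(tcs, raw_path)
  }
  manifest$stages$input <- list(n_replicates = length(tcs))

  # stage 2: preprocess
  pp <- lapply(tcs, preprocess, theta_ref = config$theta_u,
               confluence_frac = config$confluence_frac,
               window = config$window, n_mad = config$n_mad)
  clean <- lapply(pp, `[[`, "tc")
  write_time_courses(clean, pth("clean.csv"))
  pp_report <- lapply(pp, `[[`, "report")
  jsonlite::write_json(pp_report, pth("preprocess_report.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$stages$preprocess <-
    list(n_points_removed = sum(vapply(pp_report, function(r)
      r$n_points_in - r$n_points_out, numeric(1))))

  # stage 3: fit (seeded so multi-start jitter is reproducible)
  set.seed(config$seed + 1L)
  fits <- vector("list", length(clean))
  for (i in seq_along(clean)) {
    tc <- clean[[i]]
    cond <- tc$condition
    untreated <- (is.na(cond$n_doses) || cond$n_doses == 0 ||
                    (!is.na(cond$concentration_nM) &&
                       cond$concentration_nM == 0))
    if (untreated) {
      fits[[i]] <- fit_untreated(tc, config$spec)
    } else {
      schedule <- schedule_from_condition(cond)
      mode <- if (cond$n_doses >= 2 && !is.na(cond$interval_d) &&
                    cond$interval_d >= config$adaptive_threshold_d)
        "adaptive" else "constant"
      fits[[i]] <- fit_model(tc, schedule, mode, config$spec,
                             theta_u = config$theta_u)
    }
  }
  treated <- which(vapply(fits, function(f) !is.null(f$mode), logical(1)))
  if (length(treated))
    fits[treated] <- apply_theta_dox_policy(
      fits[treated], config$theta_u, config$spec$theta_dox_threshold)
  summary_df <- do.call(rbind, lapply(fits, fit_summary_row))
  jsonlite::write_json(summary_df, pth("fits.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  manifest$stages$fit <- list(
    n_fits = length(fits),
    n_converged = sum(summary_df$status == 0),
    median_nrmse = median(summary_df$nrmse))

  # stage 4: gof table
  gof_df <- summary_df[, c("replicate", "experiment", "concentration_nM",
                           "interval_d", "n_doses", "mode", "nrmse", "r2",
                           "pcc", "ccc")]
  write.csv(gof_df, pth("gof.csv"), row.names = FALSE)
  manifest$stages$gof <- list(median_ccc = median(gof_df$ccc, na.rm = TRUE))

  # stage 5: empirical formulas (varying-concentration design only)
  formulas <- NULL
  tr <- summary_df[summary_df$mode != "untreated", ]
  conc <- sort(unique(tr$concentration_nM))
  if (config$design == 1 && length(conc) >= 4) {
    med <- function(target)
      vapply(conc, function(cc) {
        vals <- vapply(tr$params[tr$concentration_nM == cc],
                       function(p) p[[if (target == "fs") "fs1" else
                         if (target == "gamma_d") "gamma_d1" else target]],
                       numeric(1))
        median(vals)
      }, numeric(1))
    formulas <- lapply(setNames(nm = c("fs", "gs", "gd", "kd", "gamma_d")),
                       function(tg) fit_formula(tg, conc, med(tg)))
    jsonlite::write_json(
      lapply(formulas, function(f)
        list(target = f$target_param, form = f$form, coef = f$coef,
             nrmse = f$gof$nrmse, r2 = f$gof$r2)),
      pth("formulas.json"), auto_unbox = TRUE, digits = NA)
    manifest$stages$formulas <- list(
      forms = vapply(formulas, `[[`, character(1), "form"))
  }

  # hash the reproducible settings only (paths vary between hosts/runs)
  cfg_json <- jsonlite::toJSON(
    config[setdiff(names(config), c("spec", "outdir", "input_csv"))],
    auto_unbox = TRUE, force = TRUE)
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest$config_hash <- unname(tools::md5sum(tf))
  unlink(tf)
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(manifest = manifest, fits = fits, formulas = formulas,
                 clean = clean, truth = truth, summary = summary_df))
}

#' Command-line interface
#'
#' A minimal verb-based CLI (`synth`, `preprocess`, `fit`, `run-all`)
#' around the pipeline, e.g.
#' `Rscript -e 'doxpop::doxpop_cli()' run-all --design 1 --seed 42 --out out/`.
#' Arguments are `--key value` pairs.
#'
#' @param args character vector of CLI arguments.
#' @return Exit status, invisibly.
#' @export
doxpop_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: doxpop <synth|preprocess|fit|run-all> [--key value ...]")
    return(invisible(1L))
  }
  verb <- args[1]
  kv <- list()
  i <- 2
  while (i < length(args) + 1) {
    if (startsWith(args[i], "--") && i < length(args)) {
      kv[[substring(args[i], 3)]] <- args[i + 1]; i <- i + 2
    } else i <- i + 1
  }
  num <- function(k, d) if (!is.null(kv[[k]])) as.numeric(kv[[k]]) else d
  chr <- function(k, d = NULL) kv[[k]] %||% d
  out <- chr("out", "doxpop_out")
  if (verb == "synth") {
    synth <- generate_experiment(num("design", 1), seed = num("seed", 1))
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_time_courses(synth$time_courses, file.path(out, "synth.csv"))
    message("wrote ", file.path(out, "synth.csv"))
  } else if (verb == "preprocess") {
    tcs <- read_time_courses(chr("in"))
    pp <- lapply(tcs, preprocess, theta_ref = num("theta-u", 53873),
                 confluence_frac = num("confluence-frac", 0.95),
                 window = num("window", 5), n_mad = num("n-mad", 3))
    write_time_courses(lapply(pp, `[[`, "tc"), chr("out", "clean.csv"))
  } else if (verb %in% c("fit", "run-all")) {
    cfg <- pipeline_config(out, design = num("design", 1),
                           input_csv = chr("in"), seed = num("seed", 1),
                           theta_u = num("theta-u", 53873))
    run_pipeline(cfg)
    message("pipeline artifacts under ", out)
  } else {
    stop("unknown verb: ", verb)
  }
  invisible(0L)
}
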