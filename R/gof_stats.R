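#' Normalized root mean squared error (percent)
#'
#' RMSE normalized by the mean of the observations and expressed as a
#' percentage. Mean-normalization (rather than range) is used throughout:
#' it is scale invariant and can legitimately exceed 100% when the
#' observed values are small relative to the errors.
#'
#' @param obs,pred numeric vectors of equal length (at least 2).
#' @return `100 * sqrt(mean((pred - obs)^2)) / mean(obs)`.
#' @export
nrmse <- function(obs, pred) {
  check_pair(obs, pred)
  m <- mean(obs)
  if (m == 0) stop("mean of observations is zero; NRMSE undefined")
  100 * sqrt(mean((pred - obs)^2)) / m
}

#' Lin's concordance correlation coefficient
#'
#' Agreement measure combining correlation with penalties for location and
#' scale shifts, using population (1/n) moments per Lin's original
#' definition:
#' `2 cov(obs, pred) / (var(obs) + var(pred) + (mean(obs) - mean(pred))^2)`.
#'
#' @inheritParams nrmse
#' @return CCC in `[-1, 1]`.
#' @export
ccc <- function(obs, pred) {
  check_pair(obs, pred)
  n <- length(obs)
  mo <- mean(obs); mp <- mean(pred)
  vo <- mean((obs - mo)^2); vp <- mean((pred - mp)^2)
  if (vo == 0 || vp == 0) stop("zero variance; CCC undefined")
  cv <- mean((obs - mo) * (pred - mp))
  2 * cv / (vo + vp + (mo - mp)^2)
}

#' Coefficient of determination and Pearson correlation
#'
#' `r2 = 1 - RSS/TSS` with the total sum of squares about the mean of the
#' observations; `pcc` is the Pearson correlation.
#'
#' @inheritParams nrmse
#' @return A list with elements `r2` and `pcc`.
#' @export
r2_pcc <- function(obs, pred) {
  check_pair(obs, pred)
  tss <- sum((obs - mean(obs))^2)
  if (tss == 0) stop("zero total sum of squares; R2 undefined")
  r2 <- 1 - sum((obs - pred)^2) / tss
  pcc <- if (stats::sd(pred) == 0) NA_real_ else stats::cor(obs, pred)
  list(r2 = r2, pcc = pcc)
}

check_pair <- function(obs, pred) {
  if (length(obs) != length(pred)) stop("obs and pred lengths differ")
  if (length(obs) < 2) stop("need at least 2 points")
  invisible(TRUE)
}

#' Quality-of-fit report for one trajectory
#'
#' @inheritParams nrmse
#' @return A list with `nrmse` (percent), `r2`, `pcc`, `ccc`, `n_points`.
#' @export
gof_report <- function(obs, pred) {
  # degenerate inputs (zero variance) yield NA metrics rather than errors
  rp <- tryCatch(r2_pcc(obs, pred),
                 error = function(e) list(r2 = NA_real_, pcc = NA_real_))
  list(nrmse = tryCatch(nrmse(obs, pred), error = function(e) NA_real_),
       r2 = rp$r2, pcc = rp$pcc,
       ccc = tryCatch(ccc(obs, pred), error = function(e) NA_real_),
       n_points = length(obs))
}

#' Two-sided Wilcoxon rank sum test
#'
#' Returns the two-sided p-value of the Mann-Whitney/Wilcoxon rank-sum
#' statistic. The exact null distribution is used for combined sample
#' sizes up to 20 when there are no ties; otherwise a normal approximation
#' with tie correction and continuity correction is applied.
#'
#' @param x,y numeric samples with at least 3 observations each.
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) >= 3, length(y) >= 3)
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (!has_ties && (m + n) <= 20) {
    p <- if (U > m * n / 2) 2 * (1 - pwilcox(U - 1, m, n)) else
      2 * pwilcox(U, m, n)
    return(min(1, p))
  }
  mu <- m * n / 2
  sigma2 <- m * n / 12 *
    ((m + n + 1) - sum(ties^3 - ties) / ((m + n) * (m + n - 1)))
  if (sigma2 <= 0) return(1)
  z <- U - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
  min(1, 2 * pnorm(-abs(z)))
}

#' Choose between constant and adaptive per-dose parameterizations
#'
#' For each condition group (matched across the two fit lists), the NRMSE
#' distributions of the constant and adaptive fits are compared with a
#' two-sided Wilcoxon rank sum test. The adaptive model is selected only
#' when its NRMSE is significantly lower at `alpha`; otherwise the
#' parsimonious constant model wins. In the study's data this selects the
#' constant model for inter-treatment intervals shorter than 8 days and
#' the adaptive model for intervals of 8 days or more.
#'
#' @param fits_constant,fits_adaptive lists of `fit_result` covering the
#'   same replicates (matched by condition and replicate id).
#' @param alpha significance level.
#' @return A data.frame with one row per condition group: `group`, `p`,
#'   `median_constant`, `median_adaptive`, `decision`.
#' @export
compare_model_versions <- function(fits_constant, fits_adaptive,
                                   alpha = 0.05) {
  key <- function(f) paste(f$tc$condition$experiment,
                           f$tc$condition$concentration_nM,
                           f$tc$condition$interval_d,
                           f$tc$condition$n_doses, sep = "|")
  rep_key <- function(fits) sort(paste(vapply(fits, key, character(1)),
                                       vapply(fits, function(f)
                                         f$tc$replicate_id, character(1))))
  if (!identical(rep_key(fits_constant), rep_key(fits_adaptive)))
    stop("constant and adaptive fits must cover the same replicates")
  gc_ <- vapply(fits_constant, key, character(1))
  ga_ <- vapply(fits_adaptive, key, character(1))
  out <- lapply(unique(gc_), function(g) {
    nc <- vapply(fits_constant[gc_ == g], function(f) f$gof$nrmse,
                 numeric(1))
    na_ <- vapply(fits_adaptive[ga_ == g], function(f) f$gof$nrmse,
                  numeric(1))
    p <- wilcoxon_rank_sum(nc, na_)
    adaptive <- p < alpha && median(na_) < median(nc)
    data.frame(group = g, p = p, median_constant = median(nc),
               median_adaptive = median(na_),
               decision = if (adaptive) "adaptive" else "constant")
  })
  do.call(rbind, out)
}
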