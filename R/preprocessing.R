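#' Detect count discontinuities caused by media handling
#'
#' A discontinuity is a point whose count drops by at least `min_drop`
#' relative to the previous point. Drops losing less than 50% of cells are
#' classified `minor` (and can be normalized away, see
#' [normalize_discontinuity()]); drops of 50% or more are `major`. Only
#' indices with valid `d - 2` and `d + 1` neighbors are reported, since the
#' normalization constant needs both.
#'
#' @param tc a [time_course()] with at least 4 points.
#' @param min_drop minimum relative drop flagged (fraction).
#' @return A data.frame with columns `index`, `drop_fraction`, `class`.
#' @export
detect_discontinuities <- function(tc, min_drop = 0.25) {
  n <- length(tc$times)
  if (n < 4) stop("need at least 4 points to detect discontinuities")
  out <- data.frame(index = integer(), drop_fraction = numeric(),
                    class = character())
  for (d in 3:(n - 1)) {  # d - 2 and d + 1 must exist
    prev <- tc$counts[d - 1]
    if (prev <= 0) next
    drop <- 1 - tc$counts[d] / prev
    if (drop >= min_drop) {
      out <- rbind(out, data.frame(
        index = d, drop_fraction = drop,
        class = if (drop < 0.5) "minor" else "major"))
    }
  }
  out
}

#' Normalization constant for a media-handling discontinuity
#'
#' The constant `alpha` matches the first derivative of the counts across
#' the gap so that dividing the pre-gap counts by `alpha` smooths the
#' series:
#' \deqn{\alpha = \frac{(N_{d-1}-N_{d-2})/(t_{d-1}-t_{d-2}) +
#'   2N_{d-1}/(t_d-t_{d-1})}{2N_d/(t_d-t_{d-1}) +
#'   (N_d-N_{d+1})/(t_{d+1}-t_d)}}
#' On a constant series `alpha = 1`; a series whose pre-gap counts are a
#' multiple `c` of the post-gap level yields `alpha` close to `c` whenever
#' the local slopes are small relative to `2N/\Delta t`.
#'
#' @param tc a [time_course()].
#' @param d index of the discontinuity (the first point after the drop);
#'   must have valid neighbors `d - 2`, `d - 1`, `d + 1`.
#' @return The positive scalar `alpha`.
#' @export
normalization_constant <- function(tc, d) {
  n <- length(tc$times)
  if (d < 3 || d > n - 1)
    stop("index d must have valid neighbors d-2 and d+1")
  tt <- tc$times; N <- tc$counts
  dt_pre <- tt[d - 1] - tt[d - 2]
  dt_gap <- tt[d] - tt[d - 1]
  dt_post <- tt[d + 1] - tt[d]
  if (dt_pre <= 0 || dt_gap <= 0 || dt_post <= 0)
    stop("nonpositive time step around discontinuity")
  num <- (N[d - 1] - N[d - 2]) / dt_pre + 2 * N[d - 1] / dt_gap
  den <- 2 * N[d] / dt_gap + (N[d] - N[d + 1]) / dt_post
  alpha <- num / den
  if (!is.finite(alpha) || alpha <= 0)
    stop("normalization failed (alpha = ", alpha,
         "); truncate the trajectory instead")
  alpha
}

#' Normalize a minor discontinuity in place
#'
#' Counts at indices before `d` are divided by the constant from
#' [normalization_constant()]; counts at `d` and beyond are untouched.
#'
#' @inheritParams normalization_constant
#' @return The corrected [time_course()] with provenance flags set.
#' @export
normalize_discontinuity <- function(tc, d) {
  alpha <- normalization_constant(tc, d)
  tc$counts[seq_len(d - 1)] <- tc$counts[seq_len(d - 1)] / alpha
  tc$provenance[seq_len(d - 1)] <- "normalized"
  attr(tc, "alpha") <- alpha
  tc
}

#' Truncate a trajectory at confluence, major drops, or repeated artifacts
#'
#' The trajectory is cut at the earliest of: (a) the first point at or
#' above `confluence_frac * theta_ref` (confluence; feeding-cycle
#' fluctuations beyond it are uninformative), (b) the first drop of at
#' least `major_drop_frac` relative to the previous point (cells lost to
#' media handling), or (c) the onset of repeated minor discontinuities
#' (`repeat_count` or more within any `repeat_window`-point window).
#'
#' @param tc a [time_course()].
#' @param theta_ref reference carrying capacity (cells).
#' @param confluence_frac fraction of `theta_ref` treated as confluence.
#' @param major_drop_frac relative single-step drop triggering rule (b).
#' @param min_drop minimum drop counted as a discontinuity for rule (c).
#' @param repeat_window,repeat_count sliding-window size and count for
#'   rule (c).
#' @return The truncated [time_course()]; attribute `"truncation_rule"`
#'   records which rule fired (`"none"`, `"confluence"`, `"major_drop"`,
#'   `"repeated_discontinuities"`).
#' @export
truncate_time_course <- function(tc, theta_ref, confluence_frac = 0.95,
                                 major_drop_frac = 0.5, min_drop = 0.25,
                                 repeat_window = 20, repeat_count = 3) {
  stopifnot(confluence_frac > 0, confluence_frac <= 1)
  n <- length(tc$times)
  cut <- n; rule <- "none"
  # "just prior to reaching confluence": the crossing point is excluded
  conf <- which(tc$counts >= confluence_frac * theta_ref)
  if (length(conf) && (conf[1] - 1) < cut) { cut <- conf[1] - 1; rule <- "confluence" }
  rel_drop <- c(0, 1 - tc$counts[-1] / pmax(tc$counts[-n], .Machine$double.eps))
  maj <- which(rel_drop >= major_drop_frac)
  if (length(maj) && (maj[1] - 1) < cut) { cut <- maj[1] - 1; rule <- "major_drop" }
  minor_idx <- which(rel_drop >= min_drop & rel_drop < major_drop_frac)
  if (length(minor_idx) >= repeat_count) {
    for (k in seq_len(length(minor_idx) - repeat_count + 1)) {
      span <- minor_idx[k + repeat_count - 1] - minor_idx[k]
      if (span < repeat_window) {
        onset <- minor_idx[k] - 1
        if (onset < cut) { cut <- onset; rule <- "repeated_discontinuities" }
        break
      }
    }
  }
  if (cut < 4) stop("truncation leaves fewer than 4 points; trajectory unusable")
  tc$times <- tc$times[seq_len(cut)]
  tc$counts <- tc$counts[seq_len(cut)]
  tc$provenance <- tc$provenance[seq_len(cut)]
  if (rule != "none") tc$provenance[cut] <- paste0("truncated-at:", rule)
  attr(tc, "truncation_rule") <- rule
  tc
}

#' Remove outliers by centered moving-median filtering
#'
#' A point is removed (not interpolated) when its count deviates from the
#' centered moving median by more than `n_mad` scaled median absolute
#' deviations (scale factor 1.4826) computed within the same window.
#' Windows with zero MAD remove nothing, so plateaus survive intact.
#'
#' @param tc a [time_course()].
#' @param window odd window length, at least 3.
#' @param n_mad threshold in scaled MADs.
#' @param max_removed_frac if more than this fraction of points is removed
#'   a warning flag is attached to the result.
#' @return The filtered [time_course()]; attribute `"removed_indices"`
#'   lists the removed positions in the input.
#' @export
remove_outliers <- function(tc, window = 5, n_mad = 3,
                            max_removed_frac = 0.1) {
  stopifnot(window >= 3, window %% 2 == 1, n_mad > 0)
  n <- length(tc$times)
  h <- (window - 1) %/% 2
  bad <- logical(n)
  for (i in seq_len(n)) {
    idx <- max(1, i - h):min(n, i + h)
    med <- median(tc$counts[idx])
    smad <- 1.4826 * median(abs(tc$counts[idx] - med))
    if (smad > 0 && abs(tc$counts[i] - med) > n_mad * smad) bad[i] <- TRUE
  }
  if (n - sum(bad) < 4)
    stop("outlier removal leaves fewer than 4 points; trajectory unusable")
  out <- tc
  out$times <- tc$times[!bad]
  out$counts <- tc$counts[!bad]
  out$provenance <- tc$provenance[!bad]
  if (sum(bad) > max_removed_frac * n)
    out$flags <- union(out$flags, "excessive_outlier_removal")
  attr(out, "removed_indices") <- which(bad)
  out
}

#' Full preprocessing pipeline for one trajectory
#'
#' Applies, in order: truncation ([truncate_time_course()]), left-to-right
#' normalization of minor discontinuities ([normalize_discontinuity()]),
#' and moving-median outlier removal ([remove_outliers()]). The order
#' mirrors the acquisition narrative: confluence and catastrophic events
#' first invalidate the tail, surviving media-handling steps are rescaled,
#' and only then are isolated spikes judged against the cleaned series.
#'
#' @inheritParams truncate_time_course
#' @inheritParams remove_outliers
#' @return A list with elements `tc` (the cleaned [time_course()]) and
#'   `report` (rules fired, alpha values, removed indices).
#' @export
preprocess <- function(tc, theta_ref = 53873, confluence_frac = 0.95,
                       major_drop_frac = 0.5, min_drop = 0.25,
                       window = 5, n_mad = 3) {
  tc1 <- truncate_time_course(tc, theta_ref, confluence_frac,
                              major_drop_frac, min_drop)
  alphas <- numeric()
  repeat {
    disc <- detect_discontinuities(tc1, min_drop)
    disc <- disc[disc$class == "minor", , drop = FALSE]
    if (!nrow(disc)) break
    tc1 <- normalize_discontinuity(tc1, disc$index[1])
    alphas <- c(alphas, attr(tc1, "alpha"))
    if (length(alphas) > length(tc1$times)) break  # safety
  }
  tc2 <- remove_outliers(tc1, window, n_mad)
  list(tc = tc2,
       report = list(replicate_id = tc$replicate_id,
                     truncation_rule = attr(tc1, "truncation_rule") %||%
                       attr(tc2, "truncation_rule") %||% "none",
                     n_points_in = length(tc$times),
                     n_points_out = length(tc2$times),
                     alphas = alphas,
                     removed_indices = attr(tc2, "removed_indices"),
                     flags = tc2$flags))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
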