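test_that("normalization constant: frozen oracle values", {
  # constant series: alpha = (0 + 2c)/(2c + 0) = 1 regardless of c
  tc <- time_course(0:5, rep(300, 6))
  expect_equal(normalization_constant(tc, 3), 1)
  # worked series by direct substitution:
  # num = (200-200)/1 + 2*200/1 = 400; den = 2*100/1 + (100-100)/1 = 200
  tc2 <- time_course(0:3, c(200, 200, 100, 100))
  expect_equal(normalization_constant(tc2, 3), 2)
  expect_error(normalization_constant(tc2, 2), "neighbors")
})

test_that("normalize_discontinuity rescales the prefix only", {
  tc <- time_course(0:3, c(200, 200, 100, 100))
  out <- normalize_discontinuity(tc, 3)
  expect_equal(out$counts, c(100, 100, 100, 100))
  # indices >= d preserved bit-exactly
  expect_identical(out$counts[3:4], tc$counts[3:4])
  # fixed point: a second pass computes alpha ~ 1 and changes nothing
  expect_equal(normalization_constant(out, 3), 1)
})

test_that("scaled-prefix series recover the scaling factor", {
  # a smooth logistic series whose first d-1 points were multiplied by c
  tc <- make_logistic_tc(times = seq(0, 300, 3))
  for (c_true in c(1.25, 1.4, 1.8)) {
    d <- 40
    counts <- tc$counts
    counts[seq_len(d - 1)] <- counts[seq_len(d - 1)] * c_true
    tc2 <- time_course(tc$times, counts)
    a <- normalization_constant(tc2, d)
    expect_lt(abs(a - c_true) / c_true, 0.1)
  }
})

test_that("detect_discontinuities classifies drops at the 50% boundary", {
  expect_equal(nrow(detect_discontinuities(make_logistic_tc())), 0)
  mk_drop <- function(frac) {
    counts <- rep(1000, 10); counts[6:10] <- 1000 * (1 - frac)
    time_course(0:9, counts)
  }
  d30 <- detect_discontinuities(mk_drop(0.3))
  expect_equal(d30$class, "minor")
  expect_equal(d30$index, 6)
  expect_equal(d30$drop_fraction, 0.3)
  expect_equal(detect_discontinuities(mk_drop(0.7))$class, "major")
})

test_that("truncation rules fire at the right indices", {
  theta <- 50000
  tc <- make_logistic_tc(theta = theta, times = seq(0, 400, 4))
  # below threshold: unchanged
  out <- truncate_time_course(tc, theta_ref = theta * 2)
  expect_equal(attr(out, "truncation_rule"), "none")
  expect_length(out$times, length(tc$times))
  # confluence: scan oracle = points strictly before the first crossing
  out2 <- truncate_time_course(tc, theta_ref = theta, confluence_frac = 0.5)
  expect_equal(attr(out2, "truncation_rule"), "confluence")
  expect_length(out2$times, sum(cumsum(tc$counts >= 0.5 * theta) == 0))
  # major drop at k: keep the points before the dropped one
  counts <- rep(1000, 20); counts[12:20] <- 350  # 65% drop at index 12
  tc3 <- time_course(0:19, counts)
  out3 <- truncate_time_course(tc3, theta_ref = 1e6)
  expect_equal(attr(out3, "truncation_rule"), "major_drop")
  expect_length(out3$times, 11)
  # repeated minor discontinuities
  counts4 <- 10000 * cumprod(c(1, rep(1, 4), 0.7, rep(1, 3), 0.7,
                               rep(1, 3), 0.7, rep(1, 5)))
  tc4 <- time_course(seq_along(counts4) - 1, counts4)
  out4 <- truncate_time_course(tc4, theta_ref = 1e6)
  expect_equal(attr(out4, "truncation_rule"), "repeated_discontinuities")
  expect_error(truncate_time_course(time_course(0:5, c(10, 10, 2, 2, 2, 2)),
                                    theta_ref = 1e6),
               "unusable")
})

test_that("moving-median outlier removal", {
  tc <- make_logistic_tc(times = seq(0, 400, 4))
  expect_length(remove_outliers(tc)$times, length(tc$times))
  # a single 10x spike is removed, and only it
  counts <- tc$counts; counts[30] <- counts[30] * 10
  out <- remove_outliers(time_course(tc$times, counts))
  expect_equal(attr(out, "removed_indices"), 30)
  # all-equal series: MAD = 0 windows remove nothing
  flat <- time_course(0:9, rep(500, 10))
  expect_length(remove_outliers(flat)$times, 10)
  # excessive removal raises a flag, not an error
  set.seed(4)
  noisy <- time_course(0:19, c(rep(100, 10), 100 * (1 + 3 * (runif(10) > 0.5))))
  out2 <- remove_outliers(noisy, max_removed_frac = 0.01)
  if (length(attr(out2, "removed_indices")) > 0)
    expect_true("excessive_outlier_removal" %in% out2$flags)
})

test_that("preprocessing pipeline is idempotent and restores artifacts", {
  w <- default_world()
  g <- generate_replicate(w$params, w$schedule, w$cadence, w$horizon,
                          noise_model(multiplicative_cv = 0,
                                      discontinuities = list(
                                        list(time = 200, lost_fraction = 0.3))))
  clean1 <- preprocess(g$tc)
  expect_length(clean1$report$alphas, 1)
  # restored to within 5% pointwise of the artifact-free truth
  truth_n <- g$truth$trajectory$N[match(clean1$tc$times, g$truth$trajectory$times)]
  expect_lt(max(abs(clean1$tc$counts - truth_n) / truth_n), 0.05)
  # second pass detects nothing and changes nothing
  clean2 <- preprocess(clean1$tc)
  expect_length(clean2$report$alphas, 0)
  expect_equal(clean2$tc$counts, clean1$tc$counts)
  expect_equal(clean2$tc$times, clean1$tc$times)
})
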