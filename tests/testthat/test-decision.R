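test_that("across-CF correlation matches a brute-force Pearson oracle", {
  set.seed(10)
  A <- matrix(runif(3 * 13, 1, 5), nrow = 3)
  B <- A + matrix(rnorm(3 * 13, sd = 0.5), nrow = 3)
  cc <- across_cf_correlation(as_profile(A), as_profile(B))
  for (k in 1:3)
    expect_equal(cc$r_k[k], bf_pearson(A[k, ], B[k, ]), tolerance = 1e-12)
  expect_equal(cc$d, 1 - mean(cc$r_k), tolerance = 1e-12)
})

test_that("decision identities: identical profiles give d = 0, anticorrelation d = 2", {
  set.seed(11)
  A <- matrix(runif(20 * 13, 1, 10), nrow = 20)
  expect_equal(across_cf_correlation(as_profile(A), as_profile(A))$d, 0,
               tolerance = 1e-12)
  B <- 30 - 2 * A  # negative affine map per segment
  expect_equal(across_cf_correlation(as_profile(A), as_profile(B))$d, 2,
               tolerance = 1e-12)
  # shape mismatch and degenerate inputs
  expect_error(across_cf_correlation(as_profile(A), as_profile(A[, 1:5])),
               "shape")
  flat <- matrix(5, nrow = 4, ncol = 13)
  expect_error(across_cf_correlation(as_profile(flat), as_profile(flat)),
               "no analyzable segments")
})

test_that("r_k is invariant to positive affine maps and CF permutation", {
  set.seed(12)
  A <- matrix(runif(10 * 13, 1, 4), nrow = 10)
  B <- matrix(runif(10 * 13, 1, 4), nrow = 10)
  base <- across_cf_correlation(as_profile(A), as_profile(B))
  scales <- runif(10, 0.5, 3)
  shifts <- runif(10, -1, 7)
  A2 <- A * scales + shifts
  cc2 <- across_cf_correlation(as_profile(A2), as_profile(B))
  expect_equal(cc2$r_k, base$r_k, tolerance = 1e-12)
  p <- sample(13)
  ccp <- across_cf_correlation(as_profile(A[, p]), as_profile(B[, p]))
  expect_equal(ccp$d, base$d, tolerance = 1e-12)
})

test_that("zero-variance segments are masked out of the average", {
  set.seed(13)
  A <- matrix(runif(5 * 13, 1, 4), nrow = 5)
  B <- matrix(runif(5 * 13, 1, 4), nrow = 5)
  A[3, ] <- 2  # flat across CF -> Pearson undefined
  cc <- across_cf_correlation(as_profile(A), as_profile(B))
  expect_false(cc$valid_mask[3])
  expect_true(is.na(cc$r_k[3]))
  keep <- setdiff(1:5, 3)
  expect_equal(cc$r_bar, mean(cc$r_k[keep]), tolerance = 1e-12)
})

test_that("the logistic SI mapping evaluates and saturates correctly", {
  expect_equal(si_from_d(0.5, list(a1 = -8, a2 = 4)), 50)
  expect_lt(si_from_d(0, list(a1 = 10, a2 = 10)), 1e-2)
  expect_equal(si_from_d(1, list(a1 = -10, a2 = 5)), 100 / (1 + exp(-5)),
               tolerance = 1e-12)
  # strictly monotone in d for a1 != 0
  d <- seq(0, 2, by = 0.05)
  expect_true(all(diff(si_from_d(d, list(a1 = -8, a2 = 4))) > 0))
  expect_true(all(diff(si_from_d(d, list(a1 = 8, a2 = -4))) < 0))
})

test_that("logistic fitting recovers noiseless and noisy parameters", {
  d <- seq(0.05, 0.95, length.out = 12)
  truth <- list(a1 = -8, a2 = 4)
  fit <- fit_logistic(d, si_from_d(d, truth))
  expect_equal(unname(coef(fit)), c(-8, 4), tolerance = 1e-6)
  expect_s3_class(fit, "si_logistic")
  expect_equal(predict(fit, newdata = 0.5), 50, tolerance = 1e-6)
  # noisy recovery: 2% SI Gaussian noise, 12 points, median over seeds
  errs <- t(vapply(1:60, function(s) {
    set.seed(s)
    si <- si_from_d(d, truth) + rnorm(12, sd = 2)
    abs(coef(fit_logistic(d, si)) / c(-8, 4) - 1)
  }, numeric(2)))
  expect_lt(stats::median(errs[, 1]), 0.1)
  expect_lt(stats::median(errs[, 2]), 0.1)
  expect_error(fit_logistic(0.5, 50), "2 ")
})

test_that("multi-start fitting reaches the optimum from flipped-sign targets", {
  d <- seq(0.1, 0.9, length.out = 10)
  for (truth in list(c(a1 = -8, a2 = 4), c(a1 = 6, a2 = -2))) {
    fit <- suppressWarnings(
      fit_logistic(d, si_from_d(d, as.list(truth))))
    expect_equal(unname(coef(fit)), unname(truth), tolerance = 1e-5)
  }
})

test_that("SRT estimation interpolates the first upward 50% crossing", {
  est <- estimate_srt(c(-6, -3), c(40, 60))
  expect_true(est$srt_defined)
  expect_equal(est$srt_db, -4.5)
  expect_equal(estimate_srt(c(-9, -6, -3), c(50, 70, 90))$srt_db, -9)
  # closed-form oracle: monotone logistic SI over a linear d(SNR)
  snr <- seq(-21, 12, by = 3)
  a1 <- -6; a2 <- 2.5
  d_lin <- 0.02 + 0.025 * (snr + 21)
  si <- 100 / (1 + exp(a1 * d_lin + a2))
  srt_exact <- ((-a2 / a1) - 0.02) / 0.025 - 21
  est2 <- estimate_srt(snr, si)
  expect_true(est2$srt_defined)
  expect_lt(abs(est2$srt_db - srt_exact), 0.15)
  # flag semantics when 50% is never crossed
  hi <- estimate_srt(snr, rep(90, length(snr)))
  expect_false(hi$srt_defined)
  expect_equal(hi$srt_db, -21)
  lo <- estimate_srt(snr, rep(10, length(snr)))
  expect_false(lo$srt_defined)
  expect_equal(lo$srt_db, 12)
})

test_that("correlation oracle agrees on many random fixtures", {
  set.seed(14)
  worst <- 0
  for (i in 1:200) {
    k <- sample(2:6, 1)
    A <- matrix(runif(k * 13, 0, 10), nrow = k)
    B <- matrix(runif(k * 13, 0, 10), nrow = k)
    cc <- across_cf_correlation(as_profile(A), as_profile(B))
    for (j in seq_len(k))
      worst <- max(worst, abs(cc$r_k[j] - bf_pearson(A[j, ], B[j, ])))
    expect_true(cc$d >= 0 && cc$d <= 2)
  }
  expect_lt(worst, 1e-10)
})
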