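test_that("CF grid is geometric from 0.5 to 8 kHz", {
  g <- default_cf_grid()
  expect_length(g, 13)
  expect_equal(g[1], 500)
  expect_equal(g[13], 8000)
  # consecutive ratio is 16^(1/12) = 2^(1/3)
  expect_equal(g[-1] / g[-13], rep(2^(1 / 3), 12), tolerance = 1e-12)
  expect_equal(default_cf_grid(2), c(500, 8000))
  expect_error(default_cf_grid(1), "at least 2")
  expect_error(default_cf_grid(13, 8000, 500), "lo_hz < hi_hz")
})

test_that("audiogram-derived loss splits two-thirds OHC, one-third IHC", {
  cfs <- default_cf_grid()
  l0 <- audiogram_to_loss(audiogram(c(250, 8000), c(0, 0)), cfs)
  expect_equal(l0$c_ohc, rep(1, 13))
  expect_equal(l0$c_ihc, rep(1, 13))
  ag60 <- audiogram(c(250, 500, 1000, 2000, 4000, 8000), rep(60, 6))
  l60 <- audiogram_to_loss(ag60, cfs, refine = FALSE)
  expect_equal(l60$ohc_loss_db, rep(40, 13), tolerance = 1e-9)
  expect_equal(l60$ihc_loss_db, rep(20, 13), tolerance = 1e-9)
  expect_equal(l60$ohc_loss_db + l60$ihc_loss_db, rep(60, 13),
               tolerance = 0.01)
  # interpolation is linear in log frequency: midpoint of {1k: 20, 4k: 60}
  li <- audiogram_to_loss(audiogram(c(1000, 4000), c(20, 60)),
                          c(1000, 2000, 4000), refine = FALSE)
  expect_equal(li$ohc_loss_db[2] + li$ihc_loss_db[2], 40, tolerance = 1e-6)
  expect_warning(audiogram_to_loss(audiogram(c(1000, 2000), c(10, 10)),
                                   cfs, refine = FALSE), "extrapolat")
  expect_error(audiogram(c(1000, 500), c(0, 0)), "increasing")
  expect_error(audiogram(c(500, 1000), c(-20, 0)), "-10")
})

test_that("silence yields the weighted spontaneous rate; rates stay finite", {
  sil <- audio_signal(rep(0, 50000), 100000)
  ng <- an_rate_response(sil)
  fib <- fiber_population()
  spont_w <- sum(fib$weights * fib$spont_rates_sps)
  expect_true(all(abs(colMeans(ng$rates_sps) / spont_w - 1) < 0.1))
  expect_true(all(ng$rates_sps >= 0))
  v <- make_vowel(0.2)
  expect_true(all(an_rate_response(v)$rates_sps >= 0))
  bad <- audio_signal(c(rep(0, 10), NaN), 100000)
  expect_error(an_rate_response(bad), "NaN")
  expect_error(an_rate_response(sil, cf_hz = 60000), "fs/2")
})

test_that("HSR fibers saturate within 10% of their rate ceiling 30 dB above threshold", {
  hsr <- fiber_population(weights = c(1, 0, 0))
  thr <- pure_tone_threshold(4000, fibers = hsr)
  ng <- an_rate_response(test_tone(4000, thr + 30), cf_hz = 4000, fibers = hsr)
  sustained <- mean(ng$rates_sps[15000:29000, 1])
  expect_gt(sustained, 0.9 * hsr$sat_rates_sps[1])
})

test_that("cochlear growth is compressive when healthy and linear without OHC gain", {
  cfg <- periphery_config()
  cf <- 2000
  drive_at <- function(level, c_ohc) {
    x <- test_tone(cf, level)
    xme <- as.numeric(signal::filter(flucsi:::middle_ear_coefs(cfg), x$samples))
    mean(flucsi:::channel_drive(xme, cf, c_ohc, 1, cfg)[15000:29000])
  }
  # healthy: 40 dB more input grows the drive by far less than 40 dB
  growth_db <- 20 * log10(drive_at(80, 1) / drive_at(40, 1))
  expect_lt(growth_db, 30)
  expect_gt(growth_db, 0)
  # without the compressive path the channel is linear in level
  lin_growth <- 20 * log10(drive_at(80, 0) / drive_at(40, 0))
  expect_equal(lin_growth, 40, tolerance = 0.5)
})

test_that("simulated thresholds reproduce audiogram losses and are monotone", {
  l60 <- flat_loss(60)
  for (cf in c(500, 2000, 8000)) {
    shift <- as.numeric(pure_tone_threshold(cf, l60)) -
      as.numeric(pure_tone_threshold(cf))
    expect_true(abs(shift - 60) <= 3)
  }
  # non-decreasing as OHC function degrades at fixed IHC, and vice versa
  thr_ohc <- vapply(c(1, 0.5, 0.2, 0.05, 0), function(co) {
    prof <- loss_profile(2000, 20 * log10(1 / max(co, 1e-3)), 0, co, 1)
    as.numeric(pure_tone_threshold(2000, prof))
  }, numeric(1))
  expect_true(all(diff(thr_ohc) >= 0))
  thr_ihc <- vapply(c(1, 0.5, 0.25, 0.1), function(ci) {
    prof <- loss_profile(2000, 0, -20 * log10(ci), 1, ci)
    as.numeric(pure_tone_threshold(2000, prof))
  }, numeric(1))
  expect_true(all(diff(thr_ihc) >= 0))
  # a loss-free profile reproduces normal hearing bit-exactly
  v <- make_vowel(0.2)
  expect_identical(an_rate_response(v, loss = nh_profile())$rates_sps,
                   an_rate_response(v)$rates_sps)
  expect_identical(as.numeric(pure_tone_threshold(2000, nh_profile())),
                   as.numeric(pure_tone_threshold(2000)))
})

test_that("neurogram computation is deterministic", {
  v <- make_vowel(0.3)
  expect_identical(an_rate_response(v)$rates_sps, an_rate_response(v)$rates_sps)
})

test_that("vowel fluctuations are stronger between formants than at them", {
  cfs <- default_cf_grid()
  fmts <- c(794, 2000, 3175)  # on-grid formants
  v <- make_vowel(0.6, 119, fmts)
  prof <- fluctuation_profile(v)
  bf <- which.min(abs(log(cfs) - log(sqrt(794 * 2000))))
  ff <- which.min(abs(log(cfs) - log(2000)))
  expect_gte(mean(prof$values[, bf] > prof$values[, ff]), 0.8)
  # contrast does not grow as IHC function degrades (c_ihc from 1 to 0.2)
  contr <- vapply(c(1, 0.6, 0.35, 0.2), function(ci) {
    lp <- loss_profile(cfs, rep(0, 13), rep(-20 * log10(ci), 13),
                       rep(1, 13), rep(ci, 13))
    p <- fluctuation_profile(v, loss = lp)
    mean(p$values[, bf] - p$values[, ff])
  }, numeric(1))
  expect_true(all(diff(contr) <= 0))
})
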