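# Shared helpers: small fixtures and independent oracles.

# Brute-force Pearson correlation, written with explicit loops so it shares
# no code path with across_cf_correlation().
bf_pearson <- function(x, y) {
  n <- length(x)
  mx <- 0; my <- 0
  for (i in seq_len(n)) { mx <- mx + x[i]; my <- my + y[i] }
  mx <- mx / n; my <- my / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# Wrap a plain matrix as a fluctuation_profile on the default CF grid.
as_profile <- function(values, cf = default_cf_grid(ncol(values))) {
  structure(list(values = values,
                 frame_times_s = seq_len(nrow(values)) * 0.01, cf_hz = cf),
            class = "fluctuation_profile")
}

# Ramped CF tone, calibrated.
test_tone <- function(freq_hz, level_db_spl, duration_s = 0.3, fs = 100000) {
  n <- round(duration_s * fs)
  x <- sin(2 * pi * freq_hz * (0:(n - 1)) / fs)
  nr <- round(0.005 * fs)
  r <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
  x[seq_len(nr)] <- x[seq_len(nr)] * r
  x[(n - nr + 1):n] <- x[(n - nr + 1):n] * rev(r)
  set_level(audio_signal(x, fs), level_db_spl)
}

# Autocorrelation F0 estimate over a frame (Hz), NA if unvoiced/weak.
estimate_f0 <- function(x, fs, f_lo = 80, f_hi = 400) {
  x <- x - mean(x)
  if (sqrt(mean(x^2)) < 1e-6) return(NA_real_)
  ac <- stats::acf(x, lag.max = round(fs / f_lo), plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  lags <- round(fs / f_hi):round(fs / f_lo)
  pk <- lags[which.max(ac[lags + 1])]
  if (ac[pk + 1] < 0.3 * ac[1]) return(NA_real_)
  fs / pk
}

# 50-ms moving-average envelope of |x|.
smoothed_envelope <- function(x, fs, win_s = 0.05) {
  w <- round(win_s * fs)
  as.numeric(stats::filter(abs(x), rep(1 / w, w), sides = 2))
}

# Small run configuration for end-to-end unit tests (not the study
# conditions; those live in the acceptance tests).
tiny_config <- function(...) {
  run_config(n_sentences = 2, sentence_duration_s = 0.8,
             snr_grid_db = c(-9, -3, 3), seed = 7, ...)
}

flat_loss <- function(total_db, cf = default_cf_grid()) {
  audiogram_to_loss(audiogram(c(250, 8000), rep(total_db, 2)), cf)
}

# Calibrations are expensive; cache them per model configuration.
tiny_cal <- local({
  cache <- new.env(parent = emptyenv())
  function(cfg) {
    key <- flucsi:::model_hash(cfg)
    if (is.null(cache[[key]]))
      cache[[key]] <- calibrate_si(cfg, default_si_targets(cfg$snr_grid_db))
    cache[[key]]
  }
})
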