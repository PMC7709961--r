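test_that("set_level calibrates under the RMS 1.0 = 94 dB SPL convention", {
  set.seed(1)
  x <- audio_signal(rnorm(10000), 48000)
  expect_equal(level_db_spl(set_level(x, 65)), 65, tolerance = 1e-12)
  # white noise calibrated to 94 dB SPL has RMS exactly 1
  expect_equal(sqrt(mean(set_level(x, 94)$samples^2)), 1, tolerance = 1e-12)
  # identity case: already at target level
  x65 <- set_level(x, 65)
  expect_identical(set_level(x65, 65)$samples, x65$samples)
  # 20 dB increase multiplies every sample by 10
  x60 <- set_level(x, 60)
  expect_equal(set_level(x60, 80)$samples, x60$samples * 10, tolerance = 1e-12)
  # idempotence
  expect_identical(set_level(set_level(x, 70), 70)$samples,
                   set_level(x, 70)$samples)
  expect_error(set_level(audio_signal(rep(0, 10), 48000), 65), "silent")
})

test_that("mix_at_snr enforces SNR and equal-level noise reference", {
  set.seed(2)
  fs <- 48000
  speech <- audio_signal(rnorm(fs), fs)
  noise <- audio_signal(rnorm(2 * fs), fs)
  for (snr in c(-12, 0, 7.5, 20)) {
    mix <- mix_at_snr(speech, noise, snr, 65)
    sp <- set_level(speech, 65)
    ncomp <- mix$sn$samples - sp$samples
    expect_equal(20 * log10(sqrt(mean(sp$samples^2)) / sqrt(mean(ncomp^2))),
                 snr, tolerance = 1e-9)
    # noise-alone reference has the same level as the noisy speech
    expect_equal(sqrt(mean(mix$n$samples^2)) / sqrt(mean(mix$sn$samples^2)),
                 1, tolerance = 1e-9)
  }
  # +6 dB SNR halves the interferer amplitude exactly
  m0 <- mix_at_snr(speech, noise, 0, 65)
  m6 <- mix_at_snr(speech, noise, 6, 65)
  n0 <- m0$sn$samples - set_level(speech, 65)$samples
  n6 <- m6$sn$samples - set_level(speech, 65)$samples
  expect_equal(n6, n0 * 10^(-6 / 20), tolerance = 1e-12)
  expect_error(mix_at_snr(speech, audio_signal(rnorm(100), 44100), 0),
               "sampling rates")
  expect_error(mix_at_snr(speech, audio_signal(rnorm(100), fs), 0), "shorter")
})

test_that("stimulus generators are pure functions of spec and seed", {
  ref <- make_speech_surrogate(duration_s = 0.8, seed = 3, fs = 32000)
  expect_identical(ref$samples,
                   make_speech_surrogate(duration_s = 0.8, seed = 3,
                                         fs = 32000)$samples)
  expect_identical(make_ssn(ref, 0.5, seed = 4)$samples,
                   make_ssn(ref, 0.5, seed = 4)$samples)
  expect_identical(make_ists_like(duration_s = 0.8, seed = 5, fs = 32000)$samples,
                   make_ists_like(duration_s = 0.8, seed = 5, fs = 32000)$samples)
  # different seeds give different waveforms
  expect_gt(max(abs(ref$samples -
                      make_speech_surrogate(duration_s = 0.8, seed = 30,
                                            fs = 32000)$samples)), 1e-4)
  # generation must not disturb the caller's RNG stream
  set.seed(99); a <- rnorm(3)
  set.seed(99); invisible(make_ssn(ref, 0.2, seed = 4)); b <- rnorm(3)
  expect_identical(a, b)
})

test_that("speech-shaped noise matches the reference long-term spectrum", {
  ref <- make_speech_surrogate(duration_s = 3, seed = 11, fs = 32000)
  ssn <- make_ssn(ref, 3, seed = 12)
  sp_r <- third_octave_levels(ref$samples, 32000, f_lo = 200, f_hi = 8000)
  sp_n <- third_octave_levels(ssn$samples, 32000, f_lo = 200, f_hi = 8000)
  dif <- sp_n$level_db - sp_r$level_db
  expect_true(all(abs(dif) < 1, na.rm = TRUE))
  expect_equal(level_db_spl(ssn), level_db_spl(ref), tolerance = 1e-9)
  expect_error(make_ssn(ref, -1, seed = 1), "positive")
})

test_that("SAM modulation has the stated envelope and spectrum", {
  ref <- make_speech_surrogate(duration_s = 5, seed = 13, fs = 32000)
  base <- make_ssn(ref, 5, seed = 14)
  sam <- make_sam(base, 8, 1)
  # depth 0 returns the re-calibrated base
  expect_equal(make_sam(base, 8, 0)$samples, base$samples, tolerance = 1e-12)
  expect_error(make_sam(base, 8, 1.2), "mod_depth")
  # full depth: envelope minima near zero at 1/8 s spacing
  env <- smoothed_envelope(sam$samples, 32000, 0.01)
  t_min <- seq(3 / 32, 5 - 0.1, by = 1 / 8)  # sin = -1 at 3/32 s
  idx <- round(t_min * 32000)
  expect_lt(stats::median(env[idx]) / stats::median(env, na.rm = TRUE), 0.12)
  # Hilbert-envelope modulation spectrum peaks at 8 Hz
  he <- hilbert_env <- flucsi:::hilbert_envelope(sam$samples)
  he <- he - mean(he)
  spec <- Mod(fft(he))[1:400]
  freqs <- (0:399) * 32000 / length(he)
  expect_equal(freqs[which.max(spec)], 8, tolerance = 0.21)
  # long-term third-octave spectrum conserved within 1 dB per band
  # (smooth-spectrum base: modulation only redistributes energy +/- 8 Hz,
  # which matters solely at cliff-like spectral edges)
  set.seed(15)
  lp <- signal::butter(2, 2000 / 16000)
  smooth_base <- set_level(audio_signal(
    as.numeric(signal::filter(lp, rnorm(5 * 32000))), 32000), 65)
  sam2 <- make_sam(smooth_base, 8, 1)
  sp_b <- third_octave_levels(smooth_base$samples, 32000, f_lo = 200, f_hi = 8000)
  sp_s <- third_octave_levels(sam2$samples, 32000, f_lo = 200, f_hi = 8000)
  expect_true(all(abs(sp_s$level_db - sp_b$level_db) < 1, na.rm = TRUE))
})

test_that("speech surrogate carries the target F0 and formant structure", {
  sp <- make_speech_surrogate(duration_s = 2, f0_hz = 119, seed = 17, fs = 32000)
  # frame-wise F0 of high-energy frames near 119 Hz
  n <- length(sp$samples)
  starts <- seq(1, n - 1280, by = 640)
  f0s <- vapply(starts, function(s)
    estimate_f0(sp$samples[s:(s + 1279)], 32000), numeric(1))
  energy <- vapply(starts, function(s)
    mean(sp$samples[s:(s + 1279)]^2), numeric(1))
  voiced <- energy > 0.25 * stats::median(energy[energy > 0])
  expect_equal(stats::median(f0s[voiced], na.rm = TRUE), 119, tolerance = 0.06)
  # deterministic vowel: spectral maxima at the configured formants within
  # one harmonic spacing
  v <- make_vowel(0.5, 119, c(700, 2200, 3300), fs = 32000)
  pw <- Mod(fft(v$samples))^2
  freqs <- (seq_along(pw) - 1) * 32000 / length(pw)
  for (f in c(700, 2200, 3300)) {
    band <- freqs > f / 1.45 & freqs < f * 1.45
    expect_lt(abs(freqs[band][which.max(pw[band])] - f), 119)
  }
  expect_error(make_vowel(0.5, -1), "positive")
  expect_error(make_vowel(0.5, 119, c(700, 20000), fs = 32000), "formants")
})

test_that("multi-talker surrogate fluctuates strongly with F0 near 207 Hz", {
  fs <- 32000
  ists <- make_ists_like(duration_s = 4, seed = 19, fs = fs)
  ref <- make_speech_surrogate(duration_s = 4, seed = 20, fs = fs)
  ssn <- make_ssn(ref, 4, seed = 21)
  env_i <- smoothed_envelope(ists$samples, fs)
  env_s <- smoothed_envelope(ssn$samples, fs)
  ratio <- function(e) {
    e <- e[!is.na(e)]
    stats::quantile(e, 0.95) / (stats::quantile(e, 0.05) + 1e-12)
  }
  expect_gt(ratio(env_i), 3 * ratio(env_s))
  # mean F0 over voiced frames within 10% of 207 Hz
  starts <- seq(1, length(ists$samples) - 1280, by = 640)
  f0s <- vapply(starts, function(s)
    estimate_f0(ists$samples[s:(s + 1279)], fs, 140, 320), numeric(1))
  energy <- vapply(starts, function(s) mean(ists$samples[s:(s + 1279)]^2),
                   numeric(1))
  voiced <- energy > 0.25 * stats::median(energy[energy > 1e-10])
  expect_equal(mean(f0s[voiced], na.rm = TRUE), 207, tolerance = 0.1)
})

test_that("WAV round trips preserve samples and handle stereo", {
  x <- set_level(audio_signal(sin(2 * pi * 440 * (0:9999) / 32000), 32000), 70)
  p <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, p, "float32")
  y <- read_wav(p)
  expect_equal(y$fs, 32000)
  expect_lt(max(abs(y$samples - x$samples)), 1e-7 * max(abs(x$samples)))
  write_wav(set_level(x, 80), p, "pcm16")  # keep samples inside [-1, 1)
  y16 <- read_wav(p)
  expect_lt(max(abs(y16$samples - set_level(x, 80)$samples)), 2^-14)
  # stereo: first channel with a warning
  con <- file(p, "wb")
  s <- matrix(as.integer(round(cbind(x$samples, -x$samples)[1:1000, ] * 2^14)),
              ncol = 2)
  inter <- as.integer(t(s))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + length(inter) * 2L), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(c(16L), con, 4, endian = "little")
  writeBin(c(1L, 2L), con, 2, endian = "little")
  writeBin(c(32000L, 32000L * 4L), con, 4, endian = "little")
  writeBin(c(4L, 16L), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(length(inter) * 2L, con, 4, endian = "little")
  writeBin(inter, con, 2, endian = "little")
  close(con)
  expect_warning(z <- read_wav(p), "first channel")
  expect_equal(z$samples, s[, 1] / 2^15, tolerance = 1e-12)
  expect_error(read_wav(file.path(tempdir(), "absent.wav")), "absent.wav")
})
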