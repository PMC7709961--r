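#' Stimulus specification
#'
#' Describes one of the seeded stimulus classes the pipeline can synthesize:
#' a harmonic speech surrogate, stationary speech-shaped noise (`ssn`),
#' sinusoidally amplitude-modulated SSN (`sam`), or a fluctuating multi-talker
#' surrogate (`ists_like`). Given the same spec (including `seed`) the
#' generators return bit-identical waveforms.
#'
#' @param kind one of `"speech_surrogate"`, `"ssn"`, `"sam"`, `"ists_like"`.
#' @param duration_s duration in seconds (> 0).
#' @param f0_hz fundamental frequency in Hz (speech surrogates; default 119,
#'   a typical male speaker; the multi-talker surrogate defaults to 207, a
#'   typical female average).
#' @param formants_hz formant (resonance) frequencies in Hz.
#' @param mod_rate_hz modulation rate for `sam`, Hz.
#' @param mod_depth modulation depth for `sam` in \[0, 1\].
#' @param seed integer seed fixing the output exactly.
#' @param fs sampling rate in Hz.
#' @return A list of class `stimulus_spec`.
#' @export
stimulus_spec <- function(kind = c("speech_surrogate", "ssn", "sam", "ists_like"),
                          duration_s = 2, f0_hz = NULL, formants_hz = NULL,
                          mod_rate_hz = 8, mod_depth = 1, seed = 1L, fs = 100000) {
  kind <- match.arg(kind)
  if (duration_s <= 0) stop("duration_s must be positive")
  if (mod_depth < 0 || mod_depth > 1) stop("mod_depth must lie in [0, 1]")
  f0_hz <- f0_hz %||% if (kind == "ists_like") 207 else 119
  formants_hz <- formants_hz %||% c(700, 2200, 3300)
  structure(list(kind = kind, duration_s = duration_s, f0_hz = f0_hz,
                 formants_hz = formants_hz, mod_rate_hz = mod_rate_hz,
                 mod_depth = mod_depth, seed = as.integer(seed), fs = fs),
            class = "stimulus_spec")
}

# Lorentzian formant envelope with a small spectral floor; local maxima sit
# at the formant frequencies. Bandwidths follow typical vocal-tract values
# (~60-160 Hz, widening with frequency) so the harmonic nearest a formant
# dominates its auditory channel.
formant_envelope <- function(f, formants_hz, bw_hz = pmax(70, 0.05 * formants_hz)) {
  env <- rep(0.01, length(f))
  for (j in seq_along(formants_hz)) {
    env <- env + 1 / (1 + ((f - formants_hz[j]) / bw_hz[j])^2)
  }
  env
}

# One voiced harmonic-complex token: harmonics of a (possibly drifting) f0 up
# to 8 kHz, weighted by the formant envelope, with raised-cosine edge ramps.
voiced_token <- function(n, fs, f0_start, f0_end, formants_hz, phases = NULL,
                         ramp_s = 0.015) {
  t_idx <- seq_len(n)
  f0_t <- seq(f0_start, f0_end, length.out = n)
  base_phase <- 2 * pi * cumsum(f0_t) / fs
  f0_mid <- (f0_start + f0_end) / 2
  nh <- max(1L, floor(min(8000, 0.45 * fs) / f0_mid))
  amps <- formant_envelope((1:nh) * f0_mid, formants_hz)
  if (is.null(phases)) phases <- rep(0, nh)
  x <- numeric(n)
  for (h in seq_len(nh)) x <- x + amps[h] * sin(h * base_phase + phases[h])
  nr <- min(n %/% 2, round(ramp_s * fs))
  if (nr > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    x[seq_len(nr)] <- x[seq_len(nr)] * ramp
    x[(n - nr + 1):n] <- x[(n - nr + 1):n] * rev(ramp)
  }
  x
}

#' Synthesize a steady synthetic vowel
#'
#' A deterministic harmonic complex at fixed `f0_hz` shaped by resonances at
#' `formants_hz`. Channels tuned between formants receive several comparable
#' harmonics whose beating creates strong rate fluctuations at F0, whereas
#' channels at a formant are dominated by a single strong harmonic — the
#' across-frequency contrast the decision metric exploits.
#'
#' @param duration_s duration in seconds.
#' @param f0_hz fundamental frequency, Hz.
#' @param formants_hz formant frequencies, Hz (each < `fs/2`).
#' @param fs sampling rate, Hz.
#' @param level_db_spl presentation level.
#' @return An [audio_signal()].
#' @export
make_vowel <- function(duration_s = 0.5, f0_hz = 119,
                       formants_hz = c(700, 2200, 3300), fs = 100000,
                       level_db_spl = 65) {
  if (f0_hz <= 0) stop("f0_hz must be positive")
  if (any(formants_hz <= 0 | formants_hz >= fs / 2))
    stop("formants must lie in (0, fs/2)")
  n <- round(duration_s * fs)
  x <- voiced_token(n, fs, f0_hz, f0_hz, formants_hz)
  set_level(audio_signal(x, fs, "vowel"), level_db_spl)
}

#' Synthesize a speech surrogate
#'
#' Concatenates several voiced harmonic-complex "syllables" with brief pauses,
#' per-syllable formant jitter, random harmonic phases, and a small linear F0
#' drift, emulating the F0-domain fluctuation structure of a male talker
#' without using recorded speech. Deterministic given the spec's seed.
#'
#' @param spec a [stimulus_spec()] (fields `duration_s`, `f0_hz`,
#'   `formants_hz`, `seed`, `fs` are used), or `NULL` to build one from the
#'   remaining arguments.
#' @param duration_s,f0_hz,formants_hz,seed,fs used when `spec` is `NULL`.
#' @param level_db_spl presentation level of the returned signal.
#' @return An [audio_signal()].
#' @export
make_speech_surrogate <- function(spec = NULL, duration_s = 2, f0_hz = 119,
                                  formants_hz = c(700, 2200, 3300),
                                  seed = 1L, fs = 100000, level_db_spl = 65) {
  if (is.null(spec))
    spec <- stimulus_spec("speech_surrogate", duration_s = duration_s,
                          f0_hz = f0_hz, formants_hz = formants_hz,
                          seed = seed, fs = fs)
  stopifnot(inherits(spec, "stimulus_spec"))
  if (spec$f0_hz <= 0) stop("f0_hz must be positive")
  if (any(spec$formants_hz <= 0 | spec$formants_hz >= spec$fs / 2))
    stop("formants must lie in (0, fs/2)")
  fs <- spec$fs
  n_total <- round(spec$duration_s * fs)
  x <- with_seed(spec$seed, {
    out <- numeric(n_total)
    pos <- 1L
    while (pos <= n_total) {
      syl_n <- round(runif(1, 0.18, 0.30) * fs)
      f0a <- spec$f0_hz * (1 + runif(1, -0.04, 0.04))
      f0b <- spec$f0_hz * (1 + runif(1, -0.04, 0.04))
      fmts <- spec$formants_hz * (1 + runif(length(spec$formants_hz), -0.08, 0.08))
      nh <- max(1L, floor(min(8000, 0.45 * fs) / ((f0a + f0b) / 2)))
      ph <- runif(nh, 0, 2 * pi)
      take <- min(syl_n, n_total - pos + 1L)
      tok <- voiced_token(syl_n, fs, f0a, f0b, fmts, phases = ph)
      out[pos:(pos + take - 1L)] <- tok[seq_len(take)]
      pos <- pos + syl_n + round(runif(1, 0.04, 0.10) * fs)
    }
    out
  })
  set_level(audio_signal(x, fs, "speech_surrogate"), level_db_spl)
}

#' Synthesize speech-shaped noise (SSN)
#'
#' Gaussian noise whose long-term spectrum matches the reference's (typically
#' the average of the target sentences) in every third-octave band, produced
#' by FFT-magnitude shaping with per-band power equalization. Deterministic
#' given `seed`; the output is calibrated to the reference's level.
#'
#' @param reference an [audio_signal()] with nonzero energy whose smoothed
#'   spectrum defines the noise coloration.
#' @param duration_s output duration in seconds (> 0).
#' @param seed integer seed.
#' @return An [audio_signal()].
#' @export
make_ssn <- function(reference, duration_s, seed = 1L) {
  stopifnot(inherits(reference, "audio_signal"))
  if (duration_s <= 0) stop("duration_s must be positive")
  if (all(reference$samples == 0)) stop("reference has zero energy")
  fs <- reference$fs
  n <- round(duration_s * fs)
  # third-octave band partition (base 50 Hz, edges at centre * 2^(+/-1/6));
  # the gain applied to each band of the noise equates its power with the
  # reference's, so the long-term band spectrum matches exactly
  centers <- 50 * 2^(seq(0, log2(fs / 2 / 50) - 1 / 6, by = 1 / 3))
  edges <- c(centers * 2^(-1 / 6), tail(centers, 1) * 2^(1 / 6))
  band_power <- function(x, fs_x) {
    nf <- length(x)
    pw <- Mod(fft(x))^2
    fr <- (0:(nf - 1)) * fs_x / nf
    vapply(seq_along(centers), function(b) {
      sel <- fr >= edges[b] & fr < edges[b + 1]
      sum(pw[sel]) / nf
    }, numeric(1))
  }
  p_ref <- band_power(reference$samples, fs)
  noise <- with_seed(seed, rnorm(n))
  X <- fft(noise)
  p_noise <- band_power(noise, fs)
  gain <- sqrt(p_ref / pmax(p_noise, .Machine$double.xmin))
  freqs <- (0:(n - 1)) * fs / n
  shape <- numeric(n)
  half <- freqs <= fs / 2
  bidx <- findInterval(freqs[half], edges)
  ok <- bidx >= 1 & bidx <= length(centers)
  shape[half][ok] <- gain[bidx[ok]]
  shape[1] <- 0  # no DC
  # Hermitian symmetry for a real output
  if (n %% 2 == 0) {
    shape[(n / 2 + 2):n] <- rev(shape[2:(n / 2)])
  } else {
    shape[((n + 1) / 2 + 1):n] <- rev(shape[2:((n + 1) / 2)])
  }
  y <- Re(fft(X * shape, inverse = TRUE) / n)
  set_level(audio_signal(y, fs, "ssn"), level_db_spl(reference))
}

#' Sinusoidally amplitude-modulate a signal
#'
#' Multiplies the waveform by `1 + mod_depth * sin(2 pi mod_rate_hz t)` and
#' re-calibrates to the level of the input, producing e.g. the 8-Hz SAM noise
#' masker from SSN.
#'
#' @param base an [audio_signal()].
#' @param mod_rate_hz modulation rate, Hz (< `fs/2`).
#' @param mod_depth modulation depth in \[0, 1\].
#' @return An [audio_signal()].
#' @export
make_sam <- function(base, mod_rate_hz = 8, mod_depth = 1) {
  stopifnot(inherits(base, "audio_signal"))
  if (mod_depth < 0 || mod_depth > 1) stop("mod_depth must lie in [0, 1]")
  if (mod_rate_hz >= base$fs / 2) stop("mod_rate_hz must be below fs/2")
  t <- (seq_along(base$samples) - 1) / base$fs
  y <- base$samples * (1 + mod_depth * sin(2 * pi * mod_rate_hz * t))
  set_level(audio_signal(y, base$fs, paste0(base$label, "+sam")),
            level_db_spl(base))
}

#' Synthesize a fluctuating multi-talker interferer
#'
#' Concatenates randomly drawn voiced and unvoiced surrogate syllables from
#' several synthetic "talkers" with F0s near `f0_hz` (default 207 Hz, a female
#' average) and differing formant sets, separated by silent gaps. The result
#' has strong temporal envelope fluctuation, emulating an
#' international-speech-test-signal-style masker. Deterministic given seed.
#'
#' @param spec a [stimulus_spec()] (kind `"ists_like"`) or `NULL`.
#' @param duration_s,f0_hz,seed,fs used when `spec` is `NULL`.
#' @param level_db_spl presentation level of the returned signal.
#' @return An [audio_signal()].
#' @export
make_ists_like <- function(spec = NULL, duration_s = 2, f0_hz = 207,
                           seed = 1L, fs = 100000, level_db_spl = 65) {
  if (is.null(spec))
    spec <- stimulus_spec("ists_like", duration_s = duration_s, f0_hz = f0_hz,
                          seed = seed, fs = fs)
  stopifnot(inherits(spec, "stimulus_spec"))
  fs <- spec$fs
  n_total <- round(spec$duration_s * fs)
  talker_f0 <- spec$f0_hz * c(0.92, 1.00, 1.09)
  talker_formants <- list(c(850, 2100, 3000), c(600, 1900, 3200),
                          c(750, 2400, 3500))
  x <- with_seed(spec$seed, {
    out <- numeric(n_total)
    pos <- 1L
    while (pos <= n_total) {
      tk <- sample.int(3L, 1L)
      syl_n <- round(runif(1, 0.12, 0.28) * fs)
      take <- min(syl_n, n_total - pos + 1L)
      if (runif(1) < 0.8) {
        f0 <- talker_f0[tk] * (1 + runif(1, -0.03, 0.03))
        nh <- max(1L, floor(min(8000, 0.45 * fs) / f0))
        tok <- voiced_token(syl_n, fs, f0, f0 * (1 + runif(1, -0.02, 0.02)),
                            talker_formants[[tk]], phases = runif(nh, 0, 2 * pi))
      } else {
        # unvoiced burst: formant-shaped noise at reduced amplitude
        ns <- rnorm(syl_n)
        tok <- 0.25 * spectral_shape(ns, fs, talker_formants[[tk]])
      }
      out[pos:(pos + take - 1L)] <- tok[seq_len(take)]
      gap <- if (runif(1) < 0.3) runif(1, 0.18, 0.35) else runif(1, 0.04, 0.12)
      pos <- pos + syl_n + round(gap * fs)
    }
    out
  })
  set_level(audio_signal(x, fs, "ists_like"), level_db_spl)
}

# Shape white noise by the formant envelope in the frequency domain.
spectral_shape <- function(x, fs, formants_hz) {
  n <- length(x)
  freqs <- (0:(n - 1)) * fs / n
  env <- formant_envelope(pmin(freqs, fs - freqs), formants_hz)
  y <- Re(fft(fft(x) * env, inverse = TRUE) / n)
  r <- sqrt(mean(y^2))
  xr <- sqrt(mean(x^2))
  if (r > 0) y * (xr / r) else y
}

#' Synthesize a stimulus from a spec
#'
#' Dispatches on `spec$kind`. SSN and SAM use a speech surrogate built from the
#' same spec's F0/formants as the spectral reference.
#'
#' @param spec a [stimulus_spec()].
#' @param level_db_spl presentation level.
#' @return An [audio_signal()].
#' @export
make_stimulus <- function(spec, level_db_spl = 65) {
  stopifnot(inherits(spec, "stimulus_spec"))
  switch(spec$kind,
    speech_surrogate = make_speech_surrogate(spec, level_db_spl = level_db_spl),
    ists_like = make_ists_like(spec, level_db_spl = level_db_spl),
    ssn = {
      ref <- make_speech_surrogate(stimulus_spec("speech_surrogate",
        duration_s = max(spec$duration_s, 2), f0_hz = spec$f0_hz,
        formants_hz = spec$formants_hz, seed = spec$seed + 1000L, fs = spec$fs),
        level_db_spl = level_db_spl)
      make_ssn(ref, spec$duration_s, seed = spec$seed)
    },
    sam = {
      ref <- make_speech_surrogate(stimulus_spec("speech_surrogate",
        duration_s = max(spec$duration_s, 2), f0_hz = spec$f0_hz,
        formants_hz = spec$formants_hz, seed = spec$seed + 1000L, fs = spec$fs),
        level_db_spl = level_db_spl)
      make_sam(make_ssn(ref, spec$duration_s, seed = spec$seed),
               spec$mod_rate_hz, spec$mod_depth)
    })
}
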