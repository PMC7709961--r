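#' Calibrated mono audio signal
#'
#' Container for a mono waveform with sound-pressure-level semantics. Samples
#' are dimensionless pressure units under the convention that a waveform with
#' RMS 1.0 corresponds to 94 dB SPL (1 Pa), so dB SPL arithmetic on digital
#' signals is exact.
#'
#' @param samples numeric vector of samples.
#' @param fs sampling rate in Hz (> 0).
#' @param label free-text label carried along for provenance.
#' @return An object of class `audio_signal` with fields `samples`, `fs`,
#'   `label`.
#' @examples
#' x <- audio_signal(sin(2 * pi * 1000 * seq(0, 0.1, by = 1 / 48000)), 48000)
#' level_db_spl(set_level(x, 65))
#' @export
audio_signal <- function(samples, fs, label = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("audio_signal needs at least one sample")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  structure(list(samples = samples, fs = as.numeric(fs), label = as.character(label)),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  lev <- if (any(x$samples != 0)) sprintf("%.1f dB SPL", level_db_spl(x)) else "silent"
  cat(sprintf("<audio_signal> %.3f s @ %g Hz, %s%s\n",
              length(x$samples) / x$fs, x$fs, lev,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' @export
length.audio_signal <- function(x) length(x$samples)

signal_rms <- function(x) sqrt(mean(x$samples^2))

#' Sound pressure level of a signal
#'
#' @param x an [audio_signal()].
#' @return Level in dB SPL under the RMS 1.0 = 94 dB SPL convention.
#' @export
level_db_spl <- function(x) {
  stopifnot(inherits(x, "audio_signal"))
  94 + 20 * log10(signal_rms(x))
}

#' Calibrate a signal to a target level
#'
#' Rescales the waveform by a positive scalar so its broadband RMS corresponds
#' to `level_db_spl` (RMS 1.0 = 94 dB SPL). The waveform shape is unchanged.
#'
#' @param x an [audio_signal()] with nonzero RMS.
#' @param level_db_spl target level in dB SPL.
#' @return A calibrated `audio_signal`.
#' @export
set_level <- function(x, level_db_spl) {
  stopifnot(inherits(x, "audio_signal"))
  r <- signal_rms(x)
  if (r == 0) stop("cannot calibrate silent signal")
  target_rms <- 10^((level_db_spl - 94) / 20)
  audio_signal(x$samples * (target_rms / r), x$fs, x$label)
}

#' Mix speech and interferer at a given SNR
#'
#' Calibrates the speech to `speech_level_db_spl`, scales an excerpt of the
#' interferer so the broadband RMS signal-to-noise ratio equals `snr_db`, and
#' forms the noisy speech `sn = speech + interferer`. The noise-alone reference
#' `n` is the *same* interferer excerpt rescaled so that `RMS(n) = RMS(sn)`,
#' i.e. the reference has the same level as the noisy speech.
#'
#' @param speech target [audio_signal()].
#' @param interferer interferer [audio_signal()], at least as long as the
#'   speech; a deterministic excerpt is cut to the speech length.
#' @param snr_db signal-to-noise ratio in dB (broadband RMS).
#' @param speech_level_db_spl speech presentation level in dB SPL.
#' @param start first sample of the interferer excerpt (default 1).
#' @param seed optional seed used to draw the excerpt start; overrides
#'   `start`. The same excerpt is used in `sn` and `n`.
#' @return A list with elements `sn` and `n` (both `audio_signal`).
#' @export
mix_at_snr <- function(speech, interferer, snr_db, speech_level_db_spl = 65,
                       start = 1L, seed = NULL) {
  stopifnot(inherits(speech, "audio_signal"), inherits(interferer, "audio_signal"))
  if (speech$fs != interferer$fs)
    stop("speech and interferer sampling rates differ")
  ns <- length(speech$samples)
  ni <- length(interferer$samples)
  if (ni < ns) stop("interferer shorter than speech")
  if (!is.null(seed)) {
    start <- with_seed(seed, sample.int(ni - ns + 1L, 1L))
  }
  start <- as.integer(start)
  if (start < 1L || start + ns - 1L > ni) stop("excerpt out of range")
  sp <- set_level(speech, speech_level_db_spl)
  exc <- interferer$samples[start:(start + ns - 1L)]
  r_exc <- sqrt(mean(exc^2))
  if (r_exc == 0) stop("interferer excerpt is silent")
  r_sp <- signal_rms(sp)
  noise <- exc * (r_sp / r_exc) * 10^(-snr_db / 20)
  sn <- audio_signal(sp$samples + noise, speech$fs,
                     label = sprintf("sn@%gdB", snr_db))
  rms_sn <- sqrt(mean(sn$samples^2))
  rms_noise <- sqrt(mean(noise^2))
  n <- audio_signal(noise * (rms_sn / rms_noise), speech$fs,
                    label = sprintf("n@%gdB", snr_db))
  list(sn = sn, n = n)
}
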