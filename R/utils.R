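# Internal helpers shared across modules.

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so seeded generators are pure functions of their arguments.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# FNV-1a over the serialized value; stable across sessions for plain lists of
# doubles/strings. Used for the frozen-calibration hash.
fnv1a_hash <- function(x) {
  bytes <- serialize(x, connection = NULL, version = 2L)
  # skip the serialization header (R version stamps would break stability)
  bytes <- bytes[-seq_len(14L)]
  h <- 2166136261
  for (b in as.integer(bytes)) {
    # xor affects only the low byte (b < 256); keep h as a double mod 2^32
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit FNV prime multiply in double arithmetic, split into 16-bit
    # halves so the low 32 bits stay exact
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

# Analytic envelope magnitude via FFT-based Hilbert transform.
hilbert_envelope <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

#' One-third-octave band levels of a waveform
#'
#' Long-term spectrum summarized in third-octave bands: band centres are
#' geometrically spaced and each band averages the periodogram power within
#' `[fc * 2^(-1/6), fc * 2^(1/6))`.
#'
#' @param samples numeric waveform.
#' @param fs sampling rate, Hz.
#' @param f_lo,f_hi lowest / highest band centre, Hz.
#' @return data.frame with `freq_hz`, `level_db`.
#' @export
third_octave_levels <- function(samples, fs, f_lo = 50, f_hi = fs / 2 * 0.9) {
  n <- length(samples)
  pw <- Mod(fft(samples))^2 / n
  freqs <- (seq_len(n) - 1) * fs / n
  keep <- freqs > 0 & freqs <= fs / 2
  pw <- pw[keep]
  freqs <- freqs[keep]
  centers <- f_lo * 2^(seq(0, log2(f_hi / f_lo), by = 1 / 3))
  lev <- vapply(centers, function(fc) {
    sel <- freqs >= fc * 2^(-1 / 6) & freqs < fc * 2^(1 / 6)
    if (!any(sel)) return(NA_real_)
    10 * log10(mean(pw[sel]) + .Machine$double.xmin)
  }, numeric(1))
  data.frame(freq_hz = centers, level_db = lev)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
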