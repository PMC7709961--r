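#' Characteristic-frequency grid
#'
#' Geometric (log-spaced) grid of characteristic frequencies, by default 13
#' CFs between 0.5 and 8 kHz, giving a ratio of 2^(1/3) between neighbours.
#'
#' @param n number of CFs (>= 2).
#' @param lo_hz,hi_hz grid endpoints in Hz (0 < lo < hi).
#' @return Numeric vector of CFs in Hz, first `lo_hz`, last `hi_hz`.
#' @export
default_cf_grid <- function(n = 13, lo_hz = 500, hi_hz = 8000) {
  if (n < 2) stop("n must be at least 2")
  if (lo_hz <= 0 || hi_hz <= lo_hz) stop("need 0 < lo_hz < hi_hz")
  exp(seq(log(lo_hz), log(hi_hz), length.out = n))
}

#' Auditory-nerve fiber population
#'
#' Population proportions and rate constants for the three spontaneous-rate
#' fiber classes (high, medium, low; HSR/MSR/LSR). The population rate is the
#' weighted mean of the three deterministic class rates — the large-n limit of
#' averaging many stochastic fibers per CF.
#'
#' @param weights HSR/MSR/LSR proportions, summing to 1 (default 0.6/0.2/0.2).
#' @param spont_rates_sps per-class spontaneous rates, spikes/s.
#' @param sat_rates_sps per-class saturation rates, spikes/s.
#' @param thresholds_db_spl per-class rate thresholds at CF, dB SPL re the
#'   normal-hearing HSR threshold (must be increasing HSR < MSR < LSR).
#' @return A list of class `fiber_population`.
#' @export
fiber_population <- function(weights = c(0.6, 0.2, 0.2),
                             spont_rates_sps = c(60, 5, 0.5),
                             sat_rates_sps = c(250, 200, 150),
                             thresholds_db_spl = c(0, 12, 25)) {
  if (abs(sum(weights) - 1) > 1e-9) stop("fiber weights must sum to 1")
  if (is.unsorted(thresholds_db_spl, strictly = TRUE))
    stop("class thresholds must increase HSR < MSR < LSR")
  structure(list(weights = weights, spont_rates_sps = spont_rates_sps,
                 sat_rates_sps = sat_rates_sps,
                 thresholds_db_spl = thresholds_db_spl),
            class = "fiber_population")
}

#' Periphery configuration
#'
#' Constants of the phenomenological auditory periphery: a middle-ear
#' band-pass, a dual-path cochlear stage per CF (a compressive, narrowly tuned
#' path whose gain is scaled by the outer-hair-cell factor `c_ohc`, plus a
#' broader linear path), saturating half-wave inner-hair-cell transduction
#' scaled by `c_ihc` with a ~3 kHz low-pass, a linear adaptation stage with
#' onset emphasis, and the fiber-class rate mapping.
#'
#' @param fs internal sampling rate, Hz. All periphery inputs must be at this
#'   rate (resample upstream).
#' @param me_lo_hz,me_hi_hz middle-ear band edges, Hz.
#' @param gain_nl small-signal gain of the compressive path (sets the maximum
#'   cochlear-gain loss, about `20*log10(gain_nl/gain_lin)` dB).
#' @param gain_lin gain of the broad linear path.
#' @param knee input amplitude where the compressive path's broken-stick
#'   nonlinearity bends (linear below, exponent `comp_exp` above).
#' @param comp_exp compression exponent above the knee.
#' @param bw_nl_erb,bw_lin_erb filter bandwidths as multiples of the ERB at CF
#'   (the linear path is broader, so tuning broadens as `c_ohc` falls).
#' @param sat_theta scale of the logarithmic compression in the IHC
#'   rectifier (`v = sat_theta * log1p(r / sat_theta)`; unit slope near zero).
#'   The default keeps transduction nearly linear over the operating range so
#'   that rate saturation happens in the fiber rate mapping, preserving deep
#'   F0-beating nulls as a temporal cue at high levels.
#' @param n_fibers fibers simulated per CF; sets the expected
#'   population-sampling fluctuation floor used by [fluctuation_profile()].
#' @param ihc_lp_hz pole frequency of the IHC membrane low-pass, Hz.
#' @param ihc_lp_order number of cascaded one-pole sections in the IHC
#'   membrane filter (7 is the customary value; the cascade removes
#'   phase-locked fine structure above ~3 kHz while passing F0-range
#'   envelope fluctuations).
#' @param adapt_tau_s adaptation time constant, s.
#' @param sustained sustained fraction after adaptation (onset gain is 1).
#' @param drive_ref drive scale giving the HSR class threshold; MSR/LSR scale
#'   by their dB offsets.
#' @param sync_exp exponent of the extra synchrony degradation with IHC
#'   loss: the fluctuating (AC) part of the receptor drive is scaled by
#'   `c_ihc^(1 + sync_exp)` while the sustained (DC) part scales with
#'   `c_ihc`, reflecting the loss of transduction fidelity for rapid
#'   fluctuations in damaged inner hair cells.
#' @param rate_exp steepness of the fiber rate-level function
#'   (`1 - exp(-(D/theta)^rate_exp)`); values near 2 give the narrow
#'   physiological dynamic range, so well-driven fibers rail at saturation
#'   and only deep envelope dips release them.
#' @return A list of class `periphery_config`.
#' @export
periphery_config <- function(fs = 100000, me_lo_hz = 350, me_hi_hz = 12000,
                             gain_nl = 800, gain_lin = 1, knee = 5e-3,
                             comp_exp = 0.3, bw_nl_erb = 1.019, bw_lin_erb = 2.2,
                             sat_theta = 20, ihc_lp_hz = 3000, ihc_lp_order = 7,
                             adapt_tau_s = 0.06,
                             sustained = 0.15, drive_ref = 0.05, rate_exp = 2,
                             sync_exp = 0.5, n_fibers = 50) {
  structure(as.list(environment()), class = "periphery_config")
}

erb_hz <- function(cf_hz) 24.7 * (4.37 * cf_hz / 1000 + 1)

middle_ear_coefs <- function(config) {
  key <- sprintf("me_%g_%g_%g", config$fs, config$me_lo_hz, config$me_hi_hz)
  if (is.null(.flucsi_env[[key]])) {
    .flucsi_env[[key]] <- signal::butter(
      1, c(config$me_lo_hz, config$me_hi_hz) / (config$fs / 2), type = "pass")
  }
  .flucsi_env[[key]]
}

middle_ear_gain <- function(cf_hz, config) {
  co <- middle_ear_coefs(config)
  z <- exp(-1i * 2 * pi * cf_hz / config$fs)
  H <- sum(co$b * z^(seq_along(co$b) - 1)) / sum(co$a * z^(seq_along(co$a) - 1))
  Mod(H)
}

# Broken-stick input/output function of the compressive path, applied to the
# local envelope: linear with slope gain_nl below the knee, exponent comp_exp
# above it; continuous at the knee.
broken_stick <- function(env, config) {
  a <- config$gain_nl
  b <- a * config$knee^(1 - config$comp_exp)
  pmin(a * env, b * env^config$comp_exp)
}

# Full per-channel chain up to the synapse drive (before the rate mapping),
# streamed in C++. The compressive path's gain follows the analytic envelope
# of the narrow filter output (cycle-by-cycle gain, not instantaneous
# waveform distortion).
channel_drive <- function(x_me, cf, c_ohc, c_ihc, config) {
  bw <- erb_hz(cf)
  channel_drive_c(x_me, cf, config$fs, config$bw_nl_erb * bw,
                  config$bw_lin_erb * bw, c_ohc, c_ihc, config$gain_nl,
                  config$gain_lin, config$knee, config$comp_exp,
                  config$sat_theta, exp(-2 * pi * config$ihc_lp_hz / config$fs),
                  as.integer(config$ihc_lp_order %||% 7),
                  exp(-1 / (config$adapt_tau_s * config$fs)),
                  config$sustained, c_ihc^(config$sync_exp %||% 0))
}

drive_to_rates <- function(drive, fibers, config) {
  theta <- config$drive_ref * 10^(fibers$thresholds_db_spl / 20)
  rates_from_drive_c(drive, fibers$weights, fibers$spont_rates_sps,
                     fibers$sat_rates_sps, theta, config$rate_exp %||% 1)
}

#' Population firing-rate response (neurogram)
#'
#' Runs a calibrated waveform through the phenomenological periphery at each
#' CF and returns the population-averaged instantaneous firing rate (time x
#' CF). Outer-hair-cell loss (`c_ohc` < 1) reduces the compressive path's gain
#' and leaves the broader linear path, raising thresholds, linearizing growth
#' and broadening tuning; inner-hair-cell loss (`c_ihc` < 1) attenuates the
#' transduction drive. The computation is fully deterministic.
#'
#' @param signal an [audio_signal()] calibrated in dB SPL, sampled at
#'   `config$fs`.
#' @param cf_hz CF grid in Hz (all below `fs/2`), default [default_cf_grid()].
#' @param loss a loss profile from [audiogram_to_loss()] or [loss_profile()],
#'   or `NULL` for normal hearing.
#' @param fibers a [fiber_population()].
#' @param config a [periphery_config()].
#' @return An object of class `neurogram`: list with `rates_sps` (matrix,
#'   time sample x CF, spikes/s), `fs`, `cf_hz`.
#' @export
an_rate_response <- function(signal, cf_hz = default_cf_grid(), loss = NULL,
                             fibers = fiber_population(),
                             config = periphery_config()) {
  stopifnot(inherits(signal, "audio_signal"))
  if (anyNA(signal$samples) || any(!is.finite(signal$samples)))
    stop("input contains NaN or non-finite samples")
  if (signal$fs != config$fs)
    stop("signal sampling rate (", signal$fs, ") must equal the pipeline rate (",
         config$fs, "); resample upstream")
  if (any(cf_hz >= config$fs / 2)) stop("CF at or above fs/2")
  c_ohc <- rep(1, length(cf_hz))
  c_ihc <- rep(1, length(cf_hz))
  if (!is.null(loss)) {
    stopifnot(inherits(loss, "loss_profile"))
    idx <- vapply(cf_hz, function(f) which.min(abs(log(loss$cf_hz) - log(f))),
                  integer(1))
    c_ohc <- loss$c_ohc[idx]
    c_ihc <- loss$c_ihc[idx]
  }
  co <- middle_ear_coefs(config)
  x_me <- as.numeric(signal::filter(co, signal$samples))
  rates <- matrix(0, nrow = length(x_me), ncol = length(cf_hz))
  for (i in seq_along(cf_hz)) {
    d <- channel_drive(x_me, cf_hz[i], c_ohc[i], c_ihc[i], config)
    rates[, i] <- drive_to_rates(d, fibers, config)
  }
  structure(list(rates_sps = rates, fs = config$fs, cf_hz = cf_hz),
            class = "neurogram")
}

#' @export
print.neurogram <- function(x, ...) {
  cat(sprintf("<neurogram> %d samples @ %g Hz x %d CFs (%.0f-%.0f Hz), mean %.1f sp/s\n",
              nrow(x$rates_sps), x$fs, length(x$cf_hz), min(x$cf_hz),
              max(x$cf_hz), mean(x$rates_sps)))
  invisible(x)
}

#' Simulated pure-tone threshold
#'
#' Lowest level on a 1-dB grid at which a 50-ms CF tone raises the mean
#' population rate above spontaneous by a criterion fraction of the
#' spontaneous-to-saturation range. Serves as the calibration oracle relating
#' audiogram-derived loss factors to simulated threshold shifts.
#'
#' @param cf CF in Hz.
#' @param loss optional loss profile (as in [an_rate_response()]).
#' @param fibers a [fiber_population()].
#' @param config a [periphery_config()].
#' @param criterion rate criterion as a fraction of the weighted
#'   spontaneous-to-saturation range (default 0.1).
#' @param duration_s tone duration, s.
#' @return Threshold in dB SPL (integer grid). If no crossing occurs below
#'   120 dB SPL, returns 120 with attribute `crossed = FALSE`.
#' @export
pure_tone_threshold <- function(cf, loss = NULL, fibers = fiber_population(),
                                config = periphery_config(), criterion = 0.1,
                                duration_s = 0.05) {
  spont_w <- sum(fibers$weights * fibers$spont_rates_sps)
  range_w <- sum(fibers$weights * (fibers$sat_rates_sps - fibers$spont_rates_sps))
  crit_rate <- spont_w + criterion * range_w
  n <- round(duration_s * config$fs)
  t <- (seq_len(n) - 1) / config$fs
  tone <- sin(2 * pi * cf * t)
  nr <- round(0.005 * config$fs)
  ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
  tone[seq_len(nr)] <- tone[seq_len(nr)] * ramp
  tone[(n - nr + 1):n] <- tone[(n - nr + 1):n] * rev(ramp)
  steady <- seq(round(0.015 * config$fs), n - nr)
  mean_rate_at <- function(level) {
    sig <- set_level(audio_signal(tone, config$fs), level)
    ng <- an_rate_response(sig, cf_hz = cf, loss = loss, fibers = fibers,
                           config = config)
    mean(ng$rates_sps[steady, 1])
  }
  lo <- -30L; hi <- 120L
  if (mean_rate_at(hi) < crit_rate)
    return(structure(120, crossed = FALSE))
  if (mean_rate_at(lo) >= crit_rate)
    return(structure(as.numeric(lo), crossed = TRUE))
  while (hi - lo > 1L) {  # rate grows monotonically with level
    mid <- (lo + hi) %/% 2L
    if (mean_rate_at(mid) >= crit_rate) hi <- mid else lo <- mid
  }
  structure(as.numeric(hi), crossed = TRUE)
}
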