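#' Modulation band-pass filter specification
#'
#' A single second-order constant-Q band-pass representing the modulation
#' tuning of midbrain neurons, centred near the target talker's fundamental
#' frequency. The -3 dB bandwidth is `fc_hz / q`, with geometric symmetry
#' about `fc_hz` (f1 * f2 = fc^2).
#'
#' @param fc_hz centre frequency, Hz (default 125, near a male F0).
#' @param q quality factor (default 1).
#' @return A list of class `modulation_filter_spec`.
#' @export
modulation_filter_spec <- function(fc_hz = 125, q = 1) {
  if (fc_hz <= 0 || q <= 0) stop("fc_hz and q must be positive")
  structure(list(fc_hz = fc_hz, q = q), class = "modulation_filter_spec")
}

# Bilinear-transformed constant-Q band-pass biquad with unity peak gain at fc.
modulation_biquad <- function(spec, fs) {
  w0 <- 2 * pi * spec$fc_hz / fs
  alpha <- sin(w0) / (2 * spec$q)
  b <- c(alpha, 0, -alpha)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Apply the modulation filter to a neurogram
#'
#' Filters each CF column causally with the same second-order constant-Q
#' band-pass: unity magnitude at `fc_hz`, zero gain at DC (the mean rate is
#' removed), enhancing rate fluctuations in the F0 range.
#'
#' @param rates a `neurogram` from [an_rate_response()].
#' @param spec a [modulation_filter_spec()].
#' @return A `neurogram` of band-passed rates (same dimensions).
#' @export
modulation_filter <- function(rates, spec = modulation_filter_spec()) {
  stopifnot(inherits(rates, "neurogram"))
  if (spec$fc_hz >= rates$fs / 2) stop("fc_hz at or above fs/2")
  co <- modulation_biquad(spec, rates$fs)
  out <- biquad_filter_c(rates$rates_sps, co$b, co$a)
  structure(list(rates_sps = out, fs = rates$fs, cf_hz = rates$cf_hz),
            class = "neurogram")
}

#' Framing specification
#'
#' @param win_s frame length, s (default 0.020).
#' @param step_s hop, s (default 0.010, i.e. 50% overlap).
#' @return A list of class `frame_spec`.
#' @export
frame_spec <- function(win_s = 0.020, step_s = 0.010) {
  if (step_s <= 0 || step_s > win_s) stop("need 0 < step_s <= win_s")
  structure(list(win_s = win_s, step_s = step_s), class = "frame_spec")
}

#' Framed fluctuation power
#'
#' Segments each CF column into frames (left-aligned from t = 0, trailing
#' partial frame dropped) and, within each frame, squares the values and
#' averages across temporal samples, yielding the fluctuation-power profile
#' `values[k, cf]` in (spikes/s)^2. Frame count is
#' `floor((T - win) / step) + 1`.
#'
#' @param filtered a `neurogram` (typically from [modulation_filter()]).
#' @param frames a [frame_spec()].
#' @return An object of class `fluctuation_profile`: `values` (segment x CF),
#'   `frame_times_s` (segment centres), `cf_hz`.
#' @export
frame_power <- function(filtered, frames = frame_spec()) {
  stopifnot(inherits(filtered, "neurogram"), inherits(frames, "frame_spec"))
  n <- nrow(filtered$rates_sps)
  win <- round(frames$win_s * filtered$fs)
  step <- round(frames$step_s * filtered$fs)
  if (n < win) stop("signal shorter than one analysis window")
  k <- floor((n - win) / step) + 1L
  sq <- filtered$rates_sps^2
  cs <- rbind(0, apply(sq, 2, cumsum))
  starts <- (seq_len(k) - 1L) * step + 1L
  vals <- (cs[starts + win, , drop = FALSE] - cs[starts, , drop = FALSE]) / win
  structure(list(values = vals,
                 frame_times_s = (starts - 1 + win / 2) / filtered$fs,
                 cf_hz = filtered$cf_hz),
            class = "fluctuation_profile")
}

#' @export
print.fluctuation_profile <- function(x, ...) {
  cat(sprintf("<fluctuation_profile> %d segments x %d CFs\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

# Equivalent noise bandwidth (Hz) of the modulation band-pass: the bandwidth
# of an ideal rectangular filter passing the same white-noise power at unity
# gain. Computed from the digital filter's magnitude response.
modulation_filter_enb <- function(spec, fs) {
  key <- sprintf("enb_%g_%g_%g", spec$fc_hz, spec$q, fs)
  if (is.null(.flucsi_env[[key]])) {
    co <- modulation_biquad(spec, fs)
    f <- seq(0, fs / 2, length.out = 2^14)
    z <- exp(-1i * 2 * pi * f / fs)
    H <- (co$b[1] + co$b[2] * z + co$b[3] * z^2) /
      (co$a[1] + co$a[2] * z + co$a[3] * z^2)
    .flucsi_env[[key]] <- sum(Mod(H)^2) * (f[2] - f[1])
  }
  .flucsi_env[[key]]
}

# Frame means of the raw (unfiltered) rates on the frame_power grid.
frame_mean_rate <- function(ng, frames) {
  n <- nrow(ng$rates_sps)
  win <- round(frames$win_s * ng$fs)
  step <- round(frames$step_s * ng$fs)
  k <- floor((n - win) / step) + 1L
  cs <- rbind(0, apply(ng$rates_sps, 2, cumsum))
  starts <- (seq_len(k) - 1L) * step + 1L
  (cs[starts + win, , drop = FALSE] - cs[starts, , drop = FALSE]) / win
}

#' Fluctuation profile of a calibrated signal
#'
#' Convenience wrapper running periphery, modulation filter and framing in
#' one call, optionally discarding initial frames to skip the filter
#' transient.
#'
#' The profile includes the expected population-sampling fluctuation floor:
#' averaging `n_fibers` (default 50) stochastic fibers per CF leaves residual
#' rate noise whose power spectral density is approximately the local mean
#' rate divided by the fiber count, so each frame value is augmented by
#' `mean_rate * ENB / n_fibers`, with ENB the modulation filter's equivalent
#' noise bandwidth. Channels with weak stimulus-driven fluctuations are thus
#' dominated by this rate-dependent floor — the audibility limit of the
#' across-CF pattern. Set `config$n_fibers = Inf` for the bare deterministic
#' profile.
#'
#' @param signal an [audio_signal()] at the pipeline rate.
#' @param cf_hz CF grid.
#' @param loss optional loss profile.
#' @param fibers fiber population.
#' @param config periphery configuration.
#' @param mod_spec modulation filter spec.
#' @param frames frame spec.
#' @param discard_s initial interval excluded from the profile (default
#'   0.05 s, covering the filter onset transient).
#' @return A `fluctuation_profile`.
#' @export
fluctuation_profile <- function(signal, cf_hz = default_cf_grid(), loss = NULL,
                                fibers = fiber_population(),
                                config = periphery_config(),
                                mod_spec = modulation_filter_spec(),
                                frames = frame_spec(), discard_s = 0.05) {
  ng <- an_rate_response(signal, cf_hz, loss, fibers, config)
  filt <- modulation_filter(ng, mod_spec)
  prof <- frame_power(filt, frames)
  n_fibers <- config$n_fibers %||% Inf
  if (is.finite(n_fibers)) {
    enb <- modulation_filter_enb(mod_spec, config$fs)
    prof$values <- prof$values + frame_mean_rate(ng, frames) * enb / n_fibers
  }
  if (discard_s > 0) {
    keep <- prof$frame_times_s >= discard_s
    prof$values <- prof$values[keep, , drop = FALSE]
    prof$frame_times_s <- prof$frame_times_s[keep]
  }
  prof
}
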