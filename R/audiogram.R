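#' Pure-tone audiogram
#'
#' @param freqs_hz strictly increasing audiometric frequencies, Hz.
#' @param thresholds_db_hl matching hearing levels in dB HL (-10 to 120).
#' @param ear `"left"` or `"right"`.
#' @return A list of class `audiogram`.
#' @export
audiogram <- function(freqs_hz, thresholds_db_hl, ear = c("left", "right")) {
  ear <- match.arg(ear)
  if (length(freqs_hz) != length(thresholds_db_hl))
    stop("freqs and thresholds must have equal length")
  if (is.unsorted(freqs_hz, strictly = TRUE))
    stop("audiogram frequencies must be strictly increasing")
  if (any(thresholds_db_hl < -10 | thresholds_db_hl > 120))
    stop("thresholds must lie in [-10, 120] dB HL")
  structure(list(freqs_hz = as.numeric(freqs_hz),
                 thresholds_db_hl = as.numeric(thresholds_db_hl), ear = ear),
            class = "audiogram")
}

#' Read audiograms from CSV
#'
#' Expects columns `ear`, `freq_hz`, `threshold_db_hl` (one row per point).
#'
#' @param path CSV path.
#' @return Named list of [audiogram()] objects (one per ear present).
#' @export
read_audiogram_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("ear", "freq_hz", "threshold_db_hl")
  if (!all(need %in% names(df)))
    stop("audiogram CSV must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$ear), function(d) {
    d <- d[order(d$freq_hz), ]
    audiogram(d$freq_hz, d$threshold_db_hl, ear = d$ear[1])
  })
  out
}

#' Per-CF hair-cell loss profile
#'
#' Holds the dB of total loss attributed to outer (OHC) and inner (IHC) hair
#' cells at each CF together with the model factors `c_ohc`, `c_ihc` in
#' \[0, 1\] (1 = intact). Usually built by [audiogram_to_loss()].
#'
#' @param cf_hz CF grid, Hz.
#' @param ohc_loss_db,ihc_loss_db per-CF loss in dB.
#' @param c_ohc,c_ihc per-CF factors in \[0, 1\].
#' @return A list of class `loss_profile`.
#' @export
loss_profile <- function(cf_hz, ohc_loss_db, ihc_loss_db, c_ohc, c_ihc) {
  stopifnot(length(cf_hz) == length(ohc_loss_db),
            length(cf_hz) == length(ihc_loss_db),
            length(cf_hz) == length(c_ohc), length(cf_hz) == length(c_ihc))
  if (any(c_ohc < 0 | c_ohc > 1 | c_ihc < 0 | c_ihc > 1))
    stop("c_ohc and c_ihc must lie in [0, 1]")
  structure(list(cf_hz = cf_hz, ohc_loss_db = ohc_loss_db,
                 ihc_loss_db = ihc_loss_db, c_ohc = c_ohc, c_ihc = c_ihc),
            class = "loss_profile")
}

#' Normal-hearing loss profile
#' @param cf_hz CF grid.
#' @return A [loss_profile()] with zero loss everywhere.
#' @export
nh_profile <- function(cf_hz = default_cf_grid()) {
  z <- rep(0, length(cf_hz))
  loss_profile(cf_hz, z, z, z + 1, z + 1)
}

# Cached NH thresholds per (cf, fibers, config) — the operating points the
# closed-form c_ohc inversion is anchored to.
nh_threshold_cached <- function(cf, fibers, config) {
  key <- paste0("nhthr_", fnv1a_hash(list(cf, unclass(fibers), unclass(config))))
  if (is.null(.flucsi_env[[key]]))
    .flucsi_env[[key]] <- as.numeric(pure_tone_threshold(cf, NULL, fibers, config))
  .flucsi_env[[key]]
}

#' Derive OHC/IHC loss factors from an audiogram
#'
#' Interpolates the audiogram linearly in log-frequency onto the CF grid,
#' splits the total loss into OHC and IHC parts (`ohc_fraction`, default two
#' thirds OHC), and converts the dB targets into the model factors `c_ohc`,
#' `c_ihc`. The IHC factor is the exact drive attenuation
#' `c_ihc = 10^(-ihc_loss_db/20)`. The OHC factor is obtained by inverting the
#' dual-path cochlear gain at the normal-hearing threshold operating point, so
#' that the simulated pure-tone threshold shift reproduces the target total
#' loss (verifiable with [pure_tone_threshold()]). OHC loss demands beyond the
#' available cochlear gain are clipped at `c_ohc = 0` with a warning.
#'
#' @param ag an [audiogram()].
#' @param cf_hz CF grid, Hz.
#' @param ohc_fraction fraction of the total loss attributed to OHCs.
#' @param fibers a [fiber_population()].
#' @param config a [periphery_config()].
#' @param refine correct the closed-form `c_ohc` against the simulated
#'   threshold shift (up to two extra [pure_tone_threshold()] evaluations per
#'   CF); recommended for losses above ~50 dB HL.
#' @return A [loss_profile()].
#' @export
audiogram_to_loss <- function(ag, cf_hz = default_cf_grid(), ohc_fraction = 2 / 3,
                              fibers = fiber_population(),
                              config = periphery_config(), refine = TRUE) {
  stopifnot(inherits(ag, "audiogram"))
  if (min(cf_hz) < min(ag$freqs_hz) || max(cf_hz) > max(ag$freqs_hz))
    warning("CF grid extends beyond audiogram; extrapolating nearest edge value")
  total <- approx(log(ag$freqs_hz), ag$thresholds_db_hl, xout = log(cf_hz),
                  rule = 2)$y
  total <- pmax(total, 0)
  ohc_db <- ohc_fraction * total
  ihc_db <- total - ohc_db
  c_ihc <- 10^(-ihc_db / 20)
  a <- config$gain_nl
  g <- config$gain_lin
  b <- a * config$knee^(1 - config$comp_exp)
  c_ohc <- numeric(length(cf_hz))
  clipped <- FALSE
  for (i in seq_along(cf_hz)) {
    if (total[i] <= 0) { c_ohc[i] <- 1; next }
    thr_nh <- nh_threshold_cached(cf_hz[i], fibers, config)
    u0 <- middle_ear_gain(cf_hz[i], config) * sqrt(2) * 10^((thr_nh - 94) / 20)
    S <- (a + g) * u0  # NH basilar-membrane drive at threshold
    solve_c <- function(target_db) {
      u1 <- u0 * 10^(target_db / 20)  # target impaired threshold amplitude
      nl_u1 <- min(a * u1, b * u1^config$comp_exp)
      (S / c_ihc[i] - g * u1) / nl_u1
    }
    ci <- min(max(solve_c(total[i]), 0), 1)
    if (refine) {
      # bisect c_ohc against the simulated threshold shift: the shift is
      # monotone decreasing in c_ohc, and the closed form only approximates
      # the interplay of compression, rectified synchrony and the rate map
      shift_at <- function(co) {
        prof1 <- loss_profile(cf_hz[i], ohc_db[i], ihc_db[i], co, c_ihc[i])
        as.numeric(pure_tone_threshold(cf_hz[i], prof1, fibers, config)) - thr_nh
      }
      if (shift_at(1) >= total[i]) {
        ci <- 1  # inner-hair-cell component alone meets or exceeds the target
      } else if (shift_at(0) <= total[i]) {
        ci <- 0
        clipped <- TRUE
      } else {
        lo <- 0; hi <- 1
        for (iter in 1:12) {
          mid <- (lo + hi) / 2
          if (shift_at(mid) > total[i]) lo <- mid else hi <- mid
          if (hi - lo < 0.002) break
        }
        ci <- (lo + hi) / 2
      }
    }
    c_ohc[i] <- ci
  }
  if (clipped)
    warning("requested OHC loss exceeds available cochlear gain at some CFs; ",
            "c_ohc clipped at 0")
  loss_profile(cf_hz, ohc_db, ihc_db, c_ohc, c_ihc)
}

#' @export
print.loss_profile <- function(x, ...) {
  cat("<loss_profile>\n")
  print(as.data.frame(x), digits = 3)
  invisible(x)
}

#' @export
as.data.frame.loss_profile <- function(x, ...) {
  data.frame(cf_hz = x$cf_hz, ohc_loss_db = x$ohc_loss_db,
             ihc_loss_db = x$ihc_loss_db, c_ohc = x$c_ohc, c_ihc = x$c_ihc)
}
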