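#' Prediction run configuration
#'
#' Bundles everything a prediction run needs: listening mode, speech level,
#' SNR grid, number of sentence surrogates, interferer class, stimulus and
#' model parameters, and the master seed. Defaults follow the study
#' conditions: 13 CFs from 0.5-8 kHz, SNRs from -21 to +12 dB in 3-dB steps,
#' ten sentences, 65 dB SPL speech for normal hearing and 80 dB SPL for
#' impaired hearing.
#'
#' @param mode `"NH"` (normal hearing) or `"HI"` (hearing impaired).
#' @param speech_level_db_spl presentation level; default 65 (NH) / 80 (HI).
#' @param snr_grid_db strictly increasing SNR grid, dB.
#' @param n_sentences number of seeded sentence surrogates averaged per SNR.
#' @param interferer `"ssn"`, `"sam"`, or `"ists_like"`.
#' @param sentence_duration_s duration of each sentence surrogate, s.
#' @param f0_hz,formants_hz target-talker fundamental and formants, Hz.
#' @param cf_hz CF grid.
#' @param fibers a [fiber_population()].
#' @param periphery a [periphery_config()].
#' @param mod_spec a [modulation_filter_spec()].
#' @param frames a [frame_spec()].
#' @param discard_s initial interval excluded from profiles, s.
#' @param seed master seed; all stimulus randomness derives from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("NH", "HI"), speech_level_db_spl = NULL,
                       snr_grid_db = seq(-21, 12, by = 3), n_sentences = 10,
                       interferer = c("ssn", "sam", "ists_like"),
                       sentence_duration_s = 2, f0_hz = 119,
                       formants_hz = c(700, 2200, 3300),
                       cf_hz = default_cf_grid(), fibers = fiber_population(),
                       periphery = periphery_config(),
                       mod_spec = modulation_filter_spec(),
                       frames = frame_spec(), discard_s = 0.05, seed = 1L) {
  mode <- match.arg(mode)
  interferer <- match.arg(interferer)
  if (is.unsorted(snr_grid_db, strictly = TRUE))
    stop("snr_grid_db must be strictly increasing")
  if (n_sentences < 1) stop("n_sentences must be at least 1")
  speech_level_db_spl <- speech_level_db_spl %||% if (mode == "HI") 80 else 65
  structure(list(mode = mode, speech_level_db_spl = speech_level_db_spl,
                 snr_grid_db = snr_grid_db, n_sentences = as.integer(n_sentences),
                 interferer = interferer,
                 sentence_duration_s = sentence_duration_s, f0_hz = f0_hz,
                 formants_hz = formants_hz, cf_hz = cf_hz, fibers = fibers,
                 periphery = periphery, mod_spec = mod_spec, frames = frames,
                 discard_s = discard_s, seed = as.integer(seed)),
            class = "run_config")
}

# Hash of the model-defining parts of a config (not mode, level, interferer,
# or SNR grid): a calibration fitted under one model configuration is frozen
# and reused across levels, interferers and listeners, but never across model
# configurations.
model_hash <- function(config) {
  fnv1a_hash(list(config$cf_hz, unclass(config$fibers),
                  unclass(config$periphery), unclass(config$mod_spec),
                  unclass(config$frames), config$discard_s, config$f0_hz,
                  config$formants_hz, config$sentence_duration_s))
}

# Seeded sentence surrogates for a config.
config_sentences <- function(config) {
  lapply(seq_len(config$n_sentences), function(i)
    make_speech_surrogate(duration_s = config$sentence_duration_s,
                          f0_hz = config$f0_hz,
                          formants_hz = config$formants_hz,
                          seed = config$seed + 100L + i,
                          fs = config$periphery$fs,
                          level_db_spl = config$speech_level_db_spl))
}

# One long interferer token per condition; excerpts are cut per sentence.
config_interferer <- function(config, sentences) {
  dur <- config$sentence_duration_s + 1
  fs <- config$periphery$fs
  ref <- audio_signal(unlist(lapply(sentences, `[[`, "samples")), fs,
                      "sentence-average reference")
  switch(config$interferer,
    ssn = make_ssn(ref, dur, seed = config$seed + 201L),
    sam = make_sam(make_ssn(ref, dur, seed = config$seed + 201L)),
    ists_like = make_ists_like(duration_s = dur, seed = config$seed + 201L,
                               fs = fs))
}

# Mean dissimilarity per SNR for one condition. The heavy inner loop: for
# each SNR and sentence, mix (sn, n), run periphery -> modulation filter ->
# framed power for both, and correlate across CF.
run_d_curve <- function(config, loss = NULL) {
  sentences <- config_sentences(config)
  interferer <- config_interferer(config, sentences)
  d <- numeric(length(config$snr_grid_db))
  for (j in seq_along(config$snr_grid_db)) {
    dj <- numeric(config$n_sentences)
    for (i in seq_len(config$n_sentences)) {
      mix <- mix_at_snr(sentences[[i]], interferer, config$snr_grid_db[j],
                        config$speech_level_db_spl,
                        seed = config$seed + 300L + i)
      pr_sn <- fluctuation_profile(mix$sn, config$cf_hz, loss, config$fibers,
                                   config$periphery, config$mod_spec,
                                   config$frames, config$discard_s)
      pr_n <- fluctuation_profile(mix$n, config$cf_hz, loss, config$fibers,
                                  config$periphery, config$mod_spec,
                                  config$frames, config$discard_s)
      dj[i] <- across_cf_correlation(pr_sn, pr_n)$d
    }
    d[j] <- mean(dj)
  }
  d
}

#' Default surrogate SI fitting targets
#'
#' A documented surrogate psychometric function used as the calibration
#' target when no measured SI scores are supplied: 50% SI at -3 dB SNR with a
#' 20%/dB slope at the midpoint, evaluated at the grid SNRs. These are not
#' listener data; replace them with measured scores when available.
#'
#' @param snr_grid_db SNR grid, dB.
#' @return data.frame with columns `snr_db`, `si_pct`.
#' @export
default_si_targets <- function(snr_grid_db = seq(-21, 12, by = 3)) {
  data.frame(snr_db = snr_grid_db,
             si_pct = 100 / (1 + exp(-0.8 * (snr_grid_db + 3))))
}

#' Fit and freeze the SI calibration
#'
#' Runs the fitting condition (normal hearing, speech in SSN at the
#' configured level) to obtain the dissimilarity `d` at each SNR, then fits
#' the logistic SI transformation to the target scores. The result carries a
#' hash of the model configuration; predictions made with this calibration
#' must use the same model configuration, and all of them share the one
#' frozen transformation.
#'
#' @param config a [run_config()]; mode, interferer and speech level are
#'   overridden to the fitting condition (normal hearing, SSN, 65 dB SPL).
#' @param targets data.frame with `snr_db`, `si_pct` (default
#'   [default_si_targets()] on the config's grid).
#' @return An object of class `si_calibration`: `logistic` (an
#'   [fit_logistic()] object), `d_per_snr`, `snr_grid_db`, `targets`, `hash`.
#' @export
calibrate_si <- function(config, targets = default_si_targets(config$snr_grid_db)) {
  stopifnot(inherits(config, "run_config"))
  fit_cfg <- config
  fit_cfg$mode <- "NH"
  fit_cfg$interferer <- "ssn"
  fit_cfg$speech_level_db_spl <- 65
  if (!all(targets$snr_db %in% config$snr_grid_db))
    stop("target SNRs must lie on the config's SNR grid")
  d <- run_d_curve(fit_cfg, loss = NULL)
  d_at <- d[match(targets$snr_db, config$snr_grid_db)]
  logistic <- fit_logistic(d_at, targets$si_pct)
  structure(list(logistic = logistic, d_per_snr = d,
                 snr_grid_db = config$snr_grid_db, targets = targets,
                 hash = model_hash(config)),
            class = "si_calibration")
}

#' @export
print.si_calibration <- function(x, ...) {
  cat(sprintf("<si_calibration> frozen logistic a1 = %.3f, a2 = %.3f (hash %s)\n",
              x$logistic$a1, x$logistic$a2, x$hash))
  invisible(x)
}

#' Save / load a frozen calibration
#'
#' Persists the fitted logistic parameters and the model-configuration hash
#' as JSON.
#'
#' @param calibration an `si_calibration`.
#' @param path JSON file path.
#' @return `save_calibration`: `path` invisibly; `load_calibration`: an
#'   `si_calibration` (without the fitting diagnostics).
#' @export
save_calibration <- function(calibration, path) {
  stopifnot(inherits(calibration, "si_calibration"))
  jsonlite::write_json(list(a1 = calibration$logistic$a1,
                            a2 = calibration$logistic$a2,
                            hash = calibration$hash,
                            snr_grid_db = calibration$snr_grid_db,
                            d_per_snr = calibration$d_per_snr),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_calibration
#' @export
load_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  logistic <- structure(list(a1 = x$a1, a2 = x$a2, fitted = NULL,
                             residuals = NULL, data = NULL, rss = NA_real_),
                        class = "si_logistic")
  structure(list(logistic = logistic, d_per_snr = x$d_per_snr,
                 snr_grid_db = x$snr_grid_db, targets = NULL, hash = x$hash),
            class = "si_calibration")
}

#' Run one prediction condition
#'
#' Predicts the psychometric function for one configuration: per SNR, the
#' dissimilarity `d` is averaged across the seeded sentence surrogates and
#' mapped through the frozen logistic to SI; the SRT is the 50% point.
#'
#' @param config a [run_config()].
#' @param loss optional [loss_profile()] (hearing-impaired ear); `NULL` for
#'   normal hearing.
#' @param calibration a frozen [calibrate_si()] result fitted under the same
#'   model configuration.
#' @return An object of class `psychometric_result` with `snr_grid_db`,
#'   `d_per_snr`, `si_per_snr`, `srt_db`, `srt_defined`, `calibration_hash`,
#'   `config`.
#' @export
run_condition <- function(config, loss = NULL, calibration) {
  stopifnot(inherits(config, "run_config"))
  if (missing(calibration) || is.null(calibration))
    stop("missing calibration: fit one first with calibrate_si() ",
         "(CLI: the `fit` command)")
  stopifnot(inherits(calibration, "si_calibration"))
  if (!identical(calibration$hash, model_hash(config)))
    stop("calibration was fitted under a different model configuration; ",
         "refusing to mix calibrations")
  d <- run_d_curve(config, loss = loss)
  si <- si_from_d(d, calibration$logistic)
  srt <- estimate_srt(config$snr_grid_db, si)
  structure(list(snr_grid_db = config$snr_grid_db, d_per_snr = d,
                 si_per_snr = si, srt_db = srt$srt_db,
                 srt_defined = srt$srt_defined,
                 calibration_hash = calibration$hash, config = config),
            class = "psychometric_result")
}

#' @export
print.psychometric_result <- function(x, ...) {
  cat(sprintf("<psychometric_result> %s, %s interferer, speech %g dB SPL\n",
              x$config$mode, x$config$interferer, x$config$speech_level_db_spl))
  cat(sprintf("  SRT = %.2f dB SNR%s\n", x$srt_db,
              if (x$srt_defined) "" else " (no 50% crossing on grid; edge reported)"))
  invisible(x)
}

#' @export
summary.psychometric_result <- function(object, ...) {
  print(object)
  print(as.data.frame(object), digits = 3)
  invisible(object)
}

#' @export
as.data.frame.psychometric_result <- function(x, ...) {
  data.frame(snr_db = x$snr_grid_db, d = x$d_per_snr, si_pct = x$si_per_snr)
}

#' @export
plot.psychometric_result <- function(x, ...) {
  plot(x$snr_grid_db, x$si_per_snr, type = "b", pch = 19,
       xlab = "SNR (dB)", ylab = "SI (%)", ylim = c(0, 100), ...)
  abline(h = 50, lty = 3)
  abline(v = x$srt_db, lty = 2)
  invisible(x)
}

#' Listener profile (both ears)
#'
#' @param id listener identifier.
#' @param audiogram_left,audiogram_right [audiogram()] objects; one may be
#'   `NULL` (single-ear prediction with a warning).
#' @return A list of class `listener_profile`.
#' @export
listener_profile <- function(id, audiogram_left = NULL, audiogram_right = NULL) {
  if (is.null(audiogram_left) && is.null(audiogram_right))
    stop("listener needs at least one audiogram")
  structure(list(id = id, audiogram_left = audiogram_left,
                 audiogram_right = audiogram_right),
            class = "listener_profile")
}

#' Hearing-impaired prediction with better-ear selection
#'
#' Converts each ear's audiogram to OHC/IHC loss factors (two-thirds OHC, one
#' third IHC by default), predicts the psychometric function per ear with the
#' frozen calibration, and takes the better ear in terms of predicted SI at
#' each SNR (ties go to the left ear). The SRT is read from the combined
#' function.
#'
#' @param config a [run_config()] in HI mode.
#' @param listener a [listener_profile()].
#' @param calibration a frozen [calibrate_si()] result (fitted on the NH
#'   condition).
#' @param ohc_fraction fraction of total loss attributed to OHCs.
#' @return A `psychometric_result` with extra fields `per_ear` (list of
#'   per-ear results) and `better_ear` (per-SNR ear choice).
#' @export
run_hi_listener <- function(config, listener, calibration, ohc_fraction = 2 / 3) {
  stopifnot(inherits(config, "run_config"), inherits(listener, "listener_profile"))
  if (config$mode != "HI") stop("config must be in HI mode")
  ears <- list()
  for (side in c("left", "right")) {
    ag <- listener[[paste0("audiogram_", side)]]
    if (is.null(ag)) next
    loss <- audiogram_to_loss(ag, config$cf_hz, ohc_fraction,
                              fibers = config$fibers, config = config$periphery)
    ears[[side]] <- run_condition(config, loss, calibration)
  }
  if (length(ears) == 1L)
    warning("single-ear listener profile; proceeding with the ", names(ears))
  if (length(ears) == 1L) {
    res <- ears[[1]]
    res$per_ear <- ears
    res$better_ear <- rep(names(ears), length(config$snr_grid_db))
    return(res)
  }
  si_l <- ears$left$si_per_snr
  si_r <- ears$right$si_per_snr
  better <- ifelse(si_r > si_l, "right", "left")  # ties -> left
  si <- pmax(si_l, si_r)
  d <- ifelse(better == "right", ears$right$d_per_snr, ears$left$d_per_snr)
  srt <- estimate_srt(config$snr_grid_db, si)
  structure(list(snr_grid_db = config$snr_grid_db, d_per_snr = d,
                 si_per_snr = si, srt_db = srt$srt_db,
                 srt_defined = srt$srt_defined,
                 calibration_hash = calibration$hash, config = config,
                 per_ear = ears, better_ear = better, listener_id = listener$id),
            class = "psychometric_result")
}

#' Normal-hearing presentation-level sweep
#'
#' Repeats the prediction at several speech levels with the same frozen
#' calibration and identical stimulus seeds, so the stimuli differ only by
#' the calibration scaling of the speech.
#'
#' @param config a [run_config()] in NH mode.
#' @param calibration a frozen [calibrate_si()] result.
#' @param levels_db_spl speech levels, dB SPL.
#' @return Named list of `psychometric_result`, one per level.
#' @export
nh_level_sweep <- function(config, calibration, levels_db_spl = c(50, 65, 80)) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode != "NH") stop("config must be in NH mode")
  out <- lapply(levels_db_spl, function(L) {
    cfg <- config
    cfg$speech_level_db_spl <- L
    run_condition(cfg, loss = NULL, calibration = calibration)
  })
  names(out) <- paste0(levels_db_spl, "dB")
  out
}
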