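---
title: "Predicting speech intelligibility from across-frequency neural fluctuation contrast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting speech intelligibility from across-frequency neural fluctuation contrast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flucsi)
```

## The model in one paragraph

`flucsi` predicts speech intelligibility (SI) and speech reception
thresholds (SRTs) for speech presented in noise, for normal-hearing (NH) and
hearing-impaired (HI) configurations. Both the noisy speech (SN) and the
noise alone (N) are passed through a nonlinear model of the auditory
periphery that produces a *neurogram*: the population-averaged instantaneous
auditory-nerve firing rate at 13 characteristic frequencies (CFs)
log-spaced from 0.5 to 8 kHz. A single modulation band-pass filter (Q = 1,
centred at 125 Hz, near a male talker's fundamental frequency F0) enhances
rate fluctuations in the F0 range; the filtered rates are squared and
averaged in 20-ms frames with 10-ms steps, giving fluctuation-power
profiles `sn(k, CF)` and `n(k, CF)`. For each frame `k` the Pearson
correlation *across CF* between the two profiles is computed, averaged over
valid frames into `r_bar`, and turned into the dissimilarity
`d = 1 - r_bar`. A logistic, `SI = 100 / (1 + exp(a1 * d + a2))`, fitted
*once* on a fitting condition and then frozen, maps `d` to SI; the SRT is
the SNR at which the predicted psychometric function crosses 50%.

The scientific premise is the vowel-coding hypothesis for the auditory
midbrain: inner-hair-cell (IHC) and rate saturation make channels tuned
*at* vowel formants respond with a nearly constant rate, while channels
*between* formants receive several comparable harmonics whose beating
produces deep rate fluctuations at F0. The resulting across-CF contrast
pattern — notches at formants, peaks between — is a speech signature that a
noise masker does not share. The more the noisy-speech profile differs from
the noise-alone profile, the more speech information survived.

## Calibration conventions

Digital signals carry sound-pressure-level semantics under the convention
that RMS 1.0 corresponds to 94 dB SPL (1 Pa), so level arithmetic on
waveforms is exact. The interferer excerpt mixed into the noisy speech is
the *same* excerpt used for the noise-alone reference, which is rescaled so
`RMS(n) = RMS(sn)` — the reference always has the level of the noisy
speech.

## Stimuli

The package synthesizes all of its stimulus classes so the pipeline can be
exercised without access to a recorded corpus:

* **Speech surrogate** (`make_speech_surrogate()`): concatenated voiced
  harmonic-complex "syllables" (F0 119 Hz with ±4% drift, random harmonic
  phases, formant resonances with per-syllable ±8% jitter, 40–100 ms
  pauses). It reproduces the property the decision metric consumes —
  F0-rate fluctuations organized by formant structure — but not phonetic
  content, consonant bursts, or coarticulation; passing tests therefore
  demonstrate the metric's behaviour on harmonic speech-like input, not
  word recognition.
* **SSN** (`make_ssn()`): Gaussian noise whose magnitude spectrum is shaped
  to the third-octave-smoothed long-term spectrum of a reference (here, the
  concatenated sentence surrogates), i.e. a stationary masker with the
  average speech spectrum.
* **SAM noise** (`make_sam()`): SSN multiplied by
  `1 + m sin(2*pi*8 t)`. The modulation depth defaults to `m = 1` (full
  modulation), the customary choice in the masking-release literature; it
  is an explicit argument.
* **Multi-talker surrogate** (`make_ists_like()`): randomly concatenated
  voiced/unvoiced syllables from three synthetic female "talkers" (F0s
  around 207 Hz, distinct formant sets) with silent gaps, yielding the
  strong temporal fluctuation of an international-speech-test-signal-style
  masker. It does not reproduce the official recording's spectra, languages
  or pause statistics.

All generators are pure functions of their spec and seed (bit-identical
across runs), and generation never perturbs the caller's RNG state.

Formant bandwidths follow typical vocal-tract values (~60–160 Hz). For
contrast demonstrations we use a vowel whose formants sit on grid CFs
(794/2000/3175 Hz): the formant-notch prediction applies at the formant's
own channel, and with a 119-Hz F0 a channel a tenth of an octave *off* a
formant legitimately contains two comparable harmonics and beats.

## The phenomenological periphery

The front end is deliberately phenomenological: a small set of stages, each
with an explicit constant, calibrated once against documented response
contracts (below). It is not a port of any published auditory-nerve model,
and `an_rate_response()` is the seam where an external periphery producing
the same time × CF rate matrix could be plugged in.

Per channel (internal rate 100 kHz; inputs must be synthesized at or
resampled to it):

1. **Middle ear**: 350 Hz – 12 kHz band-pass (2nd-order Butterworth).
2. **Dual-path cochlear stage**: a narrow (1.019 ERB) gammatone path whose
   envelope passes a broken-stick gain — linear gain 800 (58 dB of
   cochlear amplification) below a knee at ~45 dB SPL, compression exponent
   0.3 above — scaled by the outer-hair-cell factor `c_ohc`; plus a broad
   (2.2 ERB) linear path of unit gain. As `c_ohc` falls the channel loses
   low-level gain and compression and its effective tuning broadens toward
   the linear path. The compressive gain follows the analytic envelope
   (cycle-by-cycle), not the instantaneous waveform, so a tone is scaled
   coherently rather than distorted.
3. **IHC transduction**: half-wave rectification with logarithmic
   compression `v = theta * log1p(r / theta)` (`theta = 20`, nearly linear
   over the operating range — rate saturation is left to the fiber rate
   map so that deep F0-beating nulls stay encoded at high levels), scaled
   by the IHC factor `c_ihc`; then a 7-pole low-pass with 3 kHz pole
   frequency, the customary IHC membrane filter, which removes
   phase-locked fine structure above ~3 kHz. The pole count matters: with
   a gentler filter, residual fine-structure ripple is amplified by the
   onset-emphasizing adaptation and corrupts both rate-level functions and
   fluctuation profiles.
4. **Adaptation**: linear onset emphasis, `out = (lp - ad) + s*ad` with a
   60-ms low-pass state `ad` and sustained fraction `s = 0.15`. IHC damage
   degrades the *synchrony* of rapid receptor-potential fluctuations on
   top of overall sensitivity, so the fluctuating part `(lp - ad)` carries
   an extra factor `c_ihc^0.5` (total AC scaling `c_ihc^1.5`, DC scaling
   `c_ihc`).
5. **Rate mapping**: three deterministic fiber classes — high-, medium-,
   low-spontaneous-rate (HSR/MSR/LSR), weights 0.6/0.2/0.2, spontaneous
   rates 60/5/0.5 sp/s, saturation 250/200/150 sp/s, thresholds offset by
   0/12/25 dB — with the steep rate-level function
   `spont + (sat - spont) * (1 - exp(-(D/theta)^2))`. The exponent 2
   narrows each class's dynamic range to physiological values: fibers
   driven well above threshold sit hard on their saturated rate and only
   deep envelope dips release them. The population rate is the weighted
   class mean — the deterministic limit of averaging many stochastic
   fibers.

### The population-sampling fluctuation floor

A real population average over ~50 fibers per CF retains residual sampling
noise whose power spectral density is roughly the local mean rate divided
by the fiber count. `fluctuation_profile()` therefore augments each frame
value by `mean_rate * ENB / n_fibers` (ENB = equivalent noise bandwidth of
the modulation filter, ~196 Hz; `n_fibers = 50`). This deterministic
expectation restores the audibility limit that the deterministic-mean
idealization would otherwise remove: channels whose stimulus-driven
fluctuations are weak — near threshold, or strongly impaired — converge to
a shared, rate-shaped floor, pulling the across-CF correlation up and the
dissimilarity down. Setting `n_fibers = Inf` yields the bare profile.

### Hearing loss parameterization

`audiogram_to_loss()` interpolates an audiogram linearly in log-frequency
onto the CF grid, attributes two thirds of the total loss to OHCs and one
third to IHCs, and converts the dB targets into `c_ohc`/`c_ihc`. The IHC
factor is the exact drive attenuation `10^(-L_ihc/20)`. The OHC factor is
first solved in closed form from the dual-path gain at the normal-hearing
threshold operating point and then refined by *bisection against the
simulated pure-tone threshold* (`pure_tone_threshold()`, a 1-dB-grid rate
criterion: +10% of the spontaneous-to-saturation range for a 50-ms CF
tone), because the closed form only approximates the interplay of
compression, rectified synchrony and the steep rate map. The refinement
converges to the target total loss within ~1 dB for flat losses of
20–60 dB HL. OHC demands beyond the available cochlear gain clip at
`c_ohc = 0` with a warning.

## Decision stage and the frozen logistic

Frames in which either profile is flat across CF (relative variance below
1e-12 of its mean square — silence or hard saturation) are excluded from
`r_bar` via a validity mask; the Pearson correlation is undefined there,
and frames of shared silence carry no evidence either way. The correlation
is computed on the fluctuation-power values themselves (no log or
amplitude transform), apart from the sampling floor described above.

The logistic parameters are estimated by nonlinear least squares
(`minpack.lm::nlsLM`) with multi-start over sign combinations plus a
logit-linearized start, tolerance 1e-10. The default fitting condition is
the NH configuration with speech in SSN at 65 dB SPL. Because the measured
SI scores of the original fitting condition are not available, the package
ships a clearly labelled *surrogate* target set
(`default_si_targets()`: 50% SI at −3 dB SNR, 20%/dB midpoint slope,
evaluated at the grid SNRs); it is an argument, and users with measured
psychometric data should supply it instead. Once fitted, the calibration
is frozen: it records a hash of the model configuration, every prediction
records that hash, and `run_condition()` refuses a calibration fitted
under a different model configuration. Predictions across presentation
levels, interferers and listeners all share the one frozen mapping.

SRTs are read as the *first upward* 50% crossing, linearly interpolated
between grid SNRs; if the psychometric function stays on one side of 50%
over the whole grid (−21 to +12 dB in 3-dB steps), the nearer grid edge is
reported with `srt_defined = FALSE`. First-crossing semantics mirror an
adaptive listening procedure and make the estimate well-defined even if
better-ear selection produces a locally non-monotone combined function.

## Study conditions and problem sizes

`run_config()` defaults encode the study conditions: 13 CFs, SNRs −21 to
+12 dB in 3-dB steps, ten seeded 2-s sentence surrogates averaged per SNR,
speech at 65 dB SPL (NH) or 80 dB SPL (HI), and per-SNR better-ear
selection on predicted SI (ties to the left ear) for two-eared listeners.
The test suite exercises the full ten-sentence NH condition end to end and
uses reduced sentence counts and durations (2–3 sentences of 0.8–1 s) for
unit-level checks, sizes chosen to probe the same mechanisms at a fraction
of the computation.

## Known limitations

* The dissimilarity scale is model-specific; `a1`, `a2` fitted on surrogate
  targets are not comparable to values fitted on listener data.
* At the full study conditions the predicted SRT ordering is
  SSN > SAM > multi-talker surrogate, as in listener data; in scaled-down
  runs (few short sentences) the two fluctuating maskers can swap. The
  stationary-vs-fluctuating ordering is robust at every size.
* Presentation-level benefits for fluctuating maskers at 80 vs 65 dB SPL
  are slightly inverted (d decreases mildly with level), so the model
  under-predicts the high-level release benefit.
* Under *mild* IHC attenuation (2–6 dB) the predicted dissimilarity can
  transiently exceed the normal-hearing value by a few percent before
  falling steeply: a small drive reduction releases rate saturation before
  the sampling floor dominates. For the moderate-to-severe IHC components
  implied by realistic audiograms (≥8 dB) the predicted d — and hence SI —
  degrades monotonically, and a flat 40 dB HL loss shifts the SSN SRT
  upward by several dB.
* The HI configuration retains most of its fluctuating-masker benefit, so
  predicted HI masking release can slightly exceed the NH value — the same
  direction of error as over-predicting HI intelligibility in fluctuating
  maskers. Strong losses can also push the HI psychometric function below
  50% over the whole SNR grid, in which case the upper grid edge is
  reported with `srt_defined = FALSE`.

```{r example, eval = FALSE}
# A reduced end-to-end run (2 sentences of 1 s; defaults are 10 x 2 s)
cfg <- run_config(n_sentences = 2, sentence_duration_s = 1, seed = 1)
cal <- calibrate_si(cfg)
nh <- run_condition(cfg, NULL, cal)
hi <- run_condition(run_config(mode = "HI", n_sentences = 2,
                               sentence_duration_s = 1, seed = 1),
                    audiogram_to_loss(audiogram(c(250, 8000), c(40, 40))),
                    cal)
summary(nh); summary(hi)
```
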