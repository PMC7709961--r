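Package: flucsi
Title: Speech Intelligibility Prediction from Across-Frequency Neural Fluctuation Contrast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts speech intelligibility (SI) and speech reception thresholds (SRTs)
    for normal-hearing and hearing-impaired listeners from simulated auditory-nerve
    firing-rate fluctuations. A phenomenological nonlinear periphery (compressive
    cochlear filtering with outer-hair-cell gain, saturating inner-hair-cell
    transduction, adaptation, and three spontaneous-rate fiber classes) produces a
    neurogram across characteristic frequencies; rate fluctuations are enhanced with a
    single modulation band-pass filter near the speech fundamental frequency, reduced
    to framed fluctuation-power profiles, and compared between noisy speech and noise
    alone via a short-term across-frequency correlation. The dissimilarity d = 1 - rbar
    is mapped to SI through a once-fitted ("frozen") logistic, and SRTs are read off as
    50-percent points. Includes seeded synthesis of speech surrogates, speech-shaped
    noise, amplitude-modulated noise, and a fluctuating multi-talker interferer, plus
    audiogram-based outer/inner hair-cell loss parameterization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
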