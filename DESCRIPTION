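Package: accmap
Title: Neural Vowel-Space Mapping from the Acoustic Change Complex
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for mapping perceptual vowel spaces from EEG responses to
    vowel changes in continuous sound. Synthesizes concatenated-vowel stimulus
    sequences (pitch-flattened, envelope-flattened, RMS-equalized tokens spliced
    with raised-cosine cross-fades), computes cochlear-scaled spectral and
    formant-difference predictors on an ERB auditory scale, simulates
    multichannel infant EEG with planted Acoustic Change Complex (ACC)
    responses, preprocesses recordings into transition-locked epochs, extracts
    a single repeatability-maximizing ACC component per subject by Denoising
    Source Separation (DSS), and derives per-pair ACC magnitudes, order
    asymmetries, mixed-effects acoustic models, and two-dimensional perceptual
    vowel maps by classical multidimensional scaling with Procrustes alignment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    car,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
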