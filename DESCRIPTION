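Package: atroscore
Title: Individual-Level Cortical Atrophy Pattern Scoring from Surface-Based Thickness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Surface-based morphometry toolkit for scoring how closely an
    individual's cortical thinning pattern resembles the group-level atrophy
    pattern of Alzheimer's disease. Per-vertex cortical thickness sampled on a
    triangulated surface is denoised by a manifold harmonic (Laplace-Beltrami
    spectral) low-pass filter, converted to normative w-scores adjusting for
    age and education, and projected through a PCA plus two-class linear
    discriminant pipeline; the signed discriminant coordinate is anchored to
    the cognitively-normal and patient training means to yield a 0-100
    atrophy-similarity score. Includes FreeSurfer binary surface and curv
    readers and writers, icosphere mesh generators, synthetic cross-sectional
    and longitudinal cohort simulators with known ground truth, stratified
    cross-validation with fold-internal normative refitting, discriminative
    and per-subject Z-score maps, longitudinal converter and decliner
    labeling rules, and random-intercept mixed-effects validation models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    lme4,
    methods,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
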