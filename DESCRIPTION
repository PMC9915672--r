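Package: popcode
Title: Population Coding Analysis of Sound Level Responses Under
    Interneuron Activation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-photon calcium-imaging studies of how
    optogenetic activation of inhibitory interneurons (SST, VIP) reshapes the
    auditory-cortex population code for sound pressure level. Provides response
    windowing (optimal and fixed one-second windows on dF/F traces), lifetime
    and activity sparseness statistics, population-vector geometry (separation
    angles and vector lengths), monotonicity classification with sigmoid and
    Gaussian response-level curve fitting under a sem-weighted McFadden
    pseudo-R-squared objective, one-vs-rest linear SVM decoding of sound level
    with PCA compression and kernel-density oversampling, an analytic two-cell
    localist-versus-distributed model, and a synthetic-data generator that
    emulates the trial structure of such experiments for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
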