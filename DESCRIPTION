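Package: modfilt
Title: Modulation Power Spectrum Filtering and Auditory Experiment Design Tools
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for constructing spectrotemporally matched auditory
    stimuli by low-pass filtering of the modulation power spectrum:
    Gaussian-window log-spectrogram analysis, two-dimensional Fourier
    modulation filtering, and iterative (Griffin-Lim style) spectrogram
    inversion back to audio. Also assembles factorial trial sequences and
    two-run scanning sessions from a sound inventory, scores
    forced-choice sound-picture matching behaviour against exact binomial
    chance, and compares groups of three-dimensional effect maps
    (unequal-variance t statistics, cluster formation at a height
    threshold, direction-based voxel categorisation, and effect sampling
    at named coordinates). Synthetic sound and map generators allow the
    full pipeline to be exercised without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
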