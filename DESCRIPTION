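Package: phasestates
Title: Dynamic Phase-Coupling Connectivity States and EEG Microstates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Resting-state EEG brain-network dynamics from band-limited
    instantaneous phases. Computes sliding-window corrected imaginary
    phase-locking values (ciPLV) between source-parcel time courses,
    reduces each window to a binary graph of the strongest connections,
    clusters windows into recurring connectivity states, and quantifies
    state coverage, Markov transitions, and across-day reliability (ICC).
    Includes minimal sensor preprocessing (resampling, FIR band-pass,
    common average reference), sign-flip parcel aggregation of vertex
    source estimates, a classical polarity-invariant microstate analysis
    for comparison, paired statistics, and a ground-truth synthetic
    generator of Markov-switching phase-locked subnetworks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
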