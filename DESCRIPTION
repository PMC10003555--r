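Package: plor
Title: Design and Analysis of Single-Round Pause-Restart (PLOR) Transcription
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing and analysing position-selective labeling of
    RNA (PLOR) experiments, in which T7 RNA polymerase is walked along a DNA
    template in discrete pause-restart steps by supplying only subsets of the
    four NTPs. The package derives the run-off transcript from a template by
    locating the T7 promoter, predicts polymerase halt positions under
    NTP-omission schedules, computes per-step stoichiometric NTP batches,
    annotates the intrinsic terminator U-tract to predict terminated and
    full-length product sizes, quantifies termination efficiency from
    band-intensity tables with replicate statistics, fits the multiplicative
    step-yield model E = Ei * Ee^n, and simulates seeded stochastic
    single-round transcription including ligand-dependent termination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
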