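Package: saccatt
Title: Microsaccade-Conditioned Analysis of Lateralized EEG Markers of
    Spatial Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking fixational eye movements to lateralized
    electrophysiological markers of covert spatial attention. Detects and
    characterizes microsaccades from high-rate gaze traces with a
    median-velocity threshold, classifies trials by the direction of the
    first gaze shift in a post-cue attention window, conditions
    contralateral-minus-ipsilateral ERP (N2pc) and alpha-band
    lateralization measures on microsaccade class, tests time courses
    with cluster-based sign-flip permutation statistics, and probes
    temporal locking with latency-sorted ERP images. Ships a synthetic
    gaze + EEG experiment generator with planted ground truth so the full
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
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
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
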