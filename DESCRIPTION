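Package: copingtrace
Title: Behavioral Coping-State Segmentation and Habenular Calcium Signal Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation of active-coping and passive-coping bouts from
    motion-index, velocity and tail-angle traces by amplitude- and
    duration-thresholding; fiber-photometry preprocessing (isosbestic
    motion-artifact correction, peri-event z-scoring, per-animal
    normalization) with bout-aligned rise-time and amplitude analyses;
    two-photon movie binning with event-triggered responsive-region
    mapping; normality-gated statistical test routing and rabies-tracing
    count filters; and seeded synthetic-data generators that emulate the
    signal structure of head-fixed mouse and zebrafish coping assays so
    the whole pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tiff,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
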