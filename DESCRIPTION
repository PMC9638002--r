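Package: ethospike
Title: Spike-Train and Behavior Analysis for Ethological-Event Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for extracellular recordings taken while an
    implanted animal freely interacts with ethological stimuli (conspecifics,
    a moving toy, food). Provides session data structures with video-ephys
    synchronization and unit quality control; an inhomogeneous-Poisson
    synthetic-session generator with ground truth for every downstream stage;
    auROC event-response scoring and unit categorization; z-scored peri-event
    dynamics with spline time-warping, onset synchrony and minutes-long
    aftereffect detection; pose-feature social-behavior classification with
    bout post-processing; cross-correlogram detection of directional putative
    monosynaptic connections with epoch-wise strength; population decoding of
    stimulus identity and behavior; and waveform-based cell typing plus
    cross-day unit matching.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    e1071,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
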