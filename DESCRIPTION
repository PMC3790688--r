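Package: rivalerp
Title: Predictive Event-Related Potential Analysis for Intermittent Binocular Rivalry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for event-related potential (ERP)
    studies of intermittent binocular rivalry, in which brain activity during a
    first display of rival gratings predicts whether visual consciousness
    changes at a second display. Provides a synthetic-data generator for the
    trial paradigm, behaviour, and condition-dependent ERP effects; BrainVision
    file input/output; preprocessing (linked-earlobe re-referencing, Kaiser
    windowed sinc FIR bandpass filtering, epoching, baseline correction, and
    peak-to-peak artifact rejection); condition-averaged ERPs with pointwise
    paired t-maps, region-of-interest significance counting with a chi-square
    check, sign-flip permutation tests, and repeated-measures ANOVAs with
    partial eta squared; and a simplified distributed source analysis on a
    spherical head model with voxelwise Hotelling T-squared statistical
    parametric maps under Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
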