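Package: lfpdbs
Title: Closed-Loop Low-Frequency DBS Simulation and Peri-Ictal LFP Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing closed-loop (responsive)
    low-frequency deep brain stimulation experiments on two-channel local
    field potential (LFP) recordings from hippocampus and medial prefrontal
    cortex. Provides a synthetic LFP generator with known ground truth
    (1/f background, band-limited oscillations, phase-amplitude-coupled
    components, controllable inter-channel coherence, scheduled ictal events
    and stimulation artifacts), an online windowed-power seizure-onset
    detector, a pulse-package stimulation scheduler with artifact injection
    and blank-and-interpolate removal, peri-ictal segmentation with Welch
    band-power estimation, magnitude-squared coherence, Tort modulation-index
    phase-amplitude coupling with comodulograms, and a one-way
    ANOVA / Tukey HSD / Kolmogorov-Smirnov group-comparison stage. Recordings
    are read and written as European Data Format (EDF) files; annotations and
    stimulation logs as CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    nortest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
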