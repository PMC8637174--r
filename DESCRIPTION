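Package: probemwl
Title: Cross-Task Mental Workload Analysis from Task-Irrelevant Auditory
    Probe EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for electroencephalography
    (EEG) based mental-workload estimation with task-irrelevant auditory
    probes. Generates synthetic multi-channel EEG for a two-task,
    two-difficulty, two-block probe-in-task design; preprocesses
    continuous recordings (zero-phase band-pass filtering, mastoid
    re-referencing, event-related potential and spectral epoching);
    extracts single-trial ERP component amplitudes (N1, eP3a, lP3a, RON)
    and Welch relative band-power features (theta, alpha, beta1, beta2);
    quantifies cross-task consistency of feature discriminability with
    the signed Fisher discriminant ratio; classifies workload with a
    radial-basis-function support vector machine under block-wise and
    cross-task transfer schemes with decision-value averaging; and
    provides bootstrap paired t-tests, bootstrap repeated-measures
    ANOVAs, and false-discovery-rate corrected statistical maps.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
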