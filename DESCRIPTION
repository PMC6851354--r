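Package: scalphfo
Title: Automated Scalp and Intracranial High-Frequency Oscillation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and clinical validation of high-frequency
    oscillations (HFO, 80-500 Hz) in scalp EEG and electrocorticography.
    Implements a three-stage Stockwell-transform-based detector with a
    background-adaptive amplitude threshold, bipolar montage construction,
    anti-aliased resampling and clean NREM epoch selection, per-channel and
    per-hemisphere rate aggregation, and the clinical statistics layer:
    ROC-derived rate threshold, predictive values with Wilson score
    intervals, log-scale regression of HFO rate on seizure frequency,
    Wilcoxon tests and pre/post concordance chi-squared. A synthetic EEG
    generator with ground truth (1/f background, amplifier noise floor,
    injected ripple and fast-ripple bursts, spike and muscle transients,
    power-law cohorts) makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
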