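Package: nfbloop
Title: Closed-Loop Theta/Beta-Ratio Neurofeedback Engine and Offline EEG Analysis
Version: 0.1.0
Authors@R: person("nfbloop", "maintainers", email = "maint@nfbloop.org", role = c("aut", "cre"))
Description: Tools for building and validating a closed-loop theta/beta-ratio
    (TBR) neurofeedback system for attention training, together with the
    offline analysis pipeline that accompanies it. Includes a real-time
    sliding-window spectral engine with muscle-artifact gating and per-subject
    calibration, feedback dynamics (helicopter altitude) and
    attention-proportional distraction scheduling, go/no-go and adaptive
    arithmetic task generators and scorers, template-subtraction cleaning of
    MR gradient and ballistocardiogram artifacts, polarity-invariant
    microstate clustering with smoothed back-fitting, session-level TBR
    statistics, BrainVision/EDF/TSV input-output, and a synthetic-EEG module
    with simulated-child behavior so every stage is testable without real
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
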