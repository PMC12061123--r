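Package: primingEEG
Title: Simulation and Analysis of Forward and Backward Affective-Priming
    EEG Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses combined forward (prime before target)
    and backward (prime after response) affective-priming experiments with
    32-channel EEG. Provides a synthetic-data generator (trial schedules,
    lognormal reaction times with a congruency shift, questionnaire scores,
    continuous event-marked EEG with 1/f background noise, blink artifacts
    and injectable condition effects), an EEG preprocessing chain (zero-phase
    band-pass filtering, common average reference, ICA-based eye-blink
    removal keyed to the Fp1 electrode, target-locked epoching with baseline
    correction and peak-to-peak artifact rejection), reaction-time statistics
    (per-participant median contrasts, one-sided Wilcoxon and t tests,
    Cohen's d, a JZS Bayes factor, Bonferroni-Holm correction, questionnaire
    correlations), event-related potential analysis (grand means, difference
    traces, running paired t-tests with exploratory longest-window selection
    and capped topographic p summaries, windowed amplitudes), and
    per-participant single-trial decoding of congruent versus incongruent
    epochs with a compact two-layer convolutional network under a balanced
    4-fold cross-validation protocol repeated over random seeds, including a
    random hyperparameter search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
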