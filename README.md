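# primingEEG

Simulation and analysis of combined **forward** and **backward (retroactive)
affective-priming** experiments with 32-channel EEG.

In an affective priming trial a participant classifies the valence
(positive/negative) of a target image that is preceded (forward priming) or
followed, after the response (backward priming), by a positive or negative
prime word.  When prime and target share valence (*congruent* trials),
reaction times to the target are typically faster than when they differ
(*incongruent*).  The backward variant is the Bem-style paradigm used to
probe claimed precognition effects.  The original study data are not
publicly deposited, so this package pairs every analysis stage with a
synthetic-data generator that emulates the experiment's statistical
structure — which makes each stage verifiable end to end.

## What the package provides

* **Synthetic data** — `make_schedule()` (400 trials in 11 blocks of 36 plus
  one of 4, balanced target valences, fair-coin primes), `simulate_rt()`
  (shifted-lognormal reaction times with a congruency shift; default
  condition medians 720 / 751 ms), `simulate_eeg()` (continuous 1/f-noise
  recordings with event markers, blink artifacts, and congruent-minus-
  incongruent effects injected at configurable electrodes/latencies),
  `simulate_questionnaires()` (FMI, BIS-11, PExE-style scores, optionally
  coupled to each participant's behavioural effect).
* **Preprocessing** — `bandpass_filter()` (zero-phase FIR, 0.1–30 Hz),
  `rereference_average()`, `fit_ica()` / `detect_blink_components()` (blink
  components flagged at |r| > 0.5 with the Fp1 channel) /
  `remove_components()`, `epoch_and_baseline()` (−60…+40 ms baseline around
  target onset), `reject_peak_to_peak()`.
* **Behaviour** — `filter_valid()` (correct responses, 250–2000 ms),
  `rt_contrast()` (per-participant median difference, congruent −
  incongruent), `paired_tests()` (one-sided Wilcoxon signed-rank, paired
  *t*, Cohen's *d* = mean/sd of the differences, JZS Bayes factor with
  Cauchy scale 0.707), `holm_correct()`, `correlate()` (Pearson and
  Spearman side by side).
* **ERPs** — `participant_erps()` (per-participant and grand means ± SEM,
  difference traces), `running_ttest()` (paired *t* at every
  electrode × timepoint, uncorrected by design), `select_longest_window()`
  (longest contiguous sub-α run across all electrodes),
  `summarize_window()` (capped median *p* in a ±10 ms neighbourhood of the
  minimum-*p* time — the numbers behind a topographic significance map),
  `windowed_amplitude()`.
* **Decoding** — a compact two-layer convolutional network built from
  scratch (`net_spec()`, `build_net()`, `train_net()`): a spatial
  convolution spanning all channels, a temporal convolution with kernel 25,
  dropout 0.5, sigmoid output; trained on single trials from the
  400–700 ms window under a balanced 4-fold cross-validation repeated with
  3 seeds (12 accuracies per participant, `train_eval_cv()`), with a
  10-draw `random_search()` over activations, filter counts, optimizers,
  learning rates and losses.
* **Pipeline** — `run_config()` + `run_pipeline()` +
  `write_result_json()`: simulate → preprocess → behaviour → ERP →
  (optional) decoding → questionnaire correlations, fully seeded and
  reproducible; BrainVision I/O via `write_brainvision()` / `read_raw()`.

## Worked example

```r
library(primingEEG)

cfg <- run_config(list(experiment = "both", n_participants = 24,
                       n_trials = 160, seed = 42))
bundle <- run_pipeline(cfg)   # ~40 s
bundle
#> <result_bundle> seed 42, config 702a7424
#>   forward: n=24 | RT diff -31.1 ms (W p=0.0263) | window: P8 588-888 ms
#>   backward: n=24 | RT diff +10.5 ms (W p=0.906) | window: Oz 500-540 ms

bundle$experiments$forward$behaviour$tests
#> <paired_test_result> n=24, one-sided
#>   Wilcoxon W=82.0 p=0.02632 | t=-2.020 p=0.02757 | d=-0.412 | BF10=2.33
```

The forward cohort shows the expected congruency advantage (negative median
reaction-time difference, one-sided Wilcoxon *p* < .05, Bayes factor above
1), and the running *t*-test recovers the injected late parietal window at
P8 — 588–888 ms against the injected 586–889 ms.  The backward cohort's
reaction times sit at a null difference, and its exploratory window
selection lands on a short spurious window (Oz, 44 ms), illustrating why
the uncorrected longest-run rule is a hypothesis-generating device rather
than a confirmatory test.  Amplitude read-out at the injected site:

```r
erps <- bundle$experiments$forward$erp$erps
attr(windowed_amplitude(erps, "P8", c(586, 889)), "mean")
#> [1] -1.085962   # injected: -1.14 uV
```

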