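---
title: "Models and methods behind primingEEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind primingEEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, numerical choices and design decisions
of the package: what the synthetic-data generator emulates (and does not),
how each analysis stage is defined, which parameters matter and why they
default to the values they do.

## The experiment being emulated

A session has 400 trials in 12 blocks (11 × 36 + 1 × 4).  Each trial pairs
a positive/negative prime word with a positive/negative target image.  In
the *forward* task the order is fixation (1200 ms) → prime (500 ms) → ISI
(300 ms) → target (up to 2000 ms, ended by the valence response) → blank
(1000 ms); the *backward* task swaps prime and target, so the prime only
appears after the response.  Target valences are exactly balanced per
session; prime valences are independent fair coin flips, which makes the
congruent/incongruent split random with expectation 50%.  `make_schedule()`
reproduces this structure bit-identically per seed, and forward/backward
schedules from one seed share their valence sequences so the two tasks can
be compared on identical stimulus material.

## Synthetic behaviour

Reaction times are shifted lognormal,

\[ \mathrm{rt} = (b - s) + c + \mathrm{Lognormal}(\log s, \sigma), \qquad
   c = \mp \delta/2 , \]

with base \(b = 735.5\) ms, shift \(s = 200\) ms and congruency effect
\(\delta\).  The shift construction keeps the *median* equal to \(b + c\)
for every \(\sigma\), so the default \(\delta = 31\) ms (forward) yields
condition medians of 720 and 751 ms; the backward default is the weak
\(\delta = 5.5\) ms trend, which a ~30-participant cohort cannot reliably
distinguish from zero — the qualitative asymmetry the analysis should
reproduce.  The distribution family is a modelling choice (the emulated
experiment reports only medians); lognormal is the standard positively
skewed reaction-time model.  \(\sigma = 0.5\) gives a realistic interquartile
spread of roughly 150 ms.

Between-participant heterogeneity enters as
\(\delta_i = \delta + 60\,\mathrm{ms} \cdot e_i\), \(e_i \sim N(0,1)\).
The value 60 ms makes the cohort-level effect size for the forward task
about \(d = 0.5\): large enough that the directional sign is recovered in
essentially every replicate cohort of 31, small enough that single
participants routinely show reversed effects, as real priming data do.
Responses are wrong with probability 0.05 and reaction times above the
2000 ms deadline become timeouts, so the validity filter (correct
responses, 250–2000 ms inclusive) has real work to do.

## Synthetic EEG

The generator has two routes with identical signal structure:

* `simulate_eeg()` builds a continuous recording: evoked templates at every
  target onset, 1/f background noise, Poisson blink transients projected
  through a frontal topography (maximal at Fp1), and event markers.  This
  is the route for exercising the full preprocessing chain.
* `simulate_participant_epochs()` emits target-locked epochs directly
  (template + 1/f noise), skipping blinks and the continuous carrier.  It
  is used for replicate-heavy statistical checks where preprocessing is
  not the question.

The evoked template is a fixed sequence of Gaussian deflections (P1 ≈
100 ms, N1 ≈ 170 ms, P2 ≈ 250 ms, and a slow positivity around 550 ms)
scaled per channel, zero before 50 ms.  Its absolute shape is deliberately
stylized: only the congruent-minus-incongruent *difference* is calibrated,
because only contrasts are constrained by the emulated results.  Effects
are injected as constant amplitudes over a window, split ±half between the
two condition templates so the grand mean is untouched.  Defaults: P8,
586–889 ms, −1.14 µV for the forward task (from the printed condition
amplitudes 0.18 and 1.32 µV); CP5, 207–290 ms and 471–526 ms, +0.32 µV for
the backward task (0.91 vs 0.59 µV; the second window has no printed
amplitudes of its own and reuses the first window's contrast).  Injection
and the `windowed_amplitude()` read-out use the same inclusive sample
convention, so noiseless round trips recover the injected value exactly —
a deliberate identity that the tests rely on.

The background is spectrally shaped Gaussian noise with slope 1 (amplitude
∝ f^(−1/2)), per-sample standard deviation 10 µV — a realistic magnitude
for band-limited scalp EEG.  Normalization is analytic rather than
empirical (the per-sample variance of the shaped process is known in
closed form), which keeps the noise exactly Gaussian; an empirical
per-stream rescaling would couple samples through the estimated scale and
visibly distort the type-I level of downstream tests.  The default
sampling rate is 250 Hz for tractability; the recording hardware rate of
1000 Hz is available, and all analysis code works on the time axis, never
on raw sample counts, so results are rate-invariant.

What the generator does *not* emulate: stimulus-category structure (faces
vs scenes), per-image valence values, drifting electrode impedances,
muscle or line-noise artifacts, and spatially correlated (volume-conducted)
backgrounds — channels are independent except for the deterministic blink
topography and templates.  Passing tests therefore show that the analysis
machinery is correct and calibrated under the stated model, not that the
pipeline is robust to every pathology of real recordings.

## Preprocessing

The chain is filter → common average reference → ICA blink removal →
epoching → baseline correction → peak-to-peak rejection, and each output
records the applied steps.

* **Filter.**  Zero-phase windowed-sinc FIR (Hamming), 0.1–30 Hz, applied
  by FFT convolution with reflection padding and exact group-delay
  compensation.  Kernel length follows a transition bandwidth of
  `max(0.25·edge, 2) Hz` on the sharper edge (1.65 s at 250 Hz); −6 dB at
  the nominal edges.  A consequence worth stating: a 0.1 Hz high-pass edge
  with a bounded kernel rolls off gently rather than sharply — the
  alternative (a 33 s kernel) buys little for simulated data and is
  configurable by filtering at a higher low edge.
* **ICA.**  FastICA (symmetric decorrelation, tanh contrast), seeded, with
  component count defaulting to the numerical rank.  No ICA implementation
  is available in the environment's R packages, so the algorithm is
  implemented here.  Components whose |Pearson r| with the (filtered,
  re-referenced) Fp1 channel exceeds 0.5 are labelled blinks; the absolute
  value is used because a component's sign is arbitrary.
* **Epochs.**  −100 ms to +1000 ms around target onset, so the −60…+40 ms
  baseline window is interior to the epoch.  Epochs are cut regardless of
  when the button press ended the target display; the analysis window runs
  to 1000 ms.  Events whose window would leave the recording are dropped
  and logged, never truncated.
* **Rejection.**  "±100 µV peak-to-peak" admits two readings; the budget
  is a single parameter (`max − min > budget`), default 200 µV (leaving a
  ±100 µV band), with 100 µV selectable for the stricter reading.  Every
  rejection logs trial, worst channel and value.

## Behavioural statistics

Per participant, the median reaction time of valid congruent and valid
incongruent trials, and their difference (congruent − incongruent).  The
battery on the cohort differences: one-sided Wilcoxon signed-rank
(congruent faster), paired *t*, Cohen's \(d = \bar{x}/s_x\), and a JZS
Bayes factor.  One-sided is the default because the priming hypothesis is
directional; sidedness is always echoed in the result and two-sided is a
flag away.  Zero differences are discarded before ranking; the exact
signed-rank null is used for n ≤ 25 without ties, the normal approximation
with continuity correction otherwise.  The Bayes factor integrates the
noncentral-*t* likelihood against a Cauchy(0, 0.707) prior on the
standardized effect (half-Cauchy for one-sided tests) by adaptive
quadrature; at \(t = -3.48\), \(n = 31\) it returns 22.2 two-sided and
44.4 one-sided, matching the reference implementation it was checked
against.  Holm correction is applied across the per-experiment test
family, and that family definition is the reported one.  Questionnaire
correlations always report Pearson and Spearman side by side — the
parametric/non-parametric discrepancy is itself a finding worth surfacing.

## ERP analysis and window selection

Per-participant condition means, grand means ± SEM, and difference traces
are plain averages; the linearity identity (difference of grand means =
grand mean of differences) is tested.  The running *t*-test computes a
two-sided paired *t* per electrode × timepoint — two-sided because no
direction is assumed for ERP contrasts — with no multiplicity correction,
by design: the procedure generates spatio-temporal hypotheses, it does not
confirm them, and the result object carries `corrected = FALSE`.

Window selection takes, across all electrodes, the longest contiguous run
of p < α.  Contiguity is defined on the sampling grid, but run length is
measured in milliseconds, so selections are comparable across sampling
rates.  Undefined p-values (zero variance across participants) break runs
— the conservative choice.  Ties resolve by earlier onset, then montage
order, and the applied tie-break is recorded.  The topographic summary
takes, per electrode, the *median* p over ±10 ms around the minimum-p time
of the selected window, capped at 0.05.  The source description of this
step is self-contradictory ("averaged resulting in a median"); the median
matches the name of the result, the mean is exposed as an option, and the
choice used is recorded in the output.  The ±10 ms neighbourhood is
anchored at the selected electrode's minimum-p time for *all* electrodes.
Because the global longest-run rule and a per-electrode report can
disagree about the most interesting electrode, the selection object also
carries the per-electrode longest runs.

On null simulations the running t-test flags close to, but measurably
below, 5% of cells (about 4–4.5% in the packaged checks): per-participant
condition counts are random, so participants' difference traces have
unequal variances, and the t-statistic across such heteroscedastic
Gaussians is mildly conservative.  On iid Gaussian differences the level
is exact, and both facts are asserted in the test suite.

## Single-trial decoding

The decoder is a two-layer convolutional network written in vectorised
base R (no deep-learning framework exists in the environment; the network
is small enough that this is a feature, not a compromise — every gradient
is checked against finite differences in the tests).  Layer 1 convolves a
kernel spanning all channels at one timepoint (a learned spatial filter
bank, collapsing the channel axis into 4–8 feature maps); layer 2
convolves 25 samples along time (valid padding, stride 1); dropout 0.5
follows each; a single sigmoid unit classifies.  Input is the 400–700 ms
window (half-open on the sampling grid: 75 samples at 250 Hz, 300 at
1000 Hz), per-channel standardized with training-fold statistics only.

The protocol: classes balanced by seeded subsampling of the majority;
4 folds built per class so every train and test split is exactly 50/50
(per-class counts beyond a multiple of four are dropped, seeded and
logged); the whole CV repeated with 3 seeds governing fold assignment,
weight initialization, shuffling and dropout — 12 accuracies per
participant.  The stated aggregation of fold accuracies is contradictory
("averaged to a median"); per seed the mean of four folds is taken and the
final summary is the mean of all twelve, with the median reported
alongside.  The random search draws 10 specifications uniformly from
activation × filters × optimizer × learning rate × loss, evaluates each
with the same CV, and returns the best with a full leaderboard.  Two
idiosyncrasies are implemented as stated rather than "fixed": an
elementwise softmax hidden activation (applied across the filter axis,
with a note when selected) and a KL-divergence loss on 0/1 labels (zero
gradient on the negative class).  Selecting hyperparameters on the same
folds that produce the reported accuracy is optimistically biased; the
package keeps the faithful protocol and leaves search off in its own
chance-level checks, since those measure the calibration of the CV
protocol, not of the selection step.

Training defaults are 80 epochs with batch size 32 (Adam, Glorot-uniform
initialization, all seeded).  Small simulations may reduce epochs; the
chance-level behaviour of null data is insensitive to this, while
separable data need roughly 40+ epochs at learning rate 1e-2 to saturate.

## Problem sizes in the packaged checks

The test suite chooses simulation sizes that keep each check sharp at
desk scale: schedule statistics use 1000 seeded sessions; noiseless
amplitude recovery is exact at any size; the window-recovery check runs
50 replicate cohorts of 31 participants × 140 trials at the default noise
level (the full 400-trial sessions raise power further but add nothing to
the property being verified); the chance-level decoding check uses 8
participants × 200 trials with 15 training epochs; type-I calibration
uses 10 replicate null cohorts of 12 participants.  All sizes are stated
in the tests themselves.

## Known limitations

* The generator's independence across channels understates the spatial
  correlation of real EEG; ICA on such data is easier than in practice.
* EDF support is not implemented; BrainVision is the only on-disk format.
* The backward task's second CP5 window reuses the first window's
  amplitude for lack of a printed value.
* The FMI coupling construction targets the *sum* score's correlation
  exactly; subscale correlations are attenuated by design.
* No cluster-based permutation correction and no source analysis: both
  are outside the modelled analysis.
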