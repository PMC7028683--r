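---
title: "Methods: pre-impact fall prediction from wearable inertial sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pre-impact fall prediction from wearable inertial sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A fall by an older adult unfolds in roughly 800 milliseconds: the person
loses support, descends, and hits the ground. A classifier that recognizes
the *descent* — after fall initiation but before body–ground impact — leaves
a window of a few hundred milliseconds in which a wearable protective
device, such as an inflatable hip airbag, can still deploy. That is a harder
and more useful target than post-hoc fall *detection*: the alarm must fire
during the fall, from nothing but the motion signals available up to "now".

fallnet frames this as three-class classification of short windows of
inertial data (tri-axial accelerometer in g, tri-axial gyroscope in °/s,
sampled at 200 Hz):

* **0 — non-fall**: ordinary activities of daily living (ADLs),
* **1 — pre-impact fall (alert)**: the descent, after initiation and before
  impact,
* **2 — fall**: impact and the settling that follows.

## Labeling model

Each recording carries a stage annotation of three 0-based sample indices
`pre_impact_start ≤ pre_impact_end ≤ fall_end` delimiting half-open
intervals: `[0, pre_impact_start)` is non-fall, `[pre_impact_start,
pre_impact_end)` is descent, `[pre_impact_end, fall_end)` is impact and
settling. Everything at or beyond `fall_end` is the state *after* the fall
incident — lying on the ground, getting up — and is removed by
`truncate_post_fall()` before any window is cut; that data belongs to
neither class and would only pollute the non-fall class. A pure-ADL trial
sets all three indices to the trial length. Annotations are inputs to the
pipeline, not outputs: the package does not attempt to discover fall onset
from raw signals.

Truncated trials are segmented by `segment_windows()` into overlapping
windows of 256 samples (1.28 s) with starts every `stride` samples; the
window count is `floor((T − 256) / stride) + 1`, and trials shorter than one
window are skipped with a warning rather than padded. Each window gets one
label from `assign_window_label()`. The default rule is **causal**: the
window is labeled by the stage of its final sample, because at inference
time the window's end is the present moment — exactly the deployment
setting. A majority-overlap rule is available as an alternative; its ties
resolve toward the later (more dangerous) stage.

Two windowing parameters deserve comment because they are design choices,
not measurements:

* **Stride.** The library default is 128 samples (50 % overlap). The
  experiment profile in `experiment_config()` uses 64 (75 % overlap):
  descent intervals last only 40–160 samples, and in a small synthetic
  cohort the denser stride keeps every fall trial represented by at least
  one pre-impact window. Stride never changes any individual window's label,
  only how many windows exist.
* **Labeling rule.** The final-sample rule makes the pre-impact class
  strictly causal but also strict: a window whose last sample falls one
  index past `pre_impact_end` is already "fall".

## Model families

Three architectures consume the same 256 × 6 window and emit three softmax
probabilities. All are built from declarative `model_config()` objects and
are pure functions of `(config, seed)`.

* **CNN** — three convolutional blocks (1-D convolution, kernel 3, 64
  channels; batch normalization; ReLU; max pooling kernel 3, stride 2),
  then flatten and two fully connected layers 1920 → 512 → 3. The per-block
  convolution paddings default to (1, 0, 1): with pooling by
  `floor((L − 3) / 2) + 1`, that is the unique padding choice under which
  the block lengths run 256 → 127 → 62 → 30 and the flattened width is
  30 × 64 = 1920, which `shape_trace()` verifies symbolically and
  `observed_shapes()` verifies on a live forward pass.
* **LSTM** — two stacked LSTM layers (hidden width 64) over the raw
  sequence, ReLU and dropout on the final time step's state, then a fully
  connected softmax head. Sizes mirror the recurrent half of the hybrid so
  the comparison is at matched recurrent capacity.
* **ConvLSTM** — the hybrid and the default: four convolutional blocks
  (padding 1 each, lengths 256 → 127 → 63 → 31 → 15) whose feature map is
  fed *as a 15-step sequence* into two stacked LSTM layers with dropout 0.5
  between and after them, then a fully connected head on the last step.
  The defaults (width 64, 4 conv blocks, 2 LSTM layers, dropout 0.5) are
  the winner of a 24-cell hyperparameter sweep over width {32, 64, 128},
  convolutional depth {2, 4}, recurrent depth {2, 4} and dropout
  {0.5, 0.8}.

The recurrent families classify from the final time step, not a temporal
average — again the causal, streaming-deployment reading. Batch
normalization uses batch statistics during training and running averages
(momentum 0.1) at inference. The whole engine is implemented in base R
on top of BLAS matrix products; convolution is evaluated as a sum of
kernel-offset matrix multiplications, which is what makes desk-scale
training practical without any deep-learning framework.

## Training protocol

`train_config()` fixes the protocol: batch size 64, 200 epochs (the
desk-scale experiment profile uses 20), learning rate 0.0005, Adam, and
**focal loss**

$$\mathrm{FL}(p_t) = -\alpha_t (1 - p_t)^{\gamma} \log(p_t),$$

averaged over the batch, where $p_t$ is the predicted probability of the
true class. Sliding windows over mostly-ADL recordings make non-fall
windows overwhelmingly dominant; rather than resampling, the loss
down-weights easy, well-classified examples through $(1-p_t)^\gamma$.
Defaults: $\gamma = 2$ and $\alpha$ = inverse class frequency on the
training windows, normalized to mean 1. With $\gamma = 0$ and $\alpha = 1$
the loss reduces exactly to mean cross-entropy, which the test suite checks
against an independent implementation. Probabilities are clamped at
$10^{-7}$, so the loss is never NaN.

Every epoch records per-class sensitivities on the training set (from the
training passes themselves, the usual learning-curve convention) and on the
evaluation set, plus the evaluation set's one-vs-rest confusion counts.
`select_best_epoch()` then applies the reporting rule: among the three
epochs with the highest *summation sensitivity* (the sum over the three
classes, evaluation set), pick the epoch with the highest non-fall +
pre-impact sum, breaking ties toward the earlier epoch. **This rule peeks
at the test fold** — the fold being evaluated influences which epoch is
reported. It is implemented literally because it is the protocol being
reproduced, and it is flagged here as optimistic; an unbiased variant would
select on a validation split carved out of the training subjects.

## Evaluation

Metrics are one-vs-rest per class: for class $k$, TP are instances of $k$
classified as $k$, FN the remainder of class $k$, TN the other classes not
classified as $k$, FP the other classes wrongly classified as $k$. Then
sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), accuracy =
(TP+TN)/total. A class absent from a test fold yields missing values, never
0 — zeros would silently deflate the means.

Cross-validation is **subject-wise**: `make_subjectwise_folds()` partitions
subjects, not windows. Elderly subjects are randomly divided into five even
groups (15 elderly → five groups of 3), young subjects likewise (23 young →
5/5/5/4/4), and each elderly group is randomly paired with a young group to
form one test fold. No subject appears in two test folds, and
`cross_validate()` asserts at window granularity that no subject leaks
between train and test. This matters because windows from one subject are
strongly correlated; a window-level split would overstate performance.
Reported numbers are macro means over folds. Per-instance latency is timed
at batch size 1 (the streaming scenario) after warm-up passes; absolute
values are hardware-dependent and only within-machine comparisons between
families are meaningful.

## The synthetic cohort

Real fall datasets require an external download and ethics-bound human
recordings, so the package ships a simulator that makes every stage
testable. `simulate_cohort()` generates subjects performing four ADL
templates (stand, walk, sit down, jog) and four fall templates (forward,
backward, lateral, vertical), writing SisFall-dialect text files (integer
ADC readings, 9 channels — the low-range accelerometer is emulated by
clipping the wide-range one) with an annotation CSV.

The signal model is deliberately simple: piecewise kinematic phase
templates, per-subject random effects (gain, cadence factor, gait phase —
drawn once per subject, so subject identity is a real statistical unit and
subject-wise splits are meaningful), and white Gaussian sensor noise
(0.03 g, 3 °/s). A fall trial concatenates a walking prefix, a descent
whose acceleration magnitude reaches a free-fall floor (0.1–0.4 g) by 60 %
of the descent duration while a half-sine gyroscope burst (100–300 °/s)
builds on the template's rotation axis, an impact pulse peaking at 3–6 g,
settling near 1 g in the landing orientation, and a post-fall tail that the
annotation excludes. Annotation indices coincide exactly with the
generative phase switches, so labels are exact by construction.

The defaults guarantee *separability*: a simple threshold rule (smoothed
acceleration magnitude dips below ~0.55 g, followed by a peak above 2 g)
distinguishes simulated falls from ADLs essentially perfectly. That
guarantee is what makes the end-to-end training test meaningful — if the
hybrid model cannot reach high held-out sensitivity on this cohort, the
defect is in the pipeline, not the data. The default desk-scale cohort is
10 subjects (6 young, 4 elderly) × 8 templates × 3 trials = 240 trials,
which trains in minutes on one CPU. Since 4 elderly subjects cannot fill
five folds, the shipped end-to-end check holds out three subjects
explicitly; the five-fold splitter is exercised on larger synthetic
cohorts.

## Limitations

* The simulator is a test harness, not biomechanics. Amplitudes, durations
  and noise levels are design choices; nothing here validates clinical
  performance, and results on synthetic data do not transfer to real falls.
* The epoch-selection rule is optimistic (see above) and is reproduced
  deliberately; numbers selected by it should be read as the protocol's
  numbers, not as unbiased generalization estimates.
* Near-falls and recoveries — the hard negatives of real deployments — are
  not simulated.
* No resampling: recordings must already be at the configured rate.
* Latency numbers are wall-clock on the current machine and meaningful only
  for comparisons within one machine.

## Reproducing an experiment

Every run is driven by one declarative `experiment_config()` (or its YAML
equivalent) and is deterministic given its seeds: `cmd_run()` writes
`report.json`, one learning-curve CSV and one checkpoint per fold, and a
config echo, and two runs with the same configuration produce bit-identical
reports. `cmd_compare()` merges several runs' reports into one
metric × class table with one column per model family.
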