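---
title: "Region-of-interest weighting by reinforcement learning: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-of-interest weighting by reinforcement learning: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(drlroi)
```

## The problem

A convolutional classifier trained on tumor-centered CT crops does not know
that the evidence for a molecular label lives in and around the lesion.  With
small cohorts it happily latches onto background structures — vessels, ribs,
reconstruction artifacts — that carry no class information, and its
generalization suffers accordingly.  `drlroi` implements a two-component
framework that addresses this failure mode: a self-attention residual
classifier, and a reinforcement-learning *generator* that learns to re-weight
the classifier's final feature map so that informative regions are amplified
and background noise suppressed.  The two are trained in alternation, each
frozen while the other learns.

## The classifier

The backbone is a CIFAR-style residual network: a 3x3 stem convolution, three
residual stages of two-convolution blocks (the second and third stage halve
the resolution), one self-attention layer over the final-stage spatial
tokens, global average pooling and a linear two-class head.  Depth is
`2 + 6 * blocks_per_stage`; the full-scale configuration
(`backbone_config()`) uses nine blocks per stage — depth 56 — with channel
plan 64/128/256 on a 128-pixel input, ending in a 256-channel 32 x 32
feature map.

The attention layer treats the final feature map's spatial positions as
tokens.  With `X` the token matrix and learned square maps `WQ`, `WK`, `WV`:
`Q = X WQ`, `K = X WK`, `V = X WV`,
`A = softmax(Q K' / sqrt(d_k))` row-wise, and the attended tokens `A V` are
added residually to `X`.  Every row of `A` sums to one by construction.
Where the attention head sits is a design choice of this package: a single
head over the final-stage tokens, placed
before pooling, because that is where long-range context is cheapest (fewest
tokens) and it leaves all other tensor shapes unchanged.  `d_k` equals the
channel count.  Setting `attention_enabled = FALSE` removes the layer
entirely, giving the plain residual ablation.

Training minimizes softmax cross-entropy — the negative log softmax
probability of the true class, averaged over the batch
(`cross_entropy_loss()`).

All forward and backward passes are implemented in the package (im2col
convolution kernels in C++, everything else in base R), with exact gradients
verified against finite differences in the test suite.

## The agent

The generator is a policy network (256 -> 512 -> 512 -> 256 with a Tanh
output) mapping the classifier's pooled final-stage state to an action
vector, plus a learned per-dimension Gaussian log standard deviation
(initialized at log 0.1).  The critic (256 -> 64 -> 1, LeakyReLU) estimates
the expected reward of a state.  The action `a` becomes multiplicative
weights `w = 1 + a` in (0, 2): in the default *spatial* mode the weight
vector is reshaped to a square grid and bilinearly upsampled over the
feature map, so one weight governs one image region; a *channel* mode (one
weight per channel) is kept as an ablation.  The policy's output layer is
zero-initialized, so the initial deterministic action is exactly zero and
gating starts as the identity.

Episodes are single-step and per batch: the frozen classifier processes a
batch, the batch-mean pooled state is the episode state, one action is
sampled (Gaussian around the pre-Tanh mean, squashed through Tanh, with the
change-of-variables correction in the log density), the gated batch is
classified, and the batch accuracy is compared to a benchmark of 0.9:
above it the reward is +1, at or below it -1.  The advantage is reward
minus the critic's value; the policy maximizes the PPO-Clip surrogate
`mean(min(rho A, clip(rho, 1 - eps, 1 + eps) A))` with clip radius
`eps = 0.2`, several Adam passes per snapshot (default 4); the critic
regresses its value to the reward by mean squared error — the simplest
value estimator consistent with the one-step episode structure.

Two stabilizers matter at small scale; both are documented design choices
of this package:

* **Advantage treatment.** Within an update, advantages are standardized
  only when the batch of episodes carries both reward signs.  When every
  episode returned the same reward there is no information that favors one
  sampled action over another — an ideal baseline would cancel the batch
  exactly — so the advantages are centered instead.  Standardizing a
  constant-reward batch would amplify critic error into full-scale
  advantages, and an uncentered constant negative advantage pushes
  probability mass away from the policy mean until the Tanh saturates (we
  observed exactly this collapse in early experiments).
* **Critic learning rate.** The critic uses a conservative fixed Adam rate
  (`critic_lr = 0.001`) rather than sharing the generator's rate; Adam's
  scale-free steps otherwise overshoot the +/-1 regression targets while
  the state distribution is still moving.

## Alternating training

Each epoch has two phases over freshly shuffled batches.  Phase 1 freezes
the generator: every batch is forwarded with the generator's deterministic
action applied to the final feature map, and the classifier is updated by
momentum SGD (initial learning rate 0.1, weight decay 5e-4).  The gate is
treated as a constant in the backward pass — no gradient flows from the
classification loss into the agent, matching the freeze semantics.  Phase 2
freezes the classifier: batches are forwarded with batch statistics (the
classifier's training-time behavior) but without updating the running
batch-norm buffers, so the classifier remains bit-identical through the
phase; actions are sampled, rewards collected, and the generator and critic
updated by PPO-Clip and MSE.  Using batch statistics here keeps the reward's
accuracy scale aligned with phase-1 training accuracy, which is what places
batch accuracies near the 0.9 benchmark where the reward is informative.
Both learning rates (classifier 0.1, generator 0.01 at full scale)
decay by a factor of 0.1 every 100 epochs; the full-scale protocol trains
600 epochs with batch size 32.  Augmentation, when configured, is applied
to the batches of both phases — it is part of the data pipeline.

Freeze contracts are auditable: `drlroi_fit(trace_freeze = TRUE)` records
checksums of both components at every phase boundary.

`drlroi_fit(warmup_epochs = k)` delays the agent phase for the first `k`
epochs.  The zero-initialized generator gates as the identity until its
first update, so the warm start is exactly classifier-only training; it
lets the classifier reach the accuracy range where the 0.9 benchmark is
informative before the agent starts learning from it.  Warm-starting, or
lowering the RL rate, is the standard remedy for RL-induced instability in
small-sample training, and the package's own sensitivity analysis (below)
motivates both.  The benchmark experiment warms up for 10 of its 60
epochs.

A divergent run (non-finite loss) aborts with a diagnostic rather than
returning a broken model.

## The phantom benchmark

No clinical cohort ships with the package, by design.  The synthetic
phantom (`phantom_config()`, `phantom_cohort()`) emulates the statistical
situation the method targets: two-class, patient-grouped, single-channel
slices in [0,1] where **all** class signal lives inside an elliptical ROI
(a mean-intensity shift `roi_contrast` plus a class-dependent speckle
frequency), while the background carries high-contrast, label-independent
distractor blobs and bars plus Gaussian acquisition noise.  Per-patient
lesion geometry (position jitter, semi-axes) is sampled once per patient;
texture phase and noise are per-slice.  Distractors can recur per patient
(`distractor_layout = "patient"`, emulating fixed surrounding anatomy) or
be drawn fresh per slice (`"slice"`, emulating unstructured clutter).  All
randomness flows from the config seed; identical configs give bit-identical
cohorts.

What the phantom does **not** model: 3-D structure, CT physics (HU
calibration, beam hardening, contrast phases), scanner heterogeneity, or
anatomically plausible backgrounds.  Passing the benchmark therefore shows
that the mechanism works when its premise holds (ROI-only signal,
distracting background); it does not certify performance on real CT.

The benchmark conditions (`phantom_benchmark_config()`) were chosen
during the design of the benchmark and then frozen: the class signal is
carried mainly by the interior speckle texture (amplitude 0.09,
frequencies 4 vs 9 cycles/image) with only a small mean shift (0.03),
against twenty strong per-slice distractors (contrast 0.4-0.7) and noise
sigma 0.15 on 48-pixel slices.  Three properties motivated this regime.
First, the distractors are unmemorizable per-slice noise that demonstrably
costs the classifier training accuracy, so suppressing background regions
genuinely raises batch accuracy — the reward points in the direction of
the mechanism.  (In a background-*memorization* regime the
training-accuracy reward points the other way: patient-specific
backgrounds help training batches while failing on held-out patients.
The `"patient"` distractor layout exists to construct that regime for
ablation studies.)  Second, a texture-borne signal produces spatially
localized convolutional activations inside the ROI for *both* classes, so
class activation maps have something to localize — a pure mean-intensity
shift is a diffuse brightness cue whose CAM evidence is weak, and the
negative class would carry no interior activation at all.  Third, at 48
pixels the depth-8 desk backbone's receptive field (about 31 pixels)
covers a neighborhood rather than the whole image, so spatial gating of
the final feature map has real localization power; at 32 pixels every
final-stage cell effectively sees the entire image and gating cannot
separate ROI from background.

## Desk-scale problem sizes

The package's experiments (`mechanism_experiment()`,
`lr_sensitivity_experiment()`, the acceptance script) run a deliberately
small instance of the framework: 24 patients per class of 3 slices each,
48 x 48 slices, the depth-8 backbone with channel plan 8/16/16 (final
feature map 16 channels at 12 x 12, a 4 x 4 spatial gate), a 64-wide
policy, 60 training epochs (the first 10 as warm start) at batch size 16
with the learning-rate decay every 15 epochs — the same
quarter-of-the-run cadence as the full-scale protocol's 100-of-600 — and
a generator learning rate of 0.003.  These sizes keep one full
RL-vs-baseline replicate around two and a half minutes of CPU time while
preserving every structural element of the full-scale configuration.

The conservative generator rate follows the package's own sensitivity
analysis: `lr_sensitivity_experiment()` runs the full-scale optimizer
recipe (generator rate 0.01) truncated to a short, augmentation-free
protocol in which the classifier is warm-started to near convergence and
then exposed to the agent, against the same protocol with the rate raised
tenfold.  Across seeds the raised rate produces clearly larger
post-warm-up loss variance: the policy mean saturates and the gate
disrupts the converged classifier.  The RL rate is the sensitive training
parameter, and the benchmark protocol responds exactly as such an
analysis prescribes — a lower rate and a warm start.

## Evaluation

Slice probabilities are softmax outputs of the gated forward pass in
evaluation mode; a patient's probability is the arithmetic mean over their
slices — the patient level is the headline result, the slice level is also
reported.  The decision threshold on patient probability is 0.5 — the
natural symmetric choice for a class-balanced validation design.  AUC is
the Mann-Whitney statistic computed from midranks (ties
count one half); its confidence interval uses the DeLong placement-value
variance with a normal approximation, truncated to [0,1] (a subject-level
bootstrap is available by option).  Paired model comparisons use the
DeLong test for correlated AUCs; the z statistic is antisymmetric in its
arguments, identical score sets give p = 1, and a zero-variance nonzero
difference raises an explicit degenerate-case error.  Both the AUC and the
test are validated in the suite against brute-force pair counting, a
Monte-Carlo coverage study, a type-I-error calibration, and an independent
implementation (pROC).

Class activation maps project the output-layer weights back onto the
(gated) final feature map, upsample bilinearly and min-max normalize; the
benchmark's localization statistic asks whether the CAM argmax of correctly
classified validation slices falls inside the ROI mask more often than that
of misclassified slices.

## Numerical conventions

* Pixel coordinates are 0-based row-major; crops are half-open intervals;
  the crop window is centered on the mask centroid rounded to the nearest
  pixel, padded with the image minimum (approximating the dark background
  of CT crops); a mask bounding box exceeding the window preserves the
  tumor boundary and resizes afterwards.  Resizing is bilinear.
* All bilinear resampling (crop resizing, gate upsampling, CAM upsampling)
  uses one align-corners kernel implemented in the package, so tests can
  verify it against hand-computed weights.
* Batch norm uses eps 1e-5 and running-stat momentum 0.1; a trailing batch
  of one sample is dropped (batch statistics are undefined on it).
* Reward boundary: accuracy exactly 0.9 counts as *not* exceeding the
  benchmark and yields -1.
* Checksums for artifact stamping and freeze audits are dual polynomial
  rolling hashes modulo 2^31 - 1, exact in double arithmetic.
* He-normal initialization for convolutions; the policy's output layer is
  zero-initialized (identity gating at the start, an unbiased starting
  point for the agent).

## Known limitations

* Training is CPU-bound R/C++; the full-scale configuration (depth 56,
  128-pixel inputs, 600 epochs) is expressible but not practical to train
  on one CPU — the package's empirical claims are desk-scale.
* The binary +/-1 reward with a fixed 0.9 benchmark is informative only
  while batch accuracies straddle the benchmark; away from that regime the
  agent learns slowly (uniform-reward episodes are, correctly, treated as
  uninformative).
* The one-step episode formulation ignores any sequential structure across
  batches; there is no discounting and no entropy bonus by default.
* Patient-level aggregation assumes slices are exchangeable within a
  patient.
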