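# drlroi

Reinforcement-learning-guided region-of-interest weighting for two-class
medical image cohorts.

## The problem

Convolutional classifiers trained on small tumor-centered CT cohorts are
easily distracted: high-contrast background structures that carry no class
information attract the model's attention and degrade its generalization.
`drlroi` implements a framework that counters this directly.  A
self-attention residual network classifies the slices; a *generator* agent,
trained by reinforcement learning, observes the classifier's pooled
final-stage feature state and emits a weight map that multiplicatively
re-scales the final feature map — amplifying regions of interest,
suppressing background — before pooling and classification.

The two components train in alternation.  With the generator frozen, the
classifier minimizes softmax cross-entropy on gated features
(momentum SGD, initial learning rate 0.1, weight decay 5e-4).  With the
classifier frozen, each batch becomes a one-step episode: an action
`a ∈ (-1,1)^d` is sampled from a Tanh-squashed Gaussian policy, applied as
weights `w = 1 + a`, and rewarded `+1` if the gated batch accuracy exceeds
0.9 and `-1` otherwise; the policy maximizes the PPO-Clip surrogate

    J(θ) = E[ min( ρ A,  clip(ρ, 1-ε, 1+ε) A ) ],   ρ = p_θ(a|s) / p_θk(a|s)

with clip radius ε = 0.2 and advantage `A = r − V(s)` from a small critic.
Both learning rates decay by 0.1 on a fixed epoch schedule.  Evaluation is
patient-level: a patient's probability is the mean over their slices;
reported metrics are accuracy, sensitivity, specificity, and ROC/AUC with
DeLong confidence intervals and the paired DeLong test between models.

Because no clinical cohort can ship with the package, it includes a
synthetic tumor-phantom generator whose class signal lives *only* inside an
elliptical ROI (mean-intensity shift plus class-dependent speckle
frequency) while the background carries heavy label-independent
distractors — the exact failure mode the mechanism targets, with
ground-truth masks to verify localization.

The networks (convolutions, batch norm, self-attention, the Gaussian-Tanh
policy) and all gradients are implemented in the package itself — C++
convolution kernels, base-R everything else — so no external deep-learning
runtime is needed.

## A worked example

```r
library(drlroi)

# a small phantom cohort: 8 patients per class, 2 slices each
cfg <- phantom_config(n_patients_per_class = 8, slices_per_patient = 2,
                      image_size = 32, roi_radius_range = c(5, 8),
                      background_distractor_count = 6, noise_sigma = 0.08,
                      roi_center_jitter = 0.08, seed = 1)
cohort <- preprocess_cohort(phantom_cohort(cfg), window = 32)
split <- split_cohort(cohort, n_val_per_class = 2, seed = 1)

fit <- drlroi_fit(
  split$train,
  backbone = backbone_config(stem_channels = 4, stage_channels = c(4, 8, 16),
                             blocks_per_stage = 1, input_size = 32),
  rl = ppo_config(hidden = c(16, 16)),
  train = train_config(epochs = 5, batch_size = 8, seed = 1))
fit
#> RL-weighted residual classifier
#>   backbone: depth 8, channels 4/8/16, input 32x32, attention on
#>   RL gating: on (spatial mode)
#>   trained 5 epochs; final loss 0.6029, train accuracy 0.708

eval_report(fit, split$val)
#> patient-level evaluation (threshold 0.5 )
#>   accuracy 0.500  sensitivity 1.000  specificity 0.000
#>   AUC 1.000  (95% CI 0.000-1.000)
#> slice-level AUC 1.000 over 8 slices
```

The fit object carries the trained classifier, generator and critic, the
per-epoch history (`fit$history`: loss, training accuracy, reward rate,
learning rates), and standard methods: `predict()` (slice- or
patient-level probabilities), `plot()` (training curves), `summary()`,
plus `drlroi_cam()` for class-activation-map overlays and
`drlroi_checkpoint()` / `drlroi_restore()` for bit-exact persistence.
At this toy scale the four validation patients are ranked perfectly
(AUC 1.0) while the five-epoch model's probabilities all still sit above
the 0.5 threshold (specificity 0); the degenerate-variance AUC interval is
reported at its widest, a warning the package makes explicit.  The full-scale
configuration (`backbone_config()` defaults: depth 56, 128-pixel input,
256-channel feature map) is the same code with bigger numbers.

The headline experiment of the package — RL-gated model versus the
identically trained no-RL baseline over five seeds, with the CAM
localization statistic — is one call:

```r
mechanism_experiment(seeds = 1:5, verbose = TRUE)
```

A command-line front end wraps the same functions
(`inst/scripts/drlroi`): `drlroi generate|train|evaluate|explain --config
<yaml>` with dot-path `--override` flags; a minimal configuration ships in
`inst/extdata/smoke.yaml`.

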