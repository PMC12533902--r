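---
title: "Methods: multi-modal cardiac diagnosis and guideline-constrained nutrition recommendation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-modal cardiac diagnosis and guideline-constrained nutrition recommendation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cardiopipe` implements a desk-scale clinical decision-support pipeline for
cardiovascular diagnostics: per-modality preprocessing, multi-feature
extraction, hybrid feature selection, a two-pathway deep classifier, a
nine-metric evaluation report, and a guideline-constrained nutrition
recommendation environment optimized with proximal policy optimization
(PPO). Everything runs on synthetic data with known ground truth, so every
stage is testable without downloads. This vignette records the models, the
tunable parameters, the numerical choices, and what the synthetic
experiments do and do not show.

## Synthetic data: the study conditions

The generators define the experimental conditions and carry their ground
truth in attributes; they are first-class, tested code.

**ECG beats** (`gen_ecg_beats`). A beat of 187 samples at 125 Hz (the
common single-beat CSV dialect) is a sum of three Gaussian bumps — P wave,
QRS complex, T wave — plus white noise (`noise_sd`, default 0.05 in
amplitude units where the R peak is ~1) and a low-frequency baseline-wander
sinusoid whose amplitude scales with the noise level so that a noiseless
call is fully deterministic. Class templates perturb R amplitude, QRS width
and T-wave shape by `class_sep` times fixed per-class offsets; `class_sep`
is a separability dial that tests exploit (a linear classifier's training
accuracy rises monotonically with it). The QRS "width" of a class is
defined as the distance between the 20%-of-peak crossings of its QRS bump —
the same convention the duration detector uses — so the generator's truth
and the detector's estimate are commensurable. What this emulates: the
gross morphology classes of a beat-level arrhythmia dataset. What it does
not: real beat-to-beat variability, pathological waveform families, or
electrode artifacts; passing tests show algorithmic correctness, not
clinical performance.

**Cardiac phantoms** (`gen_cardiac_images`). Short-axis geometric
phantoms: a bright elliptical annulus ("myocardium") around a darker
cavity, textured with smoothed noise, quantized to 256 gray levels. Class
controls wall-thickness fraction, cavity eccentricity and overall size
(healthy / thick-walled / dilated thin-walled). Masks mark the annulus.
These are geometric, not anatomical; they exist so shape and texture
features have known targets (e.g. the cavity eccentricity recovered from
mask moments matches the configured value within 0.05).

**Tabular records** (`gen_patient_records`). Thirteen clinically scaled
columns using the standard 13-predictor schema names, a binary target drawn
from a logistic model over only the `n_signal` signal features
(coefficients recorded), independent noise features, and injected missing
cells plus mean ± 6 sd outliers at stated fractions. The 6 sd magnitude
guarantees the z-score rule (threshold 3) trips on every injected cell.
**Wearable metadata** (`gen_metadata`) adds continuous wearable summaries,
a categorical activity level, and exact duplicate rows at 5% for the
cleaning stage.

**Food database and profiles** (`gen_food_db`, `gen_patient_profile`).
Twenty items drawn from five serving archetypes (balanced, high-fiber,
snack, indulgent/fried, fish) with realistic per-serving nutrient means and
~15% multiplicative jitter over five tracked nutrients (sodium mg,
saturated fat g, fiber g, calories kcal, cholesterol mg). The archetype mix
is half balanced so that a five-serving day near the guideline targets
exists — a property the recommendation experiments rely on. Profiles encode
one-day guideline data (bounds, targets with a 15% tolerance band, hard
maxima, risk weights): the healthy profile's targets
(2000 mg sodium, 12 g saturated fat, 28 g fiber, 2000 kcal, 270 mg
cholesterol) are defaults inspired by the major dietary guidelines, not
values any specific document prints; hypertension tightens sodium and
weights it 5x in the risk term; dyslipidemia weights cholesterol/saturated
fat and forbids fried items.

## Preprocessing

*Wavelet denoising.* The continuous wavelet transform that motivates the
denoising stage is realized, as is standard, by a discrete decomposition: a
periodized orthogonal filter bank (Daubechies-4, level 3 by default). With
orthonormal filters the periodized analysis operator is orthogonal, so
synthesis is its adjoint and round-trips are exact to machine precision
(tested at ~1e-10). Signals whose length is not a multiple of `2^level` are
symmetrically extended and truncated after reconstruction. Detail
coefficients are shrunk with the universal threshold
`sigma * sqrt(2 log n)`, `sigma = median(|d1|)/0.6745`. The default rule is
**hard** thresholding: measured on the synthetic beats at an exact 5 dB
input SNR, soft shrinkage's constant bias attenuates the few large QRS
coefficients and yields ~10 dB output, while hard thresholding yields
~11.3-11.8 dB; soft remains one flag away. This is the one place the
package's default departs from the more common textbook soft rule, and it
is a measured, signal-class-specific choice.

*Degenerate min-max ranges* map to the lower bound with a warning instead
of erroring: constant columns occur in small synthetic tables and should
not abort a pipeline. *Histogram equalization* uses half-up rounding of
`cdf * (levels - 1)` so the mapping is platform-stable (R's default
round-half-even would differ at exact .5 ties). *Bilinear resizing* uses
align-corners sampling so an identity resize is exact. *Z-score outliers*
use the population standard deviation (consistent with the moment
formulas below); flagged values are reported and, in the pipeline,
winsorized to mu ± 3 sigma rather than dropped. *Metadata cleaning*
removes exact duplicates over all columns (no fuzzy matching), encodes
categoricals by first appearance, and records every fitted statistic so
train-fitted transforms replay unchanged on held-out data — the package
always fits normalization on training data only, a leakage guard applied
as standard practice.

## Feature extraction

ECG features per beat: the five statistical moments (population formulas,
divisor n; kurtosis is excess kurtosis with the −3 correction), QRS
duration, three periodogram band powers (0-5, 5-15, 15-40 Hz), and an SDNN
proxy. True normal-to-normal intervals do not exist on single-beat rows, so
the proxy is the population SD of within-beat peak intervals and is
documented as such; `hrv_sdnn` itself takes genuine interval sequences.
The QRS detector thresholds at theta = 0.2 of the peak absolute amplitude
and expands from the global peak — the simplest defensible detector for
single-beat inputs; the duration counts the supra-threshold samples, so a
10-sample rectangular pulse at 125 Hz reads 80 ms. The periodogram is
`|DFT|^2/(N fs)` (power per Hz, Parseval-consistent); a flag restores the
un-squared magnitude variant for comparison.

Image features: circularity `4 pi A / p^2` with the perimeter from a
Moore-neighbor boundary trace (diagonal steps weight sqrt(2); a rasterized
r = 30 disk scores ~0.906), bounding-box aspect ratio, moment-ellipse
eccentricity, GLCM statistics (defaults: distance 1, four angles, 16
uniform levels, symmetrized, normalized; natural-log entropy with
`0 log 0 = 0`; degenerate correlation defined as 1), and an LBP histogram
(radius 1, 8 neighbors starting east going counter-clockwise, border
excluded, `s(0) = 1`), pooled to energy/entropy in the assembled schema.

Tabular/metadata features: min-max-scaled predictors passed through, plus
per-row moment augmentation.

## Hybrid feature selection

ReliefF with k = 10 neighbors (default: all instances in deterministic
order; seeded subsampling optional), L1 distances on internally
min-max-scaled features, misses weighted by class prior, and learning rate
`1/m` so weights are averages. The classical orientation (misses far and
hits near give high weight) is the default; the opposite printed
orientation is available via `literal_sign = TRUE`. Pearson correlations
are taken against the integer-coded label (a caveat for multi-class
targets, where the coding imposes an order); constant features get
correlation 0 with a warning. Both signals are rescaled to [0, 1]
(|correlation| first) and combined as
`alpha * relieff + (1 - alpha) * |pearson|` with alpha = 0.5 by default;
ranks break ties by feature index. The brute-force neighbor-search oracle
in the test suite pins the vectorized implementation exactly on all small
fixtures; on the planted-truth generator (n = 2000, 5 signal + 8 noise
features) the top-5 contains at least 4 planted features in at least 15 of
20 replicates.

## The two-pathway classifier

Pathway 1: conv1d(32, kernel 3) → maxpool(2) → dropout(0.5) → conv1d(64) →
maxpool(2) → inception block (parallel 1/3/5 kernels plus a pooled 1x1
branch, 16 channels each, channel-concatenated) → LSTM(64), last hidden
state. Pathway 2 (the angular-feature branch): conv1d(128) → ReLU →
maxpool(2) → batch norm → flatten. Both outputs concatenate into a
128 → 64 fully connected head with dropout and a softmax over classes.
Kernel 3, pool 2, branch width 16, the FC sizes, Adam at 1e-3, batch 32 and
20 epochs are exposed defaults. The model is instantiated per modality on
its 1-D input — raw denoised beats for ECG, selected feature vectors
otherwise (zero-padded to the minimal admissible length when a top-k
selection is shorter than the pooling chain allows); no cross-modal fusion
layer exists because evaluation is per-dataset. The LSTM consumes the
inception block's output positions as time steps.

The network core is authored in-package (no deep-learning framework is a
dependency): vectorized conv1d via im2col, pooling with argmax caches,
inverted dropout, batch norm with running statistics, full BPTT through the
LSTM, and Adam with folded bias correction. Every layer's analytic gradient
is checked against central finite differences in the test suite — this is
the load-bearing correctness argument for the whole training stack.
Training is fully seeded (initialization, shuffling, dropout), so repeated
runs are bit-identical. Early stopping at epoch-training accuracy 0.98 is
on by default; with 50% dropout the per-epoch training accuracy saturates
just below 0.99 even on cleanly separable data, so the conventional 0.995
would never trigger. At the reference conditions (5 classes, 500/class
train, 100/class test, seed fixed) the model reaches ≥ 0.95 held-out
accuracy within its 20-epoch budget, typically stopping after ~6 epochs.

Splitting is stratified to within one sample per class; k-fold
cross-validation rotates the fold counter across classes so no fold is
empty even at leave-one-out, stores all out-of-fold predictions, and its
pooled accuracy equals the fold-size-weighted mean of fold accuracies
exactly — the bookkeeping identity the harness tests assert at 1e-12.

## The nine-metric report

Accuracy, precision, recall, F1, Jaccard (macro by default, micro and
weighted available, and the mode is recorded in the report), the multiclass
Matthews correlation from the confusion matrix, Cohen's kappa, Hamming loss
(equal to 1 − accuracy for single-label tasks, asserted as an invariant),
and R² computed literally on the integer-coded labels. R² on class labels
is statistically odd — it depends on the arbitrary integer coding — but it
is part of the reported battery and is implemented as printed, with this
caveat recorded. Degenerate cases: empty per-class denominators contribute
0; a single-class input warns and sets the chance-corrected statistics
to 0; constant true labels define R² as 1 for a perfect prediction and 0
otherwise.

## The nutrition decision process

A one-day episode has `horizon = 5` meal slots. The state holds the
profile (age, BMI, model-predicted risk, preference tags, exclusions,
guideline data), the cumulative nutrient intake, the step index and the
choice history. The feasible-action mask removes items that would push any
nutrient above its upper bound, excluded items, and items carrying a
forbidden tag; masking is the caller's obligation at step time, and calling
with an infeasible action is a contract violation, not a recoverable state.
The guideline *lower* bounds are enforced terminally — a per-step lower
bound would make every first step infeasible since no single serving meets
a daily minimum — via a quadratic shortfall penalty added to the adherence
component at episode end. An empty feasible set terminates the episode with
an `infeasible` flag rather than an exception.

The reward is `alpha*adherence + beta*risk + gamma*preference +
delta*diversity + eta*cost` with defaults 1, 1, 0.5, 0.3, 0.1 and inner
coefficients lambda_viol = 1 (preference violation), rho = 0.5 (per
repetition), kappa = 0.05 (per currency unit). Two design choices matter:

1. **Normalization.** Inside the environment all nutrient quantities are
   divided by the profile's target vector, so the five components are
   commensurate regardless of physical units (milligrams of sodium would
   otherwise dwarf grams of fat by four orders of magnitude in the
   quadratic terms). The standalone term functions keep raw units.
2. **Proration.** The adherence term compares cumulative intake to targets
   literally; applied per step against full-day targets it would penalize
   any policy at early steps regardless of quality. By default the
   environment prorates the targets by episode progress `(t+1)/horizon`
   (tolerances stay at their full-day width), so an on-track policy scores
   zero throughout; `prorate_adherence = FALSE` restores the literal
   comparison. The risk term is not prorated: exceeding a full-day hard
   maximum mid-day is genuinely bad.

## PPO

Standard clipped-surrogate PPO with generalized advantage estimation:
epsilon = 0.2, entropy coefficient 0.01, value coefficient 0.5,
gamma = 0.99, lambda = 0.95, Adam at 3e-4, 4 epochs over each rollout in
minibatches of 64, advantages normalized per update. The actor-critic is a
shared two-layer tanh trunk (64 units) with linear policy and value heads.
Masking is realized as −Inf logits before the softmax, so infeasible
actions have exactly zero sampling probability and the entropy is taken
over feasible actions only; the training loop additionally counts
upper-bound violations (the count is asserted to be zero — the mask
guarantee). GAE uses the standard backward recursion and is pinned to a
double-loop evaluation of the defining series at 1e-12. The PPO gradient
(clipped surrogate, entropy and value terms through the shared trunk) is
finite-difference-checked like the supervised network.

The state featurization — profile scalars, fractional intake `c/u`,
episode progress, and a per-item already-chosen indicator — is a design
choice the method itself does not dictate. The reference experiment (20
items, horizon 5, 200 updates of 128 steps, five seeds, ~1 minute per
seed) yields zero bound violations, a final mean adherence penalty above
−0.05 on the normalized scale (near-target intake), and a mean episode
reward whose 20-update window means are nondecreasing in at least 80% of
adjacent comparisons; learning curves are summarized in 20-update windows
(a tenth of the run) because episode rewards at a 128-step rollout average
only ~25 episodes and are noisy at finer resolution. Greedy decoding
(`recommend`) emits the plan, nutrient totals, lower-bound shortfalls and
reward components. Portion sizes are not modeled — actions are discrete
servings; portion scaling would multiply the nutrient vector and is noted
as an extension.

## Problem sizes and determinism

The shipped experiments use: 2,500/500 train/test beats for the
classifier; 50 replicates for denoising; 20 replicates of n = 2000 for
selection recovery; five 200-update PPO seeds; a 90-beat set for the CV
harness. These sizes were chosen so the full suite demonstrates every
claim at desk scale on a single CPU. Every stochastic component consumes
an explicit seed, and a global seed derives per-stage seeds
deterministically; generators restore the caller's RNG state.

## Known limitations

Synthetic generators are deliberately simple; no claim transfers to real
ECG, MRI or clinical-record data. The classifier is trained per modality
with no cross-modal fusion. The nutrition environment tracks five
nutrients over one day with discrete servings and no portion scaling. No
statistical significance machinery (the evaluation reports point metrics
and fold dispersion only), no ROC/AUC, no record linkage beyond exact
duplicates, and no date handling beyond ISO-8601.
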