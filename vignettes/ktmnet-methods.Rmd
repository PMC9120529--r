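---
title: "Multitask staging and MMSE trajectory prediction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multitask staging and MMSE trajectory prediction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ktmnet)
```

## The problem

Disease progression in Alzheimer's cohorts is tracked through two coupled
outcomes: the categorical stage a subject reaches (AD, MCI that converts to
AD within 24 months, MCI that remains stable, cognitively normal) and the
numerical trajectory of cognitive screening scores, here the Mini-Mental
State Examination (MMSE, an integer 0–30 scale) at baseline and at 6, 12
and 24 months. Both outcomes are predicted from the same baseline
measurements — MRI volumetrics, PET uptake values, CSF analytes, cognitive
test batteries and risk factors — so a single network that learns both
tasks jointly can exploit their shared structure. `ktmnet` implements such
a multitask network together with the preprocessing, synthetic-cohort
simulation, nested cross-validation, evaluation and ablation machinery
needed to study it end to end without access to any restricted clinical
data.

## The network

Inputs are 36 tabular features in five modality blocks (7 MRI, 3 PET, 19
cognitive, 3 CSF, 4 risk factors; see `default_schema()`). The stages are:

1. **Modality encoders.** Each block of width $n$ passes through two fully
   connected layers of widths $2n$ and $n$ with identity activation — a
   per-modality linear re-representation that lets the optimizer re-weight
   features inside a modality before any cross-modality mixing.
2. **Fusion.** The encoded blocks are concatenated in schema order
   (width 36).
3. **Gaussian kernelization.** A layer of 100 radial-basis units, unit $j$
   emitting $\exp(-\lVert x - c_j\rVert^2 / 2\sigma_j^2)$ with learnable
   center $c_j$ and learnable bandwidth $\sigma_j > 0$. Bandwidth
   positivity is guaranteed by a softplus reparameterization. Centers are
   initialized from a standard Gaussian; bandwidths start at $\sqrt{d}$
   (with $d = 36$ the fused width) because squared distances between
   standardized $d$-dimensional points concentrate near $2d$ — starting at
   $\sigma = 1$ would drive every unit to $e^{-d}$, numerically zero, and
   the whole trunk would be born dead. Outputs lie in $(0, 1]$.
4. **Tensorization.** The 100-vector is reshaped row-major to a
   $10 \times 10$ map (`tensorize()`), then filtered by two stride-1,
   same-padding $3\times3$ convolution branches with dilation rates 1
   and 2, 10 kernels each and linear activation, concatenated along depth
   to a $10 \times 10 \times 20$ tensor. At stride 1 a transposed
   convolution spans exactly the linear maps of an ordinary convolution
   with a spatially flipped kernel, so the branches are implemented with a
   single dilated-convolution primitive; the distinction is a
   reparameterization of the same family.
5. **Feature extraction.** One convolution with 64 filters, ReLU, and
   dropout 0.10, flattened to the shared representation. The default
   kernel is $3 \times 3$ with valid padding, giving a flatten width of
   $8 \cdot 8 \cdot 64 = 4096$, on which the head dimensions depend. A
   $4 \times 4$ kernel remains configurable (`fe_kernel_size`), flattening
   to $7 \cdot 7 \cdot 64 = 3136$; the two choices cannot both be
   satisfied simultaneously, and the 4096-wide representation is treated
   as the defining one.
6. **Heads.** Two fully connected output layers: four ReLU units for the
   MMSE at the four timepoints (predictions are therefore non-negative)
   and four softmax units for the class probabilities. Both carry an L1
   weight penalty (`l1_coeff`, default $10^{-4}$). An optional shared
   dense ReLU layer between the flatten and the heads is available with
   width from $\{256, 128, 64, 32, 16, 8\}$; the default is none, which
   keeps the architecture minimal and, empirically, protects the
   regression head (see *Operating point*).

Dropout (rate 0.10) is applied at three points during training only: after
the Gaussian layer, after the feature-extraction ReLU, and after the
flatten. The network consumes standardized features; on raw measurement
scales the Gaussian layer underflows, which is why z-scoring is part of the
pipeline contract rather than a cosmetic step.

All forward and backward passes are implemented directly in R matrix code
(im2col gathers plus GEMMs for the convolutions); the analytical gradients
of every stage, including the RBF centers and bandwidths, are verified
against central finite differences in the test suite.

## Objective and training

The joint loss is

$$\mathrm{Loss} = \alpha \cdot \mathrm{MSE}(y_r, \hat y_r)
  + \beta \cdot \mathrm{CE}(y_c, \hat y_c)$$

with MSE averaged over all subject-timepoint residuals (keeping $\alpha$
comparable across designs with different numbers of timepoints) and CE the
categorical cross-entropy of the 4-way softmax, probabilities clamped to
$[10^{-7}, 1 - 10^{-7}]$. Only the ratio $\beta/\alpha$ matters, so
$\alpha$ is fixed at 1 and $\beta$ is the searched hyperparameter over
$\{10, 20, 200\}$. The L1 penalties of the head weights are added during
training.

Optimization is Adam (learning rate $10^{-3}$, moment decays 0.9/0.999),
mini-batches of 150 with per-epoch reshuffling, at most 200 epochs, early
stopping when the validation joint loss fails to improve for 30 consecutive
epochs, and restoration of the best-validation weights (without
restoration, a run that stops on patience would return a degraded model).
One initialization choice departs from the all-zero bias convention: the
regression head's output biases start at the training-set target means.
MMSE targets are trained on their raw 0–30 scale, and Adam's per-parameter
step bound means a zero-initialized output would spend a large share of
the epoch budget climbing a known offset before learning anything
subject-specific; starting at the marginal means removes that dead phase
without touching the model family.
All stochastic pieces — initialization, shuffling, dropout — run off one
seeded RNG stream, so identical configurations reproduce identical
histories and weights bit for bit.

The evaluation protocol is nested: a stratified 15% of subjects is reserved
for hyperparameter search by 3-fold cross-validation (grid = $\beta$ ×
head width; the winning cell minimizes mean validation loss, ties broken by
lower variance, then smaller width); the remaining 85% undergoes stratified
10-fold cross-validation, each fold training with a further stratified 10%
inner holdout for early stopping and z-scoring statistics fit on the
training portion only. Fold membership is a pure function of subject ids
and the plan seed, so variant comparisons on the same plan are paired.
One hyperparameter set, chosen once on the search pool, is reused across
all main folds.

## Synthetic cohorts

The generator (`synthetic_spec()`, `generate_cohort()`) emulates the
structure of the 1,117-subject multimodal cohort this class of model is
typically developed on:

* **Class mixture.** Proportions 157/191/441/328 for AD / MCI-C / MCI-NC /
  CN, apportioned by largest remainder so counts are deterministic.
* **Baseline MMSE.** Class-conditional Gaussians with means 23.24, 27.23,
  28.30, 29.15 and sds 1.96, 1.75, 1.59, 1.01. Observed scores are
  integer-rounded and clipped to $[0, 30]$; because the ceiling at 30
  truncates the upper tail for high-scoring classes, the *latent* class
  means are calibrated by root-finding on the exact discretized
  expectation so that the *observed* means match the targets.
* **Trajectories.** Each subject's latent baseline declines linearly in
  time to $b(1 - f)$ at month 24, with $f$ = 0.13 for AD, 0.127 for MCI
  converters, 0.01 for stable MCI and 0 for controls, observed at every
  visit with Gaussian noise. The default noise sd of 2 points sits at the
  upper end of published short-interval MMSE retest variability in
  impaired populations; it is deliberately conservative so that regression
  performance is judged against a non-trivial noise floor.
* **Features.** Class-conditional Gaussians with equicorrelation 0.3
  inside each modality block, class mean shifts of magnitude
  `feature_effect` along tiled Hadamard directions (all class pairs
  equally separated), and per-class dispersion scales (1.35, 1.15, 1.00,
  0.85) reflecting the larger biomarker spread of more impaired groups —
  which also makes the optimal decision boundary quadratic, so a linear
  classifier cannot saturate the problem. Draws are mapped affinely onto
  plausible measurement units (CSF analytes in pg/mL, volumes in mm³, …)
  so simulated CSVs exercise the analyte range filters meaningfully;
  z-scoring makes the mapping invisible to the network.
* **Separability oracle.** `bayes_accuracy()` classifies generated
  features with the true class-conditional densities — the ceiling for any
  classifier on these cohorts. On a 20,000-subject draw the oracle gives
  accuracy 0.875 at the default `feature_effect = 0.55` and 0.900 at
  0.62; the latter value is used wherever a strongly separable cohort is
  required.

The generator does **not** emulate: discrete covariates (sex and APOE4 are
continuous here), cross-modality correlation beyond what class membership
induces, missingness patterns, or any coupling between a subject's features
and their within-class MMSE level. That last simplification bounds the
achievable regression error from below at roughly
$\sqrt{\mathrm{noise}^2 + \overline{\mathrm{sd}^2_{\text{class}}}} \approx 2.5$
MMSE points; passing tests therefore demonstrate that the pipeline learns
the class-conditional structure, not that it would attain any particular
error on real clinical data.

## Preprocessing

Mirroring standard practice for this kind of cohort table: subjects with
any missing MMSE, label or feature are excluded (no imputation); CSF total
tau outside the closed interval [80, 1300] is excluded (bounds for other
analytes are configurable but not invented); the near-proxy clinical scores
ADAS11, ADAS13, MoCA, CDR and CDRSB are dropped as label/target leakage —
the union of the two plausible drop lists, the conservative anti-leakage
choice; and features are z-scored with training-partition statistics only.
MMSE is a regression target and never an input feature.

## Operating point and scaled-down study sizes

Grid evaluation on separable synthetic cohorts reproduces the see-saw the
multitask design is known for: pushing $\beta$ up favours the classifier
at the regression head's expense and vice versa. The operating point used
throughout the bundled evaluation — $\alpha = 1$, $\beta = 20$, with a
64-unit shared head layer — was chosen from the two searched grids as the
cell that keeps both tasks healthy (the hidden layer speeds the
classifier's convergence within the early-stopping window; the
mean-initialized regression bias keeps the extra depth from starving the
regression head). `network_config()` itself defaults to no hidden layer,
the minimal architecture; both knobs remain searchable through
`hyperparameter_search()`.

For desk-scale reproducibility the bundled evaluation uses 600-subject
cohorts, `feature_effect = 0.62`, 3-fold cross-validation with a 10% inner
validation split, and a 150-epoch cap with patience 30 — sizes chosen so
the full study (three seeds, full model plus ablation, paired folds) runs
on a single CPU in minutes while leaving clear margins on the properties
being checked. Generator calibration checks use 5,000 subjects.

## Numerical choices

* Probability clamping at $10^{-7}$ before logarithms.
* Softplus bandwidth reparameterization; squared distances floored at 0
  against rounding.
* Argmax label decisions break ties toward the lowest index in the fixed
  class order AD, MCI-C, MCI-NC, CN.
* One-vs-rest AUC uses average ranks, i.e. the midpoint tie convention of
  the Mann–Whitney statistic, equal to trapezoidal ROC integration.
* Per-fold metrics undefined in a fold (a class absent, a constant
  prediction vector) are excluded from aggregates and counted, never
  zero-filled. Paired t-tests with zero-variance differences are flagged
  degenerate with p forced to 1 (no difference) or 0 (constant non-zero
  difference) rather than erroring.
* Cross-validation aggregates are mean ± sample sd across folds; the
  confusion matrix is summed element-wise over folds.
* Constant features standardize to 0 with scale 1 and a warning.

## Known limitations

Early stopping monitors the joint validation loss, which the (faster
converging) regression term dominates at $\beta = 20$; runs can therefore
halt while the classifier is still improving slowly, one more face of the
task trade-off. The generator leaves a subject's within-class MMSE level
statistically independent of their features, so per-timepoint correlations
on synthetic cohorts are structurally modest (the class signal is the only
shared information) even when RMSE sits near its floor. The CLI checkpoint
format is R's native RDS; it is a runtime artifact, not an interchange
format.
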