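# ktmnet

Joint modelling of Alzheimer's disease progression from multimodal tabular
data: one network, two tasks. `ktmnet` classifies subjects into the four
24-month outcome groups — AD, MCI converter (MCI-C), MCI non-converter
(MCI-NC), cognitively normal (CN) — and simultaneously predicts their
Mini-Mental State Examination (MMSE) scores at baseline, 6, 12 and 24
months, all from baseline MRI, PET, CSF, cognitive-test and risk-factor
features. It is aimed at researchers studying multitask disease-progression
models who need a fully inspectable, dependency-light implementation that
runs anywhere R runs — including the network itself, which is implemented
in plain R matrix code with hand-derived, finite-difference-verified
gradients.

## The model

Five modality blocks $x_{m_1}, \dots, x_{m_5}$ (36 features in total) are
encoded by per-modality linear layers ($n \to 2n \to n$), fused by
concatenation, and kernelized by 100 Gaussian radial-basis units

$$z_j = \exp\!\left(-\frac{\lVert x - c_j \rVert^2}{2\sigma_j^2}\right),$$

with learnable centers $c_j$ and bandwidths $\sigma_j$. The 100-vector is
reshaped row-major into a $10\times10$ map, filtered by two stride-1
dilated convolution branches (rates 1 and 2, 10 kernels each) into a
$10\times10\times20$ tensor, passed through a 64-filter ReLU convolution
and flattened to a 4096-wide shared representation feeding two heads: a
4-unit ReLU regression head $\hat y_r$ (MMSE at four timepoints) and a
4-unit softmax classification head $\hat y_c$. Training minimizes

$$\mathrm{Loss} = \alpha\,\mathrm{MSE}(y_r,\hat y_r)
  + \beta\,\mathrm{CE}(y_c,\hat y_c) + \lambda_1 \lVert W_{\text{heads}}\rVert_1$$

with Adam, early stopping on a validation split, and a nested
stratified protocol (15% hyperparameter pool with 3-fold search over
$\beta \in \{10,20,200\}$ and head widths, 10-fold cross-validation on the
rest). A calibrated synthetic-cohort generator reproduces the class
mixture, baseline MMSE distributions and per-class 24-month decline of a
realistic 1,117-subject cohort, so the entire pipeline is testable without
restricted clinical data. See `vignette("ktmnet-methods")` for the full
account.

## Worked example

```r
library(ktmnet)

# 1. simulate a separable 600-subject cohort (Bayes ceiling ~ 0.9)
spec   <- synthetic_spec(n_subjects = 600, feature_effect = 0.62, seed = 1)
cohort <- generate_cohort(spec)
summarize_trajectories(cohort)

# 2. cross-validate the full multitask network
report <- aggregate_cv(cross_validate(
  cohort,
  net_cfg   = network_config(head_hidden_width = 64),
  loss_cfg  = loss_config(alpha = 1, beta = 20),
  train_cfg = training_config(max_epochs = 150, patience = 30, seed = 1),
  plan      = split_plan(main_folds = 3, seed = 1)))
report
glance(report)
```

On a single CPU this prints (about 3 minutes):

```
# A tibble: 4 × 7
  class  MMSE_M0 MMSE_M6 MMSE_M12 MMSE_M24     n rel_decline_24m
  <chr>    <dbl>   <dbl>    <dbl>    <dbl> <dbl>           <dbl>
1 AD        23.7    23       22.1     20.7    84        0.126
2 MCI-C     27.2    26.7     25.7     24.0   103        0.118
3 MCI-NC    28.3    28.5     28.4     28.2   237        0.00343
4 CN        29.3    29.2     29.2     29.3   176        0.000775

<ktm_eval> 3-fold aggregate
  accuracy: 75.17 +/- 3.69 %
  mean RMSE across timepoints: 2.781

# A tibble: 1 × 7
  n_folds accuracy_mean accuracy_sd mean_rmse mean_corr mean_auc n_excluded
    <int>         <dbl>       <dbl>     <dbl>     <dbl>    <dbl>      <int>
1       3          75.2        3.69      2.78     0.455    0.911          0
```

The trajectory table is the generator's calibration check: per-class mean
MMSE at the four visits (AD declines ~13% over 24 months, controls are
flat). The report aggregates the held-out folds: 4-class accuracy far
above both chance (25%) and the majority class (~39%), and a mean
per-timepoint MMSE error within 1.5x the generative observation noise
(sd 2 points). `tidy(report)` exposes every per-class and per-timepoint
metric; `autoplot(report)` draws the pooled confusion matrix.

Ablations run under identical, paired folds:

```r
ab <- run_ablation_study(cohort, c("de1", "de3"),
                         loss_cfg  = loss_config(beta = 20),
                         train_cfg = training_config(max_epochs = 150,
                                                     patience = 30, seed = 1),
                         plan      = split_plan(main_folds = 3, seed = 1))
ab$comparison   # Table of per-timepoint RMSE/correlation + accuracy per variant
ab$ttests       # paired t-tests of each variant against the full model
```

There is also a command-line interface (installed as `exec/ktmnet`):

```sh
ktmnet simulate --out cohort.csv --seed 1 --n-subjects 600
ktmnet preprocess --data cohort.csv --out clean.csv --stats zscore.json
ktmnet cv --data clean.csv --out report.json --folds 10 --seed 1
ktmnet ablate --data clean.csv --out ablation.csv --variants full,de1,de2,de3
```

Every artifact-producing command writes a JSON run manifest (config
snapshot, seeds, input digests) so a run is reproducible from the manifest
alone.

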