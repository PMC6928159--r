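# nervedki

Diffusion-MRI biomarkers of peripheral-nerve regeneration: a tested,
reusable implementation of the analysis pipeline used to ask whether
diffusion tensor (DTI) and diffusion kurtosis (DKI) imaging can tell a
recovering nerve repair from a failing one.

## The problem and the model

After a nerve is cut and surgically repaired, roughly half of repairs fail,
and electrophysiology cannot detect failure until months have passed.
In rat sciatic nerve, the water-diffusion profile of the tissue distal to
the injury tracks regeneration: radial diffusivity (RD) falls and axial
diffusivity (AD) recovers as axons regrow. This package implements the full
chain from raw diffusion-weighted signals to a probabilistic recovery call:

1. **DKI signal model.** Per voxel, the log signal is quadratic in the
   diffusion weighting b:
   `ln S(b, n) = ln S0 − b·D_app(n) + (b²/6)·MD²·Σ nᵢnⱼnₖnₗ Wᵢⱼₖₗ`,
   with `D_app(n) = Σ nᵢnⱼ Dᵢⱼ`, D the diffusion tensor (µm²/ms) and W the
   dimensionless rank-4 kurtosis tensor. The 22 parameters are estimated by
   two-pass weighted linear least squares (`fit_wlls()`), and reduced to the
   scalar indices FA, MD, AD, RD (from D) and MK, AK, RK (from W).
2. **Slice-wise aggregation.** Voxel maps are averaged over manual ROIs per
   slice, labeled proximal / injury / distal, and filtered by the outlier
   rules RD > 1 µm²/ms, RK < 0 or RK > 2.
3. **Recovery classifier.** A linear SVM in the distal week-4 RD-vs-AD
   plane separates crush injuries (which reliably recover) from cut/repair
   injuries (which have not yet recovered), giving a decision line
   `RD = slope·AD + intercept` with bootstrap uncertainties. Decision
   values are calibrated into recovery probabilities by Platt scaling with
   smoothed targets — the calibration of choice when the classes are fully
   separable and plain logistic regression degenerates.
4. **FA threshold.** For a cylindrically symmetric tensor,
   `FA = (1 − RD/AD) / sqrt(1 + 2(RD/AD)²)`, so a zero-offset RD/AD
   boundary maps to a unique FA cut-off (`fa_from_ratio(0.40)` = 0.5222).
5. **Group statistics.** Welch t-tests per cohort pair / timepoint /
   parameter with Benjamini–Hochberg FDR adjustment, and Pearson
   correlations of recovery probabilities against behavior (SFI, foot-fault
   score) and of scalar indices against histological axon density.

Because the original scan data are not public, the package ships a
first-class synthetic-data generator (`simulate_study()`) that reproduces
the study design — cohorts sham = 21, crush = 23, cut/repair = 19 across
1/2/4/12 weeks — with linearly separable week-4 distal clusters, behavioral
recovery curves and density–diffusivity coupling, all from a single seed.

## Worked example

```r
library(nervedki)
library(dplyr)

study <- simulate_study(study_config(seed = 1))
study
#> <nerve_study> 63 animals (crush = 23, cut_repair = 19, sham = 21)
#>   819 slice records, 357 behavioral records

model <- train_recovery_model(study$slices, seed = 1)
model
#> <recovery_model> boundary RD = 0.356 (+/- 0.018) * AD + 0.027 (+/- 0.024)
#>   FA threshold 0.5750 +/- 0.0221 (intercept 0.027 ignored by the zero-offset assumption)
#>   trained on 66 distal week-4 slice records (0 excluded as outliers)

kept <- filter_outliers(study$slices)$kept
cl <- classify_study(kept, model$boundary, model$platt)
correlate_probability_behavior(cl$nerves, study$behavior, week = 12)
#> # A tibble: 2 × 5
#>   x           y         r        p     n
#> 1 probability sfi   0.986 3.60e-9     12
#> 2 probability ff    0.984 7.59e-9     12
```

The boundary slope (≈ 0.36 on this seed) is the RD/AD ratio at which a
distal slice switches sides; every week-4 crush slice sits on the recovered
side and every week-4 cut/repair slice on the other, and the per-nerve mean
probabilities at week 12 track the behavioral outcome almost perfectly —
the generator couples both to the same latent recovery state. Plots:
`autoplot(study)` shows the RD-vs-AD plane per timepoint,
`autoplot(model$boundary)` the training points with the fitted line.

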