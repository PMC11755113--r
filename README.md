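# covpattern

Spatial covariance pattern analysis for parametric PET volumes, built
around scaled subprofile model principal component analysis (SSM/PCA).

The package is for neuroimaging researchers who have per-subject parametric
SUVr images in a common anatomical space (for example cholinergic
[<sup>18</sup>F]FEOBV PET in a Parkinson's disease case-control cohort) and
want to

* derive a **disease-related covariance pattern** — a voxel-weight map whose
  expression separates patients from controls,
* derive **cognition-related patterns** whose expression tracks composite
  neuropsychological domain scores within the patient group,
* **score individual subjects** by pattern expression, and
* know how much of each pattern to trust, via leave-one-out
  cross-validation and bootstrap voxel-stability analysis.

## The method in brief

Per subject, voxels at or above 3% of the maximum SUVr form a mask; the
intersection over subjects is the common mask. Masked uptake is
log-transformed, and the voxelwise mean over healthy controls (the *group
mean profile*, GMP) is subtracted, giving subject residual profiles:

    SRP_i(v) = log SUVr_i(v) − GMP(v),    v ∈ common mask

PCA of the SRP matrix (subjects × voxels) retains the smallest set of
components explaining ≥ 90% of variance. Stepwise regression under BIC —
logistic on disease state (HC = 0 / PD = 1), linear on composite cognition
z-scores (patient-group PCA) — selects components, and the pattern is the
coefficient-weighted eigenvector sum:

    P(v) = Σ_j β_j · e_j(v)

A subject's pattern expression (*subject score*) is the inner product
⟨P, SRP_i⟩ over common-mask voxels. Validation: leave-one-out
cross-validation re-derives masks, profile, PCA and model per fold
(Student's t, ROC/AUC, Pearson r on held-out scores); stability: 5000
bootstrap replicates of the pattern determination, excluding voxels whose
two-tailed 95% CI straddles zero.

Cognition input is a long-format table of raw test scores; tests are
z-scored to the control group, sign-aligned so higher is better, and
averaged into memory / attention / executive / visuospatial composites plus
a global mean (see `default_domain_map()`).

Because cohorts of this kind are rarely shareable, the package ships a
first-class phantom generator (`make_phantom_cohort()`): brain-shaped
volumes with a known embedded disease pattern, latent covariance networks,
and cognition scores tied to a network loading — every pipeline stage is
testable against ground truth.

## Worked example

```r
library(covpattern)

ph  <- make_phantom_cohort(phantom_spec(seed = 1))   # 10 HC + 34 PD, 32^3 grid
fit <- derive_disease_pattern(ph$volumes, ph$labels)
fit
#> <pattern_fit> target: disease
#> <pc_basis> 43 components over 7208 voxels
#>   selected: 31 components explaining 90.7% of variance (target 90%)
#> <stepwise_model> logistic regression on 44 subjects
#>   components: {1} explaining 27.7% of variance
#>   BIC: 20.389

cv <- loocv_disease(ph$volumes, ph$labels)
cv
#> <crossval_result> target: disease (44 held-out subjects)
#>   t = -7.037, p = 1.29e-08, AUC = 0.979, sens = 0.91, spec = 1.00
```

31 components reach the 90% variance target; the stepwise logistic model
keeps one of them. In leave-one-out cross-validation the held-out subject
scores separate the groups (pooled-variance t = −7.04 with controls
first, so patients express the pattern more strongly), with AUC 0.979 and
sensitivity 91% / specificity 100% at the Youden operating point.

```r
hc  <- ph$labels$subject_id[ph$labels$group == "HC"]
composites <- composite_scores(zscore_tests(ph$cognition, hc))
glance(loocv_cognition(ph$volumes, ph$labels, composites, "global"))
#> # A tibble: 1 × 6
#>   target n_folds n_empty     r        p     n
#> 1 global      34       0 0.971 1.70e-21    34

bs <- bootstrap_pattern(fit$srp, ph$labels$group, "logistic",
                        n_boot = 500, seed = 2)
bs
#> <bootstrap_summary> 500 replicates (seed 2)
#>   stable voxels: 2206 / 7208 (30.6%)
```

Held-out global-cognition scores correlate r = 0.97 with the measured
composites (the phantom's cognition link is strong by construction), and
the bootstrap retains 2206 stable voxels, concentrated inside the embedded
pattern.

`autoplot()` methods cover the scree plot (`pc_basis`), score distributions
and scatter (`crossval_result`, plus `plot_roc()`), and stable-pattern
slices (`bootstrap_summary`); `tidy()`/`glance()` give broom-style
summaries throughout. `run_derive()` / `run_report()` persist a full run
(NIfTI patterns, TSV scores, JSON manifest), and `inst/cli/covpattern.R` is
a thin command-line wrapper (`simulate | derive | crossval | bootstrap |
report`).

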