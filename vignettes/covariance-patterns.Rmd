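---
title: "Deriving and validating spatial covariance patterns from parametric PET volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating spatial covariance patterns from parametric PET volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covpattern)
```

## The model

covpattern implements scaled subprofile model principal component analysis
(SSM/PCA), a multivariate method for finding brain-wide covariance patterns
in parametric PET uptake images and quantifying their expression in
individual subjects. The intended setting is a case-control cohort —
here framed as healthy controls (HC) and Parkinson's disease (PD) patients
scanned with a cholinergic tracer — where the scientific questions are
(i) which spatial pattern of uptake distinguishes patients from controls,
and (ii) which patterns track cognitive performance within the patient
group.

The processing chain, given SUVr volumes in a common anatomical space:

1. **Masking.** Per subject, keep voxels with uptake at or above a fraction
   (default 3%) of that subject's maximum; intersect all subject masks into
   the common mask. The threshold is inclusive.
2. **Log transform and referencing.** Take the natural log of uptake within
   the common mask; compute the voxelwise mean over controls (the *group
   mean profile*) and subtract it from every subject's log image. The rows
   of the resulting subjects-by-voxels matrix are *subject residual
   profiles* (SRP). No further within-subject or across-subject demeaning
   is applied: intensity normalization already happened in the SUVr
   calculation, and the only centering in the model is against the control
   profile.
3. **Decomposition.** PCA of the SRP matrix (subjects as rows). The
   smallest number of components whose variance fractions sum to at least
   90% is retained. Because voxels far outnumber subjects, the
   decomposition runs through the subject-by-subject covariance matrix;
   this is algebraically the SVD of the SRP.
4. **Pattern models.** Disease: stepwise logistic regression of group
   (HC = 0, PD = 1) on the retained component scores under the Bayesian
   information criterion. Cognition: the decomposition is re-run on patient
   rows only, then stepwise linear regression of the composite cognition
   z-score (per domain, and for global cognition). The voxel pattern is the
   coefficient-weighted sum of the selected components' eigenvectors; the
   intercept is not spatialized.
5. **Subject scores.** A pattern's expression in a subject is the inner
   product of its voxel weights with the subject's SRP over all common-mask
   voxels, with no post-hoc standardization. For training subjects this
   equals the coefficient-weighted sum of their component scores — the
   algebraic identity the test suite checks to 1e-8.
6. **Validation.** Leave-one-out cross-validation re-derives *everything*
   (masks, profile, decomposition, model, pattern) on the training subjects
   of each fold, and scores the held-out subject on the training artifacts.
   Disease performance is summarized by a pooled-variance t-test, ROC/AUC
   (Mann-Whitney with ties counted 0.5) and the Youden operating point;
   cognition performance by Pearson correlation between held-out scores
   and measured composites.
7. **Stability.** Bootstrap resampling of subjects re-runs the pattern
   determination per replicate; voxels whose two-tailed 95% percentile
   interval of replicate weights straddles zero are excluded from the
   original pattern, leaving the stable pattern.

## Cognitive composite scores

Raw neuropsychological endpoints are z-scored to the control group — the
control mean is subtracted and the control sample SD (n − 1 denominator,
the appropriate convention for a reference group of ten) divides the
result. Endpoints where a higher raw value means worse performance
(completion times: Trail Making A/B, Stroop card times) are multiplied by
−1 so that higher is always better. Within-domain means form the four
composite scores (memory, attention, executive, visuospatial) and their
mean is the global score. Consequences of this construction: control-group
composites have mean zero exactly, and composites are invariant to any
positive affine rescaling of raw test units.

Missing tests are omitted from the domain mean (no imputation); a subject
with no test in a domain gets `NA` there and is dropped from models
targeting that domain. A domain map with a single test per domain is
allowed with a warning — the at-least-two-tests rule is a battery design
recommendation, not a scoring constraint. Which endpoints are inverted is
part of the run configuration (`default_domain_map()`), since any given
battery's conventions vary; the default marks exactly the time-based
endpoints.

## Numerical and design choices

* **Log base** — natural log. Component selection and patterns are
  invariant to the base up to a global scale.
* **Voxel order** — masked voxels are vectorized in R's native column-major
  array order; the mapping is deterministic and identical for all subjects
  in a run, which is all downstream algebra needs.
* **No column centering before PCA** — the SRP is already referenced to the
  control profile, so "variance" means total squared SRP mass. Demeaning
  each voxel across subjects first is available via
  `fit_pca(center_columns = TRUE)` but is off by default.
* **Eigenvector signs** — pinned by making each component's
  largest-magnitude loading positive. Patterns are invariant to this choice
  because regression coefficients absorb signs (a tested property).
* **Stepwise direction** — bidirectional: forward steps adding the
  candidate that most decreases BIC, interleaved with backward sweeps
  removing any term whose removal decreases BIC, until no move improves.
  Ties break toward the lowest component index, making the result
  independent of candidate order. Forward-only is available by
  configuration. The candidate pool is exactly the components retained by
  the 90% rule.
* **BIC conventions** — logistic: −2·loglik + k·ln n; linear with profiled
  Gaussian variance: n·ln(RSS/n) + k·ln n, k counting the intercept.
  Constants are dropped consistently; only differences matter.
* **Perfect separation** — small cohorts regularly separate perfectly in
  logistic fits. Diverging coefficient vectors are rescaled so the largest
  magnitude equals 20 (rescaling preserves the decision boundary, unlike
  per-coefficient clipping), keeping BIC finite and selection
  deterministic; a warning is raised.
* **Scoring-time clamping** — a held-out or new subject may have
  non-positive uptake inside the *training* mask. At scoring time such
  values are clamped to the smallest positive masked training value with a
  warning. At training time the same situation is an error: masks and data
  disagreeing in training indicate an upstream problem.
* **Cross-validation folds** — the common mask and profile are recomputed
  per fold from training data only; strict leakage avoidance dominates
  fidelity to any unstated shortcut, and a perturbation test asserts that
  a fold's training artifacts are bit-identical under changes to the
  held-out subject. For cognition patterns the controls are never held out:
  they supply the fixed reference profile in every fold, and folds rotate
  over patients. Folds whose stepwise model is intercept-only yield a
  held-out score of 0 and are flagged rather than aborting the run.
* **Bootstrap scheme** — the common mask and profile are fixed at their
  original-sample values inside replicates so all replicate patterns share
  one voxel space (per-voxel quantiles are undefined otherwise). Disease
  resampling is stratified by class, preserving both group counts;
  cognition resampling is simple within patients, redrawing (and counting)
  replicates with a constant response. Intercept-only replicates contribute
  zero vectors — conservative, since they widen intervals toward zero.
  Intervals are percentile (order statistics), not BCa. Orientation across
  replicates is pinned by the response coding (PD = 1, higher cognition z
  positive), not by eigenvector signs. All draws consume a single seeded
  stream, so a summary is bit-identical under a fixed seed.

## The phantom cohort generator

No subject-level data ships with the package; `make_phantom_cohort()`
generates a synthetic cohort in which every downstream claim can be checked
against known ground truth. The generative model works in log-uptake space,
so the pipeline's log transform linearizes it exactly:

log-uptake_i(v) = baseline(v) + δ·s_i·1[i ∈ PD]·D(v) + Σ_k λ_ik·C_k(v) + ε_i(v)

* An ellipsoidal brain-shaped support (default 32×32×32 grid) carries a
  smooth radial baseline peaking at SUVr 4; background voxels sit at uptake
  0.02 — near zero but positive, so the fractional-maximum mask rule is
  exercised without log-domain errors and the common mask reproduces the
  support.
* `D` is the disease pattern: a focal posterior deficit blob plus a smaller
  anterior increase, unit-norm, truncated at 1.8 SD so that its support
  contains only voxels carrying a non-negligible effect (boundary weight
  about 20% of peak) — patterns in this field are reported as focal
  clusters, and a support made mostly of vanishing Gaussian tails would
  make "inside the pattern" meaningless. δ defaults to 0.2 log-units, and
  each patient carries a multiplicative severity s_i ~ N(1, 0.3²),
  emulating the heterogeneous disease stage of a real patient group.
* Three unit-norm latent covariance patterns `C_k` (orthogonalized against
  `D` and each other) carry subject loadings λ_ik ~ N(0, τ_k²),
  τ = (0.15, 0.12, 0.10). Only the first is cognition-linked; the others
  are nuisance networks. Embedding several networks with comparable
  eigenvalues matters: with a single clean pattern, component selection is
  trivially stable across bootstrap replicates and the CI-straddle rule
  loses its object. Real cohort models in this setting need 3–6 components.
* Voxel noise is white with SD 0.02 log-units (about 2% uptake), smoothed
  with a 1-voxel Gaussian kernel for spatial correlation. The level is set
  so the structured patterns lead the eigenspectrum — in real cohorts of
  this kind a modest number of components carries on the order of
  70–90% of subject variance, and a phantom drowned in unstructured noise
  would not be in that regime.
* Cognition: latent domain abilities g_ik = a·λ_i1 + ε (a = 10, ability
  noise SD 0.5), and per-test raw scores as test-specific affine transforms
  of the ability plus measurement noise (SD 0.3), with the time-based tests
  generated inverted. Controls receive test scores too, so standardization
  has its reference group.

With all variance sources at zero the generator emits identical,
strictly positive volumes — a degenerate case the tests use to pin the
centering identities.

What the phantom does *not* emulate: scanner physics (PSF, scatter,
partial-volume effects), anatomical atlases and hemispheric asymmetry,
reference-region misnormalization, and non-Gaussian or spatially
non-stationary noise. Passing tests therefore demonstrate the correctness
and calibration of the *pipeline* under a known covariance structure, not
the clinical performance of any pattern on real data.

## Problem sizes in the tests

The unit suite runs small phantoms (16³ grid, 5 HC / 12 PD) for speed; the
acceptance-style checks use the default cohort shape (32³ grid,
10 HC / 34 PD) with 200–500 bootstrap replicates and 20 null cohorts for
the calibration bands. The 5000-replicate bootstrap is the production
default of `covpattern_config()`, not a test-time setting.

## Known limitations

* Stepwise selection under BIC is liberal at small n: a spurious candidate
  passes the penalty with probability around 7–8% at n = 34. This is a
  property of the selection rule itself; the bootstrap stability analysis
  is the intended counterweight.
* On null cohorts, LOOCV AUC tends slightly *below* 0.5 (seen around
  0.38–0.45 in the calibration tests): in-sample selection bias
  anti-correlates with held-out scores, a well-known cross-validation
  artifact that the wide null band acknowledges.
* The cognition folds keep the control profile fixed; if controls were
  resampled per fold the held-out scores would change slightly. The choice
  is an interpretation of "patients only" fold rotation and is flagged in
  the function documentation.
* A new subject scored on a trained pattern must be on the same voxel grid;
  no resampling or registration is performed by this package.

## A worked end-to-end run

```{r example, eval = FALSE}
ph <- make_phantom_cohort(phantom_spec(seed = 1))

fit <- derive_disease_pattern(ph$volumes, ph$labels)
glance(fit$basis)       # components retained by the 90% rule
tidy(fit$model)         # selected components and coefficients

cv <- loocv_disease(ph$volumes, ph$labels)
glance(cv)              # t, p, AUC, sensitivity, specificity
autoplot(cv); plot_roc(cv)

hc <- ph$labels$subject_id[ph$labels$group == "HC"]
composites <- composite_scores(zscore_tests(ph$cognition, hc))
cvg <- loocv_cognition(ph$volumes, ph$labels, composites, "global")
glance(cvg)             # r, p

bs <- bootstrap_pattern(fit$srp, ph$labels$group, "logistic",
                        n_boot = 5000, seed = 2)
glance(bs)              # stable voxel counts
autoplot(bs)            # stable pattern, mid-axial slice
```
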