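---
title: "Brain age estimation in the baboon: models, calibration and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain age estimation in the baboon: models, calibration and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, how the synthetic data generator was
calibrated, the numerical choices that matter, and what the passing test
suite does and does not demonstrate about real data.

## The estimation framework

A subject's structural scan is reduced to a gray-matter (GM) probability
map, the map to a feature vector, and the vector to a single estimated
brain age. The chain is:

1. *Artifact correction.* One multiplicative gain per slice is estimated
   as the ratio of the slice's masked median intensity to a smoothed
   across-slice profile and divided out (sagittal-type acquisitions leave
   exactly this kind of protocol-dependent slice artifact). A spatially
   adaptive non-local-means filter then removes high-frequency noise.
2. *Segmentation.* An expectation-maximization (EM) mixture with one
   Gaussian intensity distribution per class (GM, WM, CSF, background) and
   a registered tissue probability map (TPM) as a spatially varying prior;
   the per-voxel posterior is likelihood × prior, renormalized. Absolute
   volume per class is posterior mass × voxel volume (ml); TIV is the sum
   over the three tissue classes, and fractional volumes divide by TIV.
3. *Feature reduction.* GM posterior maps are smoothed with a 3-mm FWHM
   Gaussian, resampled to 3 mm, masked, centred and projected onto
   principal components (at most n − 1 of them).
4. *Age regression.* A relevance vector regression (RVR) with linear
   kernel `K(x_i, x_j) = x_i · x_j` plus a bias column. Per-basis
   precisions α and the noise precision β are re-estimated by the standard
   fixed-point updates on the marginal likelihood; bases whose α diverges
   are pruned, leaving a sparse set of relevance vectors. No kernel
   parameters need tuning, and the fit is deterministic.
5. *Scores.* `BrainAGE = BA − CA`; cohort accuracy is pooled LOOCV MAE and
   Pearson r. In the cross-validation, the mask, centring, PCA *and* the
   RVR are refit on each fold's n − 1 training subjects — the held-out
   subject contributes nothing to its own prediction. (A global-PCA
   variant is available via `pca_per_fold = FALSE`; per-fold refitting is
   the default because it is the only reading that provably avoids
   leakage.)

Assumptions worth stating: tissue classes are unimodal in intensity after
denoising (one Gaussian per class); within-subject inhomogeneity beyond
slice gains is left to the denoiser rather than modelled as a polynomial
bias field; registration is affine only — no diffeomorphic refinement —
so anatomical correspondence across subjects is approximate and the GM
features are unmodulated posterior probabilities, not Jacobian-scaled
volumes.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the study conditions
under which every downstream claim is checked.

Each phantom is a deformed concentric geometry — WM core, GM ribbon, CSF
shell — built by ranking a smoothly perturbed radial field and cutting it
at the voxel counts that realise the requested tissue fractions exactly.
Intensities follow the T1-like ordering CSF < GM < WM (class means 0.25,
0.60, 0.95 on an arbitrary scale), degraded by a smooth multiplicative
bias field (amplitude 0.04), per-slice gains (log-SD 0.05 along the third
axis), and additive Gaussian noise (SD 0.02 by default, 0.03 in the
segmentation stress tests).

Tissue-fraction trajectories against age $a$ (years) are, for females

$$\mathrm{GM}(a) = 0.522 - 0.0055\,a, \qquad
  \mathrm{CSF}(a) = 0.177 + 0.0035\,a,$$

and for males

$$\mathrm{GM}(a) = 0.48532 - 0.00186\,a - 0.00008\,a^2, \qquad
  \mathrm{CSF}(a) = 0.21256 + 0.00022\,a + 0.00006\,a^2,$$

with WM the complement. TIV is drawn per sex from N(186.7, 14.4²) ml
(females) and N(210.4, 14.0²) ml (males). These coefficients were
calibrated once so that a 29-animal cohort aged 4–22 years reproduces the
reference morphometry of the adult baboon — fractional GM ≈ 0.47/0.46
(female/male) with SD ≈ 0.03, fractional WM ≈ 0.32 rising with age,
female CSF rising, absolute GM ≈ 87/96 ml — and were not revisited
afterwards. Subject-level biological variability is a fractional-GM
noise term (SD 0.012, exchanged against CSF), chosen so that the
feature-space age signal-to-noise ratio is about 2; it also matches the
residual scatter implied by the reference cohort's fractional-GM SD and
its strong female linear age fit. Shape individuality is six seeded
low-frequency cosine deformation modes at 1.5% radial amplitude — a
modest, deliberately conservative realism term.

The MNR (maternal nutrient restriction) insult is *accelerated aging along
the female trajectory*: the age advance is chosen so fractional GM drops
by exactly `mnr_gm_offset` (default 2.7 × 0.0055 = 0.01485, i.e. +2.7
brain-years at any age under the linear female GM trajectory). The
rebalanced mass follows the trajectory — about 64% into CSF, 36% into WM.
An earlier design that transferred the whole decrement into CSF was
rejected because it is *off the aging manifold*: the trained model reads
such a perturbation as only ~1.8 equivalent years, so it is not an
"atrophy offset equivalent to +2.7 brain-years" by the model's own ground
truth. MNR males are unaffected, matching the reference female-specific
finding.

Default grid: 48³ voxels at 1.75 mm. The voxel size is set by geometry: a
~200 ml brain (sphere radius ≈ 36 mm) must fit the 48³ box with margin
for deformation and the CSF shell, which a 1 mm grid cannot provide at
desk scale. All randomness flows from one master seed through stable
integer mixing (`child_seed`), so cohorts, phantoms and whole pipeline
runs are bit-reproducible.

What the generator does *not* emulate: cortical folding and gyral
anatomy, MR physics (relaxometry, k-space, partial volume from acquisition
geometry), skull and extra-cranial tissue, registration failure modes from
head positioning, or any model of gestation and diet itself. Passing tests
therefore demonstrate internal consistency of the method under controlled
geometry and noise — not performance on real scans.

## Template construction

The species template starts from a reference TPM rescaled isotropically
about its prior centre of mass so its brain prior mass hits the target
volume (~200 ml) within 1%, then resampled to the requested isotropic
grid. Iterations then segment each subject with the current TPM, register
into template space, take the voxel-wise *median* across subjects per
class (robust to a corrupted or failed subject), smooth with a 2-mm FWHM
kernel and renormalize. Because the reference atlas a real study would
rescale is not shippable, the package constructs a synthetic human-scale
reference (`synthetic_reference_tpm()`, ~1400 ml), clearly labelled as
such.

Design choices the source description left open, fixed here: the
"change between iterations" metric is the mean absolute voxel-wise TPM
difference over the brain mask (default stop tolerance 1e-3, at most 6
iterations); the median is taken per class first and renormalized
afterwards (renormalizing first would couple classes before aggregation);
the background class is recomputed as 1 − (GM+WM+CSF) after smoothing so
normalization is guaranteed; the brain mask is non-background prior
> 0.5; template space is the initial scaled-reference grid throughout.

## Numerical choices

* FWHM to sigma: σ = FWHM / (2√(2 ln 2)); Gaussian smoothing is separable
  with edge-renormalized kernels, so means are preserved near boundaries.
* Slice-gain profile: running median, then a wide running mean (window
  ≈ n/4 slices). If the smoothed profile explains less variation than the
  residual gains (near-uniform anatomy), it collapses to a constant so
  gains are recovered exactly instead of partially absorbed. All-zero or
  background-only slices keep gain 1; output mean intensity is restored
  to the input mean.
* Non-local means: patch distances are noise-compensated
  (`max(d² − 2σ², 0)`); the local noise SD comes from box-averaged
  pseudo-residuals but is capped at 1.5× a robust global level, because
  pseudo-residuals at tissue boundaries reflect structure, not noise —
  uncapped, the filter blurs exactly where edges must be kept.
* EM segmentation: class moments initialize from prior-majority voxels
  only (soft prior boundaries otherwise drag initial means across
  classes); exactly tied priors spread coincident class means over
  quantiles; class SDs are floored at 2% of the intensity range so a
  denoised flat region cannot collapse to near-zero variance and push its
  outlier tail into a neighbouring class. Convergence: relative
  log-likelihood change below 1e-5 (default), 50 iterations cap. Classes
  with essentially zero prior mass are dropped with a warning.
* Registration: cost is 1 − r² between the 2-mm-smoothed images (the
  squared error after the per-evaluation optimal linear intensity map,
  invariant to differing foreground/background balance), evaluated on at
  most 20,000 strided voxels; coarse grid search (translations at
  ±2-voxel steps, or scale 0.7–1.4) then Nelder–Mead with a restart. A
  restart that cannot improve the cost counts as convergence evidence;
  a non-converged result is flagged, not hidden.
* RVR: α initialized at 1/n², β at 10/var(y); pruning threshold 1e6 on α
  (the bias column is never pruned); convergence at 1e-4 relative change
  of the marginal likelihood, 500 iterations cap. β is capped at
  1e10/var(y): on noiseless data it otherwise diverges and destroys the
  posterior computation. A singular posterior system is retried once with
  a ridge jitter, then errors. A constant response short-circuits to the
  bias-only model. With `max_iter = 0` and fixed hyperparameters the
  posterior mean is exactly kernel ridge regression — the equivalence the
  test suite checks against a closed-form oracle at 1e-6.
* Trajectory model selection: the default rule picks the order with the
  higher adjusted R² among models whose overall F is significant at 0.05,
  ties to the lower order — this mirrors how the reference volume tables
  mark their best fits. Note its known behaviour: for true-linear data it
  retains the quadratic term whenever that term's added F exceeds 1,
  which happens in roughly a third of null draws, so it tops out near
  two-thirds correct order recovery. The nested-F rule
  (`rule = "nested"`, quadratic term tested at 0.05) recovers the true
  order in ≳90% of calibrated simulations and is the right tool when
  order recovery itself is the goal.
* ANCOVA: `value ~ group + age`, group tested by Type-II sums of squares,
  partial η² = SS_group/(SS_group + SS_residual); two-group summary-stat
  ANOVA uses the pooled-variance closed form and reports F (not t), with
  an infinite-F sentinel and warning for zero pooled variance with
  unequal means. No multiple-testing correction is applied anywhere, and
  p-values come from the F distribution.
* Human-equivalent age: a fixed factor of 3.5, exactly consistent with
  the 4→14, 22→77 and 5→17.5 year anchors.

## Problem sizes

The test suite and acceptance script run at the sizes the package treats
as its reference desk-scale conditions: 48³ phantom grids for
acceptance-level checks (LOOCV over 20 seeded 29-subject cohorts; 50
seeded MNR experiments; 3%-noise segmentation), and 24³–32³ grids for
unit-level properties, where the same code paths run in milliseconds.
Trajectory-selection properties use 200 simulated cohorts of 15.

## Known limitations

* *Regression dilution in group contrasts.* Out-of-sample brain-age
  predictions shrink toward the training mean by roughly
  SNR²/(1 + SNR²); at the calibrated feature-space SNR ≈ 2 that factor is
  ≈ 0.8, so a programmed +2.7-year group offset is recovered as ≈ 2.0–2.4
  years on average. This is a property of any mean-square-optimal
  estimator, not a bug: accurate individual prediction (low MAE) and
  unattenuated group-difference recovery are in tension at fixed SNR, and
  the seed-ensemble checks in the test suite sit close to the edge of
  their recovery band for exactly this reason. Applications comparing
  groups should
  either accept the conservative bias or calibrate the score scale (e.g.
  by the LOOCV slope of BA on CA) — such a correction is deliberately not
  applied here because the reference method does not describe one.
* *Affine-only registration.* Without diffeomorphic refinement, template
  sharpness and cross-subject correspondence are limited; on real brains
  this would blur the GM feature maps and lower accuracy relative to a
  DARTEL-class pipeline.
* *Phantom simplicity.* No folding, no acquisition physics, pre-stripped
  heads. Dice ≥ 0.95 on phantoms says the EM machinery is correct, not
  that real baboon scans would segment at that accuracy.
* *Small experimental groups.* With 5 females per group, the ANCOVA on
  scores has limited power and single-seed group differences scatter by
  ±1 year or more; all group-level claims here are made over seed
  ensembles.
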