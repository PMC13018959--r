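---
title: "Fuzzy-mask radiomics: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy-mask radiomics: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzrad)
library(dplyr)
```

## The problem

Radiomic features are quantitative descriptors (intensity statistics,
texture measures) computed over a delineated region of interest of a medical
image. Their clinical usefulness hinges on *reliability*: the same tumor,
delineated slightly differently, should yield nearly the same feature values
and nearly the same model predictions. Manual and automatic delineations of
head-and-neck tumors on CT are uncertain at the boundary — partial volume
effects, beam hardening, and microscopic infiltration all blur where the
tumor "ends" — and the peritumoral neighbourhood (bone, air cavities, soft
tissue) has extreme intensity contrasts, so small contour shifts can swing
feature values wildly.

`fuzzrad` implements a fuzzy-mask approach to this problem, end to end:

1. **Mask fuzzification** — a binary mask becomes a membership field
   $\mu \in [0,1]$ by 3D Gaussian filtering, with two derived binary
   controls: the *core* (voxels with $\mu = 1$, a shrunk mask) and the
   *support* (voxels with $\mu > 0$, an extended mask).
2. **Membership-weighted feature extraction** — intensity,
   intensity-histogram, grey-level co-occurrence (GLCM) and neighbouring
   grey-level dependence (NGLDM) features where every voxel contributes
   in proportion to $\mu$.
3. **Reliability analysis** — a perturbation chain (contour randomization,
   rigid motion, additive noise) simulates delineation uncertainty; the
   consistency intraclass correlation ICC(C,1) across 20 perturbed
   realizations quantifies per-feature stability.
4. **Relevance analysis** — hierarchical clustering at a correlation-distance
   threshold counts non-redundant feature clusters.
5. **Survival modeling** — repeated 7:3 train/validation splits,
   mRMR feature ranking, ridge-penalized Cox models tuned by 5-fold CV,
   scored by Harrell's C, time-dependent AUC, and the ICC of risk scores
   across perturbed validation sets.
6. **Synthetic phantoms** — lumpy ellipsoidal tumors with configurable
   peritumoral bone/air structures and linked exponential survival, so the
   whole pipeline is testable without any imaging archive.

## Fuzzification model

The fuzzy mask is the binary mask convolved with a normalized discrete
Gaussian. The physical scale is tied to the in-plane pixel size $u$ of the
grid: $\sigma_{mm} = m \cdot u$ with multiplier $m \in \{0.5, 1, 1.5\}$ for
sensitivity sweeps ($m = 1$ default). We convert $\sigma_{mm}$ per axis to
voxel units, so smoothing is isotropic *in millimetres*: on anisotropic
grids (e.g. 1 mm in-plane, 3 mm slices) the kernel is correspondingly
narrower in slice units rather than inflating the physical blur. The
alternative — filtering in voxel units — would make the fuzzy band's
physical width depend on slice thickness; we flag this as the main
sensitivity-analysis axis for anyone comparing against other toolkits.

Numerical choices:

* kernel truncation at $4\sigma$ per axis, normalized to unit sum — deep
  interior voxels then reach $\mu = 1$ exactly up to float error, and total
  membership mass equals the binary voxel count to better than $10^{-6}$
  relative whenever the mask keeps a truncation radius of clearance from
  the volume boundary (the phantom generator enforces this margin);
* core and support thresholds use $\varepsilon = 10^{-6}$ on $\mu$ rather
  than exact `== 1` / `!= 0` comparisons, which would be float-hostile;
* an empty core (all $\mu < 1$, typical for tumors under roughly 100
  voxels) is a *warning* (`fuzzrad_empty_core`), not an error: cohort logic
  is expected to drop such patients from core-mask analyses.

## Weighted feature extraction

The guiding invariants, both enforced by tests, are:

* **binary limit** — with $\mu \in \{0,1\}$ every feature reduces exactly to
  its classical definition on the masked voxels;
* **weight-scale invariance** — multiplying all memberships by a constant
  changes nothing (all statistics use normalized weights; the extensive
  features Energy and the nonuniformities are rescaled by the support voxel
  count, which restores the classical value in the binary limit without
  breaking scale invariance).

Discretization uses fixed bin number (32 bins over the support-region
intensity range, maximum intensity in the top, right-closed bin) by default;
fixed bin size (25 HU) is a config option. The discretization region is
always the support ($\mu > \varepsilon$), so weighted sums never meet
undefined levels. No HU re-segmentation window is applied by default.

For the GLCM, the weight of an ordered voxel pair is the *product*
$w(p)\,w(p+d)$ — it reduces to classical counting at binary weights and
factorizes cleanly; `min` and `mean` rules are available config
alternatives since the choice is not dictated by the method itself. All 13
unique distance-1 directions accumulate into a single merged, symmetrized
matrix (the merged full-volume aggregation dialect). With any non-binary
membership present the raw matrix becomes real-valued — this continuous
interpolation between co-occurrence cells is precisely the mechanism that
smooths out extreme boundary intensities.

For the NGLDM (26-connectivity, distance 1, level tolerance
$\alpha = 0$), neighbors *gate* the dependence count while only the center
voxel's membership contributes mass; neighbors outside the support never
count. This is the simplest weighting that keeps the binary limit exact.

Degenerate values (zero variance, single grey level) yield `NaN` features
with a recorded note; they are filtered later by the reliability stage, not
imputed.

## Perturbation chain

Delineation uncertainty is simulated by composing, in fixed order:

1. **contour randomization** — a smooth random displacement field (white
   noise smoothed with a 4 mm Gaussian, each component rescaled to a target
   SD in mm) warps the mask, which is re-binarized at 0.5;
2. **rigid motion** — rotation about the z-axis through the mask centroid,
   then translation; image trilinear, mask linear-then-threshold-0.5;
3. **additive Gaussian image noise**.

The order matters: contour randomization is defined in the native frame and
noise must never be resampled. Default sampling bounds — translations within
±1 mm per axis, rotations within ±10°, noise SD up to 20 HU, contour
magnitude 0.5–2 mm — are of the scale used in perturbation-robustness
studies of CT radiomics and are fully configurable; they are declared
defaults of this implementation, not values recovered from any specific
study. The identity spec reproduces its input bit-exactly, and integer-voxel
translations are exact array shifts (interpolation weights within $10^{-9}$
of the lattice are snapped), which pins down the resampling conventions.

At the default contour magnitudes the warp changes a sphere's Dice overlap
with its original to roughly 0.7–0.95 (simulated band, frozen in the test
suite) while mean mask volume over 20 draws stays within 10% of the
original.

## Reliability, relevance, and their cut points

ICC(C,1) is computed from the two-way (subjects × realizations) ANOVA
decomposition,
$\mathrm{ICC} = (MS_{rows} - MS_{err}) / (MS_{rows} + (k-1) MS_{err})$,
which by construction ignores additive per-realization offsets. Categories
follow the conventional cut points 0.5 / 0.75 / 0.9 with boundary values
assigned upward (the interval notation "0.75–0.9" is ambiguous at its
endpoints; we resolve it toward the higher category, and a feature counts
as *reliable* at ICC ≥ 0.75). Rows containing NaN are dropped with a count,
not imputed. An all-constant matrix has an undefined ICC (`NaN`), reported
as category `"undefined"`.

Relevance uses hierarchical clustering on the correlation distance
$d = 1 - r$. The linkage method is a genuine free choice — the count of
clusters depends on it — so it is always reported alongside the counts;
*average* linkage is the default (robust for correlation screens; MATLAB's
`linkage` would default to single), with single/complete selectable. The
dendrogram is cut so that features merge only at heights strictly below
the threshold (default 0.25). Cluster counts are non-increasing in the
threshold; this shape property is tested.

## Survival modeling loop

Candidates are selected cohort-level (reliability filter, then one
representative per cluster: highest ICC, lexicographic ties); ranking is
per training split. mRMR for censored outcomes is not canonically defined,
so relevance is the distance of a feature's univariate concordance from 0.5
and redundancy the mean absolute Pearson correlation to the already-selected
set — this matches the concordance objective of the final model. The model
is a ridge-penalized Cox regression: the "penalized" family is a free
choice, and ridge keeps coefficients stable across the 50 repeated splits
while feature-count selection is already handled by mRMR plus CV (lasso and
elastic-net remain options). Model size (2–15 by default) and penalty
strength are chosen jointly by event-stratified 5-fold cross-validated
concordance; ties prefer the smaller model and the stronger penalty. Splits
are 7:3, stratified on the event indicator. The Wilcoxon rank-sum comparison
of C-index distributions uses the two-sided normal approximation with tie
correction.

Harrell's C counts comparable pairs (earlier observed event vs longer
survival) with score ties at 0.5. The time-dependent AUC is the
cumulative/dynamic form with inverse-probability-of-censoring weights from
the Kaplan–Meier estimate of the censoring distribution, evaluated at 1, 3
and 5 years and averaged; without censoring it reduces exactly to the plain
binary AUC of status-at-horizon, a reduction the tests verify numerically.

## What the phantoms emulate — and what they do not

`make_phantom()` builds a lumpy ellipsoid (radius modulated by smoothed
angular noise) in a soft-tissue background, with optional bone-like
(+700 HU) and air-like (−950 HU) structures abutting the tumor along one
axis, heterogeneous intra-tumor texture (smoothed noise with per-patient
SD), and global acquisition noise. `make_cohort()` draws per-patient
volumes (uniform, default 1,000–9,000 voxels, spanning several 5k-voxel
strata), heterogeneity (10–50 HU) and mean tumor density (40–80 HU) —
between-patient variation on this scale is what makes reliability analysis
meaningful at all; a cohort of near-identical tumors has no between-subject
variance and every ICC collapses toward zero by construction. Survival
times are exponential with log-hazard linear in standardized generator
parameters (default: hazard ratio 2 per SD of heterogeneity), with
independent exponential censoring whose rate is solved numerically for the
target censoring fraction (default 30%).

This emulates the *structure* the method needs — intensity cliffs at the
boundary, size strata, a planted image-derived hazard — not CT physics. No
beam hardening, no partial-volume point-spread model, no scanner
heterogeneity, no anatomical shape realism. Passing tests therefore show
that the algorithms are correct and that the claimed mechanisms operate in
the stated direction on controlled inputs; they do not certify effect sizes
on clinical data.

## Problem sizes used by the checks

The test suite and the acceptance script run entirely on generated data:
mask-algebra sweeps use 100 phantoms of $28^3$ voxels; matrix oracles use
$4^3$–$6^3$ patches; the mechanism experiment uses 10 phantoms of $36^3$
voxels with a bone slab and 20 perturbations each under binary and fuzzy
masks; modeling calibration uses cohorts of n = 300 with 50 repeated
splits. These sizes were chosen so that every stage — including exhaustive
brute-force oracles — runs comfortably on a single desktop core while
leaving the statistical conclusions stable under reasonable seed changes.

## Known limitations

* Shape/morphology features are not defined for fuzzy masks and are out of
  scope; GLRLM/GLSZM/NGTDM families are extension points.
* Only axis-aligned grids are supported; oblique NIfTI affines are rejected
  rather than resampled, and no inter-patient resampling is performed (each
  subject is processed on its native grid).
* No ICC confidence intervals; the absolute-agreement form ICC(A,1) is not
  implemented.
* The contour-randomization operator is a smooth displacement-field warp;
  supervoxel-based randomization is a non-goal.
* Whether to resample to isotropic voxels before extraction is exposed only
  as an upstream choice for the caller; the package default is no
  resampling.
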