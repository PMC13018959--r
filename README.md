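# fuzzrad

Fuzzy-mask radiomics for CT: membership-weighted feature extraction with
reliability, relevance and survival-modeling analysis, plus a synthetic
phantom generator so the entire pipeline runs without any imaging archive.

## The problem

Radiomics turns a delineated tumor region into quantitative features
(intensity statistics, texture matrices) for prognosis models. The weak
point is the delineation itself: tumor boundaries on head-and-neck CT are
genuinely ambiguous, and the peritumoral neighbourhood — bone, air
cavities, soft tissue — has such extreme intensity contrasts that a
millimetre of contour drift can swing feature values and, downstream, model
predictions. A *binary* mask forces every boundary voxel into an all-or-none
decision and inherits that instability.

`fuzzrad` replaces the binary mask with a **fuzzy membership mask**: the
binary delineation is Gaussian-filtered (SD tied to the in-plane pixel size
*u*, σ = *m·u*, *m* = 1 by default) into a field μ ∈ [0, 1], and every
feature is computed with voxels weighted by μ. Two derived binary masks
bracket it: the **core** (α-cut, μ = 1; a shrunk mask) and the **support**
(μ > 0; an extended mask). Weighted statistics use normalized weights
(weighted moments, weighted histograms, GLCM pair weights *w(p)·w(p+d)*,
NGLDM center-weighted dependence counts), so everything reduces exactly to
the classical IBSI-style definitions when μ is binary — and becomes a
real-valued, boundary-smoothed generalization when it is not.

Around the extractor the package implements the full evaluation protocol:

* a **perturbation chain** (smooth contour randomization → rigid rotation +
  translation → additive image noise) simulating delineation uncertainty;
* **ICC(C,1)** — two-way consistency intraclass correlation — across 20
  perturbed realizations per feature, with the poor/moderate/good/excellent
  categories at 0.5/0.75/0.9 and 5k-voxel tumor-volume stratification;
* **redundancy analysis** by hierarchical clustering at a correlation
  distance threshold (default 0.25);
* a **repeated survival-modeling loop**: 50× event-stratified 7:3 splits,
  mRMR ranking, ridge-penalized Cox fits tuned by 5-fold cross-validated
  concordance, scored with Harrell's C, 1/3/5-year IPCW time-dependent AUC,
  Wilcoxon rank-sum comparisons between mask kinds, and the ICC of risk
  scores across perturbed validation sets;
* a **phantom generator**: lumpy ellipsoidal tumors with configurable
  bone/air structures abutting the boundary and exponential survival whose
  hazard is driven by planted image parameters.

## Worked example

```r
library(fuzzrad)

ph <- make_phantom(phantom_config(shape = c(40, 40, 40), radii_mm = c(8, 8, 8),
                                  adjacency = "bone", seed = 7))
masks <- comparative_masks(ph$mask, multiplier = 1)
sapply(masks, function(m) sum(m$data > 0))
#>     bin   fuzzy    core support
#>    2026   10322      61    8165
```

A ~2,000-voxel tumor gains a wide fuzzy halo; only 61 voxels keep full
membership (small tumors can lose the core entirely — that is reported as a
structured warning, not an error).

```r
fv <- list(bin  = extract_all(ph$image, masks$bin),
           fuzz = extract_all(ph$image, masks$fuzzy),
           ext  = extract_all(ph$image, masks$support))
sapply(fv, function(x) round(c(mean = x$stat_Mean3D, contrast = x$glcm_Contrast3D), 3))
#>             bin   fuzz     ext
#> mean     61.631 62.911 107.099
#> contrast 14.631  3.153  20.939
```

This is the mechanism in one table: the phantom has a +700 HU bone slab
touching the tumor. The extended mask's mean is dragged to 107 HU by slab
voxels; the membership-weighted mean (62.9) stays next to the binary one
(61.6) because boundary voxels are down-weighted rather than included or
excluded wholesale, and the weighted GLCM contrast collapses from 14.6 to
3.2 as extreme boundary co-occurrences lose weight.

```r
pp <- perturb_chain(ph$image, ph$mask, sample_perturbations(3, seed = 1)[[1]])
c(original = sum(ph$mask$data), perturbed = sum(pp$mask$data))
#>  original perturbed
#>      2026      2142

set.seed(2)
subj <- rnorm(10, sd = 3)
m <- outer(subj, rep(1, 4)) + matrix(rnorm(40), 10, 4) + outer(rep(1, 10), 0:3)
icc_c1(m)
#> # A tibble: 1 × 7
#>     icc category ms_rows ms_error     n     k n_dropped
#>   <dbl> <chr>      <dbl>    <dbl> <int> <int>     <int>
#> 1 0.841 good        34.5     1.55    10     4         0
```

ICC(C,1) is consistency-form: the per-column offsets `0:3` cost nothing;
only subject-by-realization disagreement does. Feature-level reliability
across 20 perturbed feature tables comes from `feature_reliability()`,
cluster counts from `cluster_count_sweep()`, and the full repeated modeling
loop from `run_experiment()`, which returns a tidy per-run table
(`tidy()`), per-mask summaries (`glance()`) and box plots (`autoplot()`).

A thin command-line front end covers the same stages
(`exec/fuzzrad phantom|fuzzify|extract|perturb|reliability|relevance|model`).

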