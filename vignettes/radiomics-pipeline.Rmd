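---
title: "Classifying glioma radiation necrosis versus recurrence: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying glioma radiation necrosis versus recurrence: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

After surgery and radiotherapy, gliomas frequently produce one of two
radiologically similar follow-up findings: tumor recurrence or radiation
necrosis. The two demand opposite management, but on structural MRI they
can be nearly indistinguishable by eye. `gliorad` implements a radiomics
pipeline that classifies the two from four registered structural MRI
modalities (T1, T1-weighted postcontrast, T2, FLAIR) plus a binary tumor
mask: a large battery of handcrafted texture/shape features and
CNN-derived deep features is extracted per patient, screened, reduced,
and combined into a small bootstrap-averaged logistic model.

Cohorts in this setting are small (tens of patients) and imbalanced
(necrosis is the rarer outcome), so the statistical machinery is built
around imbalance-adjusted bootstrap resampling and the 0.632+
optimism-corrected AUC rather than a held-out split.

Throughout, label 1 denotes necrosis (the positive class) and label 0
recurrence.

## Pipeline overview

1. **ROI conditioning** (`bounding_box()`, `wavelet_bandpass()`,
   `resample_isotropic()`, `quantize()`): each modality volume is cropped
   to the mask bounding box, band-pass filtered in the wavelet domain,
   resampled to an isotropic grid, and gray-level quantized.
2. **Handcrafted features** (`extract_handcrafted()`): 4 shape features
   computed once from the mask, plus 43 texture statistics (3 global
   moments, 9 GLCM, 13 GLRLM, 13 GLSZM, 5 NGTDM) for every point of a
   240-combination extraction-parameter grid — 10,320 texture features
   per modality, 41,284 features for a 4-modality study.
3. **Deep features** (`extract_deep()`): the axial slice with the
   largest tumor area and its two neighbours form a 3-channel image per
   modality, forwarded through a backend honoring the AlexNet-FC7
   (227-pixel input, 4,096 units) or Inception-v3 average-pool
   (299-pixel input, 2,048 units) contract: 16,384 and 8,192 features
   over four modalities, 24,576 together.
4. **Univariate screening** (`univariate_screen()`): Spearman rank
   correlation of each feature with the outcome, Bonferroni-corrected.
5. **Feature reduction** (`reduce_features()`): stepwise forward
   selection by a gain equation balancing outcome association against
   redundancy measured by the maximal information coefficient (MIC),
   producing 25 ordered features per initial set; a handcrafted and a
   deep reduced set can be fused to 50 (`fuse_features()`).
6. **Model selection** (`forward_select()`): greedy growth of logistic
   models of order 1–10 from every starter feature, scored by the 0.632+
   bootstrap AUC; the order with the maximal score wins
   (`choose_order()`).
7. **Model construction** (`average_coefficients()`,
   `predict_probability()`): per-replicate in-bag logistic fits averaged
   coefficient-wise; probabilities via the logistic transform.
8. **Evaluation** (`evaluate_ensemble()`, `paired_ttest()`,
   `auc_trace()`): per-replicate training-role (in-bag) and
   validation-role (out-of-bag) AUC/Se/Sp/Acc with means, SDs, SEs, and
   paired comparisons between feature sets.

`run_pipeline()` binds stages 4–8 (and optionally 1–3) behind a single
declarative configuration with one master seed; every artifact records
the configuration hash so a run is reproducible from its outputs.

## The models

### Gain-equation feature reduction

With `d` features already selected (indexed `c = 1..d` in selection
order) and `D` features remaining, the gain of candidate `j` is

$$\bar{G}_j = \gamma\,\overline{|r_s|}(x_j, y)
  + \delta_a \sum_{c=1}^{d} \frac{2(d-c+1)}{d(d+1)}
    \overline{(1 - \mathrm{MIC}(x_c, x_j))}
  + \delta_b \frac{1}{D}\sum_{k=1}^{D}
    \overline{(1 - \mathrm{MIC}(x_k, x_j))},$$

where each overline is a mean over imbalance-adjusted bootstrap
replicates. The triangular weights sum to 1 for any `d`, weighting
redundancy against earlier (stronger) selections more heavily. Defaults
are `gamma = 0.5`, `delta_a = 0.5`, `delta_b = 0`; the third term is
inert by default but implemented and tested. The feature with maximal
gain is selected at each step until the target size (default 25) is
reached, and the final list is ordered by descending gain at selection.

Two deliberate choices here. First, the association term uses the
*absolute* Spearman correlation: strong negative correlates are as
predictive as positive ones, and a signed term would anti-select them
(set `absolute_rs = FALSE` in `gain_config()` for the signed variant).
Second, all bootstrap-averaged terms share one ensemble, reused across
candidates *and* across selection steps. Reuse across candidates removes
resampling noise from within-step comparisons; reuse across steps makes
the pair-level MIC averages cacheable, which turns an otherwise
quadratic-in-`D` recomputation into one row of MIC evaluations per
selection. Both are variance-reduction choices, not statements about the
sampling distribution.

### Maximal information coefficient

MIC is computed exactly within the standard admissible grid family: for
every grid size $k \times l$ with $k \cdot l \le \max(4, n^{0.6})$, one
axis is split into `l` equal-probability bins (ties kept together, bin =
⌈l·rank/n⌉ with max-ranks), and the partition of the other axis into at
most `k` bins is optimized *exactly* by dynamic programming over
tie-group boundaries; both orientations are searched, each entry is
normalized by $\log_2 \min(k, l_\mathrm{achieved})$, and the maximum is
returned. The `max(4, ·)` floor keeps the 2×2 grid admissible below
n ≈ 10, where the bare $n^{0.6}$ bound would exclude every grid. The
test suite verifies the DP against exhaustive enumeration of all cut
subsets at small `n`, including at an inflated grid bound that exercises
deeper grids.

### 0.632+ bootstrap AUC

For each replicate `b` with in-bag sample $x^{*b}$ and out-of-bag set
$x^{*b(0)}$:

$$\mathrm{AUC}' = \max(0.5,\ \mathrm{AUC}(x^{*b}, x^{*b(0)})), \qquad
\alpha^b = \frac{0.632}{1 - 0.368\,R^b},$$

$$\overline{\mathrm{AUC}}_{0.632+} = \frac{1}{B}\sum_{b=1}^{B}
  (1-\alpha^b)\,\mathrm{AUC}(x, x) + \alpha^b\,\mathrm{AUC}',$$

with the relative overfitting rate $R^b = 1$ when the out-of-bag AUC
falls below 0.5, $R^b = (\mathrm{AUC}(x,x) - \mathrm{AUC}(x^{*b},
x^{*b(0)})) / (\mathrm{AUC}(x,x) - 0.5)$ while the out-of-bag AUC lies
between 0.5 and the apparent AUC, and 0 otherwise, clipped to [0, 1]
with a guard when the apparent AUC is exactly 0.5. The middle condition
is the standard relative-overfitting-rate reading; the estimator is a
per-replicate convex combination of the apparent and clipped out-of-bag
AUCs, so $\alpha^b \in [0.632, 1]$ always.

### Imbalance-adjusted resampling

Each of the N draws of a replicate first picks a class with probability
1/2, then a uniform member of that class, so the rare class is not
underrepresented in-bag. Replicates whose in-bag multiset or out-of-bag
set lacks a class are redrawn (bounded at 100 retries; with a singleton
class, where that is unattainable, only a non-empty out-of-bag set is
required). A `"uniform"` mode provides the classical bootstrap, whose
expected distinct in-bag fraction 0.632 underlies the estimator's name —
at N = 51 that is ≈ 32 distinct in-bag and ≈ 19 out-of-bag patients. The
two modes differ slightly in expected in-bag composition; the pipeline
default is the imbalance-adjusted mode.

### Logistic fitting and averaging

Per-replicate fits are ridge-penalized IRLS with penalty
`ridge = 1e-4` on slopes only (the intercept is never penalized). With
in-bag sizes near 32 and up to 10 features, complete separation is
common and the unpenalized MLE diverges; the small ridge bounds
coefficients while leaving well-conditioned fits essentially at the MLE
(the test suite checks agreement with `glm` to well under 10% on
well-conditioned data). Features are z-scored with whole-sample
constants before fitting so that coefficients averaged across replicates
(Eq.-wise, intercept included) live on a common scale; the constants are
stored in the fitted model and applied when scoring raw inputs. A
zero-variance in-bag column is dropped from that fit with coefficient 0.

## Texture statistic conventions

All four matrix families aggregate the 13 unique 3D directions into a
single merged matrix (not per-direction averages). Definitions follow
the common radiomics conventions:

* GLCM: symmetric, distance-1, in-mask pairs only, normalized to sum 1.
  `Correlation` is imputed 0 for a single-level ROI.
* GLRLM: runs are maximal collinear constant-level in-mask sequences.
  Because runs from all 13 directions are merged, run percentage is
  normalized as `RP = runs / (13 × voxels)` so that its (0, 1] range
  contract survives the merge.
* GLSZM: zones are 26-connected constant-level components; `ZP = zones /
  voxels`.
* NGTDM: Amadasun–King statistics with an epsilon stabilizer (1e-6) in
  the Coarseness and Strength denominators.
* Gray level `g` in weighted statistics is the integer level `1..n_gray`,
  never the original intensity.

Degenerate statistics (e.g. a one-voxel ROI after coarse resampling) are
imputed as 0 with a warning — `extract_handcrafted()` collects these
into one summary message — keeping the feature table rectangular.

The default extraction grid is ratio_R ∈ {1/2, 2/3, 1, 3/2, 2} ×
scale_mm ∈ {1, 2, 3, 4} × quantizer ∈ {equal, uniform, lloyd} ×
n_gray ∈ {8, 16, 32, 64}: 240 combinations × 43 statistics = 10,320
texture features per modality. Every axis of the grid is configurable
via `texture_grid()`.

The wavelet band-pass step uses a one-level periodized 3D transform with
the sym8 basis by default (haar available), implemented as an orthogonal
transform so that `ratio_R = 1` reconstructs the input to numerical
precision; `ratio_R` multiplies the LLL and HHH sub-bands while the six
band-pass sub-bands pass unchanged. Odd axes are padded by edge
replication and cropped after reconstruction.

Shape features: `Volume` is voxel count × voxel volume; `Size` the
maximal pairwise distance between surface-voxel centers; `Solidity` the
mask volume over the volume of the convex hull of the surface voxels'
corner points (so a solid cube scores exactly 1); `Eccentricity`
$\sqrt{1 - \lambda_{\min}/\lambda_{\max}}$ from the second-moment
ellipsoid. The 3D convex hull is computed by an incremental algorithm
in-package. Shape features are computed once per study from the mask,
not per modality, since the segmentation is shared across registered
modalities.

## Deep-feature backends

Pretrained CNN weights are not bundled: the pipeline's contribution is
the surrounding machinery, and the package must run fully offline. The
backend registry accepts any extractor honoring the (input side, output
dimension) contract; two deterministic stubs shaped like AlexNet-FC7 and
Inception-v3-average-pool are built in. Each stub downsamples the
3-channel input to 32×32 and applies a fixed seeded random projection —
deterministic and approximately distance-preserving, so class-separable
images yield class-separable features, which is sufficient to exercise
fusion and selection. Stub features are *not* semantically meaningful;
conclusions about real deep features require a real backend. Channel
intensities are min–max scaled to [0, 1] per channel before the forward
pass (constancy decided before bilinear resizing, which introduces
rounding noise of order 1e-16 that a later min–max scale would amplify);
the in-plane crop uses the 3D bounding box's axial footprint.

## Univariate screening

`spearman_rs()` uses average ranks and the large-sample t approximation
for p values, with a constant-feature fallback of r_s = 0, p = 1.
`univariate_screen()` takes an explicit comparison count `K` for the
Bonferroni threshold α/K rather than always inferring it from the table
width, because screening is sometimes calibrated at a coarser grouping
(e.g. the statistic-family level: 4 nontexture + 43 statistics × 4
modalities = 176 comparisons for handcrafted features); `K` defaults to
the feature count.

## What the synthetic generators emulate — and what they do not

`generate_phantom()` builds ellipsoidal lesions centered in the grid;
inside-mask intensities come from Gaussian noise smoothed with a
class-specific correlation length and mapped affinely to class
mean/SD — the simplest generator giving class-separable texture-matrix
statistics. Default class parameters make recurrent lesions
finer-textured (correlation length 1.5 mm, higher SD) and brighter on
T1C, and necrotic lesions smoother (3 mm), darker on T1C, brighter on
T2/FLAIR — a caricature of the contrast behaviour that motivates
multimodality imaging. Deliberately *not* modelled: scanner physics,
bias fields, registration error, cysts, edema, irregular margins.
Passing tests therefore demonstrate that the machinery recovers known
structure under its own assumptions, not clinical performance.

`generate_feature_table()` emulates a reduced feature-selection problem
directly: standard-normal noise features with block-equicorrelation
(default block size 10, correlation 0.3), and an informative subset
shifted by `effect_size` SD units in the positive class. The default
cohort is 16 necrosis / 35 recurrence, mirroring the imbalance the
pipeline is designed around; both counts are configurable.

## Problem sizes used in tests and the acceptance script

The statistical behaviour checks run at deliberately modest sizes,
chosen as the smallest instances where each property is meaningfully
exercised: oracle comparisons for texture matrices on ≤ 5³ ROIs; MIC
versus exhaustive enumeration at n ≤ 10; greedy-versus-exhaustive model
search on 6 features with a 50-replicate ensemble; parameter recovery
over 20 seeds at the cohort's 16/35 split with 50 candidate features
reduced to 12 (25-replicate gain averages) and searched to order 5 with
5 starters over 200-replicate ensembles; null calibration on permuted
labels with 200-replicate ensembles. The acceptance script reduces a
200-feature table and a 256-feature table with 50-replicate gain
averages: the reduction/fusion set sizes it reports are invariant to the
replicate count, which only smooths the gain estimates. Full-cohort
runs at B = 1000 are the package defaults.

## Known limitations

* The gain equation's reduction cost is dominated by MIC evaluations;
  with `delta_b > 0` it grows quadratically in the candidate count.
* The supplement-level extraction-parameter grid and the exact
  statistic-family composition in the original analysis setting are not
  public; the defaults here follow the conventions of the MATLAB
  radiomics toolbox that setting was built on, and every axis is
  configurable. Feature *names* are package-specific, not IBSI-exact.
* Stub deep backends validate plumbing and dimension contracts only.
* Evaluation's "validation" metrics are out-of-bag metrics of
  per-replicate refits; the final averaged-coefficient model is a
  convenience summary whose out-of-sample behaviour is estimated by the
  same 0.632+ machinery, not by an external test set.
* 2D (slice-wise) texture variants are not implemented.
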