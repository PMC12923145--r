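---
title: "Topology-aware intratumoral heterogeneity scoring: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology-aware intratumoral heterogeneity scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Early lung adenocarcinomas seen as small CT nodules (5–30 mm) range from
in-situ / minimally invasive lesions, which are essentially cured by limited
resection, to invasive adenocarcinoma, which demands lobectomy and nodal
dissection. Histological invasiveness correlates with *intratumoral
heterogeneity* (ITH): the spatial disorganization of tissue phenotypes inside
the lesion. This package quantifies that disorganization directly from a CT
volume and a binary nodule segmentation, and provides the downstream
machinery — synthetic data, a classifier bench, SHAP attribution, and forward
feature selection — needed to evaluate the score as a predictive biomarker
without any clinical data.

## The score

Let $\Omega'$ be the region scored: either the axial slice of the mask with
the most in-mask pixels (2D mode) or the full voxel set (3D mode). Every
in-mask element receives a local feature vector (Section below), the vectors
are partitioned by K-means into $K$ subregions ("habitats"), and each
subregion $C_i$ is decomposed into connected components under the
mode-specific topology — 8-connectivity for pixels, 26-connectivity for
voxels. With $n_i$ the component count of subregion $i$, $S_{i,\max}$ the
element count of its largest component, and $S_{total}$ the total element
count of $\Omega'$:

$$\mathrm{ITH} \;=\; 1 \;-\; \frac{1}{S_{total}} \sum_{i=1}^{K}
\frac{S_{i,\max}}{n_i}.$$

The sum runs over non-empty subregions; empty ones (K-means may occupy fewer
than $K$ labels) contribute nothing. All quantities are element counts, so
the score is dimensionless, independent of voxel-spacing metadata, and lies
in $[0, 1)$: it is exactly $0$ iff every non-empty subregion is a single
connected blob, and approaches $1$ as subregions shatter into many similar
fragments. Splitting any subregion's components (count up, largest component
not larger) strictly increases the score — the monotonicity that makes it a
fragmentation measure.

Defaults follow the published procedure this implements: $K = 6$, a
$2\times2$ ($2\times2\times2$) sliding kernel, $N = 104$ features,
8/26-connectivity fixed per mode.

## The local feature bank

The reference procedure never enumerates its 104 per-element features, so the
bank here is an explicit, versioned stand-in, built to be rich, local,
deterministic, and cheap: center intensities (raw and clipped to the lung
window, level −600 HU width 1500 HU); first-order statistics (mean, variance,
skewness proxy, min, max, range, energy, 16-level quantized entropy) of the
sliding kernel and of box neighborhoods of radii 1–3; finite-difference
gradients and second derivatives per axis; the nine separable
smooth/edge/spot 3×3 in-plane filter responses on raw and windowed copies;
and a handful of normalized contrast summaries (center z-scores, coefficients
of variation, range ratios, smoothed absolute gradients). The count is
asserted to be exactly 104 at construction. Only the *richness* matters
downstream: the contribution of the method is the topology-aware score, not
the identity of any single feature.

Three conditioning choices matter:

* **Mask-aware intensities** (`mask_fill = TRUE`, default). The kernel of a
  boundary voxel reaches outside the segmentation into air at roughly
  −1000 HU. If those values are used verbatim, every nodule carries a strong
  boundary-shell signature: clusters organize around the rim, and even a
  perfectly homogeneous zero-noise lesion scores ≈ 0.25 rather than ≈ 0 (we
  measured exactly this during development). The default therefore replaces
  out-of-mask intensities with iteratively dilated in-mask values before any
  windowed computation, which restores the identity *homogeneous nodule ⇒
  score 0* and makes the score reflect internal tissue organization rather
  than lesion silhouette. Set `mask_fill = FALSE` to reproduce the naive
  behaviour.
* **Standardization** (`standardize = TRUE`). K-means is scale-sensitive;
  columns are standardized to zero mean and unit population variance.
  Columns with standard deviation below `1e-8` are mapped to zero rather
  than divided by a vanishing scale, so numerically constant inputs cannot
  be amplified into pseudo-structure.
* **Kernel anchoring.** A $2\times2(\times2)$ kernel has no center; it is
  anchored at its minimum corner, so element $x$ aggregates $x$ and its
  positive-direction neighbors. Out-of-grid positions are edge-replicated.

## Clustering

Per-image K-means with k-means++ seeding, 10 restarts, Lloyd iterations
(cap 300, tolerance $10^{-4}$), lowest within-cluster sum of squares wins.
Seeding is performed over a canonical lexicographic ordering of the feature
rows, which makes the spatial partition invariant to the storage order of
the mask elements. If the mask contains at most $K$ distinct feature
vectors, each distinct vector becomes its own pure cluster (the relevant
degenerate case is the exactly-homogeneous nodule, which collapses to a
single occupied label and scores 0). Cluster label identities are
arbitrary; every downstream quantity is label-permutation invariant.

## Synthetic data: what it emulates and what it does not

`generate_phantom()` builds an ellipsoidal nodule (default grid
36×48×48 voxels at 1×0.7×0.7 mm, in-plane semi-axes 8–14 voxels — the 5–30 mm
band of screening practice) whose mask is divided into 1–6 phenotypes, each
placed as a requested number of disjoint 26-connected blobs (Voronoi cells
of well-separated seeds, colored so same-phenotype cells never touch, with a
slab-layout fallback; the construction is verified against the returned
truth grid, so the ground-truth component counts are exact by construction).
Phenotypes differ by a mean offset (default contrast 300 HU on a −600 HU
ground-glass base — the pGGN-to-solid attenuation range) plus iid Gaussian
noise (default 15 HU, typical thin-section reconstruction noise). What it
does **not** emulate: partial-volume blur, anisotropic reconstruction
kernels, beam hardening, vessels/bronchi traversing the lesion, or
spatially correlated noise. A green phantom test therefore establishes that
the pipeline recovers *designed* topology at realistic contrast-to-noise,
not that clinical scores are reproduced.

`generate_cohort()` emulates a stage-I adenocarcinoma table: binary
invasiveness label at prevalence 0.66; sex (66% female), age (median ≈ 57),
nodule size (median ≈ 15.8 mm, clipped to 5–30), CT density
(pGGN/PSN/SN ≈ 54/26/20%), lobe location, six binary morphological signs at
their published marginal rates, and 2D/3D ITH scores in $[0,1)$. All
label–feature couplings flow through one latent invasiveness variable
$v = \mathrm{effect}\cdot(\mathrm{label} - 0.66) + \mathcal N(0,1)$ with
logistic links; the single `effect` knob (default 1.5) scales every
coupling, so `effect = 0` yields an exactly label-independent null cohort.
Coupling strengths are fixed constants chosen once: the 3D ITH slope (1.0)
dominates the 2D slope (0.45), size (0.13 on log-scale) and density (0.5 on
the ordinal latent), mirroring the importance hierarchy the method is meant
to exhibit; morphological signs get weak slopes (0.25). These are stated
world-building constants, not fitted quantities.

## The classifier bench

Six tree-ensemble classifiers share one exact-greedy CART engine
(second-order gradient statistics, midpoint thresholds, split rule
`x < thr`): first-order gradient boosting (GBDT), second-order depth-wise
boosting with L2 penalty (XGBoost-style), leaf-wise best-first growth
(LightGBM-style), oblivious/symmetric trees (CatBoost-style), SAMME AdaBoost
with weighted CART weak learners, and a bootstrap random forest with
per-node feature subsampling. None of the upstream libraries exist in this
environment, so the variants are implemented natively; the CatBoost variant
keeps symmetric trees but **not** ordered boosting / ordered target
statistics, and categorical inputs are ordinal-encoded for all models rather
than one-hot or target-encoded.

Hyperparameters are tuned by grid search embedded in stratified 5-fold CV:
for every grid point, out-of-fold predictions are assembled (each training
row predicted exactly once, asserted), the point with the highest mean OOF
AUC wins, and the model is refit on the full training part. Default grids
are small (8 points per classifier over estimator count, tree size, learning
rate) and overridable; the framework, not the grid content, is the contract.
Metrics: rank-based AUC; accuracy, precision, recall and F1 at threshold
0.5 with weighted class averaging by default (`average = "binary"`/`"macro"`
available — published recall patterns are ambiguous about the averaging
convention, so it is a switch rather than a guess). Class-group score
comparisons use the two-sided Wilcoxon rank-sum test, chosen for
distribution-freeness.

## SHAP attribution and forward selection

Feature attribution uses path-dependent TreeSHAP on the model margin
(log-odds for boosters, $2F$ for AdaBoost, probability for the forest),
implemented natively with per-node training covers as the conditional
expectation weights. Two properties are enforced by test: *local accuracy*
(attributions plus the expected value reproduce the margin to $10^{-6}$) and
*exactness* (agreement to $10^{-9}$ with a brute-force subset-enumeration
Shapley oracle on small ensembles). Global importance is the mean absolute
SHAP value over the supplied cohort (the training part, by default); ties
break by column order.

Forward selection retrains each classifier on nested prefixes of its own
SHAP ranking under 5-fold CV, producing one AUC trajectory per classifier.
"Consistently highest trajectory" is operationalized as highest mean AUC
across prefix lengths, tie-broken by the full-feature AUC. The knee point
$l^*$ is the first prefix length whose marginal AUC gain is $\le \varepsilon$
(default $\varepsilon = 0$); if every gain is positive, $l^* = N$ (the scan
would otherwise exit unassigned). CV noise can trigger premature knees at
$\varepsilon = 0$; a trailing-window smoothing of the trajectory is
deliberately **not** applied by default, and $\varepsilon$ is exposed
instead.

## Numerical and degenerate-input policy

* Score identities are exact, not approximate: integer component counts and
  sizes, one floating division per cluster.
* Ties: equal-count largest slices resolve to the lowest slice index;
  nearest-centroid ties resolve to the lowest centroid index; importance
  ties resolve to original column order — all for replay determinism.
* Degenerate inputs fail fast with stage-named errors: empty masks, masks
  smaller than $K$, single-row standardization, single-class parts for AUC,
  ratio outside $(0,1)$, fewer than 2 members per class per split, and
  infeasible phantom blob packings.
* Every stochastic step (seeding, restarts, splits, folds, subsampling) is
  driven by an explicit integer seed; reruns are bitwise identical.

## Known limitations

* The feature bank is a documented stand-in; scores are comparable across
  runs of this package but not numerically against other ITH-score
  implementations.
* Per-image clustering means subregion labels carry no cross-patient
  identity, and no biological meaning (necrosis vs. cellularity) is claimed
  for any habitat.
* With `mask_fill = FALSE`, boundary-shell structure dominates small
  lesions and homogeneous nodules score ≈ 0.25; this configuration exists
  for comparison only.
* The CatBoost-style learner omits ordered boosting; on very small cohorts
  its overfitting behaviour will differ from the upstream library.
* Cohort marginals are loose emulations of a published table, not a
  distributional claim; clinical AUCs are not reproducible from synthetic
  cohorts and are not targeted by any test.
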