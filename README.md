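# ithscore

Topology-aware quantification of **intratumoral heterogeneity (ITH)** for
segmented lung nodules on CT, with the full evaluation bench needed to study
the score as a biomarker of adenocarcinoma invasiveness — entirely on
synthetic data.

## Who this is for

Radiomics and medical-image-analysis researchers who have (a) a CT volume
and a co-registered binary nodule mask (NIfTI or NRRD), or (b) a tabular
clinicoradiologic cohort, and want a reproducible, dependency-light R
implementation of habitat-fragmentation ITH scoring plus the downstream
model-selection machinery (gradient-boosting bench, SHAP importance,
forward feature selection).

## The score

Each in-mask element gets a 104-dimensional local feature vector from a
2×2 (2D) or 2×2×2 (3D) sliding kernel and surrounding box neighborhoods.
K-means (K = 6) partitions the elements into phenotypic subregions, and each
subregion is decomposed into connected components — 8-connectivity on the
largest axial slice (2D score), 26-connectivity over the volume (3D score).
With `n_i` components per subregion, largest-component size `S_i,max`, and
total size `S_total`:

    ITH = 1 − (1 / S_total) · Σ_i  S_i,max / n_i        ∈ [0, 1)

0 means every subregion is one contiguous blob; values near 1 mean extreme
spatial fragmentation. Everything is an element count, so voxel spacing and
intensity calibration cancel.

## Worked example

```r
library(ithscore)

# a synthetic nodule with 3 phenotypes, each fragmented into 3 blobs
ph <- generate_phantom(phantom_spec(fragmentation = 3, seed = 42))
write_phantom(ph, "nodule_image.nii.gz", "nodule_mask.nii.gz")

img <- read_nodule("nodule_image.nii.gz", "nodule_mask.nii.gz")
compute_ith(img, "3D", seed = 42)
#> <ith_result> 3D ITH score = 0.71109 (K = 6, N = 104, 26-connectivity)
compute_ith(img, "2D", seed = 42)
#> <ith_result> 2D ITH score = 0.69293 (K = 6, N = 104, 8-connectivity)
```

A heavily fragmented phantom scores ≈ 0.71: the per-cluster summary shows
why — most of the six subregions break into 2–3 disconnected pieces, so each
contributes only `largest/components` of its area to the contiguity sum
(Σ = 1521 of 5264 voxels). A phantom with contiguous phenotypes
(`fragmentation = 1`) scores ≈ 0, and a homogeneous noise-free nodule scores
exactly 0.

```r
co <- generate_cohort(600, seed = 42)           # synthetic invasiveness cohort
compare_groups(co$ith3d, co$label)$p_value      # IAC vs AIS/MIA rank-sum
#> 4.54e-43

cfg <- bench_config(classifiers = c("catboost", "xgboost", "rf"), seed = 42)
parts <- stratified_split(co, 0.7, seed = 42)   # 7:3 stratified
tuned <- tune_and_fit(parts$train, cfg)         # grid search inside 5-fold CV
round(evaluate(tuned$models[["xgboost"]], parts$test), 3)
#>       auc  accuracy precision    recall        f1
#>     0.810     0.733     0.733     0.733     0.733

global_importance(tuned$models[["xgboost"]], encode_cohort(parts$train))[1:3, ]
#>  feature importance rank
#>    ith3d      1.369    1
#>    ith2d      0.196    2
#>  size_mm      0.172    3

run_selection(parts$train, cfg, epsilon = 0, tuned = tuned)
#> <selection_report> best classifier: xgboost, knee l* = 3
#> optimal subset: ith3d, ith2d, size_mm
```

The 3D ITH score carries the dominant SHAP importance by construction of the
generator, the mean out-of-fold AUC picks the best of the six classifiers,
and the knee point truncates the SHAP-ranked feature list where marginal AUC
gain stops.

## Command line

```sh
Rscript inst/cli/ith score   --image img.nii.gz --mask mask.nii.gz --mode both --seed 1 --out scores.json
Rscript inst/cli/ith phantom --fragmentation 3 --seed 1 --out-prefix ph
Rscript inst/cli/ith cohort  --n 500 --seed 1 --out cohort.csv
Rscript inst/cli/ith bench   --cohort cohort.csv --quick --out report.json
Rscript inst/cli/ith ablate  --cohort cohort.csv --classifiers catboost,gbdt --quick --out traj.json
```

Every run writes a `.manifest.json` next to its output; replaying a manifest
reproduces outputs bitwise (all randomness flows from `--seed`).

## Package layout

- `R/`, `src/` — feature bank, clustering, topology score (Rcpp connected
  components), phantom/cohort generators, six-classifier CART/boosting
  engine, TreeSHAP, selection framework, CLI.
- `tests/testthat/` — unit + property tests per module, brute-force oracles
  (flood fill, subset-enumeration Shapley), and the acceptance suite.
- `vignettes/ith-scoring-methods.Rmd` — model, parameter and design notes.
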