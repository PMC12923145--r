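Package: ithscore
Title: Topology-Aware 2D/3D Intratumoral Heterogeneity Scoring for CT Nodules
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies intratumoral heterogeneity (ITH) of lung nodules on CT as the
    spatial fragmentation of phenotypic subregions. Local radiomic features are extracted
    per in-mask element with a small sliding window, partitioned by K-means into K habitat
    subregions, and each subregion's connected-component topology (8-connectivity on the
    largest axial slice, 26-connectivity over the full volume) is summarised into a
    dimensionless score in [0,1). Ships a synthetic nodule-phantom and clinicoradiologic
    cohort generator, a six-classifier gradient-boosting/forest bench with grid search
    inside stratified 5-fold cross-validation, TreeSHAP-based global feature importance,
    and SHAP-guided forward feature selection with knee-point identification.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
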