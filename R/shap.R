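# SHAP attribution and the SHAP-guided forward-selection framework:
# TreeSHAP values on the model margin, global importance I_i = mean |phi_i|,
# per-classifier prefix AUC trajectories, comparative best-classifier
# selection, and knee-point identification of the optimal feature subset.

#' TreeSHAP values for a fitted tree-ensemble model
#'
#' Path-dependent TreeSHAP on the model's margin scale. The local-accuracy
#' identity holds: rowSums(phi) + expected value = margin(x).
#'
#' @param model an `ith_model` (tree ensembles only).
#' @param x numeric matrix with the model's feature columns.
#' @return Matrix n x p of SHAP values with attribute `expected_value`.
#' @export
shap_values <- function(model, x) {
  if (!inherits(model, "ith_model"))
    stage_error("shap_selection", "unsupported model: TreeSHAP needs a tree ensemble")
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != model$n_features)
    stage_error("shap_selection", "feature count mismatch")
  phi <- cpp_treeshap(model$trees, x, model$n_features)
  colnames(phi) <- model$feature_names
  attr(phi, "expected_value") <- model$base + cpp_forest_expectation(model$trees)
  phi
}

#' Global SHAP importance ranking
#'
#' I_i = (1/N) sum_j |phi_i(j)| over the supplied cohort; features ranked in
#' descending importance, ties broken by original column order.
#'
#' @param model an `ith_model`.
#' @param x numeric matrix (typically the training part).
#' @return An object of class `importance_ranking`: data frame with columns
#'   feature, importance, rank (in ranked order).
#' @export
global_importance <- function(model, x) {
  if (nrow(as.matrix(x)) == 0L) stage_error("shap_selection", "empty data")
  phi <- shap_values(model, x)
  I <- colMeans(abs(phi))
  ord <- order(-I, seq_along(I))
  structure(data.frame(feature = model$feature_names[ord],
                       importance = unname(I[ord]),
                       rank = seq_along(I),
                       stringsAsFactors = FALSE),
            class = c("importance_ranking", "data.frame"))
}

#' Prefix AUC trajectory for one classifier
#'
#' For i = 1..N, refits the classifier on the first i ranked features with
#' stratified K-fold CV and records the mean OOF AUC.
#'
#' @param classifier classifier id.
#' @param ranking an `importance_ranking` covering the candidate features.
#' @param train training cohort part.
#' @param seed RNG seed (folds shared across prefixes).
#' @param params hyperparameters for the classifier (default method defaults).
#' @param folds CV folds.
#' @return An object of class `selection_trajectory`: classifier, ranked
#'   features, `auc` vector (one per prefix).
#' @export
trajectory <- function(classifier, ranking, train, seed = 1L, params = list(),
                       folds = 5L) {
  stopifnot(inherits(ranking, "importance_ranking"))
  feats <- ranking$feature
  x <- encode_cohort(train, feats)
  y <- train$label
  fold <- make_folds(y, folds, seed)
  aucs <- vapply(seq_along(feats), function(i) {
    xi <- x[, seq_len(i), drop = FALSE]
    oof <- rep(NA_real_, length(y))
    for (f in seq_len(folds)) {
      tr <- fold != f
      m <- fit_classifier(xi[tr, , drop = FALSE], y[tr], classifier, params,
                          seed = seed + f)
      oof[!tr] <- predict(m, xi[!tr, , drop = FALSE], type = "prob")
    }
    auc_score(y, oof)
  }, numeric(1))
  structure(list(classifier = classifier, features = feats, auc = aucs),
            class = "selection_trajectory")
}

#' Select the classifier with the consistently highest trajectory
#'
#' Operationalized as highest mean AUC across prefix lengths; ties broken by
#' the AUC at the full feature set, then by input order.
#'
#' @param trajectories list of `selection_trajectory` objects over the same
#'   prefixes.
#' @return The winning classifier id.
#' @export
select_best <- function(trajectories) {
  if (!length(trajectories)) stage_error("shap_selection", "no trajectories")
  lens <- vapply(trajectories, function(t) length(t$auc), integer(1))
  if (length(unique(lens)) != 1L)
    stage_error("shap_selection", "trajectories cover different prefix sets")
  means <- vapply(trajectories, function(t) mean(t$auc), numeric(1))
  finals <- vapply(trajectories, function(t) t$auc[length(t$auc)], numeric(1))
  best <- order(-means, -finals)[1]
  trajectories[[best]]$classifier
}

#' Knee-point identification
#'
#' Scans l = 1..N-1 and returns the first l with
#' Delta = AUC_{l+1} - AUC_l <= epsilon; if no such l exists, returns N.
#'
#' @param traj a `selection_trajectory` or numeric AUC vector.
#' @param epsilon non-negative marginal-gain threshold (default 0).
#' @return Integer knee point l*.
#' @export
find_knee <- function(traj, epsilon = 0) {
  auc <- if (inherits(traj, "selection_trajectory")) traj$auc else as.numeric(traj)
  n <- length(auc)
  if (n < 2L) stage_error("shap_selection", "trajectory length must be >= 2")
  if (epsilon < 0) stage_error("shap_selection", "epsilon must be >= 0")
  for (l in seq_len(n - 1L)) {
    if (auc[l + 1L] - auc[l] <= epsilon) return(l)
  }
  n
}

#' SHAP-guided iterative feature selection (end to end)
#'
#' Phase 1: for each classifier, fit on all features, rank by global SHAP
#' importance, and trace the prefix AUC trajectory under K-fold CV. Phase 2:
#' select the classifier with the consistently highest trajectory. Phase 3:
#' knee-point identification on the winner yields the optimal subset S*.
#'
#' @param train training cohort part.
#' @param config a [bench_config()]; classifiers and seed are honoured, and
#'   each classifier uses its best grid point from a prior [tune_and_fit()]
#'   when `tuned` is supplied.
#' @param epsilon knee threshold (default 0).
#' @param tuned optional `cv_report` from [tune_and_fit()] supplying fitted
#'   full-feature models (skips refitting).
#' @return An object of class `selection_report`: trajectories, rankings,
#'   best classifier, knee `l_star` and `optimal_subset`.
#' @export
run_selection <- function(train, config = bench_config(), epsilon = 0,
                          tuned = NULL) {
  cols <- feature_config_columns(config$feature_config)
  x <- encode_cohort(train, cols)
  if (is.null(tuned)) tuned <- tune_and_fit(train, config)
  trajs <- list(); rankings <- list()
  for (cl in config$classifiers) {
    model <- tuned$models[[cl]]
    rk <- global_importance(model, x)
    # prefix refits reuse the tuned hyperparameters
    trajs[[cl]] <- trajectory(cl, rk, train, seed = config$seed,
                              params = model$params, folds = config$cv_folds)
    trajs[[cl]]$params <- model$params
    rankings[[cl]] <- rk
  }
  best <- select_best(trajs)
  l_star <- find_knee(trajs[[best]], epsilon)
  structure(list(trajectories = trajs, rankings = rankings,
                 best_classifier = best, l_star = l_star,
                 optimal_subset = trajs[[best]]$features[seq_len(l_star)],
                 epsilon = epsilon),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> best classifier: %s, knee l* = %d\n",
              x$best_classifier, x$l_star))
  cat("optimal subset:", paste(x$optimal_subset, collapse = ", "), "\n")
  invisible(x)
}
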