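# Machine-learning bench: stratified splitting, grid search embedded within
# stratified 5-fold cross-validation with out-of-fold (OOF) AUC selection,
# test-set metrics, the six-configuration feature-ablation study, and the
# two-group ITH comparison.

FEATURE_CONFIGS <- c("2DITH-3DITH-CR", "2DITH-CR", "3DITH-CR", "CR", "2DITH", "3DITH")
CR_COLUMNS <- c("age", "sex", "size_mm", "density", "location", "margin",
                "lobulation", "spiculation", "vascular_convergence", "vacuole",
                "pleural_indentation", "shape")

#' Columns used by a feature configuration
#'
#' @param config one of the six ablation configurations.
#' @return Character vector of cohort column names.
#' @export
feature_config_columns <- function(config) {
  config <- match.arg(config, FEATURE_CONFIGS)
  switch(config,
         "2DITH-3DITH-CR" = c(CR_COLUMNS, "ith2d", "ith3d"),
         "2DITH-CR" = c(CR_COLUMNS, "ith2d"),
         "3DITH-CR" = c(CR_COLUMNS, "ith3d"),
         "CR" = CR_COLUMNS,
         "2DITH" = "ith2d",
         "3DITH" = "ith3d")
}

#' Encode cohort columns as a numeric model matrix
#'
#' Ordinal integer codes for factors (density pGGN<PSN<SN as 0/1/2, location
#' and sex as level codes); only the requested columns are read.
#'
#' @param cohort a `cohort_table` (or data.frame with its schema).
#' @param columns columns to encode (default: full configuration).
#' @return Numeric matrix with one column per requested cohort column.
#' @export
encode_cohort <- function(cohort, columns = feature_config_columns("2DITH-3DITH-CR")) {
  miss <- setdiff(columns, names(cohort))
  if (length(miss))
    stage_error("model_bench", paste("cohort lacks column(s):", paste(miss, collapse = ", ")))
  enc <- lapply(columns, function(cn) {
    v <- cohort[[cn]]
    if (is.factor(v)) as.numeric(v) - 1 else as.numeric(v)
  })
  m <- do.call(cbind, enc)
  colnames(m) <- columns
  m
}

#' Stratified train/test split
#'
#' Per-class sampling so each part's class proportion is within one sample of
#' the overall proportion; parts are disjoint and exhaustive.
#'
#' @param cohort a `cohort_table`.
#' @param ratio training fraction, strictly in (0, 1).
#' @param seed RNG seed.
#' @return List with `train` and `test` data frames.
#' @export
stratified_split <- function(cohort, ratio = 0.7, seed = 1L) {
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1)
    stage_error("model_bench", "split ratio must be strictly between 0 and 1")
  y <- cohort$label
  if (length(unique(y)) < 2L)
    stage_error("model_bench", "both classes must be present")
  if (any(table(y) < 2L))
    stage_error("model_bench", "each class needs at least 2 members")
  with_seed(seed, {
    tr_idx <- unlist(lapply(unique(y), function(cl) {
      ids <- which(y == cl)
      sample(ids, round(ratio * length(ids)))
    }))
  })
  tr_idx <- sort(tr_idx)
  list(train = cohort[tr_idx, , drop = FALSE],
       test = cohort[setdiff(seq_len(nrow(cohort)), tr_idx), , drop = FALSE])
}

# stratified fold ids 1..k
make_folds <- function(y, k = 5L, seed = 1L) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      ids <- sample(which(y == cl))
      fold[ids] <- rep_len(seq_len(k), length(ids))
    }
  })
  if (any(vapply(seq_len(k), function(f) length(unique(y[fold == f])) < 2L, TRUE)))
    stage_error("model_bench", "degenerate fold with a single class; use more data")
  fold
}

#' Rank-based AUC
#'
#' @param y binary labels; @param p scores.
#' @return AUC in [0, 1].
#' @export
auc_score <- function(y, p) {
  y <- as.numeric(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stage_error("model_bench", "AUC undefined: single-class part")
  r <- rank(p, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# accuracy/precision/recall/F1 at a threshold; weighted averaging over both
# classes by default, "binary" reports the positive class only
classification_metrics <- function(y, p, threshold = 0.5,
                                   average = c("weighted", "binary", "macro")) {
  average <- match.arg(average)
  yhat <- as.integer(p >= threshold)
  acc <- mean(yhat == y)
  per_class <- function(cl) {
    tp <- sum(yhat == cl & y == cl)
    prec <- if (sum(yhat == cl) > 0) tp / sum(yhat == cl) else 0
    rec <- if (sum(y == cl) > 0) tp / sum(y == cl) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(precision = prec, recall = rec, f1 = f1, support = sum(y == cl))
  }
  m <- vapply(c(0, 1), per_class, numeric(4))
  out <- switch(average,
    binary = m[1:3, 2],
    macro = rowMeans(m[1:3, , drop = FALSE]),
    weighted = as.vector(m[1:3, ] %*% (m[4, ] / sum(m[4, ]))))
  names(out) <- c("precision", "recall", "f1")
  c(accuracy = acc, out)
}

#' Evaluate a fitted model on a cohort part
#'
#' AUC from predicted probabilities plus accuracy/precision/recall/F1 at the
#' 0.5 threshold (weighted averaging by default).
#'
#' @param model an `ith_model`.
#' @param part cohort data frame containing the model's feature columns.
#' @param threshold decision threshold.
#' @param average `"weighted"`, `"binary"` or `"macro"`.
#' @return Named numeric vector: auc, accuracy, precision, recall, f1.
#' @export
evaluate <- function(model, part, threshold = 0.5, average = "weighted") {
  stopifnot(inherits(model, "ith_model"))
  if (nrow(part) == 0L) stage_error("model_bench", "empty evaluation part")
  x <- encode_cohort(part, model$feature_names)
  p <- predict(model, x, type = "prob")
  c(auc = auc_score(part$label, p),
    classification_metrics(part$label, p, threshold, average))
}

#' Bench configuration
#'
#' @param classifiers subset of the six classifier ids.
#' @param grids named list of per-classifier hyperparameter grids
#'   (default [ith_default_grids()]).
#' @param cv_folds CV folds (default 5).
#' @param split_ratio train fraction for [stratified_split()] (default 0.7).
#' @param seed RNG seed shared by split, folds and fits.
#' @param feature_config one of the six ablation configurations.
#' @param average metric averaging mode.
#' @return An object of class `bench_config`.
#' @export
bench_config <- function(classifiers = ITH_CLASSIFIERS, grids = ith_default_grids(),
                         cv_folds = 5L, split_ratio = 0.7, seed = 1L,
                         feature_config = "2DITH-3DITH-CR", average = "weighted") {
  classifiers <- match.arg(classifiers, ITH_CLASSIFIERS, several.ok = TRUE)
  if (cv_folds < 2L) stage_error("model_bench", "cv_folds must be >= 2")
  feature_config <- match.arg(feature_config, FEATURE_CONFIGS)
  structure(list(classifiers = classifiers, grids = grids,
                 cv_folds = as.integer(cv_folds), split_ratio = split_ratio,
                 seed = as.integer(seed), feature_config = feature_config,
                 average = average),
            class = "bench_config")
}

#' Grid search within stratified K-fold CV
#'
#' For every classifier and grid point, OOF predictions are assembled from
#' the hold-out folds (each training row predicted exactly once); the grid
#' point maximizing mean OOF AUC wins and the model is refit on the full
#' training part with the winning parameters.
#'
#' @param train training cohort part.
#' @param config a [bench_config()].
#' @return An object of class `cv_report`: per-classifier best parameters,
#'   OOF AUC, refit models and the OOF prediction matrix.
#' @export
tune_and_fit <- function(train, config = bench_config()) {
  cols <- feature_config_columns(config$feature_config)
  x <- encode_cohort(train, cols)
  y <- train$label
  if (any(table(y) < config$cv_folds))
    stage_error("model_bench", "need >= cv_folds members per class in train")
  fold <- make_folds(y, config$cv_folds, config$seed)
  models <- list(); rows <- list(); oof_best <- list()
  for (cl in config$classifiers) {
    grid <- config$grids[[cl]] %||% list(list())
    best <- NULL
    for (gi in seq_along(grid)) {
      oof <- rep(NA_real_, length(y))
      for (f in seq_len(config$cv_folds)) {
        tr <- fold != f
        m <- fit_classifier(x[tr, , drop = FALSE], y[tr], cl, grid[[gi]],
                            seed = config$seed + f)
        oof[!tr] <- predict(m, x[!tr, , drop = FALSE], type = "prob")
      }
      stopifnot(!anyNA(oof))  # OOF covers each training row exactly once
      a <- auc_score(y, oof)
      if (is.null(best) || a > best$auc + 1e-12)
        best <- list(auc = a, params = grid[[gi]], oof = oof)
    }
    models[[cl]] <- fit_classifier(x, y, cl, best$params, seed = config$seed)
    oof_best[[cl]] <- best$oof
    rows[[cl]] <- data.frame(classifier = cl, oof_auc = best$auc,
                             params = paste(names(best$params),
                                            unlist(best$params),
                                            sep = "=", collapse = ","),
                             stringsAsFactors = FALSE)
  }
  structure(list(models = models, table = do.call(rbind, rows),
                 oof = oof_best, y = y, config = config),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report>\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Six-configuration feature-ablation study
#'
#' Runs [tune_and_fit()] and [evaluate()] once per feature configuration with
#' a shared stratified split and seed, mirroring the ablation design
#' (full / 2D-only / 3D-only / CR-only combinations). With several
#' classifiers configured, each configuration reports its best classifier by
#' test AUC.
#'
#' @param cohort a `cohort_table`.
#' @param config a [bench_config()]; its `feature_config` is ignored.
#' @return An object of class `ablation_report`: data frame with one row per
#'   configuration and part (train OOF / test), plus the fitted models.
#' @export
ablation_study <- function(cohort, config = bench_config(classifiers = "catboost")) {
  parts <- stratified_split(cohort, config$split_ratio, config$seed)
  rows <- list(); models <- list()
  for (fc in FEATURE_CONFIGS) {
    cfg <- config
    cfg$feature_config <- fc
    rep_fc <- tune_and_fit(parts$train, cfg)
    best_cl <- NULL; best_m <- NULL; best_metrics <- NULL
    for (cl in names(rep_fc$models)) {
      met <- evaluate(rep_fc$models[[cl]], parts$test, average = config$average)
      if (is.null(best_metrics) || met["auc"] > best_metrics["auc"] + 1e-12) {
        best_metrics <- met; best_cl <- cl; best_m <- rep_fc$models[[cl]]
      }
    }
    models[[fc]] <- best_m
    rows[[length(rows) + 1L]] <- data.frame(
      configuration = fc, part = "train_oof", classifier = best_cl,
      auc = rep_fc$table$oof_auc[rep_fc$table$classifier == best_cl],
      accuracy = NA, precision = NA, recall = NA, f1 = NA)
    rows[[length(rows) + 1L]] <- data.frame(
      configuration = fc, part = "test", classifier = best_cl,
      auc = best_metrics[["auc"]], accuracy = best_metrics[["accuracy"]],
      precision = best_metrics[["precision"]], recall = best_metrics[["recall"]],
      f1 = best_metrics[["f1"]])
  }
  structure(list(table = do.call(rbind, rows), models = models,
                 split = parts, config = config),
            class = "ablation_report")
}

#' Two-group comparison of ITH scores
#'
#' Two-sided Wilcoxon rank-sum comparison of scores between classes.
#'
#' @param scores numeric scores; @param labels binary group labels.
#' @return List with `statistic` and `p_value`.
#' @export
compare_groups <- function(scores, labels) {
  g1 <- scores[labels == 1]; g0 <- scores[labels == 0]
  if (length(g1) < 3L || length(g0) < 3L)
    stage_error("model_bench", "need >= 3 observations per group")
  wt <- suppressWarnings(wilcox.test(g1, g0, alternative = "two.sided"))
  p <- wt$p.value
  if (is.nan(p)) p <- 1  # complete ties: the normal approximation degenerates
  list(statistic = unname(wt$statistic), p_value = min(p, 1))
}
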