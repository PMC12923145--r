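# Six tree-ensemble classifiers on a shared CART engine (src/trees.cpp).
# Each returns an additive forest over a margin; the probability link is
# logistic for the boosters, plogis(2F) for SAMME AdaBoost, and identity
# (clipped) for the random forest, whose trees vote probabilities directly.

ITH_CLASSIFIERS <- c("gbdt", "adaboost", "xgboost", "lightgbm", "catboost", "rf")

default_params <- function(method) {
  switch(method,
    gbdt = list(n_trees = 150L, learning_rate = 0.1, max_depth = 3L,
                subsample = 1, lambda = 0),
    xgboost = list(n_trees = 150L, learning_rate = 0.1, max_depth = 3L,
                   lambda = 1, subsample = 1, colsample = 1),
    lightgbm = list(n_trees = 150L, learning_rate = 0.1, max_leaves = 15L,
                    lambda = 1),
    catboost = list(n_trees = 200L, learning_rate = 0.1, max_depth = 4L,
                    lambda = 3),
    adaboost = list(n_trees = 80L, max_depth = 2L, learning_rate = 1),
    rf = list(n_trees = 300L, max_depth = 10L, mtry = 0L, min_child = 2L),
    stage_error("model_bench", paste("unknown classifier:", method)))
}

#' Default hyperparameter grids
#'
#' Small documented grids (8 points per classifier) over estimator count,
#' tree size and learning rate. The tuning framework, not the grid content,
#' is the contract; grids are overridable via [bench_config()].
#'
#' @return Named list: per classifier, a list of parameter lists.
#' @export
ith_default_grids <- function() {
  gr <- function(...) {
    g <- expand.grid(..., stringsAsFactors = FALSE)
    lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
  }
  list(
    gbdt = gr(n_trees = c(100L, 200L), max_depth = c(2L, 3L),
              learning_rate = c(0.05, 0.1)),
    adaboost = gr(n_trees = c(50L, 100L), max_depth = c(1L, 2L),
                  learning_rate = c(0.5, 1)),
    xgboost = gr(n_trees = c(100L, 200L), max_depth = c(2L, 3L),
                 learning_rate = c(0.05, 0.1)),
    lightgbm = gr(n_trees = c(100L, 200L), max_leaves = c(7L, 15L),
                  learning_rate = c(0.05, 0.1)),
    catboost = gr(n_trees = c(100L, 200L), max_depth = c(3L, 4L),
                  learning_rate = c(0.05, 0.1)),
    rf = gr(n_trees = c(200L, 400L), mtry = c(0L, 3L), min_child = c(2L, 5L)))
}

#' Fit one of the six classifiers
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y binary 0/1 response.
#' @param method one of `"gbdt"`, `"adaboost"`, `"xgboost"`, `"lightgbm"`,
#'   `"catboost"`, `"rf"`.
#' @param params named list overriding the per-method defaults.
#' @param seed RNG seed for row/feature subsampling.
#' @return An object of class `ith_model`.
#' @export
fit_classifier <- function(x, y, method = ITH_CLASSIFIERS, params = list(),
                           seed = 1L) {
  method <- match.arg(method)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (length(y) != nrow(x)) stage_error("model_bench", "x/y length mismatch")
  if (any(!y %in% c(0, 1))) stage_error("model_bench", "y must be binary 0/1")
  p <- merge_params(default_params(method), params)
  seed <- as.integer(seed)
  fit <- switch(method,
    gbdt = cpp_boost(x, y, p$n_trees, p$learning_rate, p$max_depth, 0L, 0L,
                     p$lambda, p$subsample, 1, 1L, 2L, seed),
    xgboost = cpp_boost(x, y, p$n_trees, p$learning_rate, p$max_depth, 0L, 0L,
                        p$lambda, p$subsample, p$colsample, 2L, 2L, seed),
    lightgbm = cpp_boost(x, y, p$n_trees, p$learning_rate, 0L, p$max_leaves, 1L,
                         p$lambda, 1, 1, 2L, 5L, seed),
    catboost = cpp_boost(x, y, p$n_trees, p$learning_rate, p$max_depth, 0L, 2L,
                         p$lambda, 1, 1, 2L, 1L, seed),
    adaboost = cpp_adaboost(x, y, p$n_trees, p$max_depth, p$learning_rate, 1L,
                            seed),
    rf = cpp_rf(x, y, p$n_trees, p$max_depth, p$min_child,
                if (p$mtry > 0) p$mtry else max(1L, floor(sqrt(ncol(x)))), seed))
  structure(list(method = method, trees = fit$trees, base = fit$base,
                 params = p, seed = seed,
                 feature_names = colnames(x) %||% paste0("f", seq_len(ncol(x))),
                 n_features = ncol(x)),
            class = "ith_model")
}

merge_params <- function(defaults, override) {
  bad <- setdiff(names(override), names(defaults))
  if (length(bad))
    stage_error("model_bench", paste("unknown parameter(s):", paste(bad, collapse = ", ")))
  modifyList(defaults, override)
}

#' Predict from a fitted classifier
#'
#' @param object an `ith_model`.
#' @param newdata numeric matrix with the model's feature columns.
#' @param type `"prob"` for class-1 probabilities, `"margin"` for the raw
#'   additive score (the scale explained by SHAP).
#' @param ... unused.
#' @export
predict.ith_model <- function(object, newdata, type = c("prob", "margin"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  if (ncol(x) != object$n_features)
    stage_error("model_bench", sprintf("model expects %d features, got %d",
                                       object$n_features, ncol(x)))
  m <- cpp_predict_forest(object$trees, object$base, x)
  if (type == "margin") return(m)
  switch(object$method,
         adaboost = plogis(2 * m),
         rf = pmin(pmax(m, 0), 1),
         plogis(m))
}

#' @export
print.ith_model <- function(x, ...) {
  cat(sprintf("<ith_model> %s: %d trees, %d features\n",
              x$method, length(x$trees), x$n_features))
  invisible(x)
}
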