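test_that("TreeSHAP satisfies local accuracy for every classifier", {
  co <- generate_cohort(150, seed = 81)
  x <- encode_cohort(co); y <- co$label
  for (m in ithscore:::ITH_CLASSIFIERS) {
    fit <- fit_classifier(x, y, m, fast_grids()[[m]][[1]], seed = 2)
    phi <- shap_values(fit, x[1:30, ])
    marg <- predict(fit, x[1:30, ], type = "margin")
    expect_lt(max(abs(rowSums(phi) + attr(phi, "expected_value") - marg)), 1e-6)
  }
  expect_error(shap_values(structure(list(), class = "lm"), x), "unsupported")
})

test_that("TreeSHAP equals brute-force subset-enumeration Shapley values", {
  set.seed(82)
  n <- 70
  x <- matrix(rnorm(n * 4), n, 4)
  colnames(x) <- paste0("f", 1:4)
  y <- as.numeric(x[, 1] + 0.6 * x[, 2] * x[, 3] + rnorm(n, 0, 0.4) > 0)
  for (m in c("xgboost", "catboost", "adaboost", "rf")) {
    fit <- fit_classifier(x, y, m,
                          params = list(n_trees = 15L, max_depth = 3L), seed = 4)
    phi <- shap_values(fit, x[1:5, ])
    bf <- brute_shap(fit, x[1:5, ])
    expect_lt(max(abs(phi - bf)), 1e-9)
  }
})

test_that("global importance follows the mean-|phi| definition and is stable", {
  co <- generate_cohort(200, seed = 83)
  x <- encode_cohort(co); y <- co$label
  fit <- fit_classifier(x, y, "catboost", fast_grids()$catboost[[1]], seed = 1)
  phi <- shap_values(fit, x)
  rk <- global_importance(fit, x)
  expect_equal(sort(rk$importance, decreasing = TRUE), rk$importance)
  expect_setequal(rk$feature, colnames(x))
  I_direct <- colMeans(abs(phi))
  expect_equal(rk$importance, unname(sort(I_direct, decreasing = TRUE)),
               tolerance = 1e-12)
  # duplicating every sample leaves the ranking unchanged
  rk2 <- global_importance(fit, x[rep(seq_len(nrow(x)), 2), ])
  expect_identical(rk$feature, rk2$feature)
})

test_that("an injected informative feature dominates the ranking", {
  set.seed(84)
  wins <- 0L
  for (r in 1:20) {
    n <- 150
    x <- matrix(rnorm(n * 6), n, 6)
    colnames(x) <- paste0("f", 1:6)
    y <- rbinom(n, 1, plogis(3 * x[, 4]))
    fit <- fit_classifier(x, y, "xgboost", list(n_trees = 60L, max_depth = 2L),
                          seed = r)
    rk <- global_importance(fit, x)
    if (rk$feature[1] == "f4") wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("trajectories are complete, nested, and flat when one feature matters", {
  co <- generate_cohort(220, seed = 85)
  # make ith3d the only informative column
  null_cols <- setdiff(names(co), c("label", "ith3d"))
  for (cn in null_cols) co[[cn]] <- sample(co[[cn]])
  cfg <- bench_config(classifiers = "catboost", grids = fast_grids(), seed = 85)
  tuned <- tune_and_fit(co, cfg)
  rk <- global_importance(tuned$models$catboost, encode_cohort(co))
  tr <- trajectory("catboost", rk, co, seed = 85,
                   params = fast_grids()$catboost[[1]])
  expect_length(tr$auc, 14L)
  expect_identical(tr$features, rk$feature)
  expect_identical(rk$feature[1], "ith3d")
  expect_lt(abs(tr$auc[1] - tr$auc[14]), 0.08)  # top feature carries the signal
})

test_that("select_best applies dominance and deterministic tie-breaks", {
  t1 <- structure(list(classifier = "a", auc = c(0.6, 0.7, 0.8)),
                  class = "selection_trajectory")
  t2 <- structure(list(classifier = "b", auc = c(0.5, 0.6, 0.7)),
                  class = "selection_trajectory")
  expect_identical(select_best(list(t1, t2)), "a")
  t3 <- structure(list(classifier = "c", auc = c(0.6, 0.7, 0.8)),
                  class = "selection_trajectory")
  expect_identical(select_best(list(t3, t1)), "c")  # identical: first wins
  # dominance in most prefixes plus higher mean
  t4 <- structure(list(classifier = "d", auc = c(0.65, 0.72, 0.78, 0.8, 0.81)),
                  class = "selection_trajectory")
  t5 <- structure(list(classifier = "e", auc = c(0.7, 0.7, 0.7, 0.7, 0.7)),
                  class = "selection_trajectory")
  expect_identical(select_best(list(t5, t4)), "d")
  expect_error(select_best(list()), "no trajectories")
})

test_that("find_knee reproduces the stated scan and epsilon monotonicity", {
  expect_identical(find_knee(c(0.5, 0.8, 0.85, 0.85, 0.85), 0), 3L)
  expect_identical(find_knee(c(0.7, 0.6, 0.65), 0), 1L)
  expect_identical(find_knee(c(0.5, 0.6, 0.7, 0.8), 0), 4L)  # strictly increasing -> N
  expect_error(find_knee(0.5), "length")
  expect_error(find_knee(c(0.5, 0.6), -1), "epsilon")
  # smaller epsilon never yields a smaller knee
  set.seed(86)
  for (r in 1:50) {
    tr <- cumsum(rnorm(8, 0.02, 0.05)) + 0.5
    eps <- sort(runif(4, 0, 0.05))
    knees <- vapply(eps, function(e) find_knee(tr, e), integer(1))
    expect_true(all(diff(knees[order(-eps)]) >= 0))
  }
})
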