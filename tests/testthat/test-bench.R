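test_that("stratified split preserves proportions and is reproducible", {
  co <- generate_cohort(100, seed = 71)
  co$label <- rep(c(1L, 0L), c(66, 34))  # fixed class counts for the arithmetic
  sp <- stratified_split(co, 0.7, seed = 1)
  expect_identical(nrow(sp$train), 70L)
  expect_true(sum(sp$train$label) %in% 46:47)
  expect_identical(nrow(sp$train) + nrow(sp$test), 100L)
  expect_identical(intersect(rownames(sp$train), rownames(sp$test)), character(0))
  sp2 <- stratified_split(co, 0.7, seed = 1)
  expect_identical(sp$train, sp2$train)
  expect_error(stratified_split(co, 1.0), "strictly between")
  expect_error(stratified_split(co, 0), "strictly between")
  co1 <- co; co1$label <- c(1L, rep(0L, 99))
  expect_error(stratified_split(co1, 0.7), "at least 2")
})

test_that("metric block follows the definitional arithmetic", {
  y <- c(rep(1, 10), rep(0, 10))
  # predictions identical to labels -> all metrics 1
  m <- ithscore:::classification_metrics(y, y, average = "weighted")
  expect_equal(unname(m), rep(1, 4))
  expect_equal(auc_score(y, y), 1)
  # flat probabilities with mixed labels -> AUC 0.5
  expect_equal(auc_score(y, rep(0.5, 20)), 0.5)
  # printed contingency TP=8 FP=2 FN=2 TN=8
  yc <- c(rep(1, 10), rep(0, 10))
  pc <- c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 8))
  mb <- ithscore:::classification_metrics(yc, pc, average = "binary")
  expect_equal(unname(mb[c("precision", "recall", "f1")]), c(0.8, 0.8, 0.8))
  mw <- ithscore:::classification_metrics(yc, pc, average = "weighted")
  expect_equal(unname(mw[c("precision", "recall", "f1")]), c(0.8, 0.8, 0.8))
  # AUC invariant under class-encoding + probability flip
  set.seed(72)
  p <- runif(20)
  expect_equal(auc_score(y, p), auc_score(1 - y, 1 - p))
})

test_that("tune_and_fit assembles OOF correctly and nails separable data", {
  set.seed(73)
  co <- generate_cohort(150, seed = 73)
  co$ith3d <- co$label + runif(150, 0, 0.4) - 0.2  # perfectly separable at 0.4
  cfg <- bench_config(classifiers = c("xgboost", "catboost"),
                      grids = fast_grids(), seed = 73)
  rep1 <- tune_and_fit(co, cfg)
  expect_true(all(vapply(rep1$oof, function(v) sum(!is.na(v)), 0L) == nrow(co)))
  expect_true(all(rep1$table$oof_auc > 0.99))
  # determinism
  rep2 <- tune_and_fit(co, cfg)
  expect_identical(rep1$table, rep2$table)
})

test_that("permuted labels give near-chance OOF AUC", {
  co <- generate_cohort(600, effect = 0, seed = 74)
  cfg <- bench_config(classifiers = c("gbdt", "catboost", "rf"),
                      grids = fast_grids(), seed = 74)
  rep1 <- tune_and_fit(co, cfg)
  expect_true(all(rep1$table$oof_auc > 0.42 & rep1$table$oof_auc < 0.58))
})

test_that("ablation runs six configurations and never reads excluded columns", {
  co <- generate_cohort(260, seed = 75)
  cfg <- bench_config(classifiers = "catboost", grids = fast_grids(), seed = 75)
  ab <- ablation_study(co, cfg)
  expect_identical(nrow(ab$table), 12L)  # 6 configurations x {train_oof, test}
  expect_identical(sum(ab$table$part == "test"), 6L)
  expect_false(any(c("ith2d", "ith3d") %in% ab$models[["CR"]]$feature_names))
  expect_identical(ab$models[["2DITH"]]$feature_names, "ith2d")
  tt <- ab$table[ab$table$part == "test", ]
  full <- tt$auc[tt$configuration == "2DITH-3DITH-CR"]
  cr <- tt$auc[tt$configuration == "CR"]
  expect_gte(full, cr - 0.02)  # ITH-dominant generator: full config at least CR
})

test_that("compare_groups behaves on ties, separation, and ordering", {
  g <- c(rep(0.4, 12), rep(0.4, 12))
  lab <- rep(c(1, 0), each = 12)
  expect_gt(compare_groups(g, lab)$p_value, 0.9)
  set.seed(76)
  x <- c(rnorm(50, 3), rnorm(50))
  l <- rep(c(1, 0), each = 50)
  expect_lt(compare_groups(x, l)$p_value, 1e-3)
  o <- sample(100)
  expect_equal(compare_groups(x, l)$p_value, compare_groups(x[o], l[o])$p_value)
  expect_error(compare_groups(x[1:2], c(1, 0)), ">= 3")
})
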