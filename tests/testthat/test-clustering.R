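fake_features <- function(X, coords = NULL, dim = NULL, mode = "2D") {
  n <- nrow(X)
  if (is.null(coords)) coords <- cbind(seq_len(n), 1L)
  if (is.null(dim)) dim <- c(n, 1L)
  structure(list(values = X, coords = coords, grid_dim = as.integer(dim),
                 mode = mode, feature_names = colnames(X) %||% paste0("f", seq_len(ncol(X))),
                 feature_kinds = rep("other", ncol(X)), standardized = TRUE),
            class = "feature_matrix")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("clustering is deterministic and recovers separated structure", {
  set.seed(31)
  X <- rbind(matrix(rnorm(60 * 3, 0, 0.2), 60, 3),
             matrix(rnorm(60 * 3, 5, 0.2), 60, 3))
  truth <- rep(1:2, each = 60)
  F <- fake_features(X)
  cm1 <- cluster_subregions(F, K = 2, seed = 7)
  cm2 <- cluster_subregions(F, K = 2, seed = 7)
  expect_identical(cm1$labels, cm2$labels)
  lab <- cm1$labels[F$coords]
  expect_equal(adjusted_rand(lab, truth), 1)
})

test_that("K identical copies of K distinct rows form pure clusters", {
  proto <- matrix(seq_len(6 * 4), 6, 4) * 10
  X <- proto[rep(1:6, times = 6), ]
  F <- fake_features(X)
  cm <- cluster_subregions(F, K = 6, seed = 1)
  lab <- cm$labels[F$coords]
  truth <- rep(1:6, times = 6)
  expect_equal(adjusted_rand(lab, truth), 1)
})

test_that("degenerate inputs are rejected with informative errors", {
  F <- fake_features(matrix(rnorm(12), 4, 3))
  expect_error(cluster_subregions(F, K = 6, seed = 1), "at least 6")
  Fb <- fake_features(matrix(c(1, NA, 3, 4, 5, 6), 3, 2))
  expect_error(cluster_subregions(Fb, K = 2, seed = 1), "non-finite")
  expect_error(cluster_subregions(F, K = 1, seed = 1), "K must be")
})

test_that("returned labeling beats random labelings on within-cluster SS", {
  set.seed(33)
  X <- matrix(rnorm(80 * 5), 80, 5)
  F <- fake_features(X)
  cm <- cluster_subregions(F, K = 4, seed = 2)
  lab <- cm$labels[F$coords]
  wcss <- function(l) {
    sum(vapply(unique(l), function(k) {
      xk <- X[l == k, , drop = FALSE]
      sum(sweep(xk, 2, colMeans(xk))^2)
    }, numeric(1)))
  }
  w0 <- wcss(lab)
  for (r in 1:50) expect_lte(w0, wcss(sample(rep_len(1:4, 80))) + 1e-9)
})

test_that("permuting row order yields the same spatial partition", {
  set.seed(34)
  X <- rbind(matrix(rnorm(40 * 4, 0, 0.5), 40, 4),
             matrix(rnorm(40 * 4, 4, 0.5), 40, 4),
             matrix(rnorm(40 * 4, -4, 0.5), 40, 4))
  n <- nrow(X)
  coords <- cbind(seq_len(n), 1L)
  F1 <- fake_features(X, coords, c(n, 1L))
  perm <- sample(n)
  F2 <- fake_features(X[perm, ], coords[perm, ], c(n, 1L))
  cm1 <- cluster_subregions(F1, K = 3, seed = 5)
  cm2 <- cluster_subregions(F2, K = 3, seed = 5)
  l1 <- cm1$labels[coords]; l2 <- cm2$labels[coords]
  expect_equal(adjusted_rand(l1, l2), 1)  # identical partition, labels may permute
})

test_that("cluster maps export as label images", {
  set.seed(35)
  m <- array(0L, c(8, 10, 10)); m[3:6, 3:8, 3:8] <- 1L
  img <- nodule_image(array(rnorm(800, -500, 100), c(8, 10, 10)), m)
  F <- standardize_features(extract_local_features(img))
  cm <- cluster_subregions(F, K = 3, seed = 1)
  p <- tempfile(fileext = ".nii.gz")
  write_cluster_map(cm, p, img$spacing)
  back <- ithscore:::read_image_any(p)
  expect_identical(array(as.integer(back$data), dim(cm$labels)), cm$labels)
  unlink(p)
})
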