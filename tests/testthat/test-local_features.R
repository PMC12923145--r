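make_region_2d <- function(inten, mask) {
  structure(list(intensities = inten, mask = mask, slice_index = 1L,
                 spacing = c(1, 1)), class = "planar_section")
}

test_that("row count, column count and constancy contracts hold", {
  set.seed(21)
  m <- matrix(0L, 12, 12); m[3:9, 3:9] <- 1L
  m[sample(which(m == 1L), 12)] <- 0L
  inten <- matrix(rnorm(144, -500, 40), 12, 12)
  F <- extract_local_features(make_region_2d(inten, m), feature_bank_spec("2D"))
  expect_identical(nrow(F$values), sum(m))
  expect_identical(ncol(F$values), 104L)
  expect_true(all(is.finite(F$values)))

  # constant region: every dispersion feature is exactly 0
  Fc <- extract_local_features(make_region_2d(matrix(-300, 12, 12), m),
                               feature_bank_spec("2D"))
  disp <- Fc$values[, Fc$feature_kinds == "dispersion", drop = FALSE]
  expect_true(all(disp == 0))

  # reduced feature_count keeps the leading columns
  F8 <- extract_local_features(make_region_2d(inten, m),
                               feature_bank_spec("2D", feature_count = 8))
  expect_identical(ncol(F8$values), 8L)
  expect_equal(F8$values, F$values[, 1:8])
})

test_that("translation of the nodule leaves features invariant up to row order", {
  set.seed(22)
  base <- array(rnorm(18 * 18 * 18, -400, 30), c(18, 18, 18))
  m <- array(0L, c(18, 18, 18)); m[5:9, 5:9, 5:9] <- 1L
  img1 <- nodule_image(base, m)
  sh <- c(3, 2, 1)
  base2 <- array(0, dim(base)); m2 <- array(0L, dim(m))
  base2[(5:9) + sh[1], (5:9) + sh[2], (5:9) + sh[3]] <- base[5:9, 5:9, 5:9]
  # fill surroundings with the same values translated so neighborhoods match
  base2[] <- -400
  idx <- as.matrix(expand.grid(1:18, 1:18, 1:18))
  src <- sweep(idx, 2, sh, "-")
  ok <- src[, 1] >= 1 & src[, 2] >= 1 & src[, 3] >= 1
  base2[idx[ok, ]] <- base[src[ok, ]]
  m2[(5:9) + sh[1], (5:9) + sh[2], (5:9) + sh[3]] <- 1L
  F1 <- extract_local_features(nodule_image(base, m))
  F2 <- extract_local_features(nodule_image(base2, m2))
  expect_equal(F2$values, F1$values, tolerance = 1e-12)
})

test_that("constant intensity shift moves location features and fixes dispersion", {
  set.seed(23)
  m <- array(0L, c(10, 14, 14)); m[3:8, 4:11, 4:11] <- 1L
  inten <- array(rnorm(prod(dim(m)), -600, 25), dim(m))
  img <- nodule_image(inten, m)
  shift <- 50
  img2 <- nodule_image(inten + shift, m)
  F1 <- extract_local_features(img)
  F2 <- extract_local_features(img2)
  loc <- F1$feature_kinds == "location"
  disp <- F1$feature_kinds == "dispersion"
  expect_equal(F2$values[, loc], F1$values[, loc] + shift, tolerance = 1e-9)
  expect_equal(F2$values[, disp], F1$values[, disp], tolerance = 1e-9)
})

test_that("standardization follows the population rule with zero-variance mapping", {
  F <- structure(list(values = cbind(a = c(1, 3), b = c(5, 5)),
                      coords = cbind(1:2, 1), grid_dim = c(2L, 1L),
                      mode = "2D", feature_names = c("a", "b"),
                      feature_kinds = c("other", "other"), standardized = FALSE),
                 class = "feature_matrix")
  S <- standardize_features(F)
  expect_equal(S$values[, "a"], c(-1, 1))
  expect_equal(S$values[, "b"], c(0, 0))

  set.seed(24)
  Fr <- F
  Fr$values <- matrix(rnorm(300), 50, 6)
  Fr$coords <- cbind(1:50, 1)
  Fr$grid_dim <- c(50L, 1L)
  Sr <- standardize_features(Fr)
  expect_true(all(abs(colMeans(Sr$values)) < 1e-10))
  expect_true(all(abs(colMeans(Sr$values^2) - 1) < 1e-10))

  F1 <- Fr; F1$values <- F1$values[1, , drop = FALSE]
  expect_error(standardize_features(F1), "2 rows")
})

test_that("degenerate grids without padding are rejected", {
  m <- matrix(1L, 1, 1)
  reg <- make_region_2d(matrix(0, 1, 1), m)
  expect_error(extract_local_features(reg, feature_bank_spec("2D", pad = FALSE)),
               "degenerate")
  expect_silent(extract_local_features(reg, feature_bank_spec("2D", pad = TRUE)))
})
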