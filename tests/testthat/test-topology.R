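as_cluster_map <- function(lab, K = max(lab), mode = if (length(dim(lab)) == 2) "2D" else "3D") {
  structure(list(labels = lab, K = as.integer(K), seed = 0L, mode = mode),
            class = "cluster_map")
}

test_that("adjacency definitions match on canonical shapes", {
  sq <- matrix(0L, 5, 5); sq[2:4, 2:4] <- 1L
  s <- label_components(as_cluster_map(sq))
  expect_identical(s$per_cluster$components, 1L)
  expect_identical(s$per_cluster$largest, 9L)

  diagpx <- matrix(0L, 4, 4); diagpx[1, 1] <- 1L; diagpx[2, 2] <- 1L
  s8 <- label_components(as_cluster_map(diagpx))
  expect_identical(s8$per_cluster$components, 1L)
  expect_identical(s8$per_cluster$largest, 2L)
  # face-only adjacency splits the diagonal pair (internal routine)
  c4 <- component_labels(diagpx, 4L)
  expect_identical(max(c4), 2L)
})

test_that("component summaries agree with the propagation oracle on random maps", {
  set.seed(51)
  for (rep in 1:60) {
    lab <- random_label_map(max_side = 14L)
    if (max(lab) == 0) next
    conn <- if (length(dim(lab)) == 2L) 8L else 26L
    s <- label_components(as_cluster_map(lab))
    o <- oracle_components(lab, conn)
    expect_identical(s$per_cluster$components, o$components)
    expect_identical(s$per_cluster$largest, o$largest)
    expect_identical(s$per_cluster$size, o$size)
  }
})

test_that("score identities and bounds hold", {
  # every non-empty cluster one component -> score exactly 0
  lab <- matrix(0L, 6, 9)
  lab[2:5, 2:4] <- 1L; lab[2:5, 6:8] <- 2L
  r <- ith_score(label_components(as_cluster_map(lab)))
  expect_identical(r$score, 0)

  # hand flood-fill example: 14-pixel cluster + two isolated corners
  lab4 <- matrix(1L, 4, 4); lab4[1, 4] <- 2L; lab4[4, 1] <- 2L
  r4 <- ith_score(label_components(as_cluster_map(lab4)))
  expect_identical(r4$score, 0.09375)

  # random maps: 0 <= score < 1; empty clusters contribute nothing
  set.seed(52)
  for (rep in 1:40) {
    lab <- random_label_map(max_side = 10L)
    if (max(lab) == 0) next
    s <- label_components(as_cluster_map(lab, K = max(lab) + 2L))  # trailing empties
    r <- ith_score(s)
    expect_gte(r$score, 0)
    expect_lt(r$score, 1)
    expect_identical(sum(s$per_cluster$size), s$total)
  }
})

test_that("score is invariant to cluster label permutation", {
  set.seed(53)
  lab <- random_label_map(max_side = 12L, three_d = TRUE)
  K <- max(lab)
  perm <- sample(K)
  lab2 <- lab
  lab2[lab > 0] <- perm[lab[lab > 0]]
  r1 <- ith_score(label_components(as_cluster_map(lab, K)))
  r2 <- ith_score(label_components(as_cluster_map(lab2, K)))
  expect_identical(r1$score, r2$score)
})

test_that("compute_ith chains the stages deterministically with provenance", {
  ph <- generate_phantom(small_phantom_spec(seed = 54))
  r1 <- compute_ith(ph$image, "3D", seed = 3)
  r2 <- compute_ith(ph$image, "3D", seed = 3)
  expect_identical(r1$score, r2$score)
  expect_identical(r1$connectivity, 26L)
  expect_identical(r1$K, 6L)
  expect_identical(r1$N, 104L)
  r2d <- compute_ith(ph$image, "2D", seed = 3)
  expect_identical(r2d$connectivity, 8L)
  expect_false(is.na(r2d$slice_index))
  expect_true(r1$score >= 0 && r1$score < 1)
  expect_true(r2d$score >= 0 && r2d$score < 1)

  # stage-named failure: mask smaller than K
  tiny <- array(0L, c(4, 6, 6)); tiny[2, 2:3, 2] <- 1L
  img <- nodule_image(array(rnorm(144), c(4, 6, 6)), tiny)
  expect_error(compute_ith(img, "3D"), "subregion_clustering")
})

test_that("JSON serialization carries the declared schema", {
  ph <- generate_phantom(small_phantom_spec(seed = 55))
  r <- compute_ith(ph$image, "3D", seed = 1)
  l <- ith_result_to_list(r)
  expect_named(l, c("mode", "score", "K", "N", "seed", "connectivity", "per_cluster"))
  expect_length(l$per_cluster, 6L)
  expect_named(l$per_cluster[[1]], c("size", "components", "largest"))
})
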