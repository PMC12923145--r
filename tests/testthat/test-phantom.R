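test_that("phantom construction honours spec and determinism", {
  sp <- small_phantom_spec(phenotype_count = 1, fragmentation = 1, noise_sd = 0,
                           seed = 61)
  ph <- generate_phantom(sp)
  vals <- ph$image$intensities[ph$image$mask == 1]
  expect_identical(length(unique(vals)), 1L)  # constant-intensity nodule
  ph2 <- generate_phantom(sp)
  expect_identical(ph$image$intensities, ph2$image$intensities)
  expect_identical(ph$truth, ph2$truth)
  expect_error(generate_phantom(small_phantom_spec(phenotype_count = 1,
                                                   fragmentation = 2)),
               "cannot be fragmented")
})

test_that("truth grids carry exactly the requested blobs per phenotype", {
  for (cfg in list(c(2, 1), c(3, 2), c(2, 4), c(4, 1))) {
    ph <- generate_phantom(small_phantom_spec(phenotype_count = cfg[1],
                                              fragmentation = cfg[2],
                                              seed = 100 + cfg[1] * 10 + cfg[2]))
    o <- oracle_components(ph$truth, 26L)  # independent flood-fill oracle
    expect_identical(o$components, rep(as.integer(cfg[2]), cfg[1]))
    # mask is fully covered by phenotypes
    expect_identical(sum(o$size), sum(ph$image$mask))
  }
})

test_that("cohort tables satisfy the schema invariants", {
  co <- generate_cohort(1000, seed = 62)
  expect_s3_class(co, "cohort_table")
  frac <- mean(co$label)
  expect_gte(frac, 0.60); expect_lte(frac, 0.72)
  expect_true(all(co$ith2d >= 0 & co$ith2d < 1))
  expect_true(all(co$ith3d >= 0 & co$ith3d < 1))
  expect_identical(levels(co$density), c("pGGN", "PSN", "SN"))
  expect_identical(levels(co$location), c("RUL", "RML", "RLL", "LUL", "LLL"))
  expect_true(all(co$label %in% 0:1))
  expect_true(all(co$size_mm >= 5 & co$size_mm <= 30))
  co2 <- generate_cohort(1000, seed = 62)
  expect_identical(co, co2)
  expect_error(generate_cohort(10), ">= 20")
})

test_that("effect = 0 removes the class difference in ITH scores", {
  set.seed(63)
  ns <- 0L
  for (r in 1:100) {
    co <- generate_cohort(100, effect = 0, seed = 6300 + r)
    p <- compare_groups(co$ith3d, co$label)$p_value
    if (p >= 0.05) ns <- ns + 1L
  }
  expect_gte(ns, 90L)  # type-I error at nominal rate under the null
})

test_that("higher fragmentation raises the 3D ITH score distribution", {
  # scaled to 12 + 12 phantoms here; the acceptance suite runs the stated 50 + 50
  lo <- hi <- numeric(12)
  for (i in 1:12) {
    lo[i] <- compute_ith(generate_phantom(small_phantom_spec(
      fragmentation = 1, seed = 6400 + i))$image, "3D", seed = i)$score
    hi[i] <- compute_ith(generate_phantom(small_phantom_spec(
      fragmentation = 4, seed = 6400 + i))$image, "3D", seed = i)$score
  }
  expect_lt(suppressWarnings(wilcox.test(hi, lo, alternative = "greater"))$p.value, 0.01)
  # contiguous-phenotype phantoms sit at the near-zero noise floor at default noise
  expect_lt(mean(lo), 0.05)
})
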