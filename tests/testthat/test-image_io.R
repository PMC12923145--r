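test_that("nodule round-trips preserve mask and intensities in both formats", {
  ph <- generate_phantom(small_phantom_spec(seed = 11))
  for (ext in c(".nii", ".nii.gz", ".nrrd")) {
    ip <- tempfile(fileext = ext); mp <- tempfile(fileext = ext)
    write_nodule(ph$image, ip, mp)
    rt <- read_nodule(ip, mp)
    expect_identical(rt$mask, ph$image$mask)
    expect_equal(rt$intensities, ph$image$intensities, tolerance = 0)
    expect_equal(rt$spacing, ph$image$spacing, tolerance = 1e-6)
    expect_identical(sum(rt$mask), sum(ph$image$mask))
    unlink(c(ip, mp))
  }
})

test_that("degenerate and multi-label masks follow the binarization contract", {
  ph <- generate_phantom(small_phantom_spec(seed = 12))
  ip <- tempfile(fileext = ".nii.gz"); mp <- tempfile(fileext = ".nii.gz")
  # all-zero mask -> degenerate-input error
  write_nodule(ph$image, ip, mp)
  zero <- array(0, dim(ph$image$mask))
  ithscore:::write_image_any(zero, ph$image$spacing, mp)
  expect_error(read_nodule(ip, mp), "degenerate")
  # {0, 255} mask reads as {0, 1} with the same foreground set
  m255 <- ph$image$mask * 255
  ithscore:::write_image_any(m255, ph$image$spacing, mp)
  rt <- read_nodule(ip, mp)
  expect_setequal(unique(as.vector(rt$mask)), c(0L, 1L))
  expect_identical(which(rt$mask == 1L), which(ph$image$mask == 1L))
  # multi-label mask rejected only under strict
  m2 <- ph$image$mask
  m2[which(m2 == 1L)[1:5]] <- 3L
  ithscore:::write_image_any(m2, ph$image$spacing, mp)
  expect_silent(read_nodule(ip, mp))
  expect_error(read_nodule(ip, mp, strict = TRUE), "distinct nonzero")
  unlink(c(ip, mp))
})

test_that("misaligned image/mask pairs raise alignment errors", {
  ph <- generate_phantom(small_phantom_spec(seed = 13))
  ip <- tempfile(fileext = ".nii"); mp <- tempfile(fileext = ".nii")
  write_nodule(ph$image, ip, mp)
  # wrong shape
  ithscore:::write_image_any(ph$image$mask[-1, , , drop = FALSE],
                             ph$image$spacing, mp)
  expect_error(read_nodule(ip, mp), "alignment")
  # wrong spacing
  ithscore:::write_image_any(ph$image$mask, ph$image$spacing * 2, mp)
  expect_error(read_nodule(ip, mp), "spacing")
  unlink(c(ip, mp))
})

test_that("largest_axial_section picks the maximal-count slice with low-index ties", {
  mk <- function(counts) {
    m <- array(0L, c(length(counts), 6, 6))
    for (i in seq_along(counts)) if (counts[i] > 0) m[i, , ][seq_len(counts[i])] <- 1L
    nodule_image(array(0, dim(m)), m)
  }
  expect_identical(largest_axial_section(mk(c(5, 12, 7)))$slice_index, 2L)
  expect_identical(largest_axial_section(mk(c(8, 8, 3)))$slice_index, 1L)
  sec <- largest_axial_section(mk(c(5, 12, 7)))
  expect_identical(sum(sec$mask), 12L)
})

test_that("selected slice equals the brute-force argmax on random masks", {
  set.seed(401)
  for (rep in 1:200) {
    d <- c(sample(2:8, 1), 5, 5)
    m <- array(rbinom(prod(d), 1, 0.4), d)
    if (sum(m) == 0) m[sample(length(m), 1)] <- 1L
    img <- nodule_image(array(rnorm(prod(d)), d), m)
    sec <- largest_axial_section(img)
    counts <- vapply(seq_len(d[1]), function(i) sum(m[i, , ]), integer(1))
    expect_identical(sec$slice_index, which(counts == max(counts))[1])
    expect_identical(sum(sec$mask), max(counts))
    # permutation stability: reordering slices still yields the max count
    perm <- sample(d[1])
    sec2 <- largest_axial_section(nodule_image(
      img$intensities[perm, , , drop = FALSE], m[perm, , , drop = FALSE]))
    expect_identical(sum(sec2$mask), max(counts))
  }
})
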