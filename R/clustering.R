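# Voxel-wise K-means habitat clustering. Seeded k-means++ initialization with
# multiple restarts; Lloyd iterations via stats::kmeans from the chosen
# centers. To make the spatial partition invariant to the row order of the
# feature matrix, k-means++ sampling is performed over a canonical (lexico-
# graphic) ordering of the rows, so permuting rows (with their coordinates)
# cannot change the selected centers.

#' Partition in-mask elements into phenotypic subregions
#'
#' K-means on the feature matrix; labels are mapped back to the spatial grid.
#'
#' @param F a `feature_matrix` (usually standardized).
#' @param K number of clusters (default 6).
#' @param seed RNG seed for k-means++ restarts.
#' @param restarts number of k-means++ restarts; lowest within-cluster sum of
#'   squares wins.
#' @param iter_max,tol Lloyd iteration cap and convergence tolerance.
#' @return An object of class `cluster_map`: integer label grid (`labels`,
#'   values 1..K in-mask, 0 outside), `K`, `seed`, `mode`, `inertia`.
#' @export
cluster_subregions <- function(F, K = 6L, seed = 1L, restarts = 10L,
                               iter_max = 300L, tol = 1e-4) {
  stopifnot(inherits(F, "feature_matrix"))
  X <- F$values
  n <- nrow(X)
  K <- as.integer(K)
  if (K < 2L) stage_error("subregion_clustering", "K must be >= 2")
  if (n < K)
    stage_error("subregion_clustering", sprintf(
      "degenerate input: %d in-mask elements but K = %d; the mask must contain at least %d elements",
      n, K, K))
  if (any(!is.finite(X)))
    stage_error("subregion_clustering", "non-finite feature values")

  # canonical row order: lexicographic over feature columns
  ord <- do.call(order, c(asplit(X, 2L), list(method = "radix")))
  Xs <- X[ord, , drop = FALSE]
  dup <- !duplicated(Xs)
  n_distinct <- sum(dup)

  labels_row <- integer(n)
  inertia <- NA_real_
  if (n_distinct == 1L) {
    labels_row[] <- 1L
    inertia <- 0
  } else if (n_distinct <= K) {
    # each distinct feature vector is its own pure cluster
    key <- cumsum(dup)                 # distinct id in canonical order
    labels_row[ord] <- key
    inertia <- 0
  } else {
    best <- NULL
    fit_one <- function(centers) {
      tryCatch(
        suppressWarnings(stats::kmeans(X, centers = centers,
                                       iter.max = iter_max, algorithm = "Lloyd")),
        error = function(e) NULL)
    }
    with_seed(seed, {
      for (r in seq_len(restarts)) {
        ci <- kmeanspp_centers(Xs, dup, K)
        fit <- fit_one(Xs[ci, , drop = FALSE])
        if (is.null(fit)) next
        if (is.null(best) || fit$tot.withinss < best$tot.withinss - tol) best <- fit
      }
    })
    if (is.null(best))
      stage_error("subregion_clustering", "K-means failed on all restarts")
    labels_row <- best$cluster
    inertia <- best$tot.withinss
  }

  lab_grid <- array(0L, dim = F$grid_dim)
  lab_grid[F$coords] <- as.integer(labels_row)
  structure(list(labels = lab_grid, K = K, seed = as.integer(seed),
                 mode = F$mode, inertia = inertia,
                 coords = F$coords),
            class = "cluster_map")
}

# k-means++ seeding over the canonically ordered rows (Xs); `dup` marks the
# first occurrence of each distinct row. Returns row indices into Xs.
kmeanspp_centers <- function(Xs, dup, K) {
  n <- nrow(Xs)
  centers <- integer(K)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(Xs, 2L, Xs[centers[1], ], "-")^2)
  for (k in 2:K) {
    tot <- sum(d2)
    centers[k] <- if (tot <= 0) {
      cand <- which(dup)
      cand[sample.int(length(cand), 1L)]
    } else {
      sample.int(n, 1L, prob = d2 / tot)
    }
    d2 <- pmin(d2, rowSums(sweep(Xs, 2L, Xs[centers[k], ], "-")^2))
  }
  centers
}

#' @export
print.cluster_map <- function(x, ...) {
  occ <- tabulate(x$labels[x$labels > 0], nbins = x$K)
  cat(sprintf("<cluster_map> %s, K = %d (%d occupied), %d labeled elements\n",
              x$mode, x$K, sum(occ > 0), sum(occ)))
  invisible(x)
}

#' Export a cluster map as a label image
#'
#' Writes the integer subregion label grid aligned to the input grid (2D maps
#' are written as a single-slice volume) for visual inspection.
#'
#' @param cmap a `cluster_map`.
#' @param path output path (`.nii`, `.nii.gz` or `.nrrd`).
#' @param spacing voxel spacing of the parent image.
#' @export
write_cluster_map <- function(cmap, path, spacing = c(1, 1, 1)) {
  stopifnot(inherits(cmap, "cluster_map"))
  lab <- cmap$labels
  if (length(dim(lab)) == 2L) {
    lab <- array(lab, dim = c(1L, dim(lab)))
    spacing <- c(1, spacing[max(1, length(spacing) - 1):length(spacing)])
  }
  write_image_any(lab, spacing, path)
  invisible(path)
}
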