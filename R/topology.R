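# Topology-aware quantification: per-cluster connected components under the
# mode-specific adjacency (8-connectivity in 2D, 26-connectivity in 3D) and
# the ITH score
#
#   score = 1 - (1/total) * sum_i largest_i / count_i
#
# over non-empty clusters i, where largest_i is the element count of cluster
# i's largest connected component and count_i its number of components.
# Every quantity is an element count, so the score is dimensionless and
# independent of voxel-spacing metadata.

#' Label connected components of a cluster label grid
#'
#' Low-level labeling routine: two elements are connected iff they share the
#' same nonzero cluster label and are adjacent under the chosen topology.
#' Exposed with a configurable connectivity for testing; the public scoring
#' API fixes 8 (2D) / 26 (3D).
#'
#' @param labels integer array (2D or 3D) of cluster labels, 0 = background.
#' @param connectivity 4 or 8 (2D grids); 6 or 26 (3D grids).
#' @return Integer array of component ids (1..n, 0 on background) with
#'   attribute `cluster` giving each component's cluster label.
#' @export
component_labels <- function(labels, connectivity) {
  dm <- dim(labels)
  if (is.null(dm) || !length(dm) %in% c(2L, 3L))
    stage_error("topology_score", "labels must be a 2D or 3D array")
  nd <- length(dm)
  valid <- if (nd == 2L) c(4L, 8L) else c(6L, 26L)
  if (!connectivity %in% valid)
    stage_error("topology_score", sprintf(
      "connectivity %s invalid for a %dD grid (use %s)", connectivity, nd,
      paste(valid, collapse = " or ")))
  diagonal <- connectivity %in% c(8L, 26L)
  cpp_label_components(as.integer(labels), as.integer(dm), diagonal)
}

#' Summarize per-cluster component topology
#'
#' For each cluster i in 1..K, records total size, the number of connected
#' components (n_i / m_i) and the size of the largest component (S_i,max /
#' V_i,max), all in elements, plus the total in-mask size (S_total / V_total)
#' and the accumulator Sigma = sum_i largest_i / count_i over non-empty
#' clusters. Empty clusters are recorded with count 0 and size 0.
#'
#' @param cmap a `cluster_map`.
#' @param connectivity 8 (2D) or 26 (3D); defaults to the mode-appropriate
#'   value and must match the map's dimensionality.
#' @return An object of class `topology_summary`.
#' @export
label_components <- function(cmap, connectivity = NULL) {
  stopifnot(inherits(cmap, "cluster_map"))
  nd <- length(dim(cmap$labels))
  expected <- if (nd == 2L) 8L else 26L
  if (is.null(connectivity)) connectivity <- expected
  if (connectivity != expected)
    stage_error("topology_score", sprintf(
      "connectivity must be %d for %s mode", expected, cmap$mode))
  comp <- component_labels(cmap$labels, connectivity)
  summarize_components(cmap$labels, comp, cmap$K, connectivity,
                       mode = if (nd == 2L) "2D" else "3D")
}

# Build a topology_summary from a cluster grid and its component labeling.
summarize_components <- function(labels, comp, K, connectivity, mode) {
  comp_cluster <- attr(comp, "cluster")
  comp_sizes <- tabulate(comp[comp > 0], nbins = max(0L, max(comp)))
  per <- data.frame(cluster = seq_len(K), size = 0L, components = 0L,
                    largest = 0L)
  csize <- tabulate(labels[labels > 0], nbins = K)
  per$size <- csize
  if (length(comp_cluster)) {
    for (i in seq_len(K)) {
      ids <- which(comp_cluster == i)
      if (length(ids)) {
        per$components[i] <- length(ids)
        per$largest[i] <- max(comp_sizes[ids])
      }
    }
  }
  total <- sum(per$size)
  ne <- per$components > 0
  sigma <- sum(per$largest[ne] / per$components[ne])
  structure(list(per_cluster = per, total = as.integer(total), sigma = sigma,
                 connectivity = as.integer(connectivity), mode = mode),
            class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf("<topology_summary> %s, %d-connectivity, total %d elements, Sigma = %.4g\n",
              x$mode, x$connectivity, x$total, x$sigma))
  print(x$per_cluster, row.names = FALSE)
  invisible(x)
}

#' Derive the ITH score from a topology summary
#'
#' score = 1 - Sigma / total, in [0, 1). The score is exactly 0 iff every
#' non-empty cluster is a single connected component.
#'
#' @param summary a `topology_summary`.
#' @param provenance optional list (K, N, seed, slice_index) recorded in the
#'   result.
#' @return An object of class `ith_result`.
#' @export
ith_score <- function(summary, provenance = list()) {
  stopifnot(inherits(summary, "topology_summary"))
  if (summary$total <= 0)
    stage_error("topology_score", "total in-mask size is 0")
  if (all(summary$per_cluster$components == 0))
    stage_error("topology_score", "no non-empty cluster")
  score <- 1 - summary$sigma / summary$total
  structure(list(mode = summary$mode, score = score,
                 connectivity = summary$connectivity,
                 K = provenance$K %||% nrow(summary$per_cluster),
                 N = provenance$N %||% NA_integer_,
                 seed = provenance$seed %||% NA_integer_,
                 slice_index = provenance$slice_index %||% NA_integer_,
                 summary = summary),
            class = "ith_result")
}

#' @export
print.ith_result <- function(x, ...) {
  cat(sprintf("<ith_result> %s ITH score = %.5f (K = %s, N = %s, %d-connectivity)\n",
              x$mode, x$score, x$K, x$N, x$connectivity))
  invisible(x)
}

#' Compute the 2D or 3D ITH score of a nodule
#'
#' Full pipeline: largest axial section (2D mode only) -> local feature
#' extraction -> standardization -> K-means subregion clustering ->
#' connected-component topology -> score. Each stage failure names the stage.
#'
#' @param img a [nodule_image()].
#' @param mode `"2D"` or `"3D"`.
#' @param spec a [feature_bank_spec()] for the chosen mode (default bank).
#' @param K number of subregion clusters (default 6).
#' @param seed RNG seed for clustering.
#' @param restarts k-means++ restarts.
#' @return An [ith_score()] result with full provenance.
#' @export
compute_ith <- function(img, mode = c("3D", "2D"), spec = NULL, K = 6L,
                        seed = 1L, restarts = 10L) {
  stopifnot(inherits(img, "nodule_image"))
  mode <- match.arg(toupper(mode[1]), c("3D", "2D"))
  if (is.null(spec)) spec <- feature_bank_spec(mode)
  if (spec$mode != mode)
    stage_error("topology_score", "spec mode does not match requested mode")
  region <- if (mode == "2D") with_stage("image_io", largest_axial_section(img)) else img
  slice_index <- if (mode == "2D") region$slice_index else NA_integer_
  F <- with_stage("local_features", extract_local_features(region, spec))
  if (spec$standardize) F <- with_stage("local_features", standardize_features(F))
  cmap <- with_stage("subregion_clustering",
                     cluster_subregions(F, K = K, seed = seed, restarts = restarts))
  summ <- with_stage("topology_score", label_components(cmap))
  res <- with_stage("topology_score", ith_score(summ, provenance = list(
    K = as.integer(K), N = ncol(F$values), seed = as.integer(seed),
    slice_index = slice_index)))
  res$cluster_map <- cmap
  res
}

#' Serialize an ITH result to a list (JSON-ready)
#'
#' @param res an `ith_result`.
#' @return A list with mode, score, K, N, seed, connectivity and the
#'   per-cluster block (size, components, largest).
#' @export
ith_result_to_list <- function(res) {
  stopifnot(inherits(res, "ith_result"))
  per <- res$summary$per_cluster
  list(mode = res$mode, score = res$score, K = res$K, N = res$N,
       seed = res$seed, connectivity = res$connectivity,
       per_cluster = lapply(seq_len(nrow(per)), function(i)
         list(size = per$size[i], components = per$components[i],
              largest = per$largest[i])))
}
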