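# Local feature bank: a fixed, versioned set of exactly 104 generic local
# features per in-mask element, computed from the intensity neighborhood of
# the element. The sliding kernel is 2x2 (2D) or 2x2x2 (3D), anchored at the
# minimum corner (the element plus its positive-direction neighbors), with
# three concentric box neighborhoods (radii 1..3) on top. Out-of-grid
# neighbors are edge-replicated; in-grid neighbors outside the mask keep
# their real intensities. The bank is an explicit documented stand-in: only
# its richness, locality and determinism matter to the downstream topology
# score, not the identity of individual features.

#' Feature bank specification
#'
#' @param mode `"2D"` or `"3D"`; fixes the sliding kernel (2x2 vs 2x2x2).
#' @param feature_count number of features kept (default 104, the full bank;
#'   smaller values keep the leading columns for experimentation).
#' @param hu_window lower/upper Hounsfield clip bounds used for the windowed
#'   intensity copy and for quantized-entropy features (default the lung
#'   window, level -600 HU / width 1500 HU).
#' @param standardize standardize columns before clustering (default TRUE).
#' @param pad allow edge-replication padding when the grid is smaller than
#'   the kernel support (default TRUE).
#' @param mask_fill replace out-of-mask intensities by iteratively dilated
#'   in-mask values before windowed feature computation (default TRUE). This
#'   keeps neighborhood features driven by nodule tissue rather than by the
#'   air/parenchyma background: without it, every nodule carries a strong
#'   boundary-shell signature and even perfectly homogeneous lesions receive
#'   clearly nonzero heterogeneity scores.
#' @return An object of class `feature_bank_spec`.
#' @export
feature_bank_spec <- function(mode = c("3D", "2D"), feature_count = 104L,
                              hu_window = c(-1350, 150), standardize = TRUE,
                              pad = TRUE, mask_fill = TRUE) {
  mode <- match.arg(toupper(mode[1]), c("3D", "2D"))
  feature_count <- as.integer(feature_count)
  if (feature_count < 2L) stage_error("local_features", "feature_count must be >= 2")
  if (feature_count > 104L)
    stage_error("local_features", "the feature bank defines at most 104 features")
  if (length(hu_window) != 2L || hu_window[1] >= hu_window[2])
    stage_error("local_features", "hu_window must be (lower, upper) with lower < upper")
  structure(list(mode = mode,
                 window = if (mode == "2D") c(2L, 2L) else c(2L, 2L, 2L),
                 feature_count = feature_count,
                 hu_window = as.numeric(hu_window),
                 standardize = isTRUE(standardize),
                 pad = isTRUE(pad),
                 mask_fill = isTRUE(mask_fill)),
            class = "feature_bank_spec")
}

# filter taps (normalized so smoothing sums to 1 and edge/spot to 0)
.taps <- list(s = c(0.25, 0.5, 0.25), e = c(-0.5, 0, 0.5), sp = c(0.25, -0.5, 0.25))

#' Extract the local feature bank
#'
#' One feature row per in-mask element. Dispersion/texture features are
#' invariant to adding a constant to all intensities; location features shift
#' by that constant (see the `kind` attribute: "location", "dispersion",
#' "other").
#'
#' @param region a `planar_section` (2D mode) or [nodule_image()] (3D mode).
#' @param spec a [feature_bank_spec()]; its mode must match the region.
#' @return An object of class `feature_matrix` with fields `values`
#'   (n x feature_count), `coords` (n x d element indices), `grid_dim`,
#'   `mode`, `feature_names`, `feature_kinds`.
#' @export
extract_local_features <- function(region, spec = NULL) {
  is2d <- inherits(region, "planar_section")
  if (!is2d && !inherits(region, "nodule_image"))
    stage_error("local_features", "region must be a planar_section or nodule_image")
  if (is.null(spec)) spec <- feature_bank_spec(if (is2d) "2D" else "3D")
  if ((spec$mode == "2D") != is2d)
    stage_error("local_features", sprintf(
      "spec mode %s does not match a %s region", spec$mode, if (is2d) "2D" else "3D"))

  a <- region$intensities
  msk <- region$mask
  if (is2d) { a <- as.matrix(a); msk <- as.matrix(msk) }
  dm <- dim(a)
  nd <- length(dm)
  if (sum(msk) < 1L) stage_error("local_features", "degenerate input: empty mask")
  if (!spec$pad && any(dm < 2L))
    stage_error("local_features",
                "degenerate input: grid smaller than the sliding kernel and padding disabled")
  storage.mode(a) <- "double"
  dimv <- as.integer(dm)
  if (isTRUE(spec$mask_fill)) a <- mask_fill_intensities(a, msk, dimv)

  lo <- spec$hu_window[1]; hi <- spec$hu_window[2]
  aw <- pmin(pmax(a, lo), hi)
  dim(aw) <- dm

  feats <- vector("list", 120L); fnames <- character(120L); fkinds <- character(120L)
  nf <- 0L
  add <- function(name, arr, kind) {
    nf <<- nf + 1L
    feats[[nf]] <<- arr; fnames[nf] <<- name; fkinds[nf] <<- kind
  }

  wsum <- function(x, l, h) cpp_window_sum(as.vector(x), dimv, l, h)
  wmin <- function(x, l, h) cpp_window_min(as.vector(x), dimv, l, h)
  wmax <- function(x, l, h) cpp_window_max(as.vector(x), dimv, l, h)
  afilt <- function(x, axis, taps) cpp_axis_filter(as.vector(x), dimv, axis - 1L, taps)

  nbhd <- list(kernel = c(0L, 1L), box1 = c(-1L, 1L), box2 = c(-2L, 2L), box3 = c(-3L, 3L))
  ncount <- vapply(nbhd, function(w) (w[2] - w[1] + 1)^nd, numeric(1))

  # A: center intensities
  add("center_raw", a, "location")
  add("center_win", aw, "location")

  # neighborhood first-order stats (mean, var, skew, min, max, range, energy)
  nb_stats <- function(x, tag) {
    out <- list()
    for (k in seq_along(nbhd)) {
      w <- nbhd[[k]]; n <- ncount[k]; nm <- names(nbhd)[k]
      s1 <- wsum(x, w[1], w[2]) / n
      s2 <- wsum(x * x, w[1], w[2]) / n
      s3 <- wsum(x * x * x, w[1], w[2]) / n
      mn <- wmin(x, w[1], w[2]); mx <- wmax(x, w[1], w[2])
      va <- pmax(s2 - s1 * s1, 0)
      sk <- (s3 - 3 * s1 * s2 + 2 * s1^3) / (va^1.5 + 1e-6)
      add(paste0(tag, "_mean_", nm), s1, "location")
      add(paste0(tag, "_var_", nm), va, "dispersion")
      add(paste0(tag, "_skew_", nm), sk, "dispersion")
      add(paste0(tag, "_min_", nm), mn, "location")
      add(paste0(tag, "_max_", nm), mx, "location")
      add(paste0(tag, "_range_", nm), mx - mn, "dispersion")
      add(paste0(tag, "_energy_", nm), s2, "other")
      out[[nm]] <- list(mean = s1, var = va, energy = s2, min = mn, max = mx)
    }
    out
  }

  raw_stats <- nb_stats(a, "raw")                # 4 x 7 = 28
  # 16-level quantized entropy on the windowed copy, all 4 neighborhoods (4)
  nlev <- 16L
  binw <- (hi - lo) / nlev
  bidx <- pmin(pmax(floor((as.vector(aw) - lo) / binw) + 1, 1), nlev)
  ent <- lapply(nbhd, function(w) numeric(length(bidx)))
  for (b in seq_len(nlev)) {
    ind <- as.double(bidx == b)
    for (k in seq_along(nbhd)) {
      w <- nbhd[[k]]
      p <- wsum(ind, w[1], w[2]) / ncount[k]
      term <- ifelse(p > 0, p * log2(p), 0)
      ent[[k]] <- ent[[k]] - term
    }
  }
  for (k in seq_along(nbhd))
    add(paste0("entropy16_", names(nbhd)[k]), ent[[k]], "other")

  # windowed copy, boxes only, without entropy (3 x 7 = 21)
  win_stats <- list()
  for (k in 2:4) {
    w <- nbhd[[k]]; n <- ncount[k]; nm <- names(nbhd)[k]
    s1 <- wsum(aw, w[1], w[2]) / n
    s2 <- wsum(aw * aw, w[1], w[2]) / n
    s3 <- wsum(aw^3, w[1], w[2]) / n
    mn <- wmin(aw, w[1], w[2]); mx <- wmax(aw, w[1], w[2])
    va <- pmax(s2 - s1 * s1, 0)
    sk <- (s3 - 3 * s1 * s2 + 2 * s1^3) / (va^1.5 + 1e-6)
    add(paste0("win_mean_", nm), s1, "location")
    add(paste0("win_var_", nm), va, "dispersion")
    add(paste0("win_skew_", nm), sk, "dispersion")
    add(paste0("win_min_", nm), mn, "location")
    add(paste0("win_max_", nm), mx, "location")
    add(paste0("win_range_", nm), mx - mn, "dispersion")
    add(paste0("win_energy_", nm), s2, "other")
    win_stats[[nm]] <- list(mean = s1, var = va)
  }

  # finite-difference gradients: slice, row, col + magnitude (4)
  zero <- numeric(length(a))
  ax_names <- c("slice", "row", "col")
  grads <- list()
  for (i in 1:3) {
    g <- if (nd == 2 && i == 1) zero else afilt(a, if (nd == 3) i else i - 1L, .taps$e)
    grads[[i]] <- g
    add(paste0("grad_", ax_names[i]), g, "dispersion")
  }
  gmag <- sqrt(grads[[1]]^2 + grads[[2]]^2 + grads[[3]]^2)
  add("grad_mag", gmag, "dispersion")

  # second derivative (spot) per axis + their sum (4)
  spots <- list()
  for (i in 1:3) {
    s2d <- if (nd == 2 && i == 1) zero else afilt(a, if (nd == 3) i else i - 1L, .taps$sp)
    spots[[i]] <- s2d
    add(paste0("spot_", ax_names[i]), s2d, "dispersion")
  }
  add("spot_sum", spots[[1]] + spots[[2]] + spots[[3]], "dispersion")

  # in-plane separable 3x3 filter responses, raw + windowed (9 + 9)
  rax <- if (nd == 3) 2L else 1L
  cax <- if (nd == 3) 3L else 2L
  for (src in c("raw", "win")) {
    x <- if (src == "raw") a else aw
    for (t1 in names(.taps)) for (t2 in names(.taps)) {
      r <- afilt(afilt(x, rax, .taps[[t1]]), cax, .taps[[t2]])
      kind <- if (t1 == "s" && t2 == "s") "location" else "dispersion"
      add(paste0("filt_", src, "_", t1, t2), r, kind)
    }
  }

  # center-contrast RMS per neighborhood (4)
  av <- as.vector(a)
  for (k in seq_along(nbhd)) {
    st <- raw_stats[[k]]
    rms <- sqrt(pmax(st$energy - 2 * av * st$mean + av * av, 0))
    add(paste0("ccontrast_", names(nbhd)[k]), rms, "dispersion")
  }

  # center z-score inside box1..3 (3)
  for (nm in c("box1", "box2", "box3")) {
    st <- raw_stats[[nm]]
    add(paste0("zscore_", nm), (av - st$mean) / (sqrt(st$var) + 1), "other")
  }

  # coefficient of variation per neighborhood (4)
  for (k in seq_along(nbhd)) {
    st <- raw_stats[[k]]
    add(paste0("cov_", names(nbhd)[k]), sqrt(st$var) / (abs(st$mean) + 1), "other")
  }

  # box1-smoothed absolute gradients + magnitude (4)
  for (i in 1:3)
    add(paste0("sgrad_", ax_names[i]), wsum(abs(grads[[i]]), -1L, 1L) / 3^nd, "dispersion")
  add("sgrad_mag", wsum(gmag, -1L, 1L) / 3^nd, "dispersion")

  # range ratios vs the widest neighborhood (3)
  r3 <- raw_stats$box3$max - raw_stats$box3$min
  for (nm in c("kernel", "box1", "box2")) {
    rn <- raw_stats[[nm]]$max - raw_stats[[nm]]$min
    add(paste0("rratio_", nm), rn / (r3 + 1), "dispersion")
  }

  # box1-smoothed absolute spot responses (3)
  for (i in 1:3)
    add(paste0("sspot_", ax_names[i]), wsum(abs(spots[[i]]), -1L, 1L) / 3^nd, "dispersion")

  # windowed kernel mean and variance (2)
  wk1 <- wsum(aw, 0L, 1L) / ncount[1]
  wk2 <- wsum(aw * aw, 0L, 1L) / ncount[1]
  add("win_mean_kernel", wk1, "location")
  add("win_var_kernel", pmax(wk2 - wk1 * wk1, 0), "dispersion")

  stopifnot(nf == 104L)
  keep <- seq_len(spec$feature_count)
  idx <- which(as.vector(msk) == 1L)
  vals <- matrix(0, length(idx), length(keep),
                 dimnames = list(NULL, fnames[keep]))
  for (j in keep) vals[, j] <- feats[[j]][idx]
  if (any(!is.finite(vals)))
    stage_error("local_features", "non-finite feature values after extraction")
  coords <- arrayInd(idx, dm)
  structure(list(values = vals, coords = coords, grid_dim = dm,
                 mode = spec$mode, feature_names = fnames[keep],
                 feature_kinds = fkinds[keep], standardized = FALSE),
            class = "feature_matrix")
}

# Iterative nearest-tissue fill: out-of-mask voxels take the mean of already
# filled box-1 neighbors, repeated until the widest neighborhood (radius 3 +
# kernel reach) sees tissue-derived values everywhere it can. Voxels beyond
# the fill horizon keep their original intensities (they only enter features
# of elements farther than the kernel support from the mask, which do not
# exist).
mask_fill_intensities <- function(a, msk, dimv) {
  filled <- as.double(as.vector(msk) == 1L)
  vals <- as.vector(a) * filled
  for (it in 1:5) {
    if (all(filled > 0)) break
    cnt <- cpp_window_sum(filled, dimv, -1L, 1L)
    sums <- cpp_window_sum(vals, dimv, -1L, 1L)
    new <- filled == 0 & cnt > 0
    if (!any(new)) break
    vals[new] <- sums[new] / cnt[new]
    filled[new] <- 1
  }
  rest <- filled == 0
  vals[rest] <- as.vector(a)[rest]
  array(vals, dim = dimv)
}

#' Standardize a feature matrix
#'
#' Column-wise population standardization (mean 0, variance 1). Columns whose
#' standard deviation falls below `tol` are mapped to all-zeros, so an exactly
#' homogeneous region yields the all-zero feature matrix rather than amplified
#' numerical noise.
#'
#' @param F a `feature_matrix`.
#' @param tol absolute standard-deviation floor below which a column is
#'   treated as constant.
#' @return The standardized `feature_matrix`.
#' @export
standardize_features <- function(F, tol = 1e-8) {
  stopifnot(inherits(F, "feature_matrix"))
  X <- F$values
  if (nrow(X) < 2L)
    stage_error("local_features", "standardization needs at least 2 rows")
  mu <- colMeans(X)
  va <- colMeans(X^2) - mu^2
  s <- sqrt(pmax(va, 0))  # population sd
  Xc <- sweep(X, 2L, mu, "-")
  keep <- s > tol
  Xc[, keep] <- sweep(Xc[, keep, drop = FALSE], 2L, s[keep], "/")
  Xc[, !keep] <- 0
  F$values <- Xc
  F$standardized <- TRUE
  F
}

#' Export a feature matrix to CSV
#'
#' Coordinate columns first (slice/row/col or row/col), then feature columns
#' in the documented bank order.
#'
#' @param F a `feature_matrix`.
#' @param path output CSV path.
#' @export
write_feature_matrix <- function(F, path) {
  stopifnot(inherits(F, "feature_matrix"))
  cn <- if (ncol(F$coords) == 3L) c("slice", "row", "col") else c("row", "col")
  df <- cbind(as.data.frame(F$coords), as.data.frame(F$values))
  names(df)[seq_along(cn)] <- cn
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
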