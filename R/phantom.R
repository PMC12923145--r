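# Synthetic data: CT nodule phantoms with known subregion topology, and
# clinicoradiologic cohort tables with Table-1-like marginals. The phantom is
# an ellipsoidal nodule (emulating 5-30 mm lesions on thin-section CT) whose
# in-mask voxels are divided into phenotype_count phenotypes, each placed as
# `fragmentation` disjoint 26-connected blobs; phenotypes differ by a mean
# intensity offset (contrast, HU) on a ground-glass background, plus iid
# Gaussian noise. The blob layout is a Voronoi partition of well-separated
# seeds, re-assigned so same-phenotype cells never touch; the returned truth
# grid therefore has exactly fragmentation components per phenotype.

#' Phantom specification
#'
#' @param grid integer length-3 grid shape (slice, row, column).
#' @param radius_range in-plane ellipsoid semi-axis range, in voxels.
#' @param phenotype_count number of phenotypes (1..6).
#' @param fragmentation blobs per phenotype (>= 1).
#' @param contrast intensity separation between adjacent phenotypes (HU).
#' @param noise_sd additive Gaussian noise sd (HU).
#' @param spacing voxel spacing in mm (slice, row, column).
#' @param base_hu background (least dense phenotype) mean intensity.
#' @param seed RNG seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(36L, 48L, 48L), radius_range = c(8, 14),
                         phenotype_count = 3L, fragmentation = 1L,
                         contrast = 300, noise_sd = 15,
                         spacing = c(1, 0.7, 0.7), base_hu = -600,
                         seed = 1L) {
  phenotype_count <- as.integer(phenotype_count)
  fragmentation <- as.integer(fragmentation)
  if (phenotype_count < 1L || phenotype_count > 6L)
    stage_error("phantom_generator", "phenotype_count must be in 1..6")
  if (fragmentation < 1L)
    stage_error("phantom_generator", "fragmentation must be >= 1")
  if (max(radius_range) * 2 + 4 > min(grid[2:3]) || max(radius_range) + 4 > grid[1])
    stage_error("phantom_generator", "radius range does not fit the grid")
  structure(list(grid = as.integer(grid), radius_range = as.numeric(radius_range),
                 phenotype_count = phenotype_count, fragmentation = fragmentation,
                 contrast = as.numeric(contrast), noise_sd = as.numeric(noise_sd),
                 spacing = as.numeric(spacing), base_hu = as.numeric(base_hu),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic CT nodule phantom
#'
#' @param spec a [phantom_spec()].
#' @return A list with `image` (a [nodule_image()]) and `truth` (integer
#'   phenotype label grid, 0 outside the nodule, exactly
#'   `spec$fragmentation` 26-connected components per phenotype).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    dm <- spec$grid
    ctr <- (dm + 1) / 2
    r_in <- runif(2, spec$radius_range[1], spec$radius_range[2])
    r_sl <- max(3, runif(1, spec$radius_range[1], spec$radius_range[2]) *
                  mean(spec$spacing[2:3]) / spec$spacing[1])
    semi <- c(r_sl, r_in)
    idx <- arrayInd(seq_len(prod(dm)), dm)
    d2 <- ((idx[, 1] - ctr[1]) / semi[1])^2 + ((idx[, 2] - ctr[2]) / semi[2])^2 +
      ((idx[, 3] - ctr[3]) / semi[3])^2
    mask_lin <- which(d2 <= 1)
    if (length(mask_lin) < 8L)
      stage_error("phantom_generator", "degenerate phantom: mask too small")
    mask <- array(0L, dm)
    mask[mask_lin] <- 1L

    n_blob <- spec$phenotype_count * spec$fragmentation
    if (spec$phenotype_count == 1L && spec$fragmentation > 1L)
      stage_error("phantom_generator",
                  "a single phenotype covering a connected mask cannot be fragmented")
    truth <- array(0L, dm)
    if (n_blob == 1L) {
      truth[mask_lin] <- 1L
    } else {
      pts <- idx[mask_lin, , drop = FALSE]
      ok <- FALSE
      check_truth <- function() {
        comp <- component_labels(truth, 26L)
        counts <- tabulate(attr(comp, "cluster"), nbins = spec$phenotype_count)
        all(counts == spec$fragmentation)
      }
      # preferred layout: Voronoi cells of well-separated seeds, colored so
      # same-phenotype cells never touch
      for (attempt in 1:15) {
        seeds <- farthest_point_seeds(pts, n_blob)
        cell <- nearest_seed(pts, pts[seeds, , drop = FALSE])
        cellg <- array(0L, dm)
        cellg[mask_lin] <- cell
        pheno_of_blob <- assign_phenotypes(cellg, n_blob,
                                           spec$phenotype_count, spec$fragmentation)
        if (is.null(pheno_of_blob)) next
        truth[] <- 0L
        truth[mask_lin] <- pheno_of_blob[cell]
        if (check_truth()) { ok <- TRUE; break }
      }
      # fallback layout: equal-count slabs along a random direction with
      # round-robin phenotypes (adjacent slabs always differ)
      if (!ok) for (attempt in 1:15) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        tproj <- pts %*% u
        slab <- as.integer(cut(rank(tproj, ties.method = "first"),
                               breaks = n_blob, labels = FALSE))
        truth[] <- 0L
        truth[mask_lin] <- (slab - 1L) %% spec$phenotype_count + 1L
        if (check_truth()) { ok <- TRUE; break }
      }
      if (!ok)
        stage_error("phantom_generator",
                    "infeasible blob packing; increase the grid or radius range")
    }

    offs <- spec$base_hu + (seq_len(spec$phenotype_count) - 1) * spec$contrast
    inten <- array(-1000, dm)  # air background
    inten[mask_lin] <- offs[truth[mask_lin]]
    if (spec$noise_sd > 0)
      inten <- inten + array(rnorm(prod(dm), 0, spec$noise_sd), dm)
    list(image = nodule_image(inten, mask, spec$spacing), truth = truth)
  })
}

# greedy farthest-point sampling of n seed rows from pts (k x 3)
farthest_point_seeds <- function(pts, n) {
  m <- nrow(pts)
  seeds <- integer(n)
  seeds[1] <- sample.int(m, 1L)
  d2 <- rowSums(sweep(pts, 2L, pts[seeds[1], ], "-")^2)
  if (n > 1) for (k in 2:n) {
    seeds[k] <- which.max(d2)
    d2 <- pmin(d2, rowSums(sweep(pts, 2L, pts[seeds[k], ], "-")^2))
  }
  seeds
}

nearest_seed <- function(pts, seed_pts) {
  d <- matrix(0, nrow(pts), nrow(seed_pts))
  for (k in seq_len(nrow(seed_pts)))
    d[, k] <- rowSums(sweep(pts, 2L, seed_pts[k, ], "-")^2)
  max.col(-d, ties.method = "first")
}

# map blobs (Voronoi cells) to phenotypes so that no two same-phenotype cells
# are 26-adjacent; greedy quota-constrained graph coloring
assign_phenotypes <- function(cellg, n_blob, n_pheno, frag) {
  dm <- dim(cellg)
  adj <- matrix(FALSE, n_blob, n_blob)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = 0:1))
  offs <- offs[offs[, 3] > 0 | offs[, 2] > 0 | (offs[, 2] == 0 & offs[, 1] > 0), ,
               drop = FALSE]  # 13 unique directions
  for (o in seq_len(nrow(offs))) {
    d <- offs[o, ]
    a <- cellg[seq(max(1, 1 - d[1]), min(dm[1], dm[1] - d[1])),
               seq(max(1, 1 - d[2]), min(dm[2], dm[2] - d[2])),
               seq(max(1, 1 - d[3]), min(dm[3], dm[3] - d[3])), drop = FALSE]
    b <- cellg[seq(max(1, 1 + d[1]), min(dm[1], dm[1] + d[1])),
               seq(max(1, 1 + d[2]), min(dm[2], dm[2] + d[2])),
               seq(max(1, 1 + d[3]), min(dm[3], dm[3] + d[3])), drop = FALSE]
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) {
      pr <- unique(cbind(a[sel], b[sel]))
      adj[pr] <- TRUE
      adj[pr[, 2:1, drop = FALSE]] <- TRUE
    }
  }
  # quota-constrained proper coloring by bounded backtracking (highest-degree
  # blobs first); NULL if no assignment found within the step budget
  deg <- rowSums(adj)
  ord <- order(-deg)
  pheno <- integer(n_blob)
  quota <- rep(frag, n_pheno)
  steps <- 0L
  dfs <- function(i) {
    if (i > n_blob) return(TRUE)
    steps <<- steps + 1L
    if (steps > 20000L) return(FALSE)
    b <- ord[i]
    banned <- unique(pheno[adj[b, ] & pheno > 0])
    for (pk in order(-quota)) {
      if (quota[pk] == 0L || pk %in% banned) next
      pheno[b] <<- pk; quota[pk] <<- quota[pk] - 1L
      if (dfs(i + 1L)) return(TRUE)
      pheno[b] <<- 0L; quota[pk] <<- quota[pk] + 1L
    }
    FALSE
  }
  if (dfs(1L)) pheno else NULL
}

#' Generate a synthetic clinicoradiologic cohort
#'
#' Emulates the variable types and approximate marginals of a stage-I lung
#' adenocarcinoma cohort: binary invasiveness label (1 = IAC, prevalence
#' ~0.66), demographics, nodule size, CT density (pGGN/PSN/SN), lobe
#' location, morphological signs, and 2D/3D ITH scores in [0, 1). All
#' label-feature couplings are driven by a single latent invasiveness
#' variable v = effect * (label - prevalence) + N(0,1) through a logistic
#' link, so `effect = 0` yields a label-independent (null) cohort. The 3D
#' ITH coupling dominates by construction.
#'
#' @param n number of rows (>= 20).
#' @param effect separation knob (default 1.5).
#' @param seed RNG seed.
#' @param prevalence IAC prevalence (default 0.66).
#' @return A `data.frame` of class `cohort_table`.
#' @export
generate_cohort <- function(n, effect = 1.5, seed = 1L, prevalence = 0.66) {
  n <- as.integer(n)
  if (n < 20L) stage_error("phantom_generator", "cohort size must be >= 20")
  with_seed(seed, {
    label <- rbinom(n, 1L, prevalence)
    v <- effect * (label - prevalence) + rnorm(n)

    ith3d <- plogis(-1.1 + 1.0 * v + rnorm(n, 0, 0.6))
    ith2d <- plogis(-1.0 + 0.45 * v + rnorm(n, 0, 0.8))
    size_mm <- pmin(pmax(exp(log(15.8) + 0.13 * v + rnorm(n, 0, 0.28)), 5), 30)
    age <- as.integer(round(pmin(pmax(57 + 1.2 * v + rnorm(n, 0, 9.5), 25), 90)))
    sex <- rbinom(n, 1L, plogis(qlogis(0.337) + 0.15 * v))  # 1 = male
    dens_latent <- 0.5 * v + rnorm(n)
    cuts <- quantile(dens_latent, c(0.54, 0.80))
    density <- cut(dens_latent, c(-Inf, cuts, Inf), labels = c("pGGN", "PSN", "SN"))
    location <- factor(sample(c("RUL", "RML", "RLL", "LUL", "LLL"), n, TRUE,
                              prob = c(0.354, 0.068, 0.169, 0.275, 0.135)),
                       levels = c("RUL", "RML", "RLL", "LUL", "LLL"))
    sign_p <- c(margin = 0.249, lobulation = 0.537, spiculation = 0.456,
                vascular_convergence = 0.773, vacuole = 0.189,
                pleural_indentation = 0.577, shape = 0.459)
    signs <- lapply(names(sign_p), function(s)
      rbinom(n, 1L, plogis(qlogis(sign_p[[s]]) + 0.25 * v)))
    names(signs) <- names(sign_p)

    df <- data.frame(label = label, sex = factor(ifelse(sex == 1, "Male", "Female"),
                                                 levels = c("Female", "Male")),
                     age = age, size_mm = size_mm, density = density,
                     location = location, margin = signs$margin,
                     lobulation = signs$lobulation, spiculation = signs$spiculation,
                     vascular_convergence = signs$vascular_convergence,
                     vacuole = signs$vacuole,
                     pleural_indentation = signs$pleural_indentation,
                     shape = signs$shape, ith2d = ith2d, ith3d = ith3d)
    class(df) <- c("cohort_table", "data.frame")
    attr(df, "effect") <- effect
    attr(df, "seed") <- as.integer(seed)
    df
  })
}

#' Write phantom outputs to disk
#'
#' Writes the image, mask and truth-label volumes as a NIfTI (or NRRD) trio.
#'
#' @param phantom result of [generate_phantom()].
#' @param image_path,mask_path,truth_path output paths.
#' @export
write_phantom <- function(phantom, image_path, mask_path, truth_path = NULL) {
  write_nodule(phantom$image, image_path, mask_path)
  if (!is.null(truth_path))
    write_image_any(phantom$truth, phantom$image$spacing, truth_path)
  invisible(NULL)
}
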