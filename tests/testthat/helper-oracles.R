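# Independent oracles and fixture builders, kept free of the implementation
# paths they check.

# Connected components by vectorized min-label propagation with pointer
# doubling (a different algorithm from the package's BFS labeling).
# Returns per-cluster component counts and largest sizes.
oracle_components <- function(lab, connectivity) {
  dm <- dim(lab)
  nd <- length(dm)
  if (nd == 2L) { lab <- array(lab, c(dm, 1L)); dm <- dim(lab) }
  diagonal <- connectivity %in% c(8L, 26L)
  offs <- as.matrix(expand.grid(-1:1, -1:1, if (dm[3] > 1) -1:1 else 0))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (!diagonal) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  n <- length(lab)
  comp <- ifelse(lab > 0, seq_len(n), 0L)
  sl <- function(k, d) seq(max(1, 1 - d), min(k, k - d))
  repeat {
    prev <- comp
    for (o in seq_len(nrow(offs))) {
      d <- offs[o, ]
      ra <- sl(dm[1], d[1]); ca <- sl(dm[2], d[2]); za <- sl(dm[3], d[3])
      rb <- ra + d[1]; cb <- ca + d[2]; zb <- za + d[3]
      la <- lab[ra, ca, za, drop = FALSE]; lb <- lab[rb, cb, zb, drop = FALSE]
      same <- la > 0 & la == lb
      if (any(same)) {
        sub <- comp[ra, ca, za, drop = FALSE]
        nb <- comp[rb, cb, zb, drop = FALSE]
        sub[same] <- pmin(sub[same], nb[same])
        comp[ra, ca, za] <- sub
      }
    }
    fg <- comp > 0
    comp[fg] <- pmin(comp[fg], comp[comp[fg]])  # pointer doubling
    if (identical(comp, prev)) break
  }
  roots <- comp[comp > 0]
  sizes <- table(roots)
  root_cluster <- lab[as.integer(names(sizes))]
  K <- max(lab)
  out <- data.frame(cluster = seq_len(K), components = 0L, largest = 0L,
                    size = as.integer(tabulate(lab[lab > 0], nbins = K)))
  for (i in seq_len(K)) {
    s <- sizes[root_cluster == i]
    if (length(s)) {
      out$components[i] <- length(s)
      out$largest[i] <- max(as.integer(s))
    }
  }
  out
}

random_label_map <- function(max_side = 20L, three_d = NA) {
  if (is.na(three_d)) three_d <- runif(1) < 0.5
  if (three_d) {
    dm <- sample(3:max_side, 3, replace = TRUE)
  } else {
    dm <- sample(3:max_side, 2, replace = TRUE)
  }
  K <- sample(2:5, 1)
  array(sample(0:K, prod(dm), replace = TRUE), dim = dm)
}

# Exact Shapley values by subset enumeration over the cover-weighted
# conditional expectation (the path-dependent value function).
brute_shap <- function(model, x) {
  p <- model$n_features
  vfun <- function(xrow, S) {
    tot <- model$base
    for (tr in model$trees) {
      rec <- function(node) {
        f <- tr$feature[node + 1]
        if (f < 0) return(tr$value[node + 1])
        l <- tr$left[node + 1]; r <- tr$right[node + 1]
        if ((f + 1) %in% S) {
          if (xrow[f + 1] < tr$thr[node + 1]) rec(l) else rec(r)
        } else {
          cl <- tr$cover[l + 1]; cr <- tr$cover[r + 1]
          if (cl + cr <= 0) return(tr$value[node + 1])
          (rec(l) * cl + rec(r) * cr) / (cl + cr)
        }
      }
      tot <- tot + rec(0)
    }
    tot
  }
  subsets <- lapply(0:(2^p - 1), function(m) which(bitwAnd(m, 2^(0:(p - 1))) > 0))
  key <- vapply(subsets, function(S) sum(2^(S - 1)), numeric(1))
  phi <- matrix(0, nrow(x), p)
  for (i in seq_len(nrow(x))) {
    vs <- vapply(subsets, function(S) vfun(x[i, ], S), numeric(1))
    for (j in seq_len(p)) {
      for (si in seq_along(subsets)) {
        S <- subsets[[si]]
        if (j %in% S) next
        s <- length(S)
        w <- factorial(s) * factorial(p - s - 1) / factorial(p)
        phi[i, j] <- phi[i, j] + w * (vs[match(sum(2^(c(S, j) - 1)), key)] - vs[si])
      }
    }
  }
  phi
}

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# Sparse "block world" label maps: each cluster is a set of isolated
# horizontal runs placed on a lattice with >= 2 cells of separation, so every
# run is exactly one connected component. block_sizes is a list (one vector
# of run lengths per cluster). Used for the fragmentation-monotonicity cases.
build_block_map <- function(block_sizes, max_len = 12L) {
  n_blocks <- sum(lengths(block_sizes))
  ncol_lat <- max_len + 3L
  nrow_need <- n_blocks
  lab <- matrix(0L, 2L * nrow_need + 3L, ncol_lat + 2L)
  r <- 1L
  for (cl in seq_along(block_sizes)) {
    for (s in block_sizes[[cl]]) {
      lab[2L * r, 2:(1L + s)] <- cl
      r <- r + 1L
    }
  }
  lab
}

# small, fast phantom spec used across tests
small_phantom_spec <- function(...) {
  phantom_spec(grid = c(24L, 32L, 32L), radius_range = c(6, 9), ...)
}

# single-grid-point hyperparameter set for fast bench runs in tests
fast_grids <- function() {
  list(gbdt = list(list(n_trees = 60L, max_depth = 2L, learning_rate = 0.1)),
       adaboost = list(list(n_trees = 40L, max_depth = 1L)),
       xgboost = list(list(n_trees = 60L, max_depth = 2L, learning_rate = 0.1)),
       lightgbm = list(list(n_trees = 60L, max_leaves = 7L, learning_rate = 0.1)),
       catboost = list(list(n_trees = 60L, max_depth = 3L, learning_rate = 0.1)),
       rf = list(list(n_trees = 60L, max_depth = 6L, mtry = 3L)))
}
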