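# Isolation-forest primitives.
#
# Random-split trees grown on small subsamples; anomalous points are
# isolated in few splits, so their average path length across trees is
# short. The raw anomaly measure used throughout this package is the
# average path length itself (larger = more normal); calibration to the
# unit interval happens against a training group's empirical distribution
# in overlap.R. Paths truncated at the height limit are extended by the
# standard average-path adjustment c(m) for the m points left in the node.

harmonic <- function(i) log(i) + 0.5772156649015329

# Expected path length of an unsuccessful BST search among m points.
avg_path_adjust <- function(m) {
  out <- numeric(length(m))
  out[m == 2] <- 1
  big <- m > 2
  out[big] <- 2 * harmonic(m[big] - 1) - 2 * (m[big] - 1) / m[big]
  out
}

# Grow one isolation tree on x[idx, ]; returns a flat node table.
grow_itree <- function(x, idx, height_limit) {
  feat <- integer(0); split <- numeric(0)
  left <- integer(0); right <- integer(0)
  leaf <- logical(0); size <- integer(0); depth <- integer(0)

  new_node <- function() {
    feat[[length(feat) + 1L]] <<- NA_integer_
    split[[length(split) + 1L]] <<- NA_real_
    left[[length(left) + 1L]] <<- NA_integer_
    right[[length(right) + 1L]] <<- NA_integer_
    leaf[[length(leaf) + 1L]] <<- TRUE
    size[[length(size) + 1L]] <<- 0L
    depth[[length(depth) + 1L]] <<- 0L
    length(feat)
  }

  build <- function(rows, d) {
    node <- new_node()
    depth[[node]] <<- d
    size[[node]] <<- length(rows)
    if (d >= height_limit || length(rows) <= 1L) return(node)
    sub <- x[rows, , drop = FALSE]
    rng_lo <- apply(sub, 2, min)
    rng_hi <- apply(sub, 2, max)
    usable <- which(rng_hi > rng_lo)
    if (length(usable) == 0L) return(node)   # all candidate features constant
    f <- if (length(usable) == 1L) usable else sample(usable, 1L)
    s <- stats::runif(1, rng_lo[f], rng_hi[f])
    go_left <- sub[, f] <= s
    if (all(go_left) || !any(go_left)) return(node)
    leaf[[node]] <<- FALSE
    feat[[node]] <<- f
    split[[node]] <<- s
    left[[node]] <<- build(rows[go_left], d + 1L)
    right[[node]] <<- build(rows[!go_left], d + 1L)
    node
  }
  build(idx, 0L)
  list(feat = feat, split = split, left = left, right = right,
       leaf = leaf, size = size, depth = depth)
}

# Path length of every row of x in one tree (vectorised level-by-level).
itree_path_length <- function(tree, x) {
  n <- nrow(x)
  cur <- rep(1L, n)
  repeat {
    active <- which(!tree$leaf[cur])
    if (length(active) == 0L) break
    node <- cur[active]
    go_left <- x[cbind(active, tree$feat[node])] <= tree$split[node]
    cur[active] <- ifelse(go_left, tree$left[node], tree$right[node])
  }
  tree$depth[cur] + avg_path_adjust(tree$size[cur])
}

# Fit an ensemble of isolation trees on a numeric matrix.
fit_iforest <- function(x, num_trees = 300, sample_size = 256, seed = 1) {
  n <- nrow(x)
  psi <- min(sample_size, n)
  height_limit <- max(1L, ceiling(log2(psi)))
  set.seed(seed)
  trees <- vector("list", num_trees)
  for (t in seq_len(num_trees)) {
    idx <- if (psi == n) seq_len(n) else sample.int(n, psi)
    trees[[t]] <- grow_itree(x, idx, height_limit)
  }
  list(trees = trees, psi = psi, height_limit = height_limit,
       num_trees = num_trees)
}

# Average path length over the ensemble: the raw "normality" score.
iforest_raw_score <- function(forest, x) {
  total <- numeric(nrow(x))
  for (tree in forest$trees) total <- total + itree_path_length(tree, x)
  total / forest$num_trees
}
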