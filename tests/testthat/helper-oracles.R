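# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's computational paths (spatial indexing, Rcpp kernels):
# plain R loops and vectorized arithmetic only.

# Minimum distance from every voxel of a (nz, ny, nx) grid to a point set,
# by accumulating pmin over points. Coordinates are zero-based (x, y, z).
bf_min_dist <- function(pts, shape) {
  grid <- expand.grid(z = 0:(shape[1] - 1), y = 0:(shape[2] - 1),
                      x = 0:(shape[3] - 1))
  d2 <- rep(Inf, nrow(grid))
  for (i in seq_len(nrow(pts))) {
    d2 <- pmin(d2, (grid$x - pts[i, 1])^2 + (grid$y - pts[i, 2])^2 +
                 (grid$z - pts[i, 3])^2)
  }
  array(sqrt(d2), dim = shape)
}

bf_expand <- function(pts, shape, radius, strict = TRUE) {
  d <- bf_min_dist(pts, shape)
  if (strict) d < radius else d <= radius
}

# Exhaustive O(|P| * |G|) matcher: fraction of rows of A within thre of B.
bf_match_fraction <- function(A, B, thre) {
  hits <- vapply(seq_len(nrow(A)), function(i) {
    dmin <- min(sqrt(colSums((t(B) - A[i, ])^2)))
    dmin < thre
  }, logical(1))
  mean(hits)
}

bf_scores <- function(P, G, thre) {
  recall <- bf_match_fraction(G, P, thre)
  precision <- bf_match_fraction(P, G, thre)
  f1 <- if (recall + precision > 0) 2 * recall * precision / (recall + precision) else 0
  list(recall = recall, precision = precision, f1 = f1)
}

# AJI by explicit pairwise Jaccard tables and greedy matching.
bf_aji <- function(G_map, P_map) {
  g <- as.integer(G_map); p <- as.integer(P_map)
  gids <- setdiff(sort(unique(g)), 0L)
  pids <- setdiff(sort(unique(p)), 0L)
  if (length(gids) == 0 && length(pids) == 0) return(1)
  used <- rep(FALSE, length(pids))
  num <- 0; den <- 0
  for (gi in gids) {
    best_j <- 0; best_jac <- 0
    for (jj in seq_along(pids)) {
      if (used[jj]) next
      inter <- sum(g == gi & p == pids[jj])
      if (inter == 0) next
      un <- sum((g == gi) | (p == pids[jj]))
      jac <- inter / un
      if (jac > best_jac) { best_jac <- jac; best_j <- jj }
    }
    if (best_j > 0) {
      used[best_j] <- TRUE
      inter <- sum(g == gi & p == pids[best_j])
      num <- num + inter
      den <- den + sum((g == gi) | (p == pids[best_j]))
    } else {
      den <- den + sum(g == gi)
    }
  }
  den <- den + sum(vapply(pids[!used], function(pj) sum(p == pj), 1))
  if (den > 0) num / den else 1
}

# Voxel-by-voxel loss with explicit loops (no vectorized shortcuts).
bf_loss <- function(yp, yg, x, t1 = 3 / 255, t2 = 103 / 255) {
  n <- length(yp)
  s_tot <- 0; s1 <- 0; s2 <- 0; s2s <- 0; n1 <- 0; n2 <- 0; n2s <- 0
  for (i in seq_len(n)) {
    a <- abs(yp[i] - yg[i])
    s_tot <- s_tot + a
    if (yg[i] > t1) { s1 <- s1 + a; n1 <- n1 + 1 }
    if (yg[i] > t2) { s2 <- s2 + a; n2 <- n2 + 1 }
    if (x[i] > t2) { s2s <- s2s + a; n2s <- n2s + 1 }
  }
  s_tot / n + (if (n1 > 0) s1 / n1 else 0) + (if (n2 > 0) s2 / n2 else 0) +
    (if (n2s > 0) s2s / n2s else 0)
}

# A short L-shaped test skeleton.
fixture_tree <- function(tree_id = 1L) {
  skeleton_tree(x = c(2, 4, 6, 6, 6), y = c(3, 3, 3, 5, 7), z = rep(4, 5),
                tree_id = tree_id)
}
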