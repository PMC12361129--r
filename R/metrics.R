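#' Matching configuration for skeleton scoring
#'
#' @param thre Matching distance threshold in voxels (default 3, equal to the
#'   region expansion radius).
#' @param squared_norm Compare the squared distance against `thre` instead of
#'   the Euclidean distance (default FALSE).
#' @param region_radius Radius used when rasterizing skeletons into instance
#'   regions (default 3).
#' @return A list of class `match_config`.
#' @export
match_config <- function(thre = 3, squared_norm = FALSE, region_radius = 3) {
  stopifnot(thre > 0, region_radius > 0)
  structure(list(thre = thre, squared_norm = squared_norm,
                 region_radius = region_radius), class = "match_config")
}

#' Point-to-set matching indicator
#'
#' Returns 1 iff the minimum Euclidean distance from `p` to any point of `G`
#' is strictly below `thre`.
#'
#' @param p Numeric 3-vector (x, y, z).
#' @param G Nonempty n x 3 matrix of reference points.
#' @param thre Threshold in voxels.
#' @param squared_norm Compare squared distance against `thre`.
#' @return 0 or 1.
#' @export
match_indicator <- function(p, G, thre = 3, squared_norm = FALSE) {
  G <- as.matrix(G)
  if (nrow(G) == 0L) stop("reference point set is empty")
  match_flags(matrix(as.numeric(p), 1, 3), G, thre, squared_norm)[1]
}

#' Skeleton-matching recall, precision and F1
#'
#' Recall is the fraction of ground-truth points within `thre` of some
#' predicted point; precision is the fraction of predicted points within
#' `thre` of some ground-truth point; F1 is their harmonic mean (0 when both
#' are 0). By convention two empty sets score perfectly; an empty ground
#' truth against a nonempty prediction yields an undefined (NaN) recall with
#' a warning.
#'
#' @param P Predicted skeleton points (n x 3 matrix, or trees accepted by
#'   [skeleton_points()], which are resampled to <= 1 voxel spacing first).
#' @param G Ground-truth skeleton points, same forms.
#' @param cfg A [match_config()].
#' @return A list with `recall`, `precision`, `f1`, `n_g`, `n_p`.
#' @export
skeleton_scores <- function(P, G, cfg = match_config()) {
  P <- as_point_matrix(P)
  G <- as_point_matrix(G)
  n_p <- nrow(P); n_g <- nrow(G)
  if (n_p == 0L && n_g == 0L)
    return(list(recall = 1, precision = 1, f1 = 1, n_g = 0L, n_p = 0L))
  if (n_g == 0L) {
    warning("empty ground truth: recall undefined")
    return(list(recall = NaN, precision = 0, f1 = NaN, n_g = 0L, n_p = n_p))
  }
  if (n_p == 0L)
    return(list(recall = 0, precision = if (n_p == 0L) NaN else 0,
                f1 = 0, n_g = n_g, n_p = 0L))
  recall <- mean(match_flags(G, P, cfg$thre, cfg$squared_norm))
  precision <- mean(match_flags(P, G, cfg$thre, cfg$squared_norm))
  f1 <- if (recall + precision > 0) 2 * recall * precision / (recall + precision) else 0
  list(recall = recall, precision = precision, f1 = f1, n_g = n_g, n_p = n_p)
}

as_point_matrix <- function(x) {
  if (is.matrix(x)) {
    if (nrow(x) > 0) stopifnot(ncol(x) == 3)
    return(unname(as.matrix(x)))
  }
  if (is.data.frame(x) && all(c("x", "y", "z") %in% names(x)))
    return(skeleton_points(x)$pts)
  if (is.list(x)) return(skeleton_points(x)$pts)
  stop("cannot interpret point set")
}

#' Rasterize skeletons into an instance map
#'
#' Each tree's radius-`region_radius` expansion is labeled with its
#' `tree_id`; interconnected skeletons should share a `tree_id` upstream.
#' Voxels claimed by several trees go to the nearer skeleton point (ties to
#' the lower (tree, node) id), so labels partition the expanded region.
#'
#' @param trees Skeleton tree(s) with `tree_id` attributes.
#' @param shape Volume dim (nz, ny, nx).
#' @param region_radius Expansion radius (default 3).
#' @param strict Strict `<` region inequality (default TRUE).
#' @param resample Resample trees first (default TRUE).
#' @return An integer 3D array; 0 is background.
#' @export
instances_from_skeletons <- function(trees, shape, region_radius = 3,
                                     strict = TRUE, resample = TRUE) {
  sp <- skeleton_points(trees, resample = resample)
  if (nrow(sp$pts) == 0L) return(array(0L, dim = as.integer(shape)))
  lab <- label_nearest(sp$pts, sp$tree, as.integer(shape), region_radius, strict)
  # make labels contiguous from 1 in ascending tree_id order
  u <- sort(unique(lab[lab > 0]))
  if (length(u) > 0 && !identical(u, seq_along(u)))
    lab[] <- match(lab, c(0L, u)) - 1L
  lab
}

#' Aggregated Jaccard Index between two instance maps
#'
#' Greedily pairs each ground-truth instance (ascending id) with the unused
#' predicted instance of largest Jaccard index (ties to the lowest id;
#' instances with zero overlap stay unmatched), then aggregates:
#' `AJI = sum(matched intersections) / (sum(matched unions) +
#' sum(unmatched G sizes) + sum(unmatched P sizes))`.
#'
#' @param G_map Ground-truth instance map (integer 3D array, 0 background).
#' @param P_map Predicted instance map, same shape.
#' @return A list with `aji` and `matched_pairs` (two-column matrix of
#'   (g, p) ids).
#' @export
aji <- function(G_map, P_map) {
  if (!identical(dim(G_map), dim(P_map))) stop("instance map shapes differ")
  g <- as.integer(G_map); p <- as.integer(P_map)
  ng <- max(g, 0L); np <- max(p, 0L)
  gsz <- tabulate(g, nbins = max(ng, 1L))
  psz <- tabulate(p, nbins = max(np, 1L))
  if (ng == 0L && np == 0L)
    return(list(aji = 1, matched_pairs = matrix(integer(0), 0, 2)))
  sel <- g > 0L & p > 0L
  inter <- matrix(0, max(ng, 1L), max(np, 1L))
  if (any(sel)) {
    key <- (g[sel] - 1L) * np + p[sel]
    cnt <- tabulate(key, nbins = ng * np)
    nz <- which(cnt > 0)
    inter[cbind((nz - 1L) %/% np + 1L, (nz - 1L) %% np + 1L)] <- cnt[nz]
  }
  used <- logical(np)
  pairs <- matrix(integer(0), 0, 2)
  num <- 0; den <- 0
  for (i in seq_len(ng)) {
    if (gsz[i] == 0L) next
    cand <- which(inter[i, ] > 0 & !used)
    if (length(cand) == 0L) next
    jac <- inter[i, cand] / (gsz[i] + psz[cand] - inter[i, cand])
    j <- cand[which.max(jac)]  # which.max takes the first (lowest id) on ties
    used[j] <- TRUE
    pairs <- rbind(pairs, c(i, j))
    num <- num + inter[i, j]
    den <- den + gsz[i] + psz[j] - inter[i, j]
  }
  unmatched_g <- setdiff(which(gsz > 0), pairs[, 1])
  unmatched_p <- setdiff(which(psz > 0), which(used))
  den <- den + sum(gsz[unmatched_g]) + sum(psz[unmatched_p])
  list(aji = if (den > 0) num / den else 1, matched_pairs = pairs)
}

#' Evaluate a reconstruction against ground truth
#'
#' Combines skeleton-matching scores with the instance-level AJI computed on
#' radius-`region_radius` expansions of both skeleton sets.
#'
#' @param pred_trees Predicted skeleton tree(s).
#' @param truth_trees Ground-truth skeleton tree(s).
#' @param shape Volume dim (nz, ny, nx) for instance rasterization.
#' @param cfg A [match_config()].
#' @return An `axon_eval` list: `recall`, `precision`, `f1`, `n_g`, `n_p`,
#'   `aji`, `matched_pairs`.
#' @export
evaluate_reconstruction <- function(pred_trees, truth_trees, shape,
                                    cfg = match_config()) {
  sc <- skeleton_scores(pred_trees, truth_trees, cfg)
  gm <- instances_from_skeletons(truth_trees, shape, cfg$region_radius)
  pm <- instances_from_skeletons(pred_trees, shape, cfg$region_radius)
  aj <- aji(gm, pm)
  structure(c(sc, list(aji = aj$aji, matched_pairs = aj$matched_pairs)),
            class = "axon_eval")
}

#' @export
print.axon_eval <- function(x, ...) {
  cat(sprintf("<axon_eval> recall %.4f  precision %.4f  F1 %.4f  AJI %.4f  (N_G %d, N_P %d)\n",
              x$recall, x$precision, x$f1, x$aji, x$n_g, x$n_p))
  invisible(x)
}
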