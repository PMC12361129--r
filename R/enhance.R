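#' Enhance a raw volume with a predicted distance field
#'
#' On the raw intensity scale the prediction is multiplied by the dtype
#' maximum and added to the image, then clipped to the dtype range:
#' `enhanced = clip(raw + dtype_max * pred, 0, dtype_max)`. A zero prediction
#' leaves the volume unchanged. Enhancement raises foreground contrast so
#' that downstream tracers work with fixed parameters.
#'
#' @param vol An [volume()] object.
#' @param pred Prediction array in \[0, 1\] with the shape of `vol`.
#' @return An enhanced [volume()] object.
#' @export
enhance_volume <- function(vol, pred) {
  stopifnot(inherits(vol, "axon_volume"))
  if (!identical(dim(vol$data), dim(pred)))
    stop("volume and prediction shapes differ")
  dmax <- vol$source_dtype_max
  raw <- vol$data * dmax + dmax * pred
  volume(pmin(pmax(raw, 0), dmax) / dmax, source_dtype_max = dmax)
}

#' Extract foreground voxel coordinates from a field
#'
#' @param pred A 3D array (prediction or normalized image).
#' @param threshold Voxels with value strictly above this are foreground.
#' @return An n x 3 matrix of zero-based (x, y, z) voxel coordinates.
#' @export
extract_foreground <- function(pred, threshold = 0.5) {
  if (inherits(pred, "axon_volume")) pred <- pred$data
  stopifnot(threshold > 0, threshold < 1)
  ind <- which(pred > threshold, arr.ind = TRUE)
  cbind(x = ind[, 3] - 1, y = ind[, 2] - 1, z = ind[, 1] - 1)
}

#' Skeletonize a foreground point cloud
#'
#' Default skeletonizer: a Euclidean minimum spanning tree over the points
#' with edges longer than `cutoff` removed, followed by pruning of spur
#' branches shorter than `prune_len` and removal of connected components
#' with fewer than `min_points` points (isolated noise). Any external
#' skeletonizer honoring the SWC contract can be used in its place.
#'
#' @param points n x 3 matrix of (x, y, z) coordinates.
#' @param cutoff Maximum edge length connecting two points (default 2).
#' @param prune_len Spur branches shorter than this are removed (default 4).
#' @param min_points Minimum component size kept (default 5).
#' @return A list of skeleton trees (`swc_forest`); empty input gives an
#'   empty list.
#' @export
skeletonize_points <- function(points, cutoff = 2, prune_len = 4, min_points = 5) {
  if (is.null(points) || nrow(points) == 0L)
    return(structure(list(), class = "swc_forest"))
  n <- nrow(points)
  if (n == 1L)
    return(as_swc_forest(skeleton_tree(points[1, 1], points[1, 2], points[1, 3])))
  ed <- neighbor_edges(points, cutoff)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$orig <- seq_len(n)
  if (length(ed$from) > 0) {
    g <- igraph::add_edges(g, rbind(ed$from, ed$to))
    igraph::E(g)$weight <- ed$w
    g <- igraph::mst(g, weights = igraph::E(g)$weight)
  }
  g <- prune_spurs(g, prune_len)
  comp <- igraph::components(g)
  keep_comp <- which(comp$csize >= max(1L, min_points))
  trees <- list()
  for (ci in seq_along(keep_comp)) {
    vs <- which(comp$membership == keep_comp[ci])
    sub <- igraph::induced_subgraph(g, vs)
    ord <- igraph::bfs(sub, root = 1, father = TRUE)
    vorder <- as.integer(ord$order)
    father <- suppressWarnings(as.integer(ord$father))[vorder]
    rank <- match(seq_along(vs), vorder)
    par <- ifelse(is.na(father), -1L, rank[father])
    orig <- igraph::V(sub)$orig[vorder]
    trees[[ci]] <- skeleton_tree(points[orig, 1], points[orig, 2], points[orig, 3],
                                 parent = par, id = seq_along(orig),
                                 tree_id = ci)
  }
  structure(trees, class = "swc_forest")
}

# Remove leaf branches shorter than prune_len that end at a junction node.
prune_spurs <- function(g, prune_len, rounds = 2) {
  if (prune_len <= 0) return(g)
  for (r in seq_len(rounds)) {
    deg <- igraph::degree(g)
    adj <- igraph::as_adj_list(g)
    leaves <- which(deg == 1)
    drop <- integer(0)
    for (lf in leaves) {
      path <- lf
      prev <- 0L
      cur <- lf
      len <- 0
      repeat {
        nb <- setdiff(as.integer(adj[[cur]]), prev)
        if (length(nb) != 1L) break     # junction reached via prev, or isolated
        nxt <- nb[1]
        len <- len + 1
        if (deg[nxt] >= 3L) {
          if (len < prune_len) drop <- c(drop, path)
          break
        }
        if (deg[nxt] == 1L) break        # bare path component: keep
        prev <- cur
        cur <- nxt
        path <- c(path, nxt)
        if (len > prune_len) break
      }
    }
    if (length(drop) == 0L) break
    keep <- setdiff(seq_len(igraph::vcount(g)), unique(drop))
    g <- igraph::induced_subgraph(g, keep)
  }
  g
}
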