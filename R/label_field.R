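#' Configuration for distance-field label generation
#'
#' @param max_spacing Maximum distance between adjacent skeleton points after
#'   resampling, in voxels.
#' @param expand_radius Radius of the spherical expansion around each
#'   skeleton point, in voxels. The expanded region is the union of open
#'   balls: a voxel belongs iff its distance to the nearest skeleton point is
#'   strictly below this radius (see `strict_less`).
#' @param sigma Decay parameter of the field `exp(-d / (2 sigma^2))`; with
#'   the default `sigma = 2` the field is about 0.47 at the region boundary
#'   d = 3.
#' @param strict_less Use the strict inequality `< expand_radius` (default)
#'   rather than `<=`.
#' @param squared_exponent Use `exp(-d^2 / (2 sigma^2))` (a conventional
#'   Gaussian) instead of the default first-power decay.
#' @return A list of class `label_config`.
#' @export
label_config <- function(max_spacing = 1, expand_radius = 3, sigma = 2,
                         strict_less = TRUE, squared_exponent = FALSE) {
  stopifnot(max_spacing > 0, expand_radius > 0, sigma > 0)
  structure(list(max_spacing = max_spacing, expand_radius = expand_radius,
                 sigma = sigma, strict_less = strict_less,
                 squared_exponent = squared_exponent),
            class = "label_config")
}

#' Resample a skeleton to a maximum node spacing
#'
#' Inserts linearly interpolated, evenly spaced nodes on every parent-child
#' edge longer than `max_spacing`, so that all edge lengths are at most
#' `max_spacing`. Original nodes are retained at their exact positions.
#'
#' @param tree A skeleton tree `data.frame`.
#' @param max_spacing Maximum allowed edge length in voxels (default 1).
#' @return A skeleton tree with consecutive ids and the same `tree_id`.
#' @export
resample_skeleton <- function(tree, max_spacing = 1) {
  stopifnot(max_spacing > 0)
  n <- nrow(tree)
  if (n == 0L) return(tree)
  ord <- swc_topo_order(tree)
  tree <- tree[ord, , drop = FALSE]
  pos <- as.matrix(tree[, c("x", "y", "z")])
  newid <- integer(n)  # old row -> new id
  out_x <- numeric(0); out_y <- numeric(0); out_z <- numeric(0)
  out_t <- integer(0); out_r <- numeric(0); out_p <- integer(0)
  nid <- 0L
  parent_row <- match(tree$parent, tree$id)
  for (i in seq_len(n)) {
    pr <- parent_row[i]
    if (is.na(pr)) {
      nid <- nid + 1L
      newid[i] <- nid
      out_x <- c(out_x, pos[i, 1]); out_y <- c(out_y, pos[i, 2])
      out_z <- c(out_z, pos[i, 3])
      out_t <- c(out_t, tree$type[i]); out_r <- c(out_r, tree$radius[i])
      out_p <- c(out_p, -1L)
      next
    }
    a <- pos[pr, ]; b <- pos[i, ]
    len <- sqrt(sum((b - a)^2))
    nseg <- max(1L, ceiling(len / max_spacing - 1e-12))
    prev <- newid[pr]
    if (nseg > 1L) {
      tfrac <- seq_len(nseg - 1L) / nseg
      for (tt in tfrac) {
        nid <- nid + 1L
        q <- a + tt * (b - a)
        out_x <- c(out_x, q[1]); out_y <- c(out_y, q[2]); out_z <- c(out_z, q[3])
        out_t <- c(out_t, tree$type[i])
        out_r <- c(out_r, tree$radius[pr] + tt * (tree$radius[i] - tree$radius[pr]))
        out_p <- c(out_p, prev)
        prev <- nid
      }
    }
    nid <- nid + 1L
    newid[i] <- nid
    out_x <- c(out_x, pos[i, 1]); out_y <- c(out_y, pos[i, 2]); out_z <- c(out_z, pos[i, 3])
    out_t <- c(out_t, tree$type[i]); out_r <- c(out_r, tree$radius[i])
    out_p <- c(out_p, prev)
  }
  res <- data.frame(id = seq_len(nid), type = out_t, x = out_x, y = out_y,
                    z = out_z, radius = out_r, parent = out_p)
  attr(res, "tree_id") <- attr(tree, "tree_id")
  res
}

# Order nodes parents-first (SWC files usually already are; enforce anyway).
swc_topo_order <- function(tree) {
  n <- nrow(tree)
  parent_row <- match(tree$parent, tree$id)
  done <- logical(n)
  ord <- integer(0)
  queue <- which(is.na(parent_row) | tree$parent == -1L)
  done[queue] <- TRUE
  ord <- queue
  while (length(ord) < n) {
    nxt <- which(!done & (is.na(parent_row) | done[parent_row]))
    if (length(nxt) == 0L) stop("skeleton has a parent cycle or orphan nodes")
    done[nxt] <- TRUE
    ord <- c(ord, nxt)
  }
  ord
}

#' Expand skeletons into a spherical region mask
#'
#' A voxel v belongs to the mask iff `min_i ||v - s_i|| < radius` over all
#' skeleton points of all trees (strict inequality; set `strict = FALSE` for
#' `<=`).
#'
#' @param trees Skeleton tree(s); should be resampled to <= 1 voxel spacing.
#' @param shape Volume dim (nz, ny, nx).
#' @param radius Expansion radius in voxels (default 3).
#' @param strict Use strict inequality (default TRUE).
#' @param resample Resample trees before expansion (default TRUE).
#' @return A logical 3D array of the given shape.
#' @export
expand_region <- function(trees, shape, radius = 3, strict = TRUE,
                          resample = TRUE) {
  stopifnot(radius > 0, length(shape) == 3L)
  sp <- skeleton_points(trees, resample = resample)
  if (nrow(sp$pts) == 0L)
    return(array(FALSE, dim = as.integer(shape)))
  nf <- nearest_field(sp$pts, as.integer(shape), radius, strict)
  mask <- is.finite(nf$dist2)
  dim(mask) <- as.integer(shape)
  mask
}

#' Perpendicular distance from a point to the local centerline
#'
#' Finds the skeleton point s(p) nearest to `p` (ties go to the lowest node
#' id) and returns the norm of the component of `p - s(p)` perpendicular to
#' the local centerline direction, i.e.
#' `||p - s(p)|| * sin(acos(<unit(p - s(p)), unit(succ - s(p))>))`.
#' The direction points toward the successor of s(p) along the skeleton; at
#' branch nodes the lowest-id child is used, at branch tips the incoming
#' (predecessor) direction is reused. A single-node skeleton falls back to
#' the Euclidean distance, and `p` coinciding with a skeleton point gives 0.
#'
#' @param p Numeric 3-vector (x, y, z).
#' @param tree A nonempty skeleton tree (resampled for faithful fields).
#' @return Distance in voxels.
#' @export
perpendicular_distance <- function(p, tree) {
  if (is.null(tree) || nrow(tree) == 0L) stop("empty skeleton tree")
  pos <- as.matrix(tree[, c("x", "y", "z")])
  d2 <- colSums((t(pos) - as.numeric(p))^2)
  i <- which.min(d2)  # first minimum = lowest node order
  w <- as.numeric(p) - pos[i, ]
  if (all(w == 0)) return(0)
  u <- successor_directions(tree)[i, ]
  if (anyNA(u)) return(sqrt(sum(w^2)))
  proj <- sum(w * u)
  sqrt(max(0, sum(w^2) - proj^2))
}

# Unit direction from each node toward its successor: first (lowest-id) child,
# or the incoming predecessor direction at branch tips; NaN for isolated nodes.
successor_directions <- function(tree) {
  n <- nrow(tree)
  pos <- as.matrix(tree[, c("x", "y", "z")])
  dirs <- matrix(NaN, n, 3)
  parent_row <- match(tree$parent, tree$id)
  child_row <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    pr <- parent_row[i]
    if (!is.na(pr) && is.na(child_row[pr])) child_row[pr] <- i
  }
  for (i in seq_len(n)) {
    j <- child_row[i]
    if (!is.na(j)) {
      v <- pos[j, ] - pos[i, ]
    } else if (!is.na(parent_row[i])) {
      v <- pos[i, ] - pos[parent_row[i], ]
    } else {
      next
    }
    len <- sqrt(sum(v^2))
    if (len > 0) dirs[i, ] <- v / len
  }
  dirs
}

#' Generate a distance-field supervision label from skeletons
#'
#' Inside the expanded region, each voxel takes
#' `exp(-dist(p, s) / (2 sigma^2))` where `dist` is the perpendicular
#' distance to the centerline of the tree owning the voxel's nearest
#' skeleton point; the field is 1 exactly on the centerline, strictly
#' decreases away from it, and is 0 outside the expanded region. Fields of
#' overlapping trees combine by voxel-wise maximum.
#'
#' @param trees Skeleton tree(s).
#' @param shape Volume dim (nz, ny, nx).
#' @param config A [label_config()].
#' @param resample Resample trees to `config$max_spacing` first (default
#'   TRUE; the field assumes resampled skeletons).
#' @return A numeric 3D array in \[0, 1\] of the given shape.
#' @export
make_distance_field <- function(trees, shape, config = label_config(),
                                resample = TRUE) {
  stopifnot(inherits(config, "label_config"), length(shape) == 3L)
  trees <- as_swc_forest(trees)
  if (resample)
    trees <- as_swc_forest(lapply(trees, resample_skeleton, config$max_spacing))
  sp <- skeleton_points(trees, resample = FALSE)
  if (nrow(sp$pts) == 0L) return(array(0, dim = as.integer(shape)))
  dirs <- do.call(rbind, lapply(trees[order(vapply(trees, function(t)
    as.integer(attr(t, "tree_id")), 1L))], successor_directions))
  decay_field(sp$pts, dirs, sp$tree, as.integer(shape),
              config$expand_radius, config$sigma,
              config$strict_less, config$squared_exponent)
}
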