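#' Configuration for the synthetic axon phantom generator
#'
#' The generator emulates the documented diversity of the fMOST axon blocks:
#' curvilinear tubes at sparse-to-dense counts, per-volume SNR spanning
#' roughly 2.5-15, within-axon intensity fluctuation including very weak
#' segments, and round/strip-shaped interfering structures that carry no
#' ground-truth skeleton.
#'
#' @param shape Volume edge lengths (x, y, z), default 192^3.
#' @param n_axons Range (min, max) of axon counts; sparse blocks use 1-4,
#'   dense ones 10-25.
#' @param tube_radius Range of tube radii in voxels.
#' @param axon_intensity Range of strong segment intensities on the raw
#'   8-bit scale.
#' @param weak_intensity Range of weak segment intensities (raw scale).
#' @param weak_segment_fraction Probability that a skeleton segment is
#'   rendered at weak intensity.
#' @param background_mean,background_std Gaussian background noise (raw
#'   scale).
#' @param snr_target Optional per-volume SNR; when set, tube intensities are
#'   rescaled so the contrast-to-noise ratio over the radius-3 expanded
#'   region matches it.
#' @param branch_prob Probability that an axon carries one side branch.
#' @param n_blob_distractors,n_strip_distractors Counts of round and
#'   strip-shaped interfering structures.
#' @param seed Integer seed; the volume and its skeletons are bit-identical
#'   across runs with the same config.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(shape = c(192, 192, 192), n_axons = c(1, 4),
                         tube_radius = c(1, 2), axon_intensity = c(100, 255),
                         weak_intensity = c(8, 30), weak_segment_fraction = 0.25,
                         background_mean = 12, background_std = 4,
                         snr_target = NULL, branch_prob = 0.2,
                         n_blob_distractors = 2, n_strip_distractors = 2,
                         seed = 1) {
  stopifnot(all(shape >= 16), all(tube_radius > 0), background_std >= 0,
            weak_segment_fraction >= 0, weak_segment_fraction <= 1)
  if (!is.null(snr_target) && snr_target <= 0) stop("snr_target must be positive")
  structure(list(shape = as.integer(shape), n_axons = n_axons,
                 tube_radius = tube_radius, axon_intensity = axon_intensity,
                 weak_intensity = weak_intensity,
                 weak_segment_fraction = weak_segment_fraction,
                 background_mean = background_mean,
                 background_std = background_std, snr_target = snr_target,
                 branch_prob = branch_prob,
                 n_blob_distractors = n_blob_distractors,
                 n_strip_distractors = n_strip_distractors,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Persistent random walk with bounded curvature; returns node positions
# spaced `step` apart, stopping at the volume boundary or max_len.
random_path <- function(shape, step = 0.75, wiggle = 0.12, max_len = 600,
                        start = NULL, dir = NULL) {
  lim <- shape - 1
  pos <- start %||% runif(3, 0.1 * lim, 0.9 * lim)
  d <- dir %||% rnorm(3)
  d <- d / sqrt(sum(d^2))
  path <- matrix(pos, 1, 3)
  for (i in seq_len(max_len)) {
    d <- d + rnorm(3, sd = wiggle)
    d <- d / sqrt(sum(d^2))
    pos <- pos + step * d
    if (any(pos < 0) || any(pos > lim)) break
    path <- rbind(path, pos)
  }
  path
}

#' Generate a synthetic axon volume with ground-truth skeletons
#'
#' Renders smooth random-walk paths as tubes with a Gaussian radial profile
#' (max-combined so intensity does not accumulate), draws per-segment
#' intensities with a weak-segment mechanism, injects blob and strip
#' distractors, and adds Gaussian background noise before rounding to the
#' 8-bit grid. Strip distractors reuse the tube renderer but carry no
#' ground-truth skeleton, providing realistic false-positive bait.
#'
#' @param cfg A [synth_config()].
#' @return A list with `vol` (an [volume()]), `trees` (ground-truth
#'   `swc_forest` with <= 1-voxel node spacing) and `meta` (per-axon segment
#'   intensities).
#' @export
generate_volume <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  shape <- cfg$shape                       # (nx, ny, nz) in SWC order
  dims <- rev(shape)                       # array dim (nz, ny, nx)
  nax <- if (cfg$n_axons[1] >= cfg$n_axons[2]) cfg$n_axons[1] else
    sample(cfg$n_axons[1]:cfg$n_axons[2], 1)
  trees <- list()
  allpts <- matrix(numeric(0), 0, 3)
  allint <- numeric(0)
  allrad <- numeric(0)
  meta <- list()
  seg_len <- 25L                           # skeleton points per intensity segment
  for (a in seq_len(nax)) {
    path <- random_path(shape)
    if (nrow(path) < 5) path <- random_path(shape, max_len = 300)
    r <- runif(1, cfg$tube_radius[1], cfg$tube_radius[2])
    nseg <- ceiling(nrow(path) / seg_len)
    weak <- runif(nseg) < cfg$weak_segment_fraction
    segint <- ifelse(weak,
                     runif(nseg, cfg$weak_intensity[1], cfg$weak_intensity[2]),
                     runif(nseg, cfg$axon_intensity[1], cfg$axon_intensity[2]))
    ptint <- segint[pmin(nseg, 1L + (seq_len(nrow(path)) - 1L) %/% seg_len)]
    tr <- skeleton_tree(path[, 1], path[, 2], path[, 3], tree_id = a)
    if (runif(1) < cfg$branch_prob && nrow(path) > 20) {
      at <- sample(5:(nrow(path) - 5), 1)
      bp <- random_path(shape, max_len = nrow(path) %/% 2,
                        start = path[at, ], dir = rnorm(3))
      if (nrow(bp) > 3) {
        bp <- bp[-1, , drop = FALSE]
        bint <- rep(segint[pmin(nseg, 1L + (at - 1L) %/% seg_len)], nrow(bp))
        ids <- nrow(path) + seq_len(nrow(bp))
        br <- data.frame(id = ids, type = 2L, x = bp[, 1], y = bp[, 2],
                         z = bp[, 3], radius = r,
                         parent = c(at, head(ids, -1L)))
        tr <- rbind(tr, br)
        attr(tr, "tree_id") <- a
        path <- rbind(path, bp)
        ptint <- c(ptint, bint)
      }
    }
    tr$radius <- r
    trees[[a]] <- tr
    allpts <- rbind(allpts, path)
    allint <- c(allint, ptint)
    allrad <- c(allrad, rep(r, nrow(path)))
    meta[[a]] <- list(radius = r, segment_intensity = segint, weak = weak)
  }
  # distractors: spherical blobs and short strip-shaped tubes, no skeleton
  if (cfg$n_blob_distractors > 0) {
    for (b in seq_len(cfg$n_blob_distractors)) {
      allpts <- rbind(allpts, runif(3, 0, shape - 1))
      allint <- c(allint, runif(1, cfg$axon_intensity[1], cfg$axon_intensity[2]))
      allrad <- c(allrad, runif(1, 2, 4))
    }
  }
  if (cfg$n_strip_distractors > 0) {
    for (s in seq_len(cfg$n_strip_distractors)) {
      sp <- random_path(shape, wiggle = 0.03, max_len = sample(15:40, 1))
      allpts <- rbind(allpts, sp)
      allint <- c(allint, rep(runif(1, cfg$axon_intensity[1], cfg$axon_intensity[2]), nrow(sp)))
      allrad <- c(allrad, rep(runif(1, cfg$tube_radius[1], cfg$tube_radius[2]), nrow(sp)))
    }
  }
  trees <- as_swc_forest(trees)
  # Weak segments stay at their absolute near-noise intensity: labeling
  # deficits make parts of an axon dim regardless of how bright the rest of
  # the block is, so SNR calibration rescales only the strong structures.
  weakpt <- allint <= cfg$weak_intensity[2]
  # configured intensities are raw center-voxel values (background included),
  # so tubes are rendered with the amplitude above the background mean
  allamp <- pmax(allint - cfg$background_mean, 0.5)
  zero <- array(0, dim = dims)
  sigA <- if (any(!weakpt))
    render_tubes(zero, dims, allpts[!weakpt, , drop = FALSE],
                 allamp[!weakpt], allrad[!weakpt]) else zero
  sigB <- if (any(weakpt))
    render_tubes(zero, dims, allpts[weakpt, , drop = FALSE],
                 allamp[weakpt], allrad[weakpt]) else zero
  s <- 1
  if (!is.null(cfg$snr_target) && length(trees) > 0) {
    mask <- expand_region(trees, dims, radius = 3)
    if (mean(pmax(sigA, sigB)[mask]) <= 0 || cfg$background_std <= 0)
      stop("snr_target infeasible: no signal or zero background noise")
    target <- cfg$snr_target * cfg$background_std
    cap <- 255 - cfg$background_mean    # headroom before 8-bit saturation
    for (it in 1:8) {                   # fixed point accounting for clipping
      ms <- mean(pmin(pmax(sigA[mask] * s, sigB[mask]), cap))
      if (ms <= 0) break
      s <- s * target / ms
    }
  }
  signal <- pmax(sigA * s, sigB)
  raw <- signal + rnorm(prod(dims), cfg$background_mean, cfg$background_std)
  raw <- pmin(pmax(round(raw), 0), 255)
  dim(raw) <- dims
  list(vol = volume(raw / 255, source_dtype_max = 255), trees = trees,
       meta = meta)
}

#' Characterize a volume with per-sub-block statistics
#'
#' Partitions the volume into sub-blocks (64^3 by default) and computes per
#' block: SNR as the contrast-to-noise ratio
#' `(mean signal - location background) / scale background` with signal
#' voxels defined by the radius-3 expanded region of the skeletons and
#' background location/scale estimated robustly (median and MAD) so bright
#' non-axonal structures do not inflate the noise estimate; axon density as
#' skeleton points per sub-block voxel; and mean intensity at skeleton
#' points. Blocks without background voxels are excluded with a warning.
#'
#' @param vol An [volume()].
#' @param trees Ground-truth skeleton tree(s) (may be empty).
#' @param block Sub-block edge length (default 64, clipped to the volume).
#' @param region_radius Radius defining signal voxels (default 3).
#' @return A list with `blocks` (one row per sub-block) and `summary`
#'   (across-block means and standard deviations).
#' @export
characterize_volume <- function(vol, trees = list(), block = 64,
                                region_radius = 3) {
  stopifnot(inherits(vol, "axon_volume"))
  dims <- dim(vol$data)
  raw <- vol$data * vol$source_dtype_max
  sp <- skeleton_points(trees)
  has_skel <- nrow(sp$pts) > 0
  mask <- if (has_skel) expand_region(trees, dims, radius = region_radius)
          else array(FALSE, dims)
  bs <- pmin(as.integer(block), dims)
  starts <- lapply(1:3, function(ax) seq(1L, dims[ax], by = bs[ax]))
  rows <- list()
  for (sz in starts[[1]]) for (sy in starts[[2]]) for (sx in starts[[3]]) {
    ez <- min(sz + bs[1] - 1L, dims[1]); ey <- min(sy + bs[2] - 1L, dims[2])
    ex <- min(sx + bs[3] - 1L, dims[3])
    sub <- raw[sz:ez, sy:ey, sx:ex]
    subm <- mask[sz:ez, sy:ey, sx:ex]
    nb <- sum(!subm)
    snr <- NA_real_
    if (nb == 0L) {
      warning("sub-block without background voxels: SNR undefined")
    } else if (any(subm)) {
      bg <- sub[!subm]
      bgsd <- mad(bg)
      if (bgsd == 0) bgsd <- sd(bg)
      snr <- if (bgsd > 0) (mean(sub[subm]) - median(bg)) / bgsd else NA_real_
    }
    inblk <- if (has_skel)
      sp$pts[, 3] >= (sz - 1) & sp$pts[, 3] <= (ez - 1) &
      sp$pts[, 2] >= (sy - 1) & sp$pts[, 2] <= (ey - 1) &
      sp$pts[, 1] >= (sx - 1) & sp$pts[, 1] <= (ex - 1)
    else logical(0)
    dens <- sum(inblk) / length(sub)
    inten <- if (any(inblk)) {
      pts <- sp$pts[inblk, , drop = FALSE]
      mean(raw[cbind(round(pts[, 3]) + 1L, round(pts[, 2]) + 1L,
                     round(pts[, 1]) + 1L)])
    } else NA_real_
    rows[[length(rows) + 1L]] <-
      data.frame(z0 = sz - 1L, y0 = sy - 1L, x0 = sx - 1L, snr = snr,
                 density = dens, mean_intensity = inten)
  }
  blocks <- do.call(rbind, rows)
  summ <- list(
    snr_mean = mean(blocks$snr, na.rm = TRUE),
    snr_sd = sd(blocks$snr, na.rm = TRUE),
    density_mean = mean(blocks$density),
    density_sd = sd(blocks$density),
    intensity_mean = mean(blocks$mean_intensity, na.rm = TRUE),
    intensity_sd = sd(blocks$mean_intensity, na.rm = TRUE)
  )
  list(blocks = blocks, summary = summ)
}

#' Select representative volumes by K-means on grayscale histograms
#'
#' Computes a normalized 256-bin grayscale histogram per volume, clusters the
#' histograms with K-means, and returns one volume per cluster (the one
#' closest to its centroid).
#'
#' @param volumes A list of [volume()] objects (or 3D arrays in \[0, 1\]).
#' @param k Number of clusters; must not exceed the number of volumes.
#' @param seed Seed for the K-means initialization.
#' @return Sorted integer indices of the selected volumes, length `k`.
#' @export
select_blocks_kmeans <- function(volumes, k, seed = 1) {
  n <- length(volumes)
  if (k > n) stop("k must not exceed the number of volumes")
  if (k == n) return(seq_len(n))
  feats <- t(vapply(volumes, function(v) {
    a <- if (inherits(v, "axon_volume")) v$data else v
    tabulate(pmin(floor(a * 256), 255) + 1L, nbins = 256L) / length(a)
  }, numeric(256)))
  set.seed(seed)
  km <- kmeans(feats, centers = k, nstart = 5, iter.max = 100)
  sel <- vapply(seq_len(k), function(ci) {
    members <- which(km$cluster == ci)
    d2 <- rowSums((feats[members, , drop = FALSE] -
                     matrix(km$centers[ci, ], length(members), 256,
                            byrow = TRUE))^2)
    members[which.min(d2)]
  }, 1L)
  sort(sel)
}
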