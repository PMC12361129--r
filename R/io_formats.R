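#' Read an SWC skeleton file
#'
#' Parses the standard 7-column SWC dialect (`id type x y z radius parent`,
#' whitespace-delimited, `#` comments) and splits the node table into its
#' root-connected components, one skeleton tree per component.
#'
#' @param path Path to an SWC file.
#' @return A list of skeleton trees. Each tree is a `data.frame` with columns
#'   `id`, `type`, `x`, `y`, `z`, `radius`, `parent` (parent of the root is
#'   -1) and an integer `tree_id` attribute, unique within the file.
#'   Coordinates are taken verbatim and interpreted as zero-based voxel
#'   units. Node order within a tree follows file order.
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("SWC file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(structure(list(), class = "swc_forest"))
  toks <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(toks, length, 1L) < 7L)
  if (length(bad))
    stop("malformed SWC line ", lineno[bad[1]], ": expected 7 columns")
  m <- suppressWarnings(vapply(toks, function(t) as.numeric(t[1:7]), numeric(7)))
  if (anyNA(m))
    stop("malformed SWC line ", lineno[which(colSums(is.na(m)) > 0)[1]],
         ": non-numeric field")
  nodes <- data.frame(
    id = as.integer(m[1, ]), type = as.integer(m[2, ]),
    x = m[3, ], y = m[4, ], z = m[5, ],
    radius = m[6, ], parent = as.integer(m[7, ])
  )
  if (anyDuplicated(nodes$id)) stop("duplicate node id in SWC file")
  if (!all(is.finite(as.matrix(nodes[, c("x", "y", "z")]))))
    stop("non-finite coordinate in SWC file")
  miss <- nodes$parent != -1L & !(nodes$parent %in% nodes$id)
  if (any(miss))
    stop("SWC parent reference to missing id ", nodes$parent[which(miss)[1]])
  split_swc_components(nodes)
}

# Partition a node table into root-connected components via union-find on
# parent links, preserving node order.
split_swc_components <- function(nodes) {
  n <- nrow(nodes)
  pos <- match(nodes$parent, nodes$id)  # NA for roots
  comp <- seq_len(n)
  find <- function(i) {
    while (comp[i] != i) {
      comp[i] <<- comp[comp[i]]
      i <- comp[i]
    }
    i
  }
  for (i in seq_len(n)) {
    if (!is.na(pos[i])) {
      a <- find(i); b <- find(pos[i])
      if (a != b) comp[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  uniq <- unique(roots)
  out <- lapply(seq_along(uniq), function(k) {
    tr <- nodes[roots == uniq[k], , drop = FALSE]
    rownames(tr) <- NULL
    attr(tr, "tree_id") <- k
    tr
  })
  structure(out, class = "swc_forest")
}

#' Write skeleton trees to an SWC file
#'
#' Nodes are renumbered consecutively across the file; each tree's root keeps
#' parent -1. Coordinates are written with 4 decimal places.
#'
#' @param trees A list of skeleton trees as returned by [read_swc()] (a bare
#'   `data.frame` is treated as a single tree).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(trees, path) {
  trees <- as_swc_forest(trees)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# id type x y z radius parent", con)
  offset <- 0L
  for (tr in trees) {
    n <- nrow(tr)
    if (n == 0L) next
    newid <- seq_len(n) + offset
    newpar <- ifelse(tr$parent == -1L, -1L,
                     newid[match(tr$parent, tr$id)])
    writeLines(sprintf("%d %d %.4f %.4f %.4f %.4f %d",
                       newid, tr$type, tr$x, tr$y, tr$z, tr$radius, newpar), con)
    offset <- offset + n
  }
  invisible(path)
}

#' @keywords internal
as_swc_forest <- function(trees) {
  if (is.data.frame(trees)) trees <- list(trees)
  for (k in seq_along(trees)) {
    if (is.null(attr(trees[[k]], "tree_id"))) attr(trees[[k]], "tree_id") <- k
  }
  structure(trees, class = "swc_forest")
}

#' Construct a skeleton tree from node fields
#'
#' @param x,y,z Numeric coordinate vectors (zero-based voxel units).
#' @param parent Integer parent ids (-1 for roots). Defaults to a simple
#'   chain.
#' @param id Node ids; defaults to `1:n`.
#' @param type,radius SWC type and radius columns (informational).
#' @param tree_id Integer instance identifier.
#' @return A skeleton tree `data.frame`.
#' @export
skeleton_tree <- function(x, y, z, parent = NULL, id = seq_along(x),
                          type = 2L, radius = 1, tree_id = 1L) {
  n <- length(x)
  if (is.null(parent)) parent <- c(-1L, head(id, -1L))
  tr <- data.frame(id = as.integer(id), type = as.integer(rep_len(type, n)),
                   x = x, y = y, z = z, radius = rep_len(radius, n),
                   parent = as.integer(parent))
  attr(tr, "tree_id") <- as.integer(tree_id)
  tr
}

#' Create a volume object
#'
#' @param data 3D numeric array with dim (nz, ny, nx), values in \[0, 1\].
#' @param source_dtype_max Raw-scale maximum of the source data (255 for
#'   8-bit, 65535 for 16-bit).
#' @return An object of class `axon_volume`.
#' @export
volume <- function(data, source_dtype_max = 255) {
  stopifnot(length(dim(data)) == 3L, all(dim(data) >= 1L))
  rng <- range(data)
  if (rng[1] < 0 || rng[2] > 1) stop("volume intensities must lie in [0, 1]")
  structure(list(data = data, source_dtype_max = source_dtype_max),
            class = "axon_volume")
}

#' @export
print.axon_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<axon_volume> %d x %d x %d (nz x ny x nx), dtype max %d, range [%.4f, %.4f]\n",
              d[1], d[2], d[3], as.integer(x$source_dtype_max),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Read a TIFF stack as a normalized volume
#'
#' Pages are z planes of y-by-x pixels. Intensities are divided by the source
#' dtype maximum (255 or 65535) so all downstream code works on a \[0, 1\]
#' scale referenced to 8-bit thresholds (for example 3/255 and 103/255).
#'
#' @param path Path to a multi-page TIFF of unsigned 8- or 16-bit integers.
#' @return An [volume()] object with dim (nz, ny, nx).
#' @export
read_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  info <- tiff::readTIFF(path, payload = FALSE)
  bits <- if (is.data.frame(info)) info$bits.per.sample[1] else 8L
  if (!bits %in% c(8L, 16L)) stop("unsupported TIFF bit depth: ", bits)
  dmax <- if (bits == 16L) 65535 else 255
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]]); nz <- length(pages)
  arr <- array(0, dim = c(nz, ny, nx))
  for (z in seq_len(nz)) arr[z, , ] <- pages[[z]]
  volume(arr / dmax, source_dtype_max = dmax)
}

#' Write a volume as a TIFF stack
#'
#' Values are multiplied by the source dtype maximum, rounded, clipped to the
#' dtype range and written as one page per z plane, so
#' `read_volume(write_volume(v))` recovers integer data bit-for-bit.
#'
#' @param vol An [volume()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "axon_volume"))
  dmax <- vol$source_dtype_max
  bits <- if (dmax > 255) 16L else 8L
  raw <- pmin(pmax(round(vol$data * dmax), 0), dmax)
  pages <- lapply(seq_len(dim(raw)[1]), function(z) raw[z, , ] / dmax)
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' Collect skeleton-point coordinates from trees
#'
#' @param trees A skeleton tree or list of trees.
#' @param resample Resample each tree to `max_spacing` before collecting
#'   (default TRUE, matching the label-generation convention).
#' @param max_spacing Spacing used when `resample` is TRUE.
#' @return A list with `pts` (n x 3 matrix of (x, y, z)), `tree` (integer
#'   tree id per row) and `node` (node id per row); rows ordered by
#'   (tree_id, node order).
#' @export
skeleton_points <- function(trees, resample = TRUE, max_spacing = 1) {
  trees <- as_swc_forest(trees)
  ids <- vapply(trees, function(t) as.integer(attr(t, "tree_id")), 1L)
  trees <- trees[order(ids)]
  pts <- matrix(numeric(0), 0, 3)
  tree <- integer(0); node <- integer(0)
  for (tr in trees) {
    if (resample) tr2 <- resample_skeleton(tr, max_spacing) else tr2 <- tr
    if (nrow(tr2) == 0L) next
    pts <- rbind(pts, as.matrix(tr2[, c("x", "y", "z")]))
    tree <- c(tree, rep(as.integer(attr(tr, "tree_id")), nrow(tr2)))
    node <- c(node, tr2$id)
  }
  dimnames(pts) <- NULL
  list(pts = pts, tree = tree, node = node)
}
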