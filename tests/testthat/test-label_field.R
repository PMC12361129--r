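test_that("resampling enforces spacing, keeps original nodes, interpolates evenly", {
  tr <- skeleton_tree(c(0, 5), c(0, 0), c(0, 0))
  r <- resample_skeleton(tr, 1)
  expect_equal(nrow(r), 6)                       # ceil(5/1) - 1 = 4 insertions
  gaps <- sqrt(diff(r$x)^2 + diff(r$y)^2 + diff(r$z)^2)
  expect_equal(gaps, rep(1, 5))
  expect_true(all(c(0, 5) %in% r$x))             # originals untouched

  # already fine spacing: unchanged geometry
  tr <- skeleton_tree(seq(0, 2, by = 0.5), rep(0, 5), rep(0, 5))
  r <- resample_skeleton(tr, 1)
  expect_equal(r$x, tr$x)
  # boundary case: exactly max_spacing stays unchanged
  tr <- skeleton_tree(c(0, 1), c(0, 0), c(0, 0))
  expect_equal(nrow(resample_skeleton(tr, 1)), 2)
  # empty tree passes through
  empty <- skeleton_tree(numeric(0), numeric(0), numeric(0),
                         parent = integer(0), id = integer(0))
  expect_equal(nrow(resample_skeleton(empty, 1)), 0)
})

test_that("resampling properties hold on random trees", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(3:12, 1)
    tr <- skeleton_tree(cumsum(runif(n, 0, 3)), cumsum(runif(n, -2, 2)),
                        cumsum(runif(n, -2, 2)))
    ms <- runif(1, 0.4, 1.5)
    r <- resample_skeleton(tr, ms)
    pos <- as.matrix(r[, c("x", "y", "z")])
    par <- match(r$parent, r$id)
    edges <- which(!is.na(par))
    lens <- sqrt(rowSums((pos[edges, , drop = FALSE] -
                            pos[par[edges], , drop = FALSE])^2))
    expect_true(all(lens <= ms + 1e-9))
    orig <- as.matrix(tr[, c("x", "y", "z")])
    for (i in seq_len(nrow(orig)))
      expect_true(min(colSums((t(pos) - orig[i, ])^2)) < 1e-18)
  }
})

test_that("expand_region matches brute-force lattice enumeration", {
  tr <- skeleton_tree(10, 10, 10)
  m <- expand_region(tr, c(21, 21, 21), radius = 3)
  expect_equal(sum(m), 93)                       # lattice points with d^2 <= 8
  expect_identical(m, bf_expand(matrix(c(10, 10, 10), 1), c(21, 21, 21), 3))

  set.seed(31)
  for (rep in 1:5) {
    shape <- c(14, 17, 12)
    pts <- cbind(runif(4, 0, 11), runif(4, 0, 16), runif(4, 0, 13))
    tr <- skeleton_tree(pts[, 1], pts[, 2], pts[, 3])
    m <- expand_region(tr, shape, radius = 2.5, resample = FALSE)
    expect_identical(m, bf_expand(pts, shape, 2.5))
  }

  # empty skeletons and corner clipping
  expect_equal(sum(expand_region(list(), c(8, 8, 8))), 0)
  corner <- expand_region(skeleton_tree(0, 0, 0), c(8, 8, 8), radius = 3)
  expect_identical(corner, bf_expand(matrix(0, 1, 3), c(8, 8, 8), 3))
  expect_lt(sum(corner), 93)
})

test_that("perpendicular distance follows the point-to-line oracle", {
  tr <- skeleton_tree(0:5, rep(0, 6), rep(0, 6))
  expect_equal(perpendicular_distance(c(2, 1.5, 0), tr), 1.5)
  expect_equal(perpendicular_distance(c(2.3, 0, 0), tr), 0)
  expect_equal(perpendicular_distance(c(3, 0, 0), tr), 0)   # on a node
  # single-node fallback is Euclidean
  expect_equal(perpendicular_distance(c(0, 0, 2), skeleton_tree(5, 0, 0)),
               sqrt(25 + 4))
  expect_error(perpendicular_distance(c(0, 0, 0), NULL), "empty")

  # random offsets from a straight line: oracle is distance to the axis
  set.seed(41)
  for (rep in 1:20) {
    p <- c(runif(1, 0.5, 4.5), runif(1, -2, 2), runif(1, -2, 2))
    expect_equal(perpendicular_distance(p, tr), sqrt(p[2]^2 + p[3]^2),
                 tolerance = 1e-12)
  }
})

test_that("distance field matches the analytic form on a straight skeleton", {
  tr <- skeleton_tree(0:20, rep(10, 21), rep(10, 21))
  cfg <- label_config(sigma = 2)
  f <- make_distance_field(tr, c(21, 21, 21), cfg)
  for (x in 5:15) for (y in 7:13) for (z in 7:13) {
    d <- sqrt((y - 10)^2 + (z - 10)^2)
    expected <- if (d < 3) exp(-d / 8) else 0
    expect_equal(f[z + 1, y + 1, x + 1], expected, tolerance = 1e-6)
  }
  # centerline voxels are exactly 1, region boundary is zeroed
  expect_equal(f[11, 11, 11], 1)
  expect_equal(max(f), 1)
  expect_equal(f[11 + 4, 11, 11], 0)
})

test_that("field values and configuration switches behave as specified", {
  # sigma = 2, perpendicular distance 1.5 -> exp(-1.5/8) ~ 0.8290
  # (line at y = 4.5 puts voxels with y = 6 at distance exactly 1.5)
  tr_half <- skeleton_tree(0:8, rep(4.5, 9), rep(4, 9))
  f_half <- make_distance_field(tr_half, c(9, 9, 9))
  expect_equal(f_half[5, 7, 5], exp(-1.5 / 8), tolerance = 1e-9)
  expect_equal(f_half[5, 7, 5], 0.8290291, tolerance = 1e-6)

  # integer-line tree: voxel (4,5,4) is at d = 1, voxel (4,6,4) at d = 2
  tr <- skeleton_tree(0:8, rep(4, 9), rep(4, 9))
  f <- make_distance_field(tr, c(9, 9, 9))
  f2 <- make_distance_field(tr, c(9, 9, 9),
                            label_config(squared_exponent = TRUE))
  expect_equal(f[5, 6, 5], exp(-1 / 8), tolerance = 1e-9)
  expect_equal(f2[5, 6, 5], exp(-1 / 8), tolerance = 1e-9)  # d = 1: same
  expect_equal(f[5, 7, 5], exp(-2 / 8), tolerance = 1e-9)
  expect_equal(f2[5, 7, 5], exp(-4 / 8), tolerance = 1e-9)  # d = 2 differs

  # strictly decreasing along a ray normal to the skeleton (z = 4..7 at x=y=4)
  ray <- f[cbind(5:8, 5, 5)]
  expect_true(all(diff(ray[ray > 0]) < 0))

  # zero outside the expanded region, in [0, 1] everywhere
  mask <- expand_region(tr, c(9, 9, 9), radius = 3)
  expect_true(all(f[!mask] == 0))
  expect_true(all(f >= 0 & f <= 1))
})

test_that("fields from multiple trees combine by voxel-wise maximum", {
  t1 <- skeleton_tree(0:8, rep(3, 9), rep(4, 9), tree_id = 1L)
  t2 <- skeleton_tree(0:8, rep(5, 9), rep(4, 9), tree_id = 2L)
  f12 <- make_distance_field(list(t1, t2), c(9, 9, 9))
  f1 <- make_distance_field(t1, c(9, 9, 9))
  f2 <- make_distance_field(t2, c(9, 9, 9))
  expect_equal(f12, pmax(f1, f2), tolerance = 1e-12)
})
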