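test_that("matching indicator uses a strict Euclidean threshold", {
  G <- rbind(c(0, 0, 0))
  expect_equal(match_indicator(c(0, 0, 0), G, 3), 1)       # member point
  expect_equal(match_indicator(c(0, 0, 3), G, 3), 0)       # exactly thre: out
  expect_equal(match_indicator(c(0, 0, 1), G, 3), 1)       # distance 1 < 3
  expect_error(match_indicator(c(0, 0, 0), matrix(numeric(0), 0, 3)), "empty")
  # squared-norm reading: squared distance compared against thre
  expect_equal(match_indicator(c(0, 0, 2), G, 3, squared_norm = TRUE), 0)
  expect_equal(match_indicator(c(0, 0, 1.7), G, 3, squared_norm = TRUE), 1)
})

test_that("skeleton scores match hand evaluation and the exhaustive matcher", {
  G <- rbind(c(0, 0, 0), c(10, 0, 0))
  P <- rbind(c(0, 0, 1), c(20, 0, 0))
  sc <- skeleton_scores(P, G)
  expect_equal(sc$recall, 0.5)
  expect_equal(sc$precision, 0.5)
  expect_equal(sc$f1, 0.5)
  expect_equal(sc$n_g, 2L)
  expect_equal(sc$n_p, 2L)

  set.seed(61)
  sc <- skeleton_scores(G, G)
  expect_equal(c(sc$recall, sc$precision, sc$f1), c(1, 1, 1))
  for (rep in 1:10) {
    P <- matrix(runif(3 * sample(5:100, 1), 0, 20), ncol = 3)
    G <- matrix(runif(3 * sample(5:100, 1), 0, 20), ncol = 3)
    thre <- runif(1, 1, 5)
    got <- skeleton_scores(P, G, match_config(thre = thre))
    want <- bf_scores(P, G, thre)
    expect_identical(got$recall, want$recall)
    expect_identical(got$precision, want$precision)
    expect_equal(got$f1, want$f1, tolerance = 1e-12)
  }
})

test_that("empty point sets follow the documented conventions", {
  none <- matrix(numeric(0), 0, 3)
  P <- rbind(c(1, 2, 3))
  both <- skeleton_scores(none, none)
  expect_equal(c(both$recall, both$precision, both$f1), c(1, 1, 1))
  expect_warning(sc <- skeleton_scores(P, none), "recall undefined")
  expect_true(is.nan(sc$recall))
  sc <- skeleton_scores(none, P)
  expect_equal(sc$recall, 0)
})

test_that("recall/precision symmetry holds for swapped point sets", {
  set.seed(62)
  for (rep in 1:25) {
    P <- matrix(runif(3 * sample(3:40, 1), 0, 15), ncol = 3)
    G <- matrix(runif(3 * sample(3:40, 1), 0, 15), ncol = 3)
    a <- skeleton_scores(P, G)
    b <- skeleton_scores(G, P)
    expect_identical(a$recall, b$precision)
    expect_identical(a$precision, b$recall)
  }
})

test_that("metrics are invariant under a common rigid translation", {
  set.seed(63)
  P <- matrix(runif(60, 0, 10), ncol = 3)
  G <- matrix(runif(45, 0, 10), ncol = 3)
  shift <- c(3.7, -1.2, 8.4)
  a <- skeleton_scores(P, G)
  b <- skeleton_scores(sweep(P, 2, shift, "+"), sweep(G, 2, shift, "+"))
  expect_equal(a[c("recall", "precision", "f1")],
               b[c("recall", "precision", "f1")])
})

test_that("instance maps label the expanded regions by nearest tree", {
  # one tree: every in-region voxel gets label 1
  t1 <- skeleton_tree(10, 10, 10, tree_id = 1L)
  im <- instances_from_skeletons(t1, c(21, 21, 21))
  expect_equal(sum(im == 1), 93)
  expect_equal(sort(unique(as.integer(im))), c(0L, 1L))

  # two distant single-point trees: two labels of 93 voxels each
  t2 <- skeleton_tree(3, 3, 3, tree_id = 1L)
  t3 <- skeleton_tree(15, 15, 15, tree_id = 2L)
  im <- instances_from_skeletons(list(t2, t3), c(21, 21, 21))
  expect_equal(sum(im == 1), 93)
  expect_equal(sum(im == 2), 93)

  # closer than 2 * radius: voxels go to the nearer skeleton, no double label
  t4 <- skeleton_tree(8, 10, 10, tree_id = 1L)
  t5 <- skeleton_tree(12, 10, 10, tree_id = 2L)
  im <- instances_from_skeletons(list(t4, t5), c(21, 21, 21))
  d1 <- bf_min_dist(matrix(c(8, 10, 10), 1), c(21, 21, 21))
  d2 <- bf_min_dist(matrix(c(12, 10, 10), 1), c(21, 21, 21))
  expect_true(all(im[d1 < pmin(d2, 3)] == 1))
  expect_true(all(im[d2 < pmin(d1, 3)] == 2))
  expect_equal(sum(im > 0), sum(pmin(d1, d2) < 3))
})

test_that("AJI reproduces hand-computed values", {
  g <- array(0L, c(6, 6, 6)); g[1:4, 1:5, 1:5] <- 1L     # 100 voxels
  p <- array(0L, c(6, 6, 6)); p[1:2, 1:5, 1:5] <- 1L     # 50-voxel subset
  expect_equal(aji(g, p)$aji, 0.5)
  expect_equal(aji(g, g)$aji, 1)
  disj <- array(0L, c(6, 6, 6)); disj[6, 6, 6] <- 1L
  expect_equal(aji(g, disj)$aji, 0)
  expect_error(aji(g, array(0L, c(2, 2, 2))), "shape")
})

test_that("AJI equals the brute-force pairwise-Jaccard oracle", {
  set.seed(64)
  for (rep in 1:8) {
    shape <- c(12, 11, 10)
    g <- instances_from_skeletons(lapply(1:3, function(i)
      skeleton_tree(runif(1, 1, 8), runif(1, 1, 9), runif(1, 1, 10),
                    tree_id = i)), shape)
    p <- instances_from_skeletons(lapply(1:3, function(i)
      skeleton_tree(runif(1, 1, 8), runif(1, 1, 9), runif(1, 1, 10),
                    tree_id = i)), shape)
    expect_equal(aji(g, p)$aji, bf_aji(g, p), tolerance = 1e-12)
  }
  # speckle maps exercise ties and unmatched instances
  for (rep in 1:5) {
    g <- array(sample(0:3, 4^3, TRUE), c(4, 4, 4))
    p <- array(sample(0:3, 4^3, TRUE), c(4, 4, 4))
    expect_equal(aji(g, p)$aji, bf_aji(g, p), tolerance = 1e-12)
  }
})

test_that("AJI is 1 exactly when the instance partitions coincide", {
  set.seed(65)
  g <- array(sample(0:2, 5^3, TRUE), c(5, 5, 5))
  expect_equal(aji(g, g)$aji, 1)
  relab <- g
  relab[g == 1L] <- 2L
  relab[g == 2L] <- 1L
  expect_equal(aji(g, relab)$aji, 1)  # identical partition, permuted ids
  p <- g
  p[which(g == 1L)[1]] <- 0L          # drop one voxel: no longer identical
  expect_lt(aji(g, p)$aji, 1)
})
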