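test_that("U-Net output shape equals input shape for toy and reference profiles", {
  m <- build_unet(net_config(levels = 3, base_channels = 8), seed = 1)
  out <- axonfield:::unet_forward(m, array(runif(24^3), c(24, 24, 24)))$out
  expect_equal(dim(out), c(24, 24, 24))

  # parameter count equals an independent layer-by-layer tally
  tally <- function(levels, base) {
    ch <- base * 2^(seq_len(levels) - 1)
    tot <- 0
    for (k in seq_len(levels)) {
      cin <- if (k == 1) 1 else ch[k - 1]
      tot <- tot + (27 * cin * ch[k] + ch[k]) + 2 * ch[k] +
        (27 * ch[k]^2 + ch[k]) + 2 * ch[k]
    }
    for (k in seq_len(levels - 1)) {
      tot <- tot + (8 * ch[k + 1] * ch[k] + ch[k]) +
        (27 * ch[k]^2 + ch[k]) + 2 * ch[k] +
        (27 * ch[k]^2 + ch[k]) + 2 * ch[k]
    }
    tot + ch[1] + 1
  }
  expect_equal(n_params(m), tally(3, 8))
  expect_equal(n_params(build_unet(net_config(levels = 2, base_channels = 4))),
               tally(2, 4))

  # reference profile: 6 levels, 16 doubling to 512, on a padded 64^3 patch
  big <- build_unet(net_config(levels = 6, base_channels = 16), seed = 1)
  expect_equal(unname(axonfield:::unet_channels(big$config)),
               c(16, 32, 64, 128, 256, 512))
  expect_equal(n_params(big), tally(6, 16))
  out <- axonfield:::unet_forward(big, array(0.5, c(64, 64, 64)))$out
  expect_equal(dim(out), c(64, 64, 64))
})

test_that("input patches must be divisible by the downsampling factor", {
  expect_error(net_config(levels = 4, input_patch = 20), "divisible")
  expect_silent(net_config(levels = 4, input_patch = 24))
})

test_that("region-weighted loss matches hand arithmetic and the brute-force oracle", {
  # 2x2x2, y_g = 0.5, y_p = 0.3, x = 0: three active terms of 0.2 each
  yg <- array(0.5, c(2, 2, 2)); yp <- array(0.3, c(2, 2, 2))
  x0 <- array(0, c(2, 2, 2))
  expect_equal(df_loss(yp, yg, x0), 0.6)
  # identical prediction: exactly zero regardless of the input image
  expect_equal(df_loss(yg, yg, array(runif(8), c(2, 2, 2))), 0)

  set.seed(51)
  for (rep in 1:8) {
    yp <- array(runif(8^3), c(8, 8, 8))
    yg <- array(runif(8^3) * rbinom(8^3, 1, 0.3), c(8, 8, 8))
    x <- array(runif(8^3, 0, 0.6), c(8, 8, 8))
    expect_equal(df_loss(yp, yg, x), bf_loss(yp, yg, x), tolerance = 1e-6)
  }
  expect_error(df_loss(yp, yg, array(0, c(2, 2, 2))), "shape")
})

test_that("loss gradient agrees with finite differences", {
  set.seed(52)
  yp <- array(runif(4^3), c(4, 4, 4))
  yg <- array(runif(4^3) * rbinom(4^3, 1, 0.5), c(4, 4, 4))
  x <- array(runif(4^3), c(4, 4, 4))
  lg <- df_loss(yp, yg, x, grad = TRUE)
  idx <- sample(length(yp), 12)
  eps <- 1e-7
  for (i in idx) {
    y1 <- yp; y1[i] <- yp[i] + eps
    y2 <- yp; y2[i] <- yp[i] - eps
    fd <- (df_loss(y1, yg, x) - df_loss(y2, yg, x)) / (2 * eps)
    expect_equal(lg$grad[i], fd, tolerance = 1e-4)
  }
})

test_that("enhancement overlays the scaled prediction with clipping", {
  set.seed(53)
  v <- volume(array(sample(0:255, 5^3, TRUE) / 255, c(5, 5, 5)))
  zero <- array(0, c(5, 5, 5))
  expect_identical(enhance_volume(v, zero)$data, v$data)  # identity

  raw <- array(0, c(5, 5, 5)); raw[1, 1, 1] <- 10 / 255; raw[2, 2, 2] <- 100 / 255
  pred <- array(0, c(5, 5, 5)); pred[1, 1, 1] <- 1; pred[2, 2, 2] <- 0.2
  enh <- enhance_volume(volume(raw), pred)
  expect_equal(enh$data[1, 1, 1] * 255, 255)              # clipped at the top
  expect_equal(enh$data[2, 2, 2] * 255, 151)              # 100 + 0.2 * 255
  expect_error(enhance_volume(v, array(0, c(2, 2, 2))), "shape")

  # saturated-limit monotonicity: re-enhancing never lowers any voxel
  p <- array(runif(5^3), c(5, 5, 5))
  once <- enhance_volume(v, p)
  twice <- enhance_volume(once, p)
  expect_true(all(twice$data >= once$data - 1e-12))
})

test_that("foreground extraction returns exactly the voxels above threshold", {
  pred <- array(0, c(4, 5, 6))
  expect_equal(nrow(extract_foreground(pred, 0.5)), 0)
  pred[2, 3, 4] <- 0.9; pred[1, 1, 1] <- 0.51; pred[4, 5, 6] <- 0.5
  pts <- extract_foreground(pred, 0.5)
  expect_equal(nrow(pts), 2)                               # 0.5 is not > 0.5
  expect_true(all(pred[cbind(pts[, 3] + 1, pts[, 2] + 1, pts[, 1] + 1)] > 0.5))
  set.seed(54)
  pred <- array(runif(4 * 5 * 6), c(4, 5, 6))
  expect_equal(nrow(extract_foreground(pred, 0.7)), sum(pred > 0.7))
})

test_that("skeletonization turns point clouds into trees as specified", {
  # collinear 1-voxel-spaced points: one unbranched path containing all
  pts <- cbind(0:10, 0, 0)
  trees <- skeletonize_points(pts, min_points = 2)
  expect_length(trees, 1)
  expect_equal(nrow(trees[[1]]), 11)
  tr <- trees[[1]]
  nchild <- tabulate(match(tr$parent[tr$parent > 0], tr$id), nbins = nrow(tr))
  deg <- nchild + as.integer(tr$parent != -1)
  expect_true(all(deg <= 2))                               # unbranched path
  expect_equal(sort(tr$x), 0:10)

  # single point
  one <- skeletonize_points(matrix(c(3, 4, 5), 1, 3))
  expect_length(one, 1)
  expect_equal(nrow(one[[1]]), 1)

  # two clusters farther apart than the cutoff become two trees
  pts <- rbind(cbind(0:5, 0, 0), cbind(0:5, 20, 0))
  trees <- skeletonize_points(pts, cutoff = 2, min_points = 2)
  expect_length(trees, 2)

  # empty input
  expect_length(skeletonize_points(matrix(numeric(0), 0, 3)), 0)
})

test_that("prediction is clamped, shape-preserving, and tiling-consistent", {
  m <- build_unet(net_config(levels = 2, base_channels = 4), seed = 7)
  v <- array(runif(20 * 18 * 22), c(20, 18, 22))  # odd sizes get padded
  out <- predict_volume(m, v)
  expect_equal(dim(out), dim(v))
  expect_true(all(out >= 0 & out <= 1))

  # zeroed output head gives a constant (zero) field
  m0 <- m
  m0$params[["head.W"]][] <- 0
  m0$params[["head.b"]] <- 0
  expect_true(all(predict_volume(m0, v) == 0))

  # tiled and untiled inference agree away from the volume border
  v <- array(runif(48^3), c(48, 48, 48))
  full <- predict_volume(m, v)
  tiled <- predict_volume(m, v, core = 16, margin = 16)
  ctr <- 17:32
  expect_lt(max(abs(full[ctr, ctr, ctr] - tiled[ctr, ctr, ctr])), 1e-6)
})
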