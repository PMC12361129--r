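test_that("generation is bit-reproducible and respects degenerate configs", {
  cfg <- synth_config(shape = c(32, 32, 32), n_axons = c(1, 3), seed = 8,
                      n_blob_distractors = 1, n_strip_distractors = 1)
  a <- generate_volume(cfg)
  b <- generate_volume(cfg)
  expect_identical(a$vol$data, b$vol$data)
  expect_identical(a$trees, b$trees)

  # no axons, no distractors: pure noise, empty skeleton set
  noise <- generate_volume(synth_config(shape = c(24, 24, 24),
                                        n_axons = c(0, 0),
                                        n_blob_distractors = 0,
                                        n_strip_distractors = 0, seed = 2))
  expect_length(noise$trees, 0)
  raw <- noise$vol$data * 255
  expect_lt(abs(mean(raw) - 12), 1)             # background mean ~ 12
  expect_lt(abs(sd(raw) - 4), 1)                # background sd ~ 4
})

test_that("generated skeletons obey node spacing and round-trip through SWC", {
  gv <- generate_volume(synth_config(shape = c(48, 48, 48), n_axons = c(2, 4),
                                     branch_prob = 1, seed = 9))
  for (tr in gv$trees) {
    pos <- as.matrix(tr[, c("x", "y", "z")])
    par <- match(tr$parent, tr$id)
    e <- which(!is.na(par))
    lens <- sqrt(rowSums((pos[e, , drop = FALSE] - pos[par[e], , drop = FALSE])^2))
    expect_true(all(lens <= 1 + 1e-9))
    expect_true(all(pos >= 0 & pos <= 47))
  }
  f <- withr::local_tempfile(fileext = ".swc")
  write_swc(gv$trees, f)
  back <- read_swc(f)
  expect_length(back, length(gv$trees))
  for (k in seq_along(back))
    expect_equal(unname(as.matrix(back[[k]][, c("x", "y", "z")])),
                 unname(as.matrix(gv$trees[[k]][, c("x", "y", "z")])),
                 tolerance = 1e-4)
})

test_that("SNR calibration closes the loop within 20 percent", {
  cfg <- synth_config(shape = c(64, 64, 64), n_axons = c(2, 4), snr_target = 8,
                      seed = 7, n_blob_distractors = 1, n_strip_distractors = 1)
  gv <- generate_volume(cfg)
  st <- characterize_volume(gv$vol, gv$trees)
  expect_lt(abs(st$summary$snr_mean - 8) / 8, 0.2)
})

test_that("measured SNR rises with axon intensity at fixed noise", {
  snr_at <- function(intens) {
    cfg <- synth_config(shape = c(48, 48, 48), n_axons = c(2, 3),
                        axon_intensity = intens, weak_segment_fraction = 0,
                        n_blob_distractors = 0, n_strip_distractors = 0,
                        seed = 13)
    gv <- generate_volume(cfg)
    characterize_volume(gv$vol, gv$trees, block = 48)$summary$snr_mean
  }
  lo <- snr_at(c(40, 60))
  hi <- snr_at(c(150, 255))
  expect_gt(hi, lo)
})

test_that("density and intensity statistics follow the construction", {
  # uniform volume with no skeleton: density 0 everywhere, SNR undefined
  v <- volume(array(0.1, c(32, 32, 32)))
  st <- characterize_volume(v, list(), block = 16)
  expect_true(all(st$blocks$density == 0))
  expect_true(all(is.na(st$blocks$snr)))

  # single straight axon: density = resampled point count / block voxels
  xs <- seq(0, 31, by = 0.8)
  tr <- skeleton_tree(xs, rep(16, length(xs)), rep(16, length(xs)))
  st <- characterize_volume(volume(array(0.05, c(32, 32, 32))), tr, block = 32)
  n_pts <- nrow(resample_skeleton(tr, 1))
  expect_equal(st$blocks$density, n_pts / 32^3)
})

test_that("K-means block selection picks one representative per family", {
  set.seed(17)
  dark <- lapply(1:4, function(i)
    volume(array(pmin(pmax(rnorm(8^3, 0.1, 0.02), 0), 1), c(8, 8, 8))))
  bright <- lapply(1:4, function(i)
    volume(array(pmin(pmax(rnorm(8^3, 0.8, 0.02), 0), 1), c(8, 8, 8))))
  vols <- c(dark, bright)
  sel <- select_blocks_kmeans(vols, 2, seed = 1)
  expect_length(sel, 2)
  expect_equal(sum(sel <= 4), 1)                # one from each family
  expect_identical(sel, select_blocks_kmeans(vols, 2, seed = 1))
  expect_identical(select_blocks_kmeans(vols, 8), 1:8)
  expect_error(select_blocks_kmeans(vols, 9), "exceed")
})

test_that("the benchmark corpus generates quickly and spans its SNR range", {
  t0 <- Sys.time()
  corpus <- synthetic_corpus(6, shape = c(48, 48, 48), seed = 3)
  dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  expect_lt(dt / 6 * 30, 120)                   # 30 volumes in well under 2 min
  snrs <- vapply(corpus, function(s)
    characterize_volume(s$vol, s$trees, block = 48)$summary$snr_mean, 1)
  expect_gt(snrs[6], snrs[1])
  # off-lattice paths: the peak label value sits just below 1 on the voxel grid
  peaks <- vapply(corpus, function(s) max(s$label), 1)
  expect_true(all(peaks > 0.9 & peaks <= 1))
})
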