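#' Robust foreground threshold for a raw volume
#'
#' `median + k * MAD` of the intensities (on the normalized scale), the
#' standard data-driven cut separating background noise from bright
#' structure; falls back to `median + k * sd` when the MAD collapses on
#' quantized data.
#'
#' @param vol An [volume()] or 3D array in \[0, 1\].
#' @param k Number of robust standard deviations above the median (default 4).
#' @return A threshold in (0, 1).
#' @export
robust_threshold <- function(vol, k = 4) {
  a <- if (inherits(vol, "axon_volume")) vol$data else vol
  s <- mad(a)
  if (s == 0) s <- sd(a)
  min(max(median(a) + k * s, 1e-6), 1 - 1e-6)
}

#' Default foreground threshold for distance-field predictions
#'
#' Half the field value at the expansion-region boundary,
#' `exp(-radius / (2 sigma^2)) / 2` (about 0.34 under the default radius 3,
#' sigma 2): a voxel is treated as foreground when the network's response
#' reaches at least half of the weakest value the supervision target takes
#' inside the expanded region.
#'
#' @param config A [label_config()] supplying radius and sigma.
#' @return A scalar threshold in (0, 1).
#' @export
foreground_threshold <- function(config = label_config()) {
  d <- config$expand_radius
  if (config$squared_exponent) d <- d^2
  0.5 * exp(-d / (2 * config$sigma^2))
}

#' Threshold-and-skeletonize reconstruction of a field or image
#'
#' The shared back end of both arms of the benchmark: voxels above the
#' threshold become a point cloud that is skeletonized into trees.
#'
#' @param field A 3D array (network prediction, raw or enhanced image).
#' @param threshold Foreground threshold; defaults to
#'   [foreground_threshold()]; `NULL` uses the data-driven
#'   [robust_threshold()] (appropriate for raw images rather than predicted
#'   fields).
#' @param cutoff,prune_len,min_points Passed to [skeletonize_points()].
#' @return An `swc_forest` (possibly empty).
#' @export
trace_field <- function(field, threshold = foreground_threshold(),
                        cutoff = 2, prune_len = 4, min_points = 6) {
  if (inherits(field, "axon_volume")) field <- field$data
  if (is.null(threshold)) threshold <- robust_threshold(field)
  pts <- extract_foreground(field, threshold)
  skeletonize_points(pts, cutoff = cutoff, prune_len = prune_len,
                     min_points = min_points)
}

#' Study conditions for the scaled-down synthetic benchmark
#'
#' A corpus of volumes spanning SNR 3-12 with weak axon segments and blob
#' and strip distractors. Per-volume seeds derive from `seed`, so the corpus
#' is fully reproducible.
#'
#' @param n Number of volumes (default 30).
#' @param shape Volume edge lengths in SWC order (default 64^3).
#' @param seed Corpus seed.
#' @param snr_range SNR targets are spread evenly over this range.
#' @return A list of `n` elements, each with `vol`, `trees`, `label`,
#'   `snr_target`.
#' @export
synthetic_corpus <- function(n = 30, shape = c(64, 64, 64), seed = 1,
                             snr_range = c(3, 12)) {
  snrs <- seq(snr_range[1], snr_range[2], length.out = n)
  lapply(seq_len(n), function(i) {
    cfg <- synth_config(shape = shape, n_axons = c(1, 4),
                        tube_radius = c(1, 2),
                        weak_segment_fraction = 0.25,
                        snr_target = snrs[i],
                        n_blob_distractors = 1, n_strip_distractors = 1,
                        seed = seed * 1000L + i)
    gv <- generate_volume(cfg)
    lab <- make_distance_field(gv$trees, dim(gv$vol$data))
    list(vol = gv$vol, trees = gv$trees, label = lab, snr_target = snrs[i])
  })
}

#' Scaled-down end-to-end benchmark on synthetic volumes
#'
#' Generates a synthetic corpus, trains the toy-profile network (3 levels, 8
#' base channels, Adam 2e-4, batch size 1) on the training portion, and
#' evaluates held-out volumes three ways: skeletons traced from the network
#' prediction, skeletons traced directly from the raw image at a robust
#' intensity threshold (the no-enhancement baseline), and instance-level AJI
#' of prediction-derived versus ground-truth skeletons.
#'
#' @param seed Corpus, split and training seed.
#' @param n_volumes,n_train Corpus size and training share (default 30 / 25).
#' @param shape Volume edge lengths (default 64^3).
#' @param epochs Training epochs (default 12).
#' @param threshold Foreground threshold on predictions (default
#'   [foreground_threshold()]).
#' @param verbose Print training progress.
#' @return A list with per-volume and mean scores for both arms, the fitted
#'   model and the history.
#' @export
benchmark_synthetic <- function(seed = 1, n_volumes = 30, n_train = 25,
                                shape = c(64, 64, 64), epochs = 12,
                                threshold = foreground_threshold(),
                                verbose = FALSE) {
  corpus <- synthetic_corpus(n_volumes, shape, seed = seed)
  # held-out volumes sample the whole SNR range, not just one end
  te_idx <- unique(round(seq(2, n_volumes - 1,
                             length.out = n_volumes - n_train)))
  train_set <- corpus[setdiff(seq_len(n_volumes), te_idx)]
  test_set <- corpus[te_idx]
  pairs <- lapply(train_set, function(s) list(x = s$vol, y = s$label))
  fit <- train_unet(
    pairs,
    net = net_config(levels = 3, base_channels = 8),
    cfg = train_config(learning_rate = 2e-4, batch_size = 1, epochs = epochs,
                       seed = seed, patch = 32,
                       split_fractions = c(train = 0.9, val = 0.1, test = 0)),
    verbose = verbose
  )
  eval_one <- function(s) {
    pred <- predict_volume(fit$model, s$vol)
    ptrees <- trace_field(pred, threshold = threshold)
    net_sc <- evaluate_reconstruction(ptrees, s$trees, dim(s$vol$data))
    btrees <- trace_field(s$vol, threshold = NULL)
    base_sc <- skeleton_scores(btrees, s$trees)
    data.frame(snr_target = s$snr_target,
               recall = net_sc$recall, precision = net_sc$precision,
               f1 = net_sc$f1, aji = net_sc$aji,
               baseline_recall = base_sc$recall,
               baseline_precision = base_sc$precision,
               baseline_f1 = base_sc$f1)
  }
  per_volume <- do.call(rbind, lapply(test_set, eval_one))
  list(per_volume = per_volume,
       mean_scores = colMeans(per_volume),
       fit = fit)
}
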