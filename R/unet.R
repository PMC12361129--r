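#' 3D U-Net architecture configuration
#'
#' The reference profile mirrors the benchmark network: a six-level encoder
#' with channels doubling from 16 to 512, a mirrored decoder using stride-2
#' transposed convolutions, and additive (residual) skip connections between
#' matching scales. Each level is a block of two 3x3x3 convolutions with
#' instance normalization and ReLU; the output head is a linear 1x1x1
#' convolution whose output is clamped to \[0, 1\] at prediction time.
#'
#' @param levels Number of resolution levels (>= 2). The reference profile
#'   uses 6; a toy profile of 3 trains in minutes on a CPU.
#' @param base_channels Channels at the finest level, doubling per level
#'   (reference profile 16, giving 16..512).
#' @param skip_mode "add" for residual fusion (default) or "concat".
#' @param input_patch Training patch edge length in voxels; must be divisible
#'   by `2^(levels - 1)`. `NULL` trains on full volumes.
#' @return A list of class `net_config`.
#' @export
net_config <- function(levels = 6, base_channels = 16, skip_mode = c("add", "concat"),
                       input_patch = NULL) {
  skip_mode <- match.arg(skip_mode)
  stopifnot(levels >= 2, base_channels >= 1)
  if (!is.null(input_patch) && input_patch %% 2^(levels - 1) != 0)
    stop("input_patch must be divisible by 2^(levels - 1) = ", 2^(levels - 1))
  structure(list(levels = as.integer(levels),
                 base_channels = as.integer(base_channels),
                 skip_mode = skip_mode, input_patch = input_patch),
            class = "net_config")
}

#' Training configuration
#'
#' Defaults follow the benchmark training recipe: Adam with initial learning
#' rate 2e-4 and batch size 1. The loss region thresholds 3/255 and 103/255
#' select weak-foreground and strong-foreground voxels of the ground-truth
#' field, and strong voxels of the input image, on the 8-bit-referenced
#' \[0, 1\] scale.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Samples per optimizer step.
#' @param epochs Training epochs.
#' @param seed Integer seed controlling split, initialization and data order.
#' @param reg1_thresh,reg2_thresh Ground-truth region thresholds (3/255,
#'   103/255).
#' @param split_fractions Named train/val/test fractions; the default
#'   replicates the 676:85:91 split ratio of the benchmark corpus.
#' @param patch Optional training patch edge length (random crops biased
#'   toward labeled voxels); `NULL` uses full volumes.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 2e-4, batch_size = 1, epochs = 10,
                         seed = 1, reg1_thresh = 3 / 255, reg2_thresh = 103 / 255,
                         split_fractions = c(train = 0.79, val = 0.10, test = 0.11),
                         patch = NULL) {
  stopifnot(learning_rate > 0, reg1_thresh > 0, reg1_thresh < 1,
            reg2_thresh > 0, reg2_thresh < 1, batch_size >= 1)
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 reg1_thresh = reg1_thresh, reg2_thresh = reg2_thresh,
                 split_fractions = split_fractions, patch = patch),
            class = "train_config")
}

unet_channels <- function(config) config$base_channels * 2^(seq_len(config$levels) - 1L)

#' Build a randomly initialized 3D U-Net
#'
#' @param config A [net_config()].
#' @param seed Seed for He-style weight initialization.
#' @return An object of class `axon_unet` holding the flat parameter list and
#'   the configuration.
#' @export
build_unet <- function(config = net_config(), seed = 1) {
  stopifnot(inherits(config, "net_config"))
  set.seed(seed)
  ch <- unet_channels(config)
  L <- config$levels
  p <- list()
  conv_w <- function(cin, cout) {
    array(rnorm(27 * cin * cout, sd = sqrt(2 / (27 * cin))), dim = c(3, 3, 3, cin, cout))
  }
  for (k in seq_len(L)) {
    cin <- if (k == 1) 1L else ch[k - 1]
    p[[paste0("enc", k, ".c1.W")]] <- conv_w(cin, ch[k])
    p[[paste0("enc", k, ".c1.b")]] <- numeric(ch[k])
    p[[paste0("enc", k, ".n1.g")]] <- rep(1, ch[k])
    p[[paste0("enc", k, ".n1.b")]] <- numeric(ch[k])
    p[[paste0("enc", k, ".c2.W")]] <- conv_w(ch[k], ch[k])
    p[[paste0("enc", k, ".c2.b")]] <- numeric(ch[k])
    p[[paste0("enc", k, ".n2.g")]] <- rep(1, ch[k])
    p[[paste0("enc", k, ".n2.b")]] <- numeric(ch[k])
  }
  for (k in seq_len(L - 1)) {
    p[[paste0("dec", k, ".up.W")]] <-
      array(rnorm(8 * ch[k + 1] * ch[k], sd = sqrt(1 / ch[k + 1])),
            dim = c(2, 2, 2, ch[k + 1], ch[k]))
    p[[paste0("dec", k, ".up.b")]] <- numeric(ch[k])
    cin <- if (config$skip_mode == "concat") 2L * ch[k] else ch[k]
    p[[paste0("dec", k, ".c1.W")]] <- conv_w(cin, ch[k])
    p[[paste0("dec", k, ".c1.b")]] <- numeric(ch[k])
    p[[paste0("dec", k, ".n1.g")]] <- rep(1, ch[k])
    p[[paste0("dec", k, ".n1.b")]] <- numeric(ch[k])
    p[[paste0("dec", k, ".c2.W")]] <- conv_w(ch[k], ch[k])
    p[[paste0("dec", k, ".c2.b")]] <- numeric(ch[k])
    p[[paste0("dec", k, ".n2.g")]] <- rep(1, ch[k])
    p[[paste0("dec", k, ".n2.b")]] <- numeric(ch[k])
  }
  p[["head.W"]] <- matrix(rnorm(ch[1], sd = 0.1 / sqrt(ch[1])), ch[1], 1)
  p[["head.b"]] <- 0
  structure(list(params = p, config = config), class = "axon_unet")
}

#' @export
print.axon_unet <- function(x, ...) {
  cat(sprintf("<axon_unet> %d levels, channels %s, %s skips, %d parameters\n",
              x$config$levels,
              paste(unet_channels(x$config), collapse = "-"),
              x$config$skip_mode, n_params(x)))
  invisible(x)
}

#' Total number of trainable parameters
#' @param model An `axon_unet`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) sum(vapply(model$params, length, 1L))

inorm_fwd <- function(x, g, b, eps = 1e-5) {
  d <- dim(x)
  N <- prod(d[1:3]); C <- d[4]
  xm <- matrix(x, N, C)
  mu <- colMeans(xm)
  v <- colMeans(xm * xm) - mu * mu
  inv <- 1 / sqrt(v + eps)
  xhat <- (xm - rep(mu, each = N)) * rep(inv, each = N)
  y <- xhat * rep(g, each = N) + rep(b, each = N)
  dim(y) <- d
  list(y = y, xhat = xhat, inv = inv, d = d)
}

inorm_bwd <- function(dy, cache, g) {
  d <- cache$d
  N <- prod(d[1:3]); C <- d[4]
  dym <- matrix(dy, N, C)
  dg <- colSums(dym * cache$xhat)
  db <- colSums(dym)
  dxhat <- dym * rep(g, each = N)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * cache$xhat)
  dx <- rep(cache$inv, each = N) *
    (dxhat - rep(m1, each = N) - cache$xhat * rep(m2, each = N))
  dim(dx) <- d
  list(dx = dx, dg = dg, db = db)
}

# Forward pass; returns linear output (no clamp) and, when train = TRUE,
# the activation cache needed for unet_backward().
unet_forward <- function(model, x, train = FALSE) {
  p <- model$params
  L <- model$config$levels
  concat <- model$config$skip_mode == "concat"
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  cache <- list(enc_in = vector("list", L), n1 = vector("list", L),
                n2 = vector("list", L), r1 = vector("list", L),
                enc_out = vector("list", L), pool = vector("list", L),
                dec_in = vector("list", L), dn1 = vector("list", L),
                dn2 = vector("list", L), dr1 = vector("list", L),
                dup_in = vector("list", L))
  a <- x
  for (k in seq_len(L)) {
    if (train) cache$enc_in[[k]] <- a
    z <- conv3_fwd(a, p[[paste0("enc", k, ".c1.W")]], p[[paste0("enc", k, ".c1.b")]])
    nf <- inorm_fwd(z, p[[paste0("enc", k, ".n1.g")]], p[[paste0("enc", k, ".n1.b")]])
    if (train) cache$n1[[k]] <- nf[c("xhat", "inv", "d")]
    r1 <- pmax(nf$y, 0)
    if (train) cache$r1[[k]] <- r1
    z <- conv3_fwd(r1, p[[paste0("enc", k, ".c2.W")]], p[[paste0("enc", k, ".c2.b")]])
    nf <- inorm_fwd(z, p[[paste0("enc", k, ".n2.g")]], p[[paste0("enc", k, ".n2.b")]])
    if (train) cache$n2[[k]] <- nf[c("xhat", "inv", "d")]
    r2 <- pmax(nf$y, 0)
    cache$enc_out[[k]] <- r2
    if (k < L) {
      pl <- pool2_fwd(r2)
      if (train) cache$pool[[k]] <- list(idx = pl$idx, xdim = dim(r2))
      a <- pl$out
    }
  }
  u <- cache$enc_out[[L]]
  for (k in rev(seq_len(L - 1))) {
    if (train) cache$dup_in[[k]] <- u
    up <- upconv2_fwd(u, p[[paste0("dec", k, ".up.W")]], p[[paste0("dec", k, ".up.b")]])
    s <- if (concat) abind4(up, cache$enc_out[[k]]) else up + cache$enc_out[[k]]
    if (!train) cache$enc_out[k] <- list(NULL)
    if (train) cache$dec_in[[k]] <- s
    z <- conv3_fwd(s, p[[paste0("dec", k, ".c1.W")]], p[[paste0("dec", k, ".c1.b")]])
    nf <- inorm_fwd(z, p[[paste0("dec", k, ".n1.g")]], p[[paste0("dec", k, ".n1.b")]])
    if (train) cache$dn1[[k]] <- nf[c("xhat", "inv", "d")]
    r1 <- pmax(nf$y, 0)
    if (train) cache$dr1[[k]] <- r1
    z <- conv3_fwd(r1, p[[paste0("dec", k, ".c2.W")]], p[[paste0("dec", k, ".c2.b")]])
    nf <- inorm_fwd(z, p[[paste0("dec", k, ".n2.g")]], p[[paste0("dec", k, ".n2.b")]])
    if (train) cache$dn2[[k]] <- nf[c("xhat", "inv", "d")]
    u <- pmax(nf$y, 0)
  }
  cache$head_in <- u
  d <- dim(u)
  N <- prod(d[1:3])
  ym <- matrix(u, N, d[4]) %*% p[["head.W"]] + p[["head.b"]]
  out <- array(ym, dim = d[1:3])
  if (train) list(out = out, cache = cache) else list(out = out)
}

abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

# Backward pass; dout has the spatial dims of the output. Returns the flat
# gradient list matching model$params.
unet_backward <- function(model, cache, dout) {
  p <- model$params
  L <- model$config$levels
  concat <- model$config$skip_mode == "concat"
  g <- rapply(p, function(v) v * 0, how = "replace")
  u <- cache$head_in
  d <- dim(u)
  N <- prod(d[1:3])
  dym <- matrix(dout, N, 1)
  g[["head.W"]] <- crossprod(matrix(u, N, d[4]), dym)
  g[["head.b"]] <- sum(dym)
  du <- matrix(dym, N, 1) %*% t(p[["head.W"]])
  dim(du) <- d

  conv_block_bwd <- function(prefix, du, relu_out2, n2c, r1, n1c, xin) {
    du <- du * (relu_out2 > 0)
    nb <- inorm_bwd(du, n2c, p[[paste0(prefix, ".n2.g")]])
    g[[paste0(prefix, ".n2.g")]] <<- g[[paste0(prefix, ".n2.g")]] + nb$dg
    g[[paste0(prefix, ".n2.b")]] <<- g[[paste0(prefix, ".n2.b")]] + nb$db
    cb <- conv3_bwd(r1, nb$dx, p[[paste0(prefix, ".c2.W")]])
    g[[paste0(prefix, ".c2.W")]] <<- g[[paste0(prefix, ".c2.W")]] + cb$dW
    g[[paste0(prefix, ".c2.b")]] <<- g[[paste0(prefix, ".c2.b")]] + cb$db
    du <- cb$dx * (r1 > 0)
    nb <- inorm_bwd(du, n1c, p[[paste0(prefix, ".n1.g")]])
    g[[paste0(prefix, ".n1.g")]] <<- g[[paste0(prefix, ".n1.g")]] + nb$dg
    g[[paste0(prefix, ".n1.b")]] <<- g[[paste0(prefix, ".n1.b")]] + nb$db
    cb <- conv3_bwd(xin, nb$dx, p[[paste0(prefix, ".c1.W")]])
    g[[paste0(prefix, ".c1.W")]] <<- g[[paste0(prefix, ".c1.W")]] + cb$dW
    g[[paste0(prefix, ".c1.b")]] <<- g[[paste0(prefix, ".c1.b")]] + cb$db
    cb$dx
  }

  dskip <- vector("list", L)
  # decoder levels in reverse of forward execution order (1 .. L-1)
  for (k in seq_len(L - 1)) {
    relu_out2 <- if (k == 1) cache$head_in else cache$dup_in[[k - 1]]
    ds <- conv_block_bwd(paste0("dec", k), du, relu_out2, cache$dn2[[k]],
                         cache$dr1[[k]], cache$dn1[[k]], cache$dec_in[[k]])
    if (concat) {
      cu <- dim(cache$dup_in[[k]])[4] * 0 + dim(cache$enc_out[[k]])[4]
      nup <- dim(ds)[4] - cu
      dup <- ds[, , , seq_len(nup), drop = FALSE]
      dskip[[k]] <- ds[, , , nup + seq_len(cu), drop = FALSE]
    } else {
      dup <- ds
      dskip[[k]] <- ds
    }
    ub <- upconv2_bwd(cache$dup_in[[k]], dup, p[[paste0("dec", k, ".up.W")]])
    g[[paste0("dec", k, ".up.W")]] <- g[[paste0("dec", k, ".up.W")]] + ub$dW
    g[[paste0("dec", k, ".up.b")]] <- g[[paste0("dec", k, ".up.b")]] + ub$db
    du <- ub$dx
  }
  # du is now the gradient on enc_out[[L]]
  for (k in rev(seq_len(L))) {
    dr2 <- if (k == L) du else {
      dd <- pool2_bwd(du, cache$pool[[k]]$idx, dim(cache$enc_out[[k]]))
      if (is.null(dskip[[k]])) dd else dd + dskip[[k]]
    }
    du <- conv_block_bwd(paste0("enc", k), dr2, cache$enc_out[[k]],
                         cache$n2[[k]], cache$r1[[k]], cache$n1[[k]],
                         cache$enc_in[[k]])
  }
  g
}

#' Region-weighted L1 loss for distance-field regression
#'
#' The loss is the sum of four mean absolute errors: over all voxels, over
#' the weak-foreground region of the ground truth (`y_g > reg1_thresh`),
#' over the strong-foreground region (`y_g > reg2_thresh`), and over the
#' bright region of the input image (`x > reg2_thresh`). A region with no
#' voxels contributes 0. The region terms up-weight the sparse axonal
#' foreground, whose voxel share is tiny in whole-volume averages.
#'
#' @param y_p Network output array.
#' @param y_g Ground-truth distance-field array (same shape).
#' @param x Input image array on the \[0, 1\] scale (same shape), or an
#'   [volume()] object.
#' @param cfg A [train_config()] providing the thresholds.
#' @param grad Also return the gradient with respect to `y_p`.
#' @return The scalar loss, or (with `grad = TRUE`) a list `loss`, `grad`.
#' @export
df_loss <- function(y_p, y_g, x, cfg = train_config(), grad = FALSE) {
  if (inherits(x, "axon_volume")) x <- x$data
  if (!identical(dim(y_p), dim(y_g)) || !identical(dim(y_p), dim(x)))
    stop("y_p, y_g and x must have identical shapes")
  diff <- y_p - y_g
  ad <- abs(diff)
  n_total <- length(ad)
  r1 <- y_g > cfg$reg1_thresh
  r2 <- y_g > cfg$reg2_thresh
  r2s <- x > cfg$reg2_thresh
  n1 <- sum(r1); n2 <- sum(r2); n2s <- sum(r2s)
  loss <- sum(ad) / n_total +
    (if (n1 > 0) sum(ad[r1]) / n1 else 0) +
    (if (n2 > 0) sum(ad[r2]) / n2 else 0) +
    (if (n2s > 0) sum(ad[r2s]) / n2s else 0)
  if (!grad) return(loss)
  w <- array(1 / n_total, dim = dim(ad))
  if (n1 > 0) w[r1] <- w[r1] + 1 / n1
  if (n2 > 0) w[r2] <- w[r2] + 1 / n2
  if (n2s > 0) w[r2s] <- w[r2s] + 1 / n2s
  list(loss = loss, grad = w * sign(diff))
}

adam_step <- function(p, g, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(p)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g[[nm]]^2
    p[[nm]] <- p[[nm]] - lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(p = p, state = state)
}

#' Train the distance-field regression network
#'
#' Adam optimization (batch size 1 by default) of [df_loss()] on
#' (volume, label) pairs. One integer seed controls the train/validation
#' split, weight initialization, crop positions and data order, so a run is
#' reproducible end to end. The parameters with the best validation loss are
#' retained (final parameters when there is no validation set).
#'
#' @param pairs A list; each element is a list with `x` (an [volume()] or 3D
#'   array) and `y` (the distance-field label array).
#' @param net A [net_config()].
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return A list of class `axon_unet_fit` with elements `model`
#'   (an `axon_unet`), `history` (data.frame of epoch, train_loss, val_loss)
#'   and `split` (index vectors).
#' @export
train_unet <- function(pairs, net = net_config(levels = 3, base_channels = 8),
                       cfg = train_config(), verbose = FALSE) {
  if (length(pairs) == 0L) stop("empty training set")
  set.seed(cfg$seed)
  n <- length(pairs)
  xs <- lapply(pairs, function(p) if (inherits(p$x, "axon_volume")) p$x$data else p$x)
  ys <- lapply(pairs, function(p) p$y)
  f <- cfg$split_fractions
  idx <- sample(n)
  ntr <- max(1L, round(f[["train"]] / sum(f) * n))
  nva <- min(n - ntr, round(f[["val"]] / sum(f) * n))
  tr_idx <- idx[seq_len(ntr)]
  va_idx <- if (nva > 0) idx[ntr + seq_len(nva)] else integer(0)
  te_idx <- setdiff(idx, c(tr_idx, va_idx))

  model <- build_unet(net, seed = cfg$seed)
  state <- list(t = 0,
                m = rapply(model$params, function(v) v * 0, how = "replace"),
                v = rapply(model$params, function(v) v * 0, how = "replace"))
  mult <- 2^(net$levels - 1)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(loss = Inf, params = model$params)
  patch <- cfg$patch %||% net$input_patch
  if (!is.null(patch) && patch %% mult != 0)
    stop("patch must be divisible by ", mult)

  crop_pair <- function(x, y) {
    d <- dim(x)
    if (is.null(patch) || all(d <= patch)) {
      # pad up to a multiple of 2^(levels-1) if needed
      if (any(d %% mult != 0)) {
        dp <- ceiling(d / mult) * mult
        x <- pad_reflect(x, dp - d)
        y <- pad_reflect(y, dp - d)
      }
      return(list(x = x, y = y))
    }
    ps <- pmin(patch, d)
    pos <- which(y > 0)
    if (length(pos) > 0) {
      ctr <- arrayInd(sample(pos, 1L), d)
      lo <- pmin(pmax(ctr - ps %/% 2, 1L), d - ps + 1L)
    } else {
      lo <- 1L + vapply(d - ps, function(m) sample.int(m + 1L, 1L) - 1L, 1L)
    }
    hi <- lo + ps - 1L
    list(x = x[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
         y = y[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE])
  }

  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(tr_idx)
    tl <- 0
    for (i in ord) {
      cp <- crop_pair(xs[[i]], ys[[i]])
      fw <- unet_forward(model, cp$x, train = TRUE)
      lg <- df_loss(fw$out, cp$y, cp$x, cfg, grad = TRUE)
      gr <- unet_backward(model, fw$cache, lg$grad)
      st <- adam_step(model$params, gr, state, cfg$learning_rate)
      model$params <- st$p
      state <- st$state
      tl <- tl + lg$loss
    }
    tl <- tl / length(ord)
    vl <- NA_real_
    if (length(va_idx) > 0) {
      vl <- mean(vapply(va_idx, function(i) {
        cp <- crop_pair(xs[[i]], ys[[i]])
        fw <- unet_forward(model, cp$x)
        df_loss(fw$out, cp$y, cp$x, cfg)
      }, numeric(1)))
      if (vl < best$loss) best <- list(loss = vl, params = model$params)
    } else {
      best <- list(loss = tl, params = model$params)
    }
    history <- rbind(history, data.frame(epoch = ep, train_loss = tl, val_loss = vl))
    if (verbose)
      message(sprintf("epoch %d: train %.5f val %.5f", ep, tl, vl))
  }
  model$params <- best$params
  structure(list(model = model, history = history,
                 split = list(train = tr_idx, val = va_idx, test = te_idx)),
            class = "axon_unet_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pad_reflect <- function(a, pad_hi, pad_lo = c(0L, 0L, 0L)) {
  d <- dim(a)
  ix <- lapply(1:3, function(ax) {
    base <- seq_len(d[ax])
    lo <- if (pad_lo[ax] > 0) rev(head(base, pad_lo[ax])) else integer(0)
    hi <- if (pad_hi[ax] > 0) rev(tail(base, pad_hi[ax])) else integer(0)
    c(lo, base, hi)
  })
  a[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
}

#' Predict a distance field for a full volume
#'
#' Runs the network over the volume, reflect-padding to the divisibility the
#' architecture needs and clamping the output to \[0, 1\]. Volumes larger
#' than `max_untiled` are processed in overlapping tiles whose `margin`
#' voxels of context are taken from the real data wherever available, so
#' tiled and untiled inference agree away from the volume border.
#'
#' @param model An `axon_unet` (or `axon_unet_fit`).
#' @param vol An [volume()] or 3D array on the \[0, 1\] scale.
#' @param core Tile edge length (multiple of `2^(levels-1)`); `NULL` picks 64.
#' @param margin Context margin per tile side (multiple of `2^(levels-1)`).
#' @param max_untiled Largest edge length processed in a single pass.
#' @return A 3D array in \[0, 1\] with the shape of the input.
#' @export
predict_volume <- function(model, vol, core = NULL, margin = 16, max_untiled = 128) {
  if (inherits(model, "axon_unet_fit")) model <- model$model
  arr <- if (inherits(vol, "axon_volume")) vol$data else vol
  d <- dim(arr)
  mult <- 2^(model$config$levels - 1)
  run <- function(a) unet_forward(model, a)$out
  if (is.null(core) && max(d) <= max_untiled) {
    dp <- ceiling(d / mult) * mult
    out <- run(pad_reflect(arr, dp - d))
    return(pmin(pmax(out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE], 0), 1))
  }
  core <- core %||% 64L
  if (core %% mult != 0 || margin %% mult != 0)
    stop("core and margin must be multiples of ", mult)
  dpad <- ceiling(d / core) * core
  big <- pad_reflect(arr, dpad - d + margin, pad_lo = rep(margin, 3))
  out <- array(0, dim = dpad)
  starts <- lapply(1:3, function(ax) seq(1L, dpad[ax], by = core))
  for (sx in starts[[1]]) for (sy in starts[[2]]) for (sz in starts[[3]]) {
    win <- big[sx:(sx + core + 2 * margin - 1),
               sy:(sy + core + 2 * margin - 1),
               sz:(sz + core + 2 * margin - 1), drop = FALSE]
    res <- run(win)
    out[sx:(sx + core - 1), sy:(sy + core - 1), sz:(sz + core - 1)] <-
      res[margin + seq_len(core), margin + seq_len(core), margin + seq_len(core)]
  }
  pmin(pmax(out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE], 0), 1)
}
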