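#' Training configuration for the neural segmentation backend
#'
#' Defaults follow the common encoder-decoder training protocol for OCT
#' boundary segmentation: Adam at learning rate 1e-4, batch size 8, 100
#' epochs, 9:1 train/test split.
#'
#' @param learning_rate Adam step size (> 0).
#' @param batch_size Minibatch size.
#' @param epochs Number of passes over the training set.
#' @param split_ratio Train fraction for [split_train_test()], in (0, 1).
#' @param base_channels Channels of the first encoder block (the reduced
#'   default keeps CPU training at desk scale).
#' @param depth Number of pooling levels (1 or 2); input sides must be
#'   divisible by `2^depth`.
#' @param seed Integer seed for weight init and batch shuffling.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 8L,
                         epochs = 100L, split_ratio = 0.9,
                         base_channels = 8L, depth = 1L, seed = 42L) {
  stopifnot(learning_rate > 0, split_ratio > 0, split_ratio < 1,
            batch_size >= 1, epochs >= 1, depth %in% c(1L, 2L))
  structure(as.list(environment()), class = "train_config")
}

#' Grouped train/test split
#'
#' Splits at the group (volume) level so that B-scans of the same volume
#' never straddle the train/test boundary.
#'
#' @param groups Vector assigning each sample to a group.
#' @param split_ratio Train fraction.
#' @param seed Integer seed.
#' @return A list with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(groups, split_ratio = 0.9, seed = 42L) {
  ug <- unique(groups)
  n_tr <- max(1L, min(length(ug) - 1L, round(split_ratio * length(ug))))
  tr_g <- withr::with_seed(seed, sample(ug, n_tr))
  list(train = which(groups %in% tr_g),
       test = which(!groups %in% tr_g))
}

#' Train the encoder-decoder (U-Net) segmentation backend
#'
#' A compact U-Net: per level two 3x3 convolutions with ReLU, 2x2 max
#' pooling on the way down, nearest-neighbour upsampling with skip
#' concatenation on the way up, and a 1x1 output convolution, trained with
#' Adam on pixel-wise binary cross-entropy. Images are normalized by their
#' own maximum so the backend shares the classical backend's invariance to
#' global intensity scaling.
#'
#' @param images List of B-scan matrices (equal sizes, sides divisible by
#'   `2^depth`).
#' @param masks List of matching 0/1 matrices.
#' @param config A [train_config()].
#' @param verbose Print the epoch loss.
#' @return A list of class `unet_model`: `params`, `config`, `descriptor`,
#'   `loss_history`.
#' @export
train_neural <- function(images, masks, config = train_config(),
                         verbose = FALSE) {
  stopifnot(length(images) >= 2, length(images) == length(masks))
  dims <- dim(images[[1]])
  for (i in seq_along(images)) {
    if (!identical(dim(images[[i]]), dims)) {
      stop("all training images must share one size; image ", i, " differs")
    }
    if (!identical(dim(masks[[i]]), dims)) {
      stop("mask ", i, " does not match its image size")
    }
    if (!all(masks[[i]] %in% c(0, 1))) {
      stop("mask ", i, " is not binary")
    }
  }
  if (any(dims %% (2^config$depth) != 0)) {
    stop("image sides must be divisible by ", 2^config$depth,
         " for depth ", config$depth)
  }
  params <- withr::with_seed(config$seed, .unet_init(config))
  opt <- .adam_init(params)
  loss_hist <- numeric(config$epochs)
  norm_im <- lapply(images, function(x) x / max(x, 1e-12))
  order_seed <- config$seed + 1L
  for (ep in seq_len(config$epochs)) {
    idx <- withr::with_seed(order_seed + ep, sample(seq_along(norm_im)))
    batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
    ep_loss <- 0
    for (bt in batches) {
      grads <- NULL
      loss <- 0
      for (i in bt) {
        fw <- .unet_forward(norm_im[[i]], params, config)
        lg <- .bce_with_logits(fw$logits, masks[[i]])
        loss <- loss + lg$loss
        g <- .unet_backward(lg$dlogits, fw, params, config)
        grads <- if (is.null(grads)) g else Map(`+`, grads, g)
      }
      grads <- lapply(grads, function(g) g / length(bt))
      upd <- .adam_step(params, grads, opt, config$learning_rate)
      params <- upd$params; opt <- upd$opt
      ep_loss <- ep_loss + loss / length(bt)
    }
    loss_hist[ep] <- ep_loss / length(batches)
    if (verbose) message(sprintf("epoch %3d  loss %.5f", ep, loss_hist[ep]))
  }
  structure(list(
    params = params,
    config = config,
    descriptor = list(architecture = "unet",
                      depth = config$depth,
                      base_channels = config$base_channels,
                      input_size = dims,
                      learning_rate = config$learning_rate,
                      batch_size = config$batch_size,
                      epochs = config$epochs,
                      seed = config$seed),
    loss_history = loss_hist
  ), class = "unet_model")
}

#' Predict a segmentation mask with a trained neural backend
#'
#' The pixel probabilities are thresholded at 0.5 and post-processed into a
#' valid mask: per A-scan column the topmost supra-threshold pixel defines
#' the surface and the mask is filled from there to the image bottom, so the
#' neural backend satisfies the same single-run contiguity invariant as the
#' classical one.
#'
#' @param model A `unet_model`.
#' @param image B-scan matrix with sides divisible by `2^depth`.
#' @return An `oct_mask` (single slice) with `surface_rows`.
#' @export
predict_neural <- function(model, image) {
  stopifnot(inherits(model, "unet_model"), is.matrix(image))
  fw <- .unet_forward(image / max(image, 1e-12), model$params, model$config)
  prob <- 1 / (1 + exp(-fw$logits))
  rows <- .first_exceed_row(prob, 0.5)
  labels <- matrix(0L, nrow(image), ncol(image))
  for (j in which(!is.na(rows))) labels[rows[j]:nrow(image), j] <- 1L
  structure(list(labels = labels, backend = "neural",
                 provenance = model$descriptor, surface_rows = rows,
                 prob = prob),
            class = "oct_mask")
}

#' Save / load a trained neural backend
#'
#' The model state goes to a single binary file, with a JSON descriptor
#' (architecture, training configuration, seed) next to it; reloading
#' reproduces predictions bit-exactly.
#'
#' @param model A `unet_model`.
#' @param path File path for the binary state (descriptor at `<path>.json`).
#' @return `load_neural` returns the `unet_model`.
#' @export
save_neural <- function(model, path) {
  stopifnot(inherits(model, "unet_model"))
  saveRDS(model, path)
  jsonlite::write_json(model$descriptor, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_neural
#' @export
load_neural <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "unet_model"))
  model
}

# ---- internals -------------------------------------------------------------

# channel plan per level; level l encoder has b * 2^(l-1) channels
.unet_plan <- function(config) {
  b <- config$base_channels
  d <- config$depth
  enc_ch <- b * 2^(seq_len(d) - 1)
  list(b = b, d = d, enc = enc_ch, bottleneck = b * 2^d)
}

.he_init <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
}

.unet_init <- function(config) {
  pl <- .unet_plan(config)
  p <- list()
  cin <- 1L
  for (l in seq_len(pl$d)) {
    co <- pl$enc[l]
    p[[paste0("enc", l, "_W1")]] <- .he_init(9 * cin, co)
    p[[paste0("enc", l, "_b1")]] <- numeric(co)
    p[[paste0("enc", l, "_W2")]] <- .he_init(9 * co, co)
    p[[paste0("enc", l, "_b2")]] <- numeric(co)
    cin <- co
  }
  p[["bott_W1"]] <- .he_init(9 * cin, pl$bottleneck)
  p[["bott_b1"]] <- numeric(pl$bottleneck)
  p[["bott_W2"]] <- .he_init(9 * pl$bottleneck, pl$bottleneck)
  p[["bott_b2"]] <- numeric(pl$bottleneck)
  cup <- pl$bottleneck
  for (l in rev(seq_len(pl$d))) {
    cat_ch <- cup + pl$enc[l]
    co <- pl$enc[l]
    p[[paste0("dec", l, "_W1")]] <- .he_init(9 * cat_ch, co)
    p[[paste0("dec", l, "_b1")]] <- numeric(co)
    p[[paste0("dec", l, "_W2")]] <- .he_init(9 * co, co)
    p[[paste0("dec", l, "_b2")]] <- numeric(co)
    cup <- co
  }
  p[["out_W"]] <- .he_init(pl$b, 1L)
  p[["out_b"]] <- 0
  p
}

.im2col <- function(X) {
  d <- dim(X); H <- d[1]; W <- d[2]; C <- d[3]
  Xp <- array(0, c(H + 2L, W + 2L, C))
  Xp[2:(H + 1), 2:(W + 1), ] <- X
  P <- matrix(0, H * W, 9L * C)
  k <- 0L
  for (c in seq_len(C)) {
    for (dj in -1:1) for (di in -1:1) {
      k <- k + 1L
      P[, k] <- Xp[(2 + di):(H + 1 + di), (2 + dj):(W + 1 + dj), c]
    }
  }
  P
}

.col2im <- function(dP, H, W, C) {
  dXp <- array(0, c(H + 2L, W + 2L, C))
  k <- 0L
  for (c in seq_len(C)) {
    for (dj in -1:1) for (di in -1:1) {
      k <- k + 1L
      dXp[(2 + di):(H + 1 + di), (2 + dj):(W + 1 + dj), c] <-
        dXp[(2 + di):(H + 1 + di), (2 + dj):(W + 1 + dj), c] +
        matrix(dP[, k], H, W)
    }
  }
  dXp[2:(H + 1), 2:(W + 1), , drop = FALSE]
}

# conv3x3 (same padding) + ReLU; returns output and cache
.conv_relu_fw <- function(X, Wm, b) {
  d <- dim(X)
  P <- .im2col(X)
  Z <- sweep(P %*% Wm, 2, b, "+")
  A <- pmax(Z, 0)
  list(out = array(A, c(d[1], d[2], ncol(Wm))), P = P, Z = Z)
}

.conv_relu_bw <- function(dOut, cache, Wm, H, W, Cin) {
  dA <- matrix(dOut, H * W, ncol(Wm))
  dZ <- dA * (cache$Z > 0)
  list(dW = crossprod(cache$P, dZ),
       db = colSums(dZ),
       dX = .col2im(dZ %*% t(Wm), H, W, Cin))
}

.maxpool_fw <- function(X) {
  d <- dim(X); H <- d[1]; W <- d[2]; C <- d[3]
  io <- seq(1, H, by = 2); jo <- seq(1, W, by = 2)
  cand <- array(0, c(H / 2, W / 2, C, 4))
  cand[, , , 1] <- X[io, jo, , drop = FALSE]
  cand[, , , 2] <- X[io + 1, jo, , drop = FALSE]
  cand[, , , 3] <- X[io, jo + 1, , drop = FALSE]
  cand[, , , 4] <- X[io + 1, jo + 1, , drop = FALSE]
  arg <- array(1L, c(H / 2, W / 2, C))
  best <- cand[, , , 1]
  for (k in 2:4) {
    sel <- cand[, , , k] > best
    arg[sel] <- k
    best[sel] <- cand[, , , k][sel]
  }
  list(out = best, arg = arg, dims = d)
}

.maxpool_bw <- function(dOut, cache) {
  d <- cache$dims
  dX <- array(0, d)
  io <- seq(1, d[1], by = 2); jo <- seq(1, d[2], by = 2)
  for (k in 1:4) {
    sel <- cache$arg == k
    g <- dOut * sel
    di <- (k == 2 || k == 4) * 1L
    dj <- (k == 3 || k == 4) * 1L
    dX[io + di, jo + dj, ] <- dX[io + di, jo + dj, ] + g
  }
  dX
}

.upsample_fw <- function(X) {
  d <- dim(X)
  idx_i <- rep(seq_len(d[1]), each = 2)
  idx_j <- rep(seq_len(d[2]), each = 2)
  X[idx_i, idx_j, , drop = FALSE]
}

.upsample_bw <- function(dOut, d_in) {
  io <- seq(1, 2 * d_in[1], by = 2); jo <- seq(1, 2 * d_in[2], by = 2)
  dOut[io, jo, , drop = FALSE] + dOut[io + 1, jo, , drop = FALSE] +
    dOut[io, jo + 1, , drop = FALSE] + dOut[io + 1, jo + 1, , drop = FALSE]
}

.unet_forward <- function(image, p, config) {
  pl <- .unet_plan(config)
  X <- array(image, c(dim(image), 1L))
  cache <- list()
  skips <- list()
  for (l in seq_len(pl$d)) {
    c1 <- .conv_relu_fw(X, p[[paste0("enc", l, "_W1")]], p[[paste0("enc", l, "_b1")]])
    c2 <- .conv_relu_fw(c1$out, p[[paste0("enc", l, "_W2")]], p[[paste0("enc", l, "_b2")]])
    skips[[l]] <- c2$out
    pool <- .maxpool_fw(c2$out)
    cache[[paste0("enc", l)]] <- list(c1 = c1, c2 = c2, pool = pool,
                                      in_dim = dim(X))
    X <- pool$out
  }
  b1 <- .conv_relu_fw(X, p$bott_W1, p$bott_b1)
  b2 <- .conv_relu_fw(b1$out, p$bott_W2, p$bott_b2)
  cache$bott <- list(c1 = b1, c2 = b2, in_dim = dim(X))
  U <- b2$out
  for (l in rev(seq_len(pl$d))) {
    up <- .upsample_fw(U)
    cat_in <- array(c(up, skips[[l]]),
                    c(dim(up)[1], dim(up)[2], dim(up)[3] + dim(skips[[l]])[3]))
    d1 <- .conv_relu_fw(cat_in, p[[paste0("dec", l, "_W1")]], p[[paste0("dec", l, "_b1")]])
    d2 <- .conv_relu_fw(d1$out, p[[paste0("dec", l, "_W2")]], p[[paste0("dec", l, "_b2")]])
    cache[[paste0("dec", l)]] <- list(c1 = d1, c2 = d2,
                                      up_in_dim = dim(U),
                                      cat_dim = dim(cat_in))
    U <- d2$out
  }
  H <- dim(U)[1]; W <- dim(U)[2]
  logits <- matrix(matrix(U, H * W, dim(U)[3]) %*% p$out_W + p$out_b, H, W)
  list(logits = logits, cache = cache, last = U)
}

.unet_backward <- function(dlogits, fw, p, config) {
  pl <- .unet_plan(config)
  g <- list()
  H <- nrow(dlogits); W <- ncol(dlogits)
  Ulast <- matrix(fw$last, H * W, dim(fw$last)[3])
  dl <- matrix(dlogits, H * W, 1)
  g$out_W <- crossprod(Ulast, dl)
  g$out_b <- sum(dl)
  dU <- array(dl %*% t(p$out_W), dim(fw$last))
  for (l in seq_len(pl$d)) {          # decoders, shallowest first
    cc <- fw$cache[[paste0("dec", l)]]
    Hc <- cc$cat_dim[1]; Wc <- cc$cat_dim[2]
    b2 <- .conv_relu_bw(dU, cc$c2, p[[paste0("dec", l, "_W2")]], Hc, Wc,
                        dim(cc$c1$out)[3])
    g[[paste0("dec", l, "_W2")]] <- b2$dW
    g[[paste0("dec", l, "_b2")]] <- b2$db
    b1 <- .conv_relu_bw(b2$dX, cc$c1, p[[paste0("dec", l, "_W1")]], Hc, Wc,
                        cc$cat_dim[3])
    g[[paste0("dec", l, "_W1")]] <- b1$dW
    g[[paste0("dec", l, "_b1")]] <- b1$db
    n_up <- cc$up_in_dim[3]
    dup <- b1$dX[, , seq_len(n_up), drop = FALSE]
    dskip <- b1$dX[, , n_up + seq_len(cc$cat_dim[3] - n_up), drop = FALSE]
    dU <- .upsample_bw(dup, cc$up_in_dim)
    fw$cache[[paste0("enc", l)]]$dskip <- dskip
  }
  cc <- fw$cache$bott
  Hb <- cc$in_dim[1]; Wb <- cc$in_dim[2]
  b2 <- .conv_relu_bw(dU, cc$c2, p$bott_W2, Hb, Wb, dim(cc$c1$out)[3])
  g$bott_W2 <- b2$dW; g$bott_b2 <- b2$db
  b1 <- .conv_relu_bw(b2$dX, cc$c1, p$bott_W1, Hb, Wb, cc$in_dim[3])
  g$bott_W1 <- b1$dW; g$bott_b1 <- b1$db
  dX <- b1$dX
  for (l in rev(seq_len(pl$d))) {     # encoders, deepest first
    cc <- fw$cache[[paste0("enc", l)]]
    dpool <- .maxpool_bw(dX, cc$pool)
    dtot <- dpool + cc$dskip
    He <- cc$in_dim[1]; We <- cc$in_dim[2]
    b2 <- .conv_relu_bw(dtot, cc$c2, p[[paste0("enc", l, "_W2")]], He, We,
                        dim(cc$c1$out)[3])
    g[[paste0("enc", l, "_W2")]] <- b2$dW
    g[[paste0("enc", l, "_b2")]] <- b2$db
    b1 <- .conv_relu_bw(b2$dX, cc$c1, p[[paste0("enc", l, "_W1")]], He, We,
                        cc$in_dim[3])
    g[[paste0("enc", l, "_W1")]] <- b1$dW
    g[[paste0("enc", l, "_b1")]] <- b1$db
    dX <- b1$dX
  }
  g[names(p)]
}

.bce_with_logits <- function(logits, y) {
  n <- length(logits)
  loss <- mean(pmax(logits, 0) - logits * y + log1p(exp(-abs(logits))))
  dl <- (1 / (1 + exp(-logits)) - y) / n
  list(loss = loss, dlogits = dl)
}

.adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

.adam_step <- function(params, grads, opt, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (nm in names(params)) {
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * grads[[nm]]
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}
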