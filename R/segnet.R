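# 3-D residual U-Net for adrenal gland segmentation, implemented natively:
# forward and backward passes are hand-derived, with im2col+GEMM
# convolution kernels in C++ (see src/nn_ops.cpp) and instance
# normalisation, activations, losses and Adam in vectorised R.
#
# Tensors are channels-first arrays dim (C, X, Y, Z).

# ---- elementary layers ------------------------------------------------------

# Convolutions run as im2col + BLAS GEMM; the col matrix is computed once in
# the forward pass and cached for the backward pass.  1x1x1 stride-1 convs
# skip im2col entirely (the input matrix IS the col matrix).

conv_out_dims <- function(dims, k, stride, pad)
  c((dims[2:4] + 2L * pad - k) %/% stride + 1L)

conv_fw <- function(x, w, b, k, stride, pad) {
  d <- dim(x)
  col <- if (k == 1L && stride == 1L) matrix(x, nrow = d[1])
         else cpp_vol2col(x, d, k, stride, pad)
  y <- w %*% col + b
  dim(y) <- c(nrow(w), conv_out_dims(d, k, stride, pad))
  list(y = y, col = col, in_dims = d)
}

conv_bw <- function(cache, w, dout, k, stride, pad) {
  dm <- matrix(dout, nrow = nrow(w))
  dw <- tcrossprod(dm, cache$col)
  db <- rowSums(dm)
  dcol <- crossprod(w, dm)
  dx <- if (k == 1L && stride == 1L) { dim(dcol) <- cache$in_dims; dcol }
        else cpp_col2vol(dcol, cache$in_dims, k, stride, pad)
  list(dx = dx, dw = dw, db = db)
}

convt_fw <- function(x, w, b, k = 2L)
  cpp_convt3d_fw(if (is.double(x)) x else as.numeric(x), dim(x), w, b, k)

convt_bw <- function(x, w, dout, k = 2L)
  cpp_convt3d_bw(if (is.double(x)) x else as.numeric(x), dim(x), w,
                 if (is.double(dout)) dout else as.numeric(dout), k)

.IN_EPS <- 1e-5

inorm_fw <- function(x, gamma, beta) {
  d <- dim(x); C <- d[1]
  xm <- matrix(x, nrow = C)
  mu <- rowMeans(xm)
  xc <- xm - mu
  v <- rowMeans(xc * xc)
  istd <- 1 / sqrt(v + .IN_EPS)
  xhat <- xc * istd
  y <- xhat * gamma + beta
  dim(y) <- d
  list(y = y, xhat = xhat, istd = istd, dims = d)
}

inorm_bw <- function(cache, gamma, dy) {
  d <- cache$dims; C <- d[1]
  dym <- matrix(dy, nrow = C)
  xhat <- cache$xhat
  dgamma <- rowSums(dym * xhat)
  dbeta <- rowSums(dym)
  n <- ncol(dym)
  dxhat <- dym * gamma
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$istd
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_fw <- function(x) { x[x < 0] <- 0; x }
relu_bw <- function(y, dy) { dy[y <= 0] <- 0; dy }

he_w <- function(c_out, fan_in, taps) {
  matrix(stats::rnorm(c_out * fan_in * taps, 0, sqrt(2 / (fan_in * taps))),
         nrow = c_out)
}

# ---- units (residual / plain) ----------------------------------------------

init_unit <- function(c_in, c_out, stride, residual) {
  p <- list(w1 = he_w(c_out, c_in, 27), b1 = numeric(c_out),
            g1 = rep(1, c_out), be1 = numeric(c_out),
            w2 = he_w(c_out, c_out, 27), b2 = numeric(c_out),
            g2 = rep(1, c_out), be2 = numeric(c_out))
  if (residual && (stride != 1L || c_in != c_out)) {
    p$ws <- he_w(c_out, c_in, 1)
    p$bs <- numeric(c_out)
  }
  p
}

unit_fw <- function(x, p, stride, residual) {
  c1 <- conv_fw(x, p$w1, p$b1, 3L, stride, 1L)
  n1 <- inorm_fw(c1$y, p$g1, p$be1)
  r1 <- relu_fw(n1$y)
  c2 <- conv_fw(r1, p$w2, p$b2, 3L, 1L, 1L)
  n2 <- inorm_fw(c2$y, p$g2, p$be2)
  sc <- NULL
  if (residual) {
    if (!is.null(p$ws)) {
      sc <- conv_fw(x, p$ws, p$bs, 1L, stride, 0L)
      y <- relu_fw(n2$y + sc$y)
    } else {
      y <- relu_fw(n2$y + x)
    }
  } else {
    y <- relu_fw(n2$y)
  }
  list(y = y, cache = list(c1 = c1[-1], c2 = c2[-1], sc = if (!is.null(sc)) sc[-1],
                           n1 = n1, r1 = r1, n2 = n2, y = y,
                           stride = stride, residual = residual))
}

unit_bw <- function(dy, p, cache) {
  dy <- relu_bw(cache$y, dy)
  g <- list()
  dx_sc <- NULL
  if (cache$residual) {
    if (!is.null(cache$sc)) {
      bw_sc <- conv_bw(cache$sc, p$ws, dy, 1L, cache$stride, 0L)
      dx_sc <- bw_sc$dx; g$ws <- bw_sc$dw; g$bs <- bw_sc$db
    } else {
      dx_sc <- dy
    }
  }
  b2 <- inorm_bw(cache$n2, p$g2, dy)
  g$g2 <- b2$dgamma; g$be2 <- b2$dbeta
  bwc2 <- conv_bw(cache$c2, p$w2, b2$dx, 3L, 1L, 1L)
  g$w2 <- bwc2$dw; g$b2 <- bwc2$db
  dr1 <- relu_bw(cache$r1, bwc2$dx)
  b1 <- inorm_bw(cache$n1, p$g1, dr1)
  g$g1 <- b1$dgamma; g$be1 <- b1$dbeta
  bwc1 <- conv_bw(cache$c1, p$w1, b1$dx, 3L, cache$stride, 1L)
  g$w1 <- bwc1$dw; g$b1 <- bwc1$db
  dx <- bwc1$dx
  if (!is.null(dx_sc)) dx <- dx + dx_sc
  list(dx = dx, grads = g)
}

# ---- model ------------------------------------------------------------------

#' Build a 3-D (residual) U-Net segmentation model
#'
#' Symmetric encoder-decoder: one unit per encoder level with stride-2
#' downsampling between levels, transposed-convolution upsampling, skip
#' concatenation, and a final 1x1x1 convolution with per-voxel softmax over
#' `n_classes` (background / left gland / right gland by default).  With
#' `residual = TRUE` every unit carries an identity (or 1x1x1 projection)
#' shortcut; with `residual = FALSE` units are plain two-convolution blocks
#' (the classical 3-D U-Net baseline).  Normalisation is instance-style,
#' robust at batch size 1-2.
#'
#' @param channel_plan strictly increasing encoder channel counts, default
#'   `c(32, 64, 128, 256, 512)`.
#' @param n_classes output channels (default 3).
#' @param residual use residual units.
#' @param seed weight-initialisation seed.
#' @return A `SegModel` object.
#' @export
build_model <- function(channel_plan = c(32, 64, 128, 256, 512),
                        n_classes = 3L, residual = TRUE, seed = 1) {
  channel_plan <- as.integer(channel_plan)
  if (length(channel_plan) < 2L || any(diff(channel_plan) <= 0))
    stop("channel_plan must be strictly increasing with length >= 2")
  set.seed(seed)
  L <- length(channel_plan)
  params <- list()
  for (l in seq_len(L)) {
    c_in <- if (l == 1L) 1L else channel_plan[l - 1]
    params[[paste0("enc", l)]] <-
      init_unit(c_in, channel_plan[l], if (l == 1L) 1L else 2L, residual)
  }
  for (l in rev(seq_len(L - 1))) {
    cu <- channel_plan[l + 1]; cl <- channel_plan[l]
    params[[paste0("up", l)]] <- list(
      w = matrix(stats::rnorm(cu * cl * 8, 0, sqrt(2 / cu)), nrow = cu),
      b = numeric(cl))
    params[[paste0("dec", l)]] <- init_unit(2L * cl, cl, 1L, residual)
  }
  params$head <- list(w = he_w(n_classes, channel_plan[1], 1),
                      b = numeric(n_classes))
  structure(list(channel_plan = channel_plan, n_classes = as.integer(n_classes),
                 residual = residual, params = params),
            class = "SegModel")
}

#' @export
print.SegModel <- function(x, ...) {
  cat(sprintf("<SegModel> 3D %sU-Net, channels (%s), %d classes, %s parameters\n",
              if (x$residual) "Res-" else "", paste(x$channel_plan, collapse = ","),
              x$n_classes, format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Number of learnable parameters
#' @param model a `SegModel`.
#' @return integer count.
#' @export
n_parameters <- function(model) {
  sum(vapply(rapply(model$params, length, how = "unlist"), identity,
             numeric(1)))
}

seg_forward <- function(model, x, keep_cache = FALSE) {
  if (length(dim(x)) == 3L) {
    dim(x) <- c(1L, dim(x))
  }
  L <- length(model$channel_plan)
  lvl <- 2^(L - 1)
  if (any(dim(x)[2:4] %% lvl != 0))
    stop("input spatial dims must be divisible by ", lvl)
  p <- model$params
  caches <- list()
  skips <- list()
  h <- x
  for (l in seq_len(L)) {
    u <- unit_fw(h, p[[paste0("enc", l)]], if (l == 1L) 1L else 2L,
                 model$residual)
    h <- u$y
    if (l < L) skips[[l]] <- h
    caches[[paste0("enc", l)]] <- u$cache
  }
  for (l in rev(seq_len(L - 1))) {
    upn <- paste0("up", l)
    up <- convt_fw(h, p[[upn]]$w, p[[upn]]$b)
    caches[[upn]] <- list(x = h)
    cat_in <- abind2(up, skips[[l]])
    u <- unit_fw(cat_in, p[[paste0("dec", l)]], 1L, model$residual)
    caches[[paste0("dec", l)]] <- u$cache
    h <- u$y
  }
  hd <- conv_fw(h, p$head$w, p$head$b, 1L, 1L, 0L)
  logits <- hd$y
  caches$head <- hd[-1]
  probs <- softmax_c(logits)
  list(probs = probs, logits = logits,
       caches = if (keep_cache) caches else NULL)
}

# concatenate two (C,X,Y,Z) tensors along channels
abind2 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1] + db[1], da[2], da[3], da[4]))
  am <- matrix(a, nrow = da[1]); bm <- matrix(b, nrow = db[1])
  outm <- rbind(am, bm)
  dim(outm) <- dim(out)
  outm
}

softmax_c <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, nrow = d[1])
  m <- exp(sweep(m, 2, apply(m, 2, max)))
  m <- sweep(m, 2, colSums(m), `/`)
  dim(m) <- d
  m
}

seg_backward <- function(model, caches, dlogits) {
  L <- length(model$channel_plan)
  p <- model$params
  grads <- list()
  bw <- conv_bw(caches$head, p$head$w, dlogits, 1L, 1L, 0L)
  grads$head <- list(w = bw$dw, b = bw$db)
  dh <- bw$dx
  for (l in seq_len(L - 1)) {
    u <- unit_bw(dh, p[[paste0("dec", l)]], caches[[paste0("dec", l)]])
    grads[[paste0("dec", l)]] <- u$grads
    # split concat gradient into upsampled part and skip part
    cu <- dim(u$dx)[1] %/% 2L
    dm <- matrix(u$dx, nrow = dim(u$dx)[1])
    dup <- dm[seq_len(cu), , drop = FALSE]
    dskip <- dm[cu + seq_len(cu), , drop = FALSE]
    sd4 <- c(cu, dim(u$dx)[2:4])
    dim(dup) <- sd4; dim(dskip) <- sd4
    upn <- paste0("up", l)
    bwu <- convt_bw(caches[[upn]]$x, p[[upn]]$w, dup)
    grads[[upn]] <- list(w = bwu$dw, b = bwu$db)
    dh <- bwu$dx
    # gradient flowing into encoder level l via the skip connection
    grads[[paste0("skipg", l)]] <- dskip
  }
  for (l in rev(seq_len(L))) {
    if (l < L) dh <- dh + grads[[paste0("skipg", l)]]
    grads[[paste0("skipg", l)]] <- NULL
    u <- unit_bw(dh, p[[paste0("enc", l)]], caches[[paste0("enc", l)]])
    grads[[paste0("enc", l)]] <- u$grads
    dh <- u$dx
  }
  grads
}

# ---- losses -----------------------------------------------------------------

as_prob_tensor <- function(probs) {
  if (length(dim(probs)) != 4L)
    stop("probs must be a (C, X, Y, Z) array")
  probs
}

check_aligned <- function(probs, target) {
  if (!all(dim(probs)[2:4] == dim(target)))
    stop("probability map and target shapes do not match: ",
         paste(dim(probs)[2:4], collapse = "x"), " vs ",
         paste(dim(target), collapse = "x"))
}

target_onehot <- function(target, n_classes) {
  tm <- matrix(0, nrow = n_classes, ncol = length(target))
  tm[cbind(as.integer(target) + 1L, seq_along(target))] <- 1
  tm
}

#' Soft Dice loss
#'
#' `1 - mean_c (2 sum(p_c t_c) + eps) / (sum p_c + sum t_c + eps)` over the
#' foreground classes present in the target.  Classes with an empty target
#' are excluded from the mean and contribute no loss (so all-background
#' patches have Dice loss 0 and are driven purely by the focal term);
#' this keeps empty-target classes from dominating the gradient.
#'
#' @param probs per-class probability array `(C, X, Y, Z)`.
#' @param target integer array of class labels `0..C-1`, same spatial dims.
#' @param eps smoothing constant.
#' @return scalar loss in \[0, 1\].
#' @export
dice_loss <- function(probs, target, eps = 1e-5) {
  dice_loss_grad(probs, target, eps, want_grad = FALSE)$loss
}

dice_loss_grad <- function(probs, target, eps = 1e-5, want_grad = TRUE) {
  probs <- as_prob_tensor(probs)
  check_aligned(probs, target)
  C <- dim(probs)[1]
  pm <- matrix(probs, nrow = C)
  tm <- target_onehot(target, C)
  fg <- 2:C
  use <- fg[rowSums(tm[fg, , drop = FALSE]) > 0]
  if (!length(use)) {
    grad <- NULL
    if (want_grad) grad <- array(0, dim(probs))
    return(list(loss = 0, grad = grad))
  }
  num <- 2 * rowSums(pm[use, , drop = FALSE] * tm[use, , drop = FALSE]) + eps
  den <- rowSums(pm[use, , drop = FALSE]) + rowSums(tm[use, , drop = FALSE]) + eps
  dice <- num / den
  loss <- 1 - mean(dice)
  grad <- NULL
  if (want_grad) {
    gm <- matrix(0, nrow = C, ncol = ncol(pm))
    K <- length(use)
    # d dice_c / d p_c(v) = (2 t_c(v) * den - num) / den^2
    gm[use, ] <- -(2 * tm[use, , drop = FALSE] * den - num) / (den^2) / K
    dim(gm) <- dim(probs)
    grad <- gm
  }
  list(loss = loss, grad = grad)
}

#' Focal loss
#'
#' Mean over voxels of `-alpha (1 - p_t)^gamma log(p_t)`, where `p_t` is the
#' predicted probability of the true class, floored at 1e-7 for stability.
#' At `gamma = 0`, `alpha = 1` this reduces to mean cross-entropy.
#'
#' @inheritParams dice_loss
#' @param gamma focusing exponent (>= 0).
#' @param alpha class weight.
#' @return scalar loss (>= 0).
#' @export
focal_loss <- function(probs, target, gamma = 2, alpha = 1) {
  focal_loss_grad(probs, target, gamma, alpha, want_grad = FALSE)$loss
}

.PT_FLOOR <- 1e-7

focal_loss_grad <- function(probs, target, gamma = 2, alpha = 1,
                            want_grad = TRUE) {
  stopifnot(gamma >= 0)
  probs <- as_prob_tensor(probs)
  check_aligned(probs, target)
  C <- dim(probs)[1]
  pm <- matrix(probs, nrow = C)
  n <- ncol(pm)
  idx <- cbind(as.integer(target) + 1L, seq_len(n))
  pt <- pmax(pm[idx], .PT_FLOOR)
  loss <- mean(-alpha * (1 - pt)^gamma * log(pt))
  grad <- NULL
  if (want_grad) {
    gpt <- alpha * (gamma * (1 - pt)^(pmax(gamma - 1, 0)) * log(pt) -
                      (1 - pt)^gamma / pt) / n
    gpt[pm[idx] < .PT_FLOOR] <- 0
    gm <- matrix(0, nrow = C, ncol = n)
    gm[idx] <- gpt
    dim(gm) <- dim(probs)
    grad <- gm
  }
  list(loss = loss, grad = grad)
}

combined_loss_grad <- function(probs, target, config) {
  dl <- dice_loss_grad(probs, target)
  fl <- focal_loss_grad(probs, target, config$focal_gamma, config$focal_alpha)
  w <- config$loss_weights
  list(loss = w[1] * dl$loss + w[2] * fl$loss,
       grad = w[1] * dl$grad + w[2] * fl$grad)
}

# chain rule through the softmax: dlogits = p * (dLdp - sum_c p_c dLdp_c)
softmax_backprop <- function(probs, dLdp) {
  C <- dim(probs)[1]
  pm <- matrix(probs, nrow = C)
  gm <- matrix(dLdp, nrow = C)
  inner <- colSums(pm * gm)
  out <- pm * sweep(gm, 2, inner)
  dim(out) <- dim(probs)
  out
}

# ---- training ---------------------------------------------------------------

#' Training configuration
#'
#' Defaults follow the published schedule: Adam, initial learning rate
#' 3e-4, decayed to 0.9 times the previous rate every 20 epochs.  The loss
#' is the unweighted sum of Dice and focal terms (`gamma` = 2, `alpha` = 1).
#'
#' @param lr0 initial learning rate.
#' @param epochs training epochs (published run: 200).
#' @param decay_factor,decay_every learning-rate schedule:
#'   `lr(e) = lr0 * decay_factor^floor(e / decay_every)`.
#' @param loss_weights `(w_dice, w_focal)`, non-negative, not both zero.
#' @param focal_gamma,focal_alpha focal-loss parameters.
#' @param batch_size patches per optimiser step.
#' @param patches_per_epoch sampled (and augmented) patches per epoch.
#' @param augment apply training-time augmentation.
#' @param valid_patches_per_volume patches used for the per-epoch
#'   validation loss.
#' @param seed integer.
#' @return A `TrainConfig` list.
#' @export
train_config <- function(lr0 = 3e-4, epochs = 200, decay_factor = 0.9,
                         decay_every = 20, loss_weights = c(1, 1),
                         focal_gamma = 2, focal_alpha = 1, batch_size = 2,
                         patches_per_epoch = 20, augment = TRUE,
                         valid_patches_per_volume = 1, seed = 1) {
  stopifnot(lr0 > 0, decay_factor > 0, decay_factor < 1,
            all(loss_weights >= 0), sum(loss_weights) > 0, epochs >= 1)
  structure(list(lr0 = lr0, epochs = as.integer(epochs),
                 decay_factor = decay_factor,
                 decay_every = as.integer(decay_every),
                 loss_weights = loss_weights, focal_gamma = focal_gamma,
                 focal_alpha = focal_alpha, batch_size = as.integer(batch_size),
                 patches_per_epoch = as.integer(patches_per_epoch),
                 augment = isTRUE(augment),
                 valid_patches_per_volume = as.integer(valid_patches_per_volume),
                 seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Learning rate at a given epoch
#' @param epoch 1-based epoch index.
#' @param config a [train_config()].
#' @return numeric learning rate `lr0 * decay^floor(epoch / decay_every)`.
#' @export
lr_at_epoch <- function(epoch, config = train_config()) {
  config$lr0 * config$decay_factor^(epoch %/% config$decay_every)
}

adam_init <- function(params)
  rapply(params, function(p) p * 0, how = "replace")

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(pn) {
    p <- params[[pn]]
    for (nm in names(p)) {
      g <- grads[[pn]][[nm]]
      state$m[[pn]][[nm]] <<- beta1 * state$m[[pn]][[nm]] + (1 - beta1) * g
      state$v[[pn]][[nm]] <<- beta2 * state$v[[pn]][[nm]] + (1 - beta2) * g * g
      mhat <- state$m[[pn]][[nm]] / (1 - beta1^t)
      vhat <- state$v[[pn]][[nm]] / (1 - beta2^t)
      params[[pn]][[nm]] <<- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      p <- params[[pn]]
    }
  }
  for (pn in names(params)) walk(pn)
  list(params = params, state = state)
}

scale_grads <- function(grads, s)
  rapply(grads, function(g) g * s, how = "replace")

add_grads <- function(a, b) {
  for (pn in names(a)) for (nm in names(a[[pn]]))
    a[[pn]][[nm]] <- a[[pn]][[nm]] + b[[pn]][[nm]]
  a
}

patch_loss_and_grads <- function(model, img, msk, config) {
  fwd <- seg_forward(model, img, keep_cache = TRUE)
  lg <- combined_loss_grad(fwd$probs, msk, config)
  dlogits <- softmax_backprop(fwd$probs, lg$grad)
  grads <- seg_backward(model, fwd$caches, dlogits)
  list(loss = lg$loss, grads = grads)
}

#' Train a segmentation model
#'
#' Optimises `w_dice * dice_loss + w_focal * focal_loss` with Adam on
#' randomly sampled, optionally augmented patches; records per-epoch
#' training and validation loss and retains the parameters of the epoch
#' with the lowest validation loss (checkpoint flag in the history).
#' Aborts with a diagnostic naming the epoch if the loss becomes
#' non-finite.
#'
#' @param model a [build_model()] `SegModel`.
#' @param train_set,valid_set lists of `list(volume, mask)` pairs,
#'   already preprocessed ([preprocess_volume()]).
#' @param config a [train_config()].
#' @param pre_config a [preprocess_config()] (patch size, foreground bias,
#'   augmentation strengths).
#' @param verbose print a log line per epoch.
#' @return `list(model, history)`; `history` is a data.frame with columns
#'   epoch, train_loss, valid_loss, lr, checkpoint.
#' @export
train_segmodel <- function(model, train_set, valid_set, config = train_config(),
                           pre_config = preprocess_config(), verbose = FALSE) {
  stopifnot(length(train_set) >= 1)
  seeds <- derive_seeds(config$seed, config$epochs + 1L, salt = 17L)
  # fixed validation patches for comparable per-epoch losses
  valid_patches <- list()
  if (length(valid_set)) {
    vp_cfg <- pre_config; vp_cfg$foreground_bias <- 1
    for (i in seq_along(valid_set))
      valid_patches <- c(valid_patches,
                         sample_patches(valid_set[[i]]$volume,
                                        valid_set[[i]]$mask, vp_cfg,
                                        n = config$valid_patches_per_volume,
                                        seed = seeds[config$epochs + 1L] + i))
  }
  state <- list(m = adam_init(model$params), v = adam_init(model$params))
  hist <- vector("list", config$epochs)
  best <- Inf; best_params <- model$params; t_step <- 0L
  for (e in seq_len(config$epochs)) {
    lr <- lr_at_epoch(e, config)
    set.seed(seeds[e])
    vol_idx <- sample.int(length(train_set), config$patches_per_epoch,
                          replace = TRUE)
    patch_seeds <- sample.int(.Machine$integer.max %/% 2,
                              config$patches_per_epoch)
    losses <- numeric(config$patches_per_epoch)
    i <- 1L
    while (i <= config$patches_per_epoch) {
      bsz <- min(config$batch_size, config$patches_per_epoch - i + 1L)
      acc <- NULL
      for (j in seq_len(bsz)) {
        k <- i + j - 1L
        rec <- train_set[[vol_idx[k]]]
        pp <- sample_patches(rec$volume, rec$mask, pre_config, n = 1,
                             seed = patch_seeds[k])[[1]]
        if (config$augment)
          pp <- augment(pp, pre_config, seed = patch_seeds[k] + 1L)
        res <- patch_loss_and_grads(model, pp$image, pp$mask, config)
        losses[k] <- res$loss
        acc <- if (is.null(acc)) res$grads else add_grads(acc, res$grads)
      }
      if (any(!is.finite(losses[i:(i + bsz - 1L)])))
        stop("training diverged (non-finite loss) at epoch ", e)
      acc <- scale_grads(acc, 1 / bsz)
      t_step <- t_step + 1L
      upd <- adam_step(model$params, acc, state, lr, t_step)
      model$params <- upd$params; state <- upd$state
      i <- i + bsz
    }
    train_loss <- mean(losses)
    valid_loss <- NA_real_
    if (length(valid_patches)) {
      vl <- vapply(valid_patches, function(pp) {
        fwd <- seg_forward(model, pp$image)
        combined_loss_grad(fwd$probs, pp$mask, config)$loss
      }, numeric(1))
      valid_loss <- mean(vl)
    }
    crit <- if (is.na(valid_loss)) train_loss else valid_loss
    ckpt <- crit < best
    if (ckpt) { best <- crit; best_params <- model$params }
    hist[[e]] <- data.frame(epoch = e, train_loss = train_loss,
                            valid_loss = valid_loss, lr = lr,
                            checkpoint = ckpt)
    if (verbose)
      message(sprintf("epoch %3d  lr %.3e  train %.4f  valid %.4f%s",
                      e, lr, train_loss, valid_loss,
                      if (ckpt) "  *" else ""))
  }
  model$params <- best_params
  list(model = model, history = do.call(rbind, hist))
}

# ---- inference --------------------------------------------------------------

#' Sliding-window inference
#'
#' Tiles the volume into patches of `patch_size` with the given fractional
#' overlap, predicts each patch, and averages probabilities where tiles
#' overlap.  Volumes smaller than the patch are padded and the output
#' cropped back.
#'
#' @param model a `SegModel`.
#' @param volume preprocessed `CTVolume`.
#' @param patch_size voxel triple, each divisible by
#'   `2^(length(channel_plan) - 1)`.
#' @param overlap fractional tile overlap in \[0, 0.9\].
#' @return `list(probs, mask)`: the per-class probability array
#'   `(C, X, Y, Z)` and the argmax `LabelMask`.
#' @export
sliding_window_infer <- function(model, volume, patch_size = c(96, 96, 96),
                                 overlap = 0.25) {
  stopifnot(inherits(volume, "CTVolume"), overlap >= 0, overlap <= 0.9)
  patch_size <- as.integer(patch_size)
  dims <- dim(volume$voxels)
  pad <- pad_to_size(volume$voxels, patch_size, 0)
  pdims <- dim(pad$arr)
  C <- model$n_classes
  starts <- lapply(1:3, function(a) {
    step <- max(1L, as.integer(ceiling(patch_size[a] * (1 - overlap))))
    s <- unique(c(seq(1L, pdims[a] - patch_size[a] + 1L, by = step),
                  pdims[a] - patch_size[a] + 1L))
    as.integer(s)
  })
  acc <- array(0, dim = c(C, pdims))
  cnt <- array(0, dim = pdims)
  for (sx in starts[[1]]) for (sy in starts[[2]]) for (sz in starts[[3]]) {
    ix <- sx + seq_len(patch_size[1]) - 1L
    iy <- sy + seq_len(patch_size[2]) - 1L
    iz <- sz + seq_len(patch_size[3]) - 1L
    probs <- seg_forward(model, pad$arr[ix, iy, iz, drop = FALSE])$probs
    acc[, ix, iy, iz] <- acc[, ix, iy, iz] + probs
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
  }
  acc <- sweep(acc, 2:4, cnt, `/`)
  ix <- pad$offset[1] + seq_len(dims[1])
  iy <- pad$offset[2] + seq_len(dims[2])
  iz <- pad$offset[3] + seq_len(dims[3])
  probs <- acc[, ix, iy, iz, drop = FALSE]
  lab <- array(max.col(t(matrix(probs, nrow = C)), ties.method = "first") - 1L,
               dim = dims)
  list(probs = probs,
       mask = label_mask(lab, volume$spacing, volume$orientation,
                         volume$origin, strict = C <= 3))
}

#' Save / load a model checkpoint
#'
#' Checkpoints bundle weights, configuration and training history in one
#' run-time archive.
#'
#' @param model `SegModel`.
#' @param path file path.
#' @param history,config optional objects stored alongside the weights.
#' @return `path` (save) or the checkpoint list (load).
#' @export
save_checkpoint <- function(model, path, history = NULL, config = NULL) {
  saveRDS(list(model = model, history = history, config = config), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
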