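tiny_model <- function(residual = TRUE, seed = 1)
  build_model(c(4, 8), n_classes = 3, residual = residual, seed = seed)

test_that("model output has the input shape with valid probabilities", {
  m <- tiny_model()
  x <- array(stats::runif(8 * 8 * 8), c(8, 8, 8))
  fwd <- adrenalseg:::seg_forward(m, x)
  expect_equal(dim(fwd$probs), c(3, 8, 8, 8))
  sums <- colSums(matrix(fwd$probs, nrow = 3))
  expect_lt(max(abs(sums - 1)), 1e-5)
  expect_error(build_model(c(8, 8)), "strictly increasing")
  expect_error(adrenalseg:::seg_forward(m, array(0, c(7, 8, 8))), "divisible")
})

test_that("capacity grows with the channel plan", {
  expect_lt(n_parameters(build_model(c(8, 16, 32), seed = 1)),
            n_parameters(build_model(c(32, 64, 128), seed = 1)))
  # plain units drop the projection shortcuts
  expect_lt(n_parameters(build_model(c(4, 8), residual = FALSE, seed = 1)),
            n_parameters(build_model(c(4, 8), residual = TRUE, seed = 1)))
})

test_that("dice loss matches its closed forms", {
  # uniform 1/3 prediction, one foreground class covering half the patch
  n <- c(4, 4, 4)
  probs <- array(1 / 3, c(3, n))
  target <- array(0L, n); target[1:2, , ] <- 1L
  expect_equal(dice_loss(probs, target), 0.6, tolerance = 1e-4)
  # perfect one-hot prediction
  onehot <- array(0, c(3, n))
  for (k in 0:2) onehot[k + 1, , , ][target == k] <- 1
  expect_lt(dice_loss(onehot, target), 1e-4)
  # empty-target foreground classes are excluded and contribute no loss
  p2 <- array(c(0.999, 1e-3 / 2, 1e-3 / 2), c(3, n))
  expect_identical(dice_loss(p2, array(0L, n)), 0)
  # with one class present, the empty class is excluded from the mean
  mixed <- array(0L, n); mixed[1, 1, 1] <- 1L
  eps <- 1e-5
  p_cls1 <- 1e-3 / 2
  want <- 1 - (2 * p_cls1 + eps) / (prod(n) * p_cls1 + 1 + eps)
  expect_equal(dice_loss(mixed_probs <- p2, mixed), want, tolerance = 1e-12)
  expect_error(dice_loss(probs, array(0L, c(2, 2, 2))), "match")
})

test_that("focal loss reduces to cross-entropy at gamma 0 and obeys the closed form", {
  set.seed(2)
  n <- c(4, 4, 2)
  logits <- array(stats::rnorm(3 * prod(n)), c(3, n))
  probs <- adrenalseg:::softmax_c(logits)
  target <- array(sample(0:2, prod(n), TRUE), n)
  pm <- matrix(probs, nrow = 3)
  ce <- -mean(log(pm[cbind(as.integer(target) + 1L, seq_len(prod(n)))]))
  expect_equal(focal_loss(probs, target, gamma = 0, alpha = 1), ce,
               tolerance = 1e-9)
  # single voxel, p_t = 0.5, gamma 2: -0.25 log(0.5)
  p1 <- array(c(0.5, 0.3, 0.2), c(3, 1, 1, 1))
  expect_equal(focal_loss(p1, array(0L, c(1, 1, 1)), gamma = 2, alpha = 1),
               -0.25 * log(0.5), tolerance = 1e-12)
  # confident-correct limit
  expect_lt(focal_loss(array(c(1 - 2e-7, 1e-7, 1e-7), c(3, 1, 1, 1)),
                       array(0L, c(1, 1, 1)), 2, 1), 1e-10)
})

test_that("analytic gradients agree with finite differences", {
  m <- tiny_model(seed = 3)
  x <- array(stats::runif(8 * 8 * 8), c(8, 8, 8))
  target <- array(sample(0:2, 512, TRUE), c(8, 8, 8))
  cfg <- train_config()
  res <- adrenalseg:::patch_loss_and_grads(m, x, target, cfg)
  f <- function(params) {
    m2 <- m; m2$params <- params
    fwd <- adrenalseg:::seg_forward(m2, x)
    adrenalseg:::combined_loss_grad(fwd$probs, target, cfg)$loss
  }
  set.seed(4)
  for (pn in c("enc1", "enc2", "up1", "dec1", "head")) {
    nm <- sample(names(m$params[[pn]]), 1)
    i <- sample(length(m$params[[pn]][[nm]]), 1)
    eps <- 1e-5
    pp <- m$params; pp[[pn]][[nm]][i] <- pp[[pn]][[nm]][i] + eps
    pm_ <- m$params; pm_[[pn]][[nm]][i] <- pm_[[pn]][[nm]][i] - eps
    num <- (f(pp) - f(pm_)) / (2 * eps)
    ana <- res$grads[[pn]][[nm]][i]
    expect_lt(abs(num - ana), 1e-5 * max(1, abs(num)))
  }
})

test_that("the learning-rate schedule follows lr0 * 0.9^floor(e/20)", {
  cfg <- train_config()
  expect_identical(lr_at_epoch(40, cfg), 3e-4 * 0.9^2)
  expect_identical(lr_at_epoch(1, cfg), 3e-4)
  expect_identical(lr_at_epoch(19, cfg), 3e-4)
  expect_identical(lr_at_epoch(65, cfg), 3e-4 * 0.9^3)
})

test_that("training memorises a single patch (loss < 0.2 of initial)", {
  rec <- fixture("rec1", function() make_phantom_record(1))
  img <- rec$volume$voxels[9:24, 17:32, 5:12]
  msk <- rec$mask$voxels[9:24, 17:32, 5:12]
  expect_gt(sum(msk > 0), 0)
  vol <- ct_volume(img, rec$volume$spacing)
  mask <- label_mask(msk, rec$mask$spacing)
  pre <- preprocess_config(patch_size = dim(img), foreground_bias = 1)
  cfg <- train_config(lr0 = 5e-3, epochs = 100, patches_per_epoch = 1,
                      batch_size = 1, augment = FALSE, seed = 1)
  m <- build_model(c(8, 16), n_classes = 3, seed = 5)
  fit <- train_segmodel(m, list(list(volume = vol, mask = mask)),
                        list(), cfg, pre)
  h <- fit$history
  expect_lt(h$train_loss[100], 0.2 * h$train_loss[1])
  expect_true(all(h$lr == lr_at_epoch(h$epoch, cfg)))
})

test_that("training is deterministic and checkpoints on improved loss", {
  rec <- fixture("rec1", function() make_phantom_record(1))
  pre <- preprocess_config(patch_size = c(16, 16, 8), foreground_bias = 1)
  cfg <- train_config(epochs = 3, patches_per_epoch = 2, batch_size = 2,
                      seed = 11)
  run <- function() train_segmodel(tiny_model(seed = 2),
                                   list(rec), list(rec), cfg, pre)
  a <- run(); b <- run()
  expect_identical(a$history, b$history)
  expect_identical(a$model$params$head$w, b$model$params$head$w)
  # checkpoint flag true exactly when validation loss improves
  prev_best <- c(Inf, utils::head(cummin(a$history$valid_loss), -1))
  expect_identical(a$history$checkpoint, a$history$valid_loss < prev_best)
})

test_that("sliding-window inference tiles, blends and pads correctly", {
  m <- tiny_model(seed = 6)
  # single-tile volume equals the direct forward pass
  v <- ct_volume(array(stats::runif(16 * 16 * 8), c(16, 16, 8)))
  direct <- adrenalseg:::seg_forward(m, v$voxels)$probs
  sw <- sliding_window_infer(m, v, c(16, 16, 8), overlap = 0)
  expect_lt(max(abs(sw$probs - direct)), 1e-6)
  # overlapping tiles still give per-voxel probabilities summing to 1
  v2 <- ct_volume(array(stats::runif(24 * 16 * 8), c(24, 16, 8)))
  sw2 <- sliding_window_infer(m, v2, c(16, 16, 8), overlap = 0.5)
  sums <- colSums(matrix(sw2$probs, nrow = 3))
  expect_lt(max(abs(sums - 1)), 1e-5)
  # exact 2-tile coverage along the long axis
  v3 <- ct_volume(array(0, c(16, 16, 16)))
  sw3 <- sliding_window_infer(m, v3, c(16, 16, 8), overlap = 0)
  expect_equal(dim(sw3$mask$voxels), c(16, 16, 16))
  # volume smaller than the patch is padded and cropped back
  v4 <- ct_volume(array(stats::runif(8 * 8 * 4), c(8, 8, 4)))
  sw4 <- sliding_window_infer(m, v4, c(16, 16, 8))
  expect_equal(dim(sw4$mask$voxels), c(8, 8, 4))
})

test_that("a non-finite loss aborts with the epoch named", {
  rec <- fixture("rec1", function() make_phantom_record(1))
  pre <- preprocess_config(patch_size = c(16, 16, 8), foreground_bias = 1)
  cfg <- train_config(epochs = 2, patches_per_epoch = 1, batch_size = 1,
                      seed = 1)
  m <- tiny_model(seed = 1)
  m$params$head$w[] <- NaN   # corrupt weights: loss is non-finite at once
  expect_error(train_segmodel(m, list(rec), list(), cfg, pre),
               "epoch 1")
})
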