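tiny_cfg <- function() unet_config(depth = 2L, base_features = 2L,
                                   input_shape = c(16L, 16L, 8L))

tiny_samples <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    m <- array(0L, c(16, 16, 8))
    c0 <- c(sample(5:12, 1), sample(5:12, 1), sample(3:6, 1))
    w <- arrayInd(seq_len(prod(dim(m))), dim(m))
    m[rowSums(sweep(w, 2, c0)^2) <= 9] <- 1L
    v <- m * 2 + array(rnorm(prod(dim(m)), 0, 0.3), dim(m))
    list(volume = v, mask = m)
  })
}

test_that("build_unet enforces the shape contract and feature doubling", {
  set.seed(1)
  m <- build_unet(tiny_cfg())
  expect_equal(dim(m$weights$enc1_conv1_W), c(3, 3, 3, 1, 2))
  expect_equal(dim(m$weights$enc2_conv1_W), c(3, 3, 3, 2, 4))
  # depth 5 / base 32 reaches 512 maps at the deepest level
  cfg5 <- unet_config(depth = 5, base_features = 32,
                      input_shape = c(48, 48, 24))
  expect_error(build_unet(cfg5), "not divisible by 16")
  cfg5b <- unet_config(depth = 5, base_features = 32,
                       input_shape = c(64, 64, 32))
  set.seed(1)
  m5 <- build_unet(cfg5b)
  expect_equal(dim(m5$weights$enc5_conv2_W)[5], 512)
  expect_error(onquant:::check_unet_shape(c(60, 64, 32), 5), "axis x")
})

test_that("the network maps input shape to output shape with values in [0,1]", {
  set.seed(2)
  m <- build_unet(tiny_cfg())
  x <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  res <- onquant:::unet_forward(m, x)
  expect_length(res$pred, 16 * 16 * 8)
  expect_true(all(res$pred >= 0 & res$pred <= 1))
})

test_that("dice_loss follows its closed form", {
  a <- array(0, c(4, 4, 2)); a[1:8] <- 1
  expect_lt(dice_loss(a, a), 0.1)          # eps-limited near 0
  b <- array(0, c(4, 4, 2)); b[9:16] <- 1
  expect_gt(dice_loss(a, b), 0.9)          # disjoint: near 1
  # |pred|=|target|=n with overlap n/2 -> 0.5 (eps -> 0)
  n <- 16
  p <- array(0, c(8, 8, 2)); p[1:n] <- 1
  t <- array(0, c(8, 8, 2)); t[(n / 2 + 1):(3 * n / 2)] <- 1
  expect_equal(dice_loss(p, t, eps = 0), 0.5)
  expect_error(dice_loss(array(0, c(2, 2, 2)), array(0, c(2, 2, 4))),
               "shape")
})

test_that("dice_loss equals 1 - dsc for binary predictions (eps -> 0)", {
  for (seed in 1:5) {
    pr <- random_mask_pair(seed)
    expect_equal(dice_loss(pr$A$voxels, pr$B$voxels, eps = 0),
                 1 - dsc(pr$A, pr$B), tolerance = 1e-12)
  }
})

test_that("augmentation honors probabilities, involution and determinism", {
  s <- tiny_samples(1, seed = 3)[[1]]
  cfg_off <- train_config()
  cfg_off$augment[c("scale_p", "flip_p", "shift_p", "noise_p",
                    "blur_p")] <- 0
  out <- augment(s, cfg_off, seed = 1)
  expect_identical(out$volume, s$volume)
  expect_identical(out$mask, s$mask)

  cfg_flip <- cfg_off
  cfg_flip$augment$flip_p <- 1
  f1 <- augment(s, cfg_flip, seed = 1)
  f2 <- augment(f1, cfg_flip, seed = 1)
  expect_identical(f2$volume, s$volume)

  cfg_all <- train_config()
  a1 <- augment(s, cfg_all, seed = 99)
  a2 <- augment(s, cfg_all, seed = 99)
  expect_identical(a1$volume, a2$volume)
  expect_identical(a1$mask, a2$mask)
  expect_true(all(a1$mask %in% c(0L, 1L)))
})

test_that("train_config validates probabilities and patience", {
  expect_error(train_config(early_stop_patience = 200, max_epochs = 150),
               "patience")
  bad <- train_config()
  expect_error(train_config(augment = modifyList(bad$augment,
                                                 list(flip_p = 1.5))),
               "probabilities")
})

test_that("early stopping counts epochs without improvement", {
  set.seed(4)
  m <- build_unet(tiny_cfg())
  s <- tiny_samples(2, seed = 4)
  # lr = 0: the validation loss never changes after epoch 1
  cfg <- train_config(lr = 0, max_epochs = 10, early_stop_patience = 2,
                      seed = 5)
  fit <- train_unet(m, s[1], s[2], cfg, use_augment = FALSE)
  expect_equal(nrow(fit$history), 3)  # 1 improvement + 2 flat epochs
  expect_equal(fit$best_epoch, 1)
  expect_error(train_unet(m, list(), s, cfg), "non-empty")
})

test_that("seeded training is bit-reproducible", {
  set.seed(6)
  m <- build_unet(tiny_cfg())
  s <- tiny_samples(3, seed = 6)
  cfg <- train_config(max_epochs = 2, early_stop_patience = 2, seed = 7)
  f1 <- train_unet(m, s[1:2], s[3], cfg)
  f2 <- train_unet(m, s[1:2], s[3], cfg)
  expect_identical(f1$history$val_loss, f2$history$val_loss)
  expect_identical(f1$model$weights, f2$model$weights)
})

test_that("a few epochs on blob samples reach useful overlap", {
  set.seed(8)
  m <- build_unet(tiny_cfg())
  s <- tiny_samples(6, seed = 8)
  # the tiny depth-2/base-2 net needs a hotter learning rate to cross the
  # 0.5 threshold within a short unit test
  cfg <- train_config(lr = 1e-2, max_epochs = 15, early_stop_patience = 15,
                      seed = 9)
  fit <- train_unet(m, s[1:5], s[6], cfg, use_augment = FALSE)
  pred <- predict_mask(fit$model, s[[6]]$volume)
  expect_gt(dsc(binary_mask(s[[6]]$mask, 1), binary_mask(pred$voxels, 1)),
            0.5)
  expect_lt(tail(fit$history$val_loss, 1), fit$history$val_loss[1])
})

test_that("predict_mask thresholds the sigmoid output", {
  set.seed(10)
  m <- build_unet(tiny_cfg())
  # force an always-off model
  m$weights$out_W[] <- 0
  m$weights$out_b <- -20
  x <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  expect_equal(sum(predict_mask(m, x)$voxels), 0)
  expect_equal(sum(predict_mask(m, x, threshold = 0)$voxels), 16 * 16 * 8)
  expect_error(predict_mask(m, array(0, c(15, 16, 8))), "divisible")
})

test_that("save/load round trips a model through the JSON checkpoint", {
  set.seed(11)
  m <- build_unet(tiny_cfg())
  f <- tempfile(fileext = ".json.gz")
  save_unet(m, f)
  m2 <- load_unet(f)
  expect_equal(m2$weights, m$weights, tolerance = 1e-12)
  expect_equal(m2$cfg$depth, m$cfg$depth)
  x <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  expect_equal(onquant:::unet_forward(m2, x)$pred,
               onquant:::unet_forward(m, x)$pred)
  unlink(f)
})

test_that("largest_component keeps the biggest blob with a raster tie-break", {
  d <- c(10, 10, 4)
  a <- array(0L, d)
  a[2:5, 2:5, 2:3] <- 1L   # 32 voxels
  a[8:9, 8:9, 2] <- 1L     # 4 voxels
  m <- largest_component(binary_mask(a, 0.3))
  expect_equal(sum(m$voxels), 32)
  expect_equal(sum(m$voxels[8:9, 8:9, 2]), 0)
  # single blob: unchanged
  b <- binary_mask(array(c(rep(1L, 8), rep(0L, 392)), d), 0.3)
  expect_identical(largest_component(b)$voxels, b$voxels)
  # two equal blobs: the one whose seed voxel comes first in column-major
  # raster order survives
  e <- array(0L, d)
  e[2:3, 2, 2] <- 1L
  e[6:7, 6, 3] <- 1L
  me <- largest_component(binary_mask(e, 0.3))
  expect_equal(sum(me$voxels[2:3, 2, 2]), 2)
  expect_equal(sum(me$voxels[6:7, 6, 3]), 0)
  # empty in, empty out
  empty <- binary_mask(array(0L, d), 0.3)
  expect_equal(sum(largest_component(empty)$voxels), 0)
})
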