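#' 3D U-Net configuration
#'
#' Encoder-decoder with `depth` resolution levels; each level holds two
#' 3x3x3 convolutions with batch normalization and ReLU, levels are joined
#' by 2x2x2 stride-2 max-pooling (encoder) and 2x2x2 stride-2
#' upconvolutions with skip concatenation (decoder), and a final 1x1x1
#' convolution with sigmoid yields a one-channel probability map of the input
#' shape.  Feature counts double per level starting at `base_features`
#' (default 32, 64, 128, 256, 512 at depth 5).  Every input axis must be
#' divisible by `2^(depth - 1)`.
#'
#' The default matches the full-size network (144 x 240 x 112 input); the
#' CPU-tested toy path uses `unet_config(depth = 3, base_features = 8,
#' input_shape = c(64, 64, 64))`.
#'
#' @param depth number of resolution levels.
#' @param base_features feature maps at the first level.
#' @param input_shape expected input voxel counts.
#' @return A `unet_config`.
#' @export
unet_config <- function(depth = 5L, base_features = 32L,
                        input_shape = c(144L, 240L, 112L)) {
  structure(list(depth = as.integer(depth),
                 base_features = as.integer(base_features),
                 input_shape = as.integer(input_shape)),
            class = "unet_config")
}

check_unet_shape <- function(shape, depth) {
  div <- 2^(depth - 1)
  bad <- which(shape %% div != 0)
  if (length(bad))
    stop(sprintf("input axis %s (size %d) not divisible by %d",
                 c("x", "y", "z")[bad[1]], shape[bad[1]], div))
  invisible(TRUE)
}

#' Build (initialize) a 3D U-Net
#'
#' He-style initialization for convolution weights, unit gamma / zero beta
#' for the normalization layers.  Weight draws come from the current RNG;
#' call `set.seed()` first for reproducible initialization.
#'
#' @param cfg a [unet_config()].
#' @return A `unet_model` (list of weight arrays plus the config).
#' @export
build_unet <- function(cfg = unet_config()) {
  check_unet_shape(cfg$input_shape, cfg$depth)
  w <- list()
  conv_init <- function(k, cin, cout) {
    sd <- sqrt(2 / (k^3 * cin))
    array(stats::rnorm(k^3 * cin * cout, 0, sd), c(k, k, k, cin, cout))
  }
  add_block <- function(pre, cin, cout) {
    w[[paste0(pre, "_conv1_W")]] <<- conv_init(3, cin, cout)
    w[[paste0(pre, "_conv1_b")]] <<- numeric(cout)
    w[[paste0(pre, "_bn1_gamma")]] <<- rep(1, cout)
    w[[paste0(pre, "_bn1_beta")]] <<- numeric(cout)
    w[[paste0(pre, "_conv2_W")]] <<- conv_init(3, cout, cout)
    w[[paste0(pre, "_conv2_b")]] <<- numeric(cout)
    w[[paste0(pre, "_bn2_gamma")]] <<- rep(1, cout)
    w[[paste0(pre, "_bn2_beta")]] <<- numeric(cout)
  }
  ch <- cfg$base_features * 2^(seq_len(cfg$depth) - 1)
  for (l in seq_len(cfg$depth))
    add_block(paste0("enc", l), if (l == 1) 1L else ch[l - 1], ch[l])
  for (l in seq_len(cfg$depth - 1)) {
    w[[paste0("dec", l, "_up_W")]] <-
      array(stats::rnorm(8 * ch[l + 1] * ch[l], 0, sqrt(2 / (8 * ch[l + 1]))),
            c(2, 2, 2, ch[l + 1], ch[l]))
    w[[paste0("dec", l, "_up_b")]] <- numeric(ch[l])
    add_block(paste0("dec", l), 2L * ch[l], ch[l])
  }
  w[["out_W"]] <- array(stats::rnorm(ch[1], 0, sqrt(1 / ch[1])),
                        c(ch[1], 1))
  # bias the sigmoid toward the background prior: thin tubular foreground is
  # ~1% of the voxels, and a neutral start stalls the Dice loss
  w[["out_b"]] <- -4
  structure(list(weights = w, cfg = cfg), class = "unet_model")
}

unet_forward <- function(model, x, target = numeric(0), want_grads = FALSE,
                         dice_eps = 1.0) {
  d <- dim(x)
  check_unet_shape(d, model$cfg$depth)
  cpp_unet_run(model$weights, as.numeric(x), d, model$cfg$depth,
               as.numeric(target), want_grads, dice_eps)
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)`, the loss used for
#' its robustness to the extreme foreground/background class imbalance of
#' thin tubular structures.  For binary predictions it equals `1 - DSC` up to
#' the smoothing term.
#'
#' @param pred probability array (values in \[0, 1\]).
#' @param target binary array of the same shape (or [binary_mask()]).
#' @param eps smoothing constant added to numerator and denominator.
#' @return Scalar loss in \[0, 1\].
#' @export
dice_loss <- function(pred, target, eps = 1.0) {
  if (inherits(pred, "volume_grid")) pred <- pred$voxels
  if (inherits(target, "volume_grid")) target <- target$voxels
  if (!identical(dim(pred), dim(target)))
    stop("pred and target shapes differ")
  p <- as.numeric(pred); t <- as.numeric(target)
  1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
}

#' Training configuration
#'
#' Defaults follow the published recipe: Adam with learning rate 1e-3, batch
#' size 1, up to 150 epochs with early stopping after 40 epochs without
#' validation-loss improvement, soft Dice loss, and on-the-fly augmentation
#' with random scaling (0.8-1.2, p = 0.5), left-right flipping (p = 0.5),
#' multiplicative intensity shifting (0.5-1.5, p = 0.3), additive Gaussian
#' noise (sigma = 0.1, p = 0.3) and Gaussian blurring (sigma 0.2-1.2 voxels,
#' p = 0.3).
#'
#' @param lr learning rate.
#' @param max_epochs epoch cap.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping; must be <= `max_epochs`.
#' @param seed RNG seed controlling shuffling and augmentation.
#' @param augment named list of augmentation parameters (see Details).
#' @param dice_eps soft Dice smoothing.
#' @return A `train_config`.
#' @export
train_config <- function(lr = 1e-3, max_epochs = 150L,
                         early_stop_patience = 40L, seed = 1L,
                         augment = list(scale_range = c(0.8, 1.2),
                                        scale_p = 0.5, flip_p = 0.5,
                                        shift_range = c(0.5, 1.5),
                                        shift_p = 0.3, noise_sigma = 0.1,
                                        noise_p = 0.3,
                                        blur_range = c(0.2, 1.2),
                                        blur_p = 0.3),
                         dice_eps = 1.0) {
  probs <- c(augment$scale_p, augment$flip_p, augment$shift_p,
             augment$noise_p, augment$blur_p)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (early_stop_patience > max_epochs)
    stop("patience must be <= max_epochs")
  structure(list(lr = lr, optimizer = "adam", batch_size = 1L,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed), augment = augment,
                 dice_eps = dice_eps),
            class = "train_config")
}

#' On-the-fly augmentation of one (volume, mask) sample
#'
#' Geometric transforms (isotropic content scaling, left-right flip) are
#' applied identically to volume and mask (nearest-neighbour for the mask,
#' which therefore stays 0/1); intensity transforms (multiplicative shift,
#' additive noise, Gaussian blur) touch the volume only.  All random draws
#' come from the R RNG; pass `seed` (or call `set.seed()` beforehand) for
#' reproducibility.
#'
#' @param sample list with `volume` and `mask` 3D arrays (or grids).
#' @param cfg a [train_config()] (its `augment` element is used).
#' @param seed optional integer seed.
#' @return list with augmented `volume` and `mask` arrays.
#' @export
augment <- function(sample, cfg = train_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- cfg$augment
  vol <- if (inherits(sample$volume, "volume_grid")) sample$volume$voxels else
    sample$volume
  msk <- if (inherits(sample$mask, "volume_grid")) sample$mask$voxels else
    sample$mask
  d <- dim(vol)
  if (stats::runif(1) < a$scale_p) {
    f <- stats::runif(1, a$scale_range[1], a$scale_range[2])
    ctr <- (d - 1) / 2  # 0-based center in index space
    M <- diag(3) / f
    t <- ctr - ctr / f
    vol <- array(cpp_resample(as.numeric(vol), d, c(1, 1, 1), c(0, 0, 0),
                              d, c(1, 1, 1), c(0, 0, 0), M, t, FALSE, 0), d)
    msk <- array(cpp_resample(as.numeric(msk), d, c(1, 1, 1), c(0, 0, 0),
                              d, c(1, 1, 1), c(0, 0, 0), M, t, TRUE, 0), d)
  }
  if (stats::runif(1) < a$flip_p) {
    vol <- vol[d[1]:1, , , drop = FALSE]
    msk <- msk[d[1]:1, , , drop = FALSE]
  }
  if (stats::runif(1) < a$shift_p)
    vol <- vol * stats::runif(1, a$shift_range[1], a$shift_range[2])
  if (stats::runif(1) < a$noise_p)
    vol <- vol + array(stats::rnorm(length(vol), 0, a$noise_sigma), d)
  if (stats::runif(1) < a$blur_p) {
    sg <- stats::runif(1, a$blur_range[1], a$blur_range[2])
    vol <- array(cpp_gauss3(as.numeric(vol), d, rep(sg, 3)), d)
  }
  list(volume = vol, mask = array(as.integer(msk != 0), d))
}

#' Train a U-Net on (volume, mask) samples
#'
#' Batch-size-1 Adam training with soft Dice loss and on-the-fly
#' augmentation.  After each epoch the mean validation loss (no augmentation)
#' is evaluated; weights are kept whenever it improves, and training stops at
#' `max_epochs` or once `early_stop_patience` consecutive epochs bring no
#' improvement.  All randomness is derived from `cfg$seed`, so two runs with
#' the same configuration produce identical histories.
#'
#' @param model a `unet_model` from [build_unet()].
#' @param train_set,val_set lists of samples, each a list with `volume` and
#'   `mask` (arrays or grids of the configured input shape).
#' @param cfg a [train_config()].
#' @param use_augment disable to train on raw samples.
#' @param verbose print per-epoch losses.
#' @return list with `model` (best checkpoint), `history` (data frame with
#'   `epoch`, `train_loss`, `val_loss`), `best_epoch` and `best_val_loss`.
#' @export
train_unet <- function(model, train_set, val_set, cfg = train_config(),
                       use_augment = TRUE, verbose = FALSE) {
  if (length(train_set) == 0 || length(val_set) == 0)
    stop("training and validation sets must be non-empty")
  set.seed(cfg$seed)
  adam_m <- lapply(model$weights, function(w) w * 0)
  adam_v <- adam_m
  tstep <- 0
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  best <- list(val = Inf, weights = model$weights, epoch = 0L)
  no_improve <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  get_arrays <- function(s) list(
    volume = if (inherits(s$volume, "volume_grid")) s$volume$voxels else
      s$volume,
    mask = if (inherits(s$mask, "volume_grid")) s$mask$voxels else s$mask)
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(length(train_set))
    tl <- 0
    for (i in ord) {
      s <- get_arrays(train_set[[i]])
      if (use_augment) s <- augment(s, cfg)
      res <- unet_forward(model, s$volume, target = s$mask,
                          want_grads = TRUE, dice_eps = cfg$dice_eps)
      tl <- tl + res$loss
      tstep <- tstep + 1
      g <- res$grads
      for (nm in names(model$weights)) {
        adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * g[[nm]]
        adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * g[[nm]]^2
        mhat <- adam_m[[nm]] / (1 - b1^tstep)
        vhat <- adam_v[[nm]] / (1 - b2^tstep)
        model$weights[[nm]] <- model$weights[[nm]] -
          cfg$lr * mhat / (sqrt(vhat) + adam_eps)
      }
    }
    vl <- mean(vapply(val_set, function(s) {
      s <- get_arrays(s)
      unet_forward(model, s$volume, target = s$mask,
                   dice_eps = cfg$dice_eps)$loss
    }, numeric(1)))
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = tl / length(train_set),
                                   val_loss = vl))
    if (verbose)
      message(sprintf("epoch %d train %.4f val %.4f", epoch,
                      tl / length(train_set), vl))
    if (vl < best$val) {
      best <- list(val = vl, weights = model$weights, epoch = epoch)
      no_improve <- 0L
    } else {
      no_improve <- no_improve + 1L
      if (no_improve >= cfg$early_stop_patience) break
    }
  }
  model$weights <- best$weights
  list(model = model, history = hist, best_epoch = best$epoch,
       best_val_loss = best$val)
}

#' Predict a binary mask with a trained U-Net
#'
#' @param model a `unet_model`.
#' @param vol a [volume_grid()] (normalized like the training data) or array.
#' @param threshold probability cut for foreground.
#' @param keep_largest apply [largest_component()] postprocessing.
#' @return A [binary_mask()] on the same grid (plain array in, plain grid
#'   geometry out with unit spacing).
#' @export
predict_mask <- function(model, vol, threshold = 0.5, keep_largest = FALSE) {
  is_vg <- inherits(vol, "volume_grid")
  x <- if (is_vg) vol$voxels else vol
  res <- unet_forward(model, x)
  p <- array(res$pred, dim(x))
  m <- if (is_vg)
    binary_mask(p >= threshold, vol$spacing, vol$origin, vol$direction)
  else binary_mask(p >= threshold, c(1, 1, 1))
  if (keep_largest) m <- largest_component(m)
  m
}

#' Keep only the largest 26-connected component
#'
#' Postprocessing that removes stray misclassified voxels far from the nerve;
#' on an empty mask it returns the mask unchanged.  When two components have
#' equal size, the one whose seed voxel comes first in column-major
#' raster-scan order (lexicographically smallest (x, y, z) index) is kept.
#'
#' @param mask a [binary_mask()].
#' @return A [binary_mask()] containing at most one connected component.
#' @export
largest_component <- function(mask) {
  d <- dim(mask$voxels)
  lab <- cpp_label26(mask$voxels != 0, d)
  if (max(lab) <= 1L) return(mask)
  sizes <- tabulate(lab)
  keep <- which.max(sizes)  # first max = smallest label = raster tie-break
  mask$voxels <- array(as.integer(lab == keep), d)
  mask
}
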