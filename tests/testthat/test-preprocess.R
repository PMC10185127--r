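test_that("eye centroids are recovered within a voxel on head phantoms", {
  ph <- rasterize_phantom(head_phantom_spec(spacing = 0.6, seed = 3))
  pair <- detect_eye_centroids(ph$volume)
  expect_lt(sqrt(sum((pair$left_centroid - c(-30, 40, 0))^2)), 0.6)
  expect_lt(sqrt(sum((pair$right_centroid - c(30, 40, 0))^2)), 0.6)
  expect_lt(pair$rotation_angle, 0.5)
})

test_that("one globe only raises 'eyes not found'", {
  ph <- rasterize_phantom(head_phantom_spec(spacing = 0.7, seed = 5,
                                            single_globe = TRUE))
  expect_error(detect_eye_centroids(ph$volume), "eyes not found")
})

test_that("mirroring swaps left/right labels consistently", {
  ph <- rasterize_phantom(head_phantom_spec(spacing = 0.7, seed = 6))
  pair <- detect_eye_centroids(ph$volume)
  mir <- ph$volume
  mir$voxels <- mir$voxels[dim(mir$voxels)[1]:1, , , drop = FALSE]
  pair_m <- detect_eye_centroids(mir)
  # the grid is x-symmetric up to one voxel; labels must stay left < right
  expect_lt(pair$left_centroid[1], pair$right_centroid[1])
  expect_lt(pair_m$left_centroid[1], pair_m$right_centroid[1])
  expect_equal(pair_m$left_centroid[2:3], pair$right_centroid[2:3],
               tolerance = 1.5)
})

test_that("centroid error stays under one voxel across 20 seeded phantoms", {
  errs <- vapply(1:20, function(seed) {
    ph <- rasterize_phantom(head_phantom_spec(spacing = 0.75,
                                              noise_sigma = 15, seed = seed))
    pair <- detect_eye_centroids(ph$volume)
    max(sqrt(sum((pair$left_centroid - c(-30, 40, 0))^2)),
        sqrt(sum((pair$right_centroid - c(30, 40, 0))^2)))
  }, numeric(1))
  expect_lt(max(errs), 0.75)
})

test_that("rotation_angle follows the arctangent and the 5-degree rule", {
  p0 <- list(left_centroid = c(-50, 20, 0), right_centroid = c(50, 20, 0))
  expect_equal(rotation_angle(p0), 0)
  p1 <- list(left_centroid = c(-50, 0, 0), right_centroid = c(50, 10, 0))
  expect_equal(rotation_angle(p1), atan(10 / 100) * 180 / pi)
  p2 <- list(left_centroid = c(-50, 0, 0), right_centroid = c(50, 7, 0))
  ang <- rotation_angle(p2)
  expect_equal(ang, atan(7 / 100) * 180 / pi, tolerance = 1e-9)
  expect_lt(ang, 5)  # below the realignment threshold: no rotation applied
  expect_error(rotation_angle(list(left_centroid = c(1, 2, 3),
                                   right_centroid = c(1, 2, 3))),
               "coincident")
})

test_that("rotate_resample is the identity on an aligned 0.3 mm volume", {
  ph <- rasterize_phantom(toy_nerve_spec(2))
  out <- rotate_resample(ph$volume, 0)
  expect_equal(dim(out$voxels), dim(ph$volume$voxels))
  expect_lt(max(abs(out$voxels - ph$volume$voxels)), 1e-9)
})

test_that("rotate_resample resamples anisotropic input to 0.3 mm isotropic", {
  vg <- volume_grid(array(rnorm(40 * 40 * 20), c(40, 40, 20)),
                    c(0.25, 0.25, 0.7))
  out <- rotate_resample(vg, 0)
  expect_equal(out$spacing, c(0.3, 0.3, 0.3))
  expect_error(rotate_resample(vg, 60), "45")
})

test_that("mask rotation is near-involutive and preserves {0,1}", {
  ph <- rasterize_phantom(toy_nerve_spec(3))
  m1 <- rotate_resample(ph$nerve, 12)
  expect_true(all(m1$voxels %in% c(0L, 1L)))
  m2 <- rotate_resample(m1, -12)
  back <- binary_mask(m2$voxels[1:64, 1:64, 1:64], 0.3)
  expect_gte(dsc(back, ph$nerve), 0.95)
})

test_that("crop_voi emits the fixed VOI shape, mirrors sides, pads corners", {
  # make the phantom left-right symmetric: midline nerve, low noise
  sp <- head_phantom_spec(spacing = 0.7, seed = 8, noise_sigma = 1)
  sp$curve_control_points <- rbind(c(0, 29, 0), c(0, 22, 0.5),
                                   c(0, 14, 1), c(0, 9, 1.5))
  ph <- rasterize_phantom(sp)
  rs <- rotate_resample(ph$volume, 0)
  pair <- detect_eye_centroids(ph$volume)
  suppressWarnings({
    left <- crop_voi(rs, pair, "left")
    right <- crop_voi(rs, pair, "right")
  })
  expect_equal(dim(left$voxels), c(144L, 240L, 112L))
  expect_equal(dim(right$voxels), c(144L, 240L, 112L))
  # symmetric phantom: the two VOIs are mirror images up to discretization
  mirrored <- right$voxels[144:1, , , drop = FALSE]
  expect_gt(cor(as.numeric(mirrored), as.numeric(left$voxels)), 0.98)
  # a globe near the volume corner forces padding with a warning
  shifted_pair <- pair
  shifted_pair$left_centroid[3] <- shifted_pair$left_centroid[3] - 10
  shifted_pair$right_centroid[3] <- shifted_pair$right_centroid[3] - 10
  expect_warning(v <- crop_voi(rs, shifted_pair, "right"), "padding")
  expect_equal(dim(v$voxels), c(144L, 240L, 112L))
})

test_that("znormalize yields mean 0 / variance 1 and rejects constants", {
  ph <- rasterize_phantom(toy_nerve_spec(4))
  z <- znormalize(ph$volume)
  n <- length(z$voxels)
  expect_lt(abs(mean(z$voxels)), 1e-6)
  expect_lt(abs(var(as.numeric(z$voxels)) * (n - 1) / n - 1), 1e-6)
  z2 <- znormalize(z)
  expect_lt(max(abs(z2$voxels - z$voxels)), 1e-6)
  expect_error(znormalize(volume_grid(array(3, c(4, 4, 4)), 1)),
               "zero variance")
})

test_that("flatten_bias removes a known bias and spares clean volumes", {
  spb <- phantom_spec(bias_coeffs = c(x = 0.15, y = 0.1), noise_sigma = 0.5)
  phb <- rasterize_phantom(spb)
  fb <- flatten_bias(phb$volume)
  bg <- phb$nerve$voxels == 0 & phb$csf$voxels == 0
  cv <- function(x) sd(x) / mean(x)
  expect_gt(cv(phb$volume$voxels[bg]) / cv(fb$voxels[bg]), 5)

  ph0 <- rasterize_phantom(phantom_spec(noise_sigma = 0.5))
  fb0 <- flatten_bias(ph0$volume)
  expect_lt(sqrt(mean((fb0$voxels / ph0$volume$voxels - 1)^2)), 0.01)

  f0 <- flatten_bias(ph0$volume, order = 0)
  expect_equal(mean(f0$voxels), 1, tolerance = 1e-12)
  neg <- ph0$volume
  neg$voxels[1] <- -1
  expect_error(flatten_bias(neg), "positive")
})

test_that("the preprocessing chain applies the 5-degree rule end to end", {
  ph <- rasterize_phantom(head_phantom_spec(spacing = 0.7, rotation_deg = 8,
                                            noise_sigma = 2, seed = 9))
  res <- suppressWarnings(preprocess_volume(ph$volume,
                                            bias_correction = FALSE))
  expect_true(res$rotated)
  expect_equal(res$angle, 8, tolerance = 0.5)
  expect_equal(dim(res$left$voxels), c(144L, 240L, 112L))
  expect_lt(abs(mean(res$right$voxels)), 1e-6)

  ph2 <- rasterize_phantom(head_phantom_spec(spacing = 0.7, rotation_deg = 4,
                                             noise_sigma = 2, seed = 10))
  res2 <- suppressWarnings(preprocess_volume(ph2$volume,
                                             bias_correction = FALSE))
  expect_false(res2$rotated)  # 4 degrees: below threshold, resample only
})
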