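# Shared generators for the test suite.  Everything is built in code at test
# time; seeds pin the stochastic cases.

# straight tube along +y, radius r mm, length L mm, optionally bare (no CSF)
cyl_spec <- function(r = 1.5, L = 30, spacing = 0.3, csf = 0, noise = 10,
                     seed = 1L) {
  margin <- r + csf + 4 * spacing
  nlat <- ceiling(2 * margin / spacing)
  ny <- ceiling((L + 2 * margin) / spacing)
  c0 <- c(margin, margin, margin)
  phantom_spec(grid_shape = c(nlat, ny, nlat), spacing = spacing,
               curve_control_points = rbind(c0, c0 + c(0, L, 0)),
               radius_profile = data.frame(frac = c(0, 1), mm = r),
               csf_thickness_profile = data.frame(frac = c(0, 1), mm = csf),
               noise_sigma = noise, seed = seed)
}

# straight tube tilted by theta degrees away from the coronal normal (+y),
# in the y-z plane
oblique_cyl_spec <- function(theta_deg, r = 1.5, L = 28, spacing = 0.3) {
  a <- theta_deg * pi / 180
  dirv <- c(0, cos(a), sin(a))
  c0 <- c(6, 3, 6)
  c1 <- c0 + L * dirv
  gs <- pmax(c(40, ceiling((c1[2] + 4) / spacing),
               ceiling((c1[3] + 6) / spacing)), 40)
  phantom_spec(grid_shape = gs, spacing = spacing,
               curve_control_points = rbind(c0, c1),
               radius_profile = data.frame(frac = c(0, 1), mm = r),
               csf_thickness_profile = data.frame(frac = c(0, 1), mm = 0))
}

# randomly curved nerve tube filling a 64^3 VOI at 0.3 mm, the toy-training
# world: radius 1.1-2 mm, CSF sheath thinning posteriorly, mild bias + noise
toy_nerve_spec <- function(seed) {
  set.seed(seed)
  x0 <- runif(1, 7.5, 11.5)
  z0 <- runif(1, 7.5, 11.5)
  xs <- pmin(pmax(x0 + cumsum(c(0, runif(3, -1.8, 1.8))), 4), 15)
  zs <- pmin(pmax(z0 + cumsum(c(0, runif(3, -1.8, 1.8))), 4), 15)
  phantom_spec(grid_shape = c(64, 64, 64), spacing = 0.3,
               curve_control_points = cbind(xs, seq(16, 2.6,
                                                    length.out = 4), zs),
               radius_profile = data.frame(frac = c(0, 1),
                                           mm = c(runif(1, 1.3, 2.0),
                                                  runif(1, 1.1, 1.7))),
               csf_thickness_profile = data.frame(frac = c(0, 0.5, 1),
                                                  mm = c(0.8, 0.5, 0.3)),
               noise_sigma = 10,
               bias_coeffs = c(x = 0.05, y = -0.04, z = 0.03),
               seed = seed)
}

toy_sample <- function(seed) {
  ph <- rasterize_phantom(toy_nerve_spec(seed))
  list(volume = znormalize(ph$volume)$voxels, mask = ph$nerve$voxels,
       nerve = ph$nerve)
}

# small random blob pair for metric-oracle equivalence (<= 200 voxels each)
random_mask_pair <- function(seed, d = c(9, 9, 9)) {
  set.seed(seed)
  mk <- function() {
    a <- array(0L, d)
    n <- sample(3:5, 1)
    for (i in seq_len(n)) {
      c0 <- sapply(d, function(k) sample(2:(k - 1), 1))
      r <- runif(1, 1, 2.6)
      w <- arrayInd(seq_len(prod(d)), d)
      a[rowSums(sweep(w, 2, c0)^2) <= r^2] <- 1L
    }
    a
  }
  A <- mk(); B <- mk()
  if (sum(A) == 0) A[4, 4, 4] <- 1L
  if (sum(B) == 0) B[5, 5, 5] <- 1L
  sp <- 0.3
  list(A = binary_mask(A, sp), B = binary_mask(B, sp))
}

# ---------------------------------------------------------------------------
# independent brute-force oracles (pure R, naive enumeration)

oracle_surface_idx <- function(mask) {
  d <- dim(mask$voxels)
  fg <- mask$voxels != 0
  w <- which(fg, arr.ind = TRUE)
  is_surf <- vapply(seq_len(nrow(w)), function(r) {
    i <- w[r, 1]; j <- w[r, 2]; k <- w[r, 3]
    for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      ii <- i + o[1]; jj <- j + o[2]; kk <- k + o[3]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3])
        return(TRUE)
      if (!fg[ii, jj, kk]) return(TRUE)
    }
    FALSE
  }, logical(1))
  w[is_surf, , drop = FALSE]
}

oracle_pairwise_dists <- function(idxA, idxB, spacing) {
  pa <- sweep(idxA - 1, 2, spacing, "*")
  pb <- sweep(idxB - 1, 2, spacing, "*")
  # exhaustive all-pairs distance table
  sqrt(outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2 +
         outer(pa[, 3], pb[, 3], "-")^2)
}

# type-7 percentile by hand (linear interpolation of order statistics)
oracle_quantile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  if (lo >= length(x)) return(x[length(x)])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

oracle_hd95 <- function(A, B) {
  D <- oracle_pairwise_dists(oracle_surface_idx(A), oracle_surface_idx(B),
                             A$spacing)
  max(oracle_quantile(apply(D, 1, min), 0.95),
      oracle_quantile(apply(D, 2, min), 0.95))
}

oracle_asd <- function(A, B) {
  D <- oracle_pairwise_dists(oracle_surface_idx(A), oracle_surface_idx(B),
                             A$spacing)
  (sum(apply(D, 1, min)) + sum(apply(D, 2, min))) / (nrow(D) + ncol(D))
}

oracle_dsc <- function(A, B) {
  a <- A$voxels != 0; b <- B$voxels != 0
  if (sum(a) + sum(b) == 0) return(1)
  2 * sum(a & b) / (sum(a) + sum(b))
}

oracle_dsc_tol <- function(A, B, tol = 1) {
  a <- A$voxels != 0; b <- B$voxels != 0
  if (sum(a) + sum(b) == 0) return(1)
  thr <- tol * max(A$spacing) + 1e-9
  count_tol <- function(diffm, other) {
    wd <- which(diffm, arr.ind = TRUE)
    if (nrow(wd) == 0) return(0)
    so <- oracle_surface_idx(other)
    D <- oracle_pairwise_dists(wd, so, A$spacing)
    sum(apply(D, 1, min) <= thr)
  }
  tA <- count_tol(a & !b, B)
  tB <- count_tol(b & !a, A)
  2 * (sum(a & b) + tA + tB) / (sum(a) + sum(b) + tA + tB)
}

# two-way ANOVA ICC(A,1) oracle from explicit sums of squares
oracle_icc_a1 <- function(r1, r2) {
  Y <- cbind(r1, r2)
  n <- nrow(Y); k <- 2
  gm <- mean(Y)
  SSR <- k * sum((rowMeans(Y) - gm)^2)
  SSC <- n * sum((colMeans(Y) - gm)^2)
  SST <- sum((Y - gm)^2)
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- (SST - SSR - SSC) / ((n - 1) * (k - 1))
  (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
}

# reference diameter profile emulating the peri-globe taper of a real nerve
reference_profile <- function(L = 12, step = 0.1) {
  s <- seq(0, L, by = step)
  dce <- 2.6 + 1.5 * exp(-s / 1.2) + 0.25 * sin(0.8 * s)
  data.frame(s_mm = s, area_mm2 = pi * (dce / 2)^2, d_ce_mm = dce,
             d_mis_mm = dce, flag = "ok", stringsAsFactors = FALSE)
}
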