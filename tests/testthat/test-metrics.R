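mask_of <- function(idx, d = c(6, 6, 6), spacing = 0.3) {
  a <- array(0L, d)
  a[idx] <- 1L
  binary_mask(a, spacing)
}

test_that("dsc follows the overlap formula and degenerate conventions", {
  A <- mask_of(1:10)
  expect_equal(dsc(A, A), 1)
  expect_equal(dsc(mask_of(1:5), mask_of(6:10)), 0)
  expect_equal(dsc(mask_of(1:2), mask_of(2:3)), 0.5)
  empty <- mask_of(integer(0))
  expect_equal(dsc(empty, empty), 1.0)
  expect_equal(dsc(empty, A), 0)
  expect_error(dsc(A, mask_of(1:10, d = c(6, 6, 5))), "same grid")
})

test_that("dsc_tolerance forgives single-voxel shifts and bounds dsc", {
  d <- c(10, 10, 6)
  a <- array(0L, d); a[3:6, 3:6, 2:4] <- 1L
  b <- array(0L, d); b[4:7, 3:6, 2:4] <- 1L  # shifted by exactly one voxel
  A <- binary_mask(a, 0.3); B <- binary_mask(b, 0.3)
  expect_equal(dsc_tolerance(A, A, 1), 1)
  expect_equal(dsc_tolerance(A, B, 1), 1.0)
  expect_equal(dsc_tolerance(A, B, 0), dsc(A, B))
  for (seed in 1:5) {
    pr <- random_mask_pair(seed)
    expect_gte(dsc_tolerance(pr$A, pr$B, 1), dsc(pr$A, pr$B))
  }
})

test_that("precision and recall follow the subset identities", {
  d <- c(8, 8, 4)
  a <- array(0L, d); a[1:40] <- 1L
  A <- binary_mask(a, 0.3)
  pr <- precision_recall(A, A)
  expect_equal(unname(pr), c(1, 1))
  half <- array(0L, d); half[1:20] <- 1L
  pr2 <- precision_recall(A, binary_mask(half, 0.3))
  expect_equal(unname(pr2), c(1, 0.5))
  dbl <- array(0L, d); dbl[1:80] <- 1L
  pr3 <- precision_recall(A, binary_mask(dbl, 0.3))
  expect_equal(unname(pr3), c(0.5, 1))
  expect_warning(pr4 <- precision_recall(A, binary_mask(array(0L, d), 0.3)),
                 "undefined")
  expect_true(is.na(pr4[["precision"]]))
})

test_that("hd95 and asd match hand-derivable cases", {
  A <- mask_of(cbind(2, 2, 2), d = c(8, 8, 8))
  B <- mask_of(cbind(5, 2, 2), d = c(8, 8, 8))  # 3 voxels = 0.9 mm apart
  expect_equal(hd95(A, B), 0.9, tolerance = 1e-12)
  expect_equal(asd(A, B), 0.9, tolerance = 1e-12)
  expect_equal(hd95(A, A), 0)
  expect_equal(asd(A, A), 0)
  expect_error(hd95(A, mask_of(integer(0), d = c(8, 8, 8))), "empty")
})

test_that("metrics are symmetric and scale linearly with spacing", {
  for (seed in 1:5) {
    pr <- random_mask_pair(seed)
    expect_equal(dsc(pr$A, pr$B), dsc(pr$B, pr$A))
    expect_equal(hd95(pr$A, pr$B), hd95(pr$B, pr$A))
    expect_equal(asd(pr$A, pr$B), asd(pr$B, pr$A))
    A2 <- binary_mask(pr$A$voxels, 0.6)
    B2 <- binary_mask(pr$B$voxels, 0.6)
    expect_equal(hd95(A2, B2), 2 * hd95(pr$A, pr$B), tolerance = 1e-9)
    expect_equal(asd(A2, B2), 2 * asd(pr$A, pr$B), tolerance = 1e-9)
  }
})

test_that("optimized metrics equal exhaustive brute-force oracles", {
  for (seed in 1:12) {
    pr <- random_mask_pair(seed)
    expect_lt(abs(dsc(pr$A, pr$B) - oracle_dsc(pr$A, pr$B)), 1e-12)
    expect_lt(abs(hd95(pr$A, pr$B) - oracle_hd95(pr$A, pr$B)), 1e-9)
    expect_lt(abs(asd(pr$A, pr$B) - oracle_asd(pr$A, pr$B)), 1e-9)
    expect_lt(abs(dsc_tolerance(pr$A, pr$B, 1) -
                    oracle_dsc_tol(pr$A, pr$B, 1)), 1e-9)
  }
})

test_that("icc_a1 matches the ANOVA oracle and its known properties", {
  expect_equal(icc_a1(c(1, 2, 3, 5), c(1, 2, 3, 5)), 1)
  r1 <- c(1, 2, 3, 4); r2 <- c(4, 3, 2, 1)
  v <- icc_a1(r1, r2)
  expect_lt(v, 0)
  expect_equal(v, oracle_icc_a1(r1, r2), tolerance = 1e-12)
  # absolute agreement penalizes a constant offset, increasingly so
  base <- c(1, 2, 3, 4, 6)
  v1 <- icc_a1(base, base + 0.5)
  v2 <- icc_a1(base, base + 1.5)
  expect_lt(v1, 1)
  expect_lt(v2, v1)
  set.seed(20)
  for (i in 1:5) {
    a <- rnorm(8); b <- 0.7 * a + rnorm(8, 0, 0.4)
    expect_equal(icc_a1(a, b), oracle_icc_a1(a, b), tolerance = 1e-10)
  }
  expect_error(icc_a1(1:4, 1:3), "length")
  expect_error(icc_a1(c(1, 2), c(1, 2)), "at least 3")
  expect_error(icc_a1(rep(1, 5), rep(1, 5)), "zero total variance")
})

test_that("metric_report aggregates per-case rows in the reporting style", {
  truths <- lapply(1:3, function(s) random_mask_pair(s)$A)
  preds <- lapply(1:3, function(s) random_mask_pair(s)$B)
  rep <- metric_report(truths, preds)
  expect_equal(nrow(rep$per_case), 3)
  expect_true(all(c("dsc", "dsc_tol1", "hd95_mm", "asd_mm") %in%
                    names(rep$per_case)))
  expect_true(all(rep$per_case$dsc_tol1 >= rep$per_case$dsc))
  expect_match(rep$aggregate$summary[1], "\\+/-")
  expect_match(rep$aggregate$summary[5], "\\[")
})
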