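sphere_mask <- function(r = 5, spacing = 0.3) {
  n <- ceiling(2 * (r + 3 * spacing) / spacing)
  d <- c(n, n, n)
  w <- arrayInd(seq_len(prod(d)), d)
  ctr <- (d - 1) / 2 * spacing
  binary_mask(array(rowSums(sweep((w - 1) * spacing, 2, ctr)^2) <= r^2, d),
              spacing)
}

test_that("mask_to_surface produces a closed mesh with accurate area", {
  m <- sphere_mask(5)
  surf <- mask_to_surface(m)
  expect_true(surface_is_closed(surf))
  expect_lt(abs(surface_area(surf) - 4 * pi * 25), 0.05 * 4 * pi * 25)
  expect_error(mask_to_surface(binary_mask(array(0L, c(4, 4, 4)), 0.3)),
               "empty")
})

test_that("Taubin smoothing shrinks the measured section (documented bias)", {
  ph <- rasterize_phantom(cyl_spec(r = 1.5, L = 24, noise = 0))
  q_off <- quantify_mask(ph$nerve, smooth = "off")
  q_on <- quantify_mask(ph$nerve, smooth = "taubin")
  d_off <- mean(q_off$profile$d_ce_mm[q_off$profile$flag == "ok"])
  d_on <- mean(q_on$profile$d_ce_mm[q_on$profile$flag == "ok"])
  expect_lte(d_on, d_off + 1e-6)
})

test_that("endpoints land near the tube ends and honor overrides", {
  ph <- rasterize_phantom(cyl_spec(r = 1.5, L = 30))
  ep <- detect_endpoints(ph$nerve)
  ends <- rbind(ph$truth$centerline_points[1, ],
                ph$truth$centerline_points[nrow(ph$truth$centerline_points), ])
  d1 <- min(sqrt(rowSums(sweep(ends, 2, ep[1, ])^2)))
  d2 <- min(sqrt(rowSums(sweep(ends, 2, ep[2, ])^2)))
  expect_lt(d1, 1.0)
  expect_lt(d2, 1.0)
  ov <- rbind(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(detect_endpoints(ph$nerve, endpoints = ov)), ov)
  # disconnected input is rejected with advice
  d <- c(10, 10, 10)
  a <- array(0L, d); a[2:3, 2:3, 2:3] <- 1L; a[7:8, 7:8, 7:8] <- 1L
  expect_error(detect_endpoints(binary_mask(a, 0.3)), "largest_component")
})

test_that("torus endpoints sit at the arc extremities, not across the chord", {
  th <- seq(0, pi / 2, length.out = 9)
  tor <- phantom_spec(grid_shape = c(50, 50, 20), spacing = 0.3,
                      curve_control_points = cbind(2.5 + 10 * cos(th),
                                                   2.5 + 10 * sin(th), 2.85),
                      radius_profile = data.frame(frac = c(0, 1), mm = 1.5),
                      csf_thickness_profile = data.frame(frac = c(0, 1),
                                                         mm = 0))
  ph <- rasterize_phantom(tor)
  ep <- detect_endpoints(ph$nerve)
  true_ends <- rbind(c(12.5, 2.5, 2.85), c(2.5, 12.5, 2.85))
  for (r in 1:2)
    expect_lt(min(sqrt(rowSums(sweep(true_ends, 2, ep[r, ])^2))), 1.2)
})

test_that("centerline of a straight cylinder rides the axis", {
  ph <- rasterize_phantom(cyl_spec(r = 1.5, L = 30))
  q <- quantify_mask(ph$nerve)
  cl <- q$centerline
  expect_equal(max(cl$s), 30, tolerance = 0.02 * 30)
  axis_xz <- ph$truth$centerline_points[1, c(1, 3)]
  int <- cl$s > 3 & cl$s < max(cl$s) - 3
  dev <- sqrt((cl$points[int, 1] - axis_xz[1])^2 +
                (cl$points[int, 3] - axis_xz[2])^2)
  expect_lt(max(dev), 0.3)
  expect_true(all(abs(sqrt(rowSums(cl$tangents^2)) - 1) < 1e-6))
  expect_true(all(diff(cl$s) > 0))
  expect_equal(cl$inscribed_radius[int], rep(1.5, sum(int)), tolerance = 0.2)
})

test_that("quarter-torus arc length is recovered within 3%", {
  th <- seq(0, pi / 2, length.out = 9)
  tor <- phantom_spec(grid_shape = c(50, 50, 20), spacing = 0.3,
                      curve_control_points = cbind(2.5 + 10 * cos(th),
                                                   2.5 + 10 * sin(th), 2.85),
                      radius_profile = data.frame(frac = c(0, 1), mm = 1.5),
                      csf_thickness_profile = data.frame(frac = c(0, 1),
                                                         mm = 0))
  q <- quantify_mask(rasterize_phantom(tor)$nerve)
  expect_equal(max(q$centerline$s), pi * 5, tolerance = 0.03 * pi * 5)
})

test_that("cross sections of a cylinder give the analytic circle", {
  ph <- rasterize_phantom(cyl_spec(r = 1.5, L = 30))
  q <- quantify_mask(ph$nerve)
  ok <- q$profile$flag == "ok"
  expect_gt(sum(ok), 150)
  expect_equal(mean(q$profile$d_ce_mm[ok]), 3.0, tolerance = 0.05)
  expect_true(all(abs(q$profile$area_mm2[ok] - pi * 1.5^2) < 0.7))
  expect_true(all(abs(q$profile$d_mis_mm[ok] - 3.0) < 0.35))
  # step and identity invariants
  expect_equal(median(diff(q$profile$s_mm)), 0.1, tolerance = 1e-9)
  expect_equal(q$profile$d_ce_mm[ok],
               2 * sqrt(q$profile$area_mm2[ok] / pi), tolerance = 1e-12)
})

test_that("elliptical sections separate CE and MIS diameters", {
  d <- c(40, 100, 30)
  w <- arrayInd(seq_len(prod(d)), d)
  x <- (w[, 1] - 1) * 0.3 - 5.85
  y <- (w[, 2] - 1) * 0.3
  z <- (w[, 3] - 1) * 0.3 - 4.35
  ell <- binary_mask(array((x / 2)^2 + z^2 <= 1 & y >= 2 & y <= 28, d), 0.3)
  q <- quantify_mask(ell)
  ok <- q$profile$flag == "ok"
  expect_equal(mean(q$profile$area_mm2[ok]), 2 * pi, tolerance = 0.07 * 2 * pi)
  expect_equal(mean(q$profile$d_ce_mm[ok]), 2 * sqrt(2), tolerance = 0.1)
  expect_equal(mean(q$profile$d_mis_mm[ok]), 2.0, tolerance = 0.35)
})

test_that("a linear taper shows up as the predicted d_CE slope", {
  tap <- phantom_spec(grid_shape = c(26, 120, 26), spacing = 0.3,
                      curve_control_points = rbind(c(3.9, 2.4, 3.9),
                                                   c(3.9, 32.4, 3.9)),
                      radius_profile = data.frame(frac = c(0, 1),
                                                  mm = c(2, 1)),
                      csf_thickness_profile = data.frame(frac = c(0, 1),
                                                         mm = 0))
  ph <- rasterize_phantom(tap)
  # orient the profile from the thick end
  q <- quantify_mask(ph$nerve, globe_center = c(3.9, 0, 3.9))
  ok <- q$profile$flag == "ok"
  slope <- unname(coef(lm(d_ce_mm ~ s_mm, q$profile[ok, ]))[2])
  expect_lt(abs(slope / (-2 / max(q$profile$s_mm)) - 1), 0.1)
})

test_that("the profile is orientation invariant within 2%", {
  mk <- function(rotdeg) {
    a <- rotdeg * pi / 180
    R <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
    cp <- t(R %*% t(rbind(c(0, -15, 0), c(0, 15, 0))))
    phantom_spec(grid_shape = c(80, 112, 24), spacing = 0.3,
                 origin = c(-12, -16.65, -3.6), curve_control_points = cp,
                 radius_profile = data.frame(frac = c(0, 1), mm = 1.5),
                 csf_thickness_profile = data.frame(frac = c(0, 1), mm = 0))
  }
  q0 <- quantify_mask(rasterize_phantom(mk(0))$nerve)
  q25 <- quantify_mask(rasterize_phantom(mk(25))$nerve)
  m0 <- mean(q0$profile$d_ce_mm[q0$profile$flag == "ok"])
  m25 <- mean(q25$profile$d_ce_mm[q25$profile$flag == "ok"])
  expect_lt(abs(m25 / m0 - 1), 0.02)
})

test_that("mesh section areas agree with an oblique mask-resampling oracle", {
  ph <- rasterize_phantom(oblique_cyl_spec(30))
  q <- quantify_mask(ph$nerve)
  ok <- which(q$profile$flag == "ok")
  pick <- ok[seq(1, length(ok), length.out = 12)]
  fg <- array(as.numeric(ph$nerve$voxels), dim(ph$nerve$voxels))
  for (i in pick) {
    p0 <- q$centerline$points[i, ]
    nrm <- q$centerline$tangents[i, ]
    ax <- which.min(abs(nrm))
    e <- c(0, 0, 0); e[ax] <- 1
    u <- c(nrm[2] * e[3] - nrm[3] * e[2], nrm[3] * e[1] - nrm[1] * e[3],
           nrm[1] * e[2] - nrm[2] * e[1])
    u <- u / sqrt(sum(u^2))
    v <- c(nrm[2] * u[3] - nrm[3] * u[2], nrm[3] * u[1] - nrm[1] * u[3],
           nrm[1] * u[2] - nrm[2] * u[1])
    # sample the mask on an in-plane grid and count in-plane area
    h <- 0.1
    g <- expand.grid(a = seq(-2.5, 2.5, by = h), b = seq(-2.5, 2.5, by = h))
    pts <- sweep(outer(g$a, u) + outer(g$b, v), 2, p0, "+")
    vals <- onquant:::interp_trilinear(fg,
                                       world_to_index(ph$nerve, pts), 0)
    a_oracle <- sum(vals >= 0.5) * h * h
    expect_lt(abs(q$profile$area_mm2[i] - a_oracle),
              0.05 * max(a_oracle, pi * 1.5^2))
  }
})

test_that("quantify_mask flags rather than drops doubtful samples", {
  ph <- rasterize_phantom(cyl_spec(r = 1.5, L = 20))
  q <- quantify_mask(ph$nerve)
  expect_true(all(q$profile$flag %in% c("ok", "cap", "invalid", "nearest")))
  expect_gt(sum(q$profile$flag == "cap"), 0)
  expect_equal(nrow(q$profile), length(q$centerline$s))
})
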