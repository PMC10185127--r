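test_that("coronal areas follow the 1/cos(theta) law and its correction", {
  ph <- rasterize_phantom(oblique_cyl_spec(0))
  q <- quantify_mask(ph$nerve)
  cp <- coronal_profile(ph$nerve, q$centerline, q$profile)
  ok <- cp$flag == "ok"
  expect_lt(mean(cp$theta_deg[ok]), 2)
  expect_equal(mean(cp$a_cor_mm2[ok] / q$profile$area_mm2[ok]), 1,
               tolerance = 0.1)
  expect_equal(mean(cp$rel_err[ok]), 0, tolerance = 0.05)
  # machine-precision identity of the correction
  expect_equal(cp$a_corr_mm2[ok],
               cp$a_cor_mm2[ok] * cos(cp$theta_deg[ok] * pi / 180),
               tolerance = 1e-12)

  ph60 <- rasterize_phantom(oblique_cyl_spec(60))
  q60 <- quantify_mask(ph60$nerve)
  cp60 <- coronal_profile(ph60$nerve, q60$centerline, q60$profile)
  ok60 <- cp60$flag == "ok"
  expect_equal(mean(cp60$theta_deg[ok60]), 60, tolerance = 2)
  expect_equal(mean(cp60$a_cor_mm2[ok60] / q60$profile$area_mm2[ok60]), 2.0,
               tolerance = 0.2)
  expect_equal(mean(cp60$a_corr_mm2[ok60] / q60$profile$area_mm2[ok60]), 1.0,
               tolerance = 0.1)
  expect_equal(mean(cp60$rel_err[ok60]), sqrt(2) - 1, tolerance = 0.06)
})

test_that("relative error grows with the local angle on a curved phantom", {
  th <- seq(0, pi / 3, length.out = 8)
  sp <- phantom_spec(grid_shape = c(30, 60, 46), spacing = 0.3,
                     curve_control_points = cbind(
                       4.5, 3 + 12 * sin(th), 3 + 12 * (1 - cos(th))),
                     radius_profile = data.frame(frac = c(0, 1), mm = 1.5),
                     csf_thickness_profile = data.frame(frac = c(0, 1),
                                                        mm = 0))
  ph <- rasterize_phantom(sp)
  q <- quantify_mask(ph$nerve, globe_center = c(4.5, 0, 0))
  cp <- coronal_profile(ph$nerve, q$centerline, q$profile)
  ok <- cp$flag == "ok" & !is.na(cp$rel_err)
  expect_gt(cor(cp$theta_deg[ok], cp$rel_err[ok], method = "spearman"), 0.9)
})

test_that("average_relative_error aligns and bounds the cohort mean", {
  mkp <- function(re) {
    data.frame(s_mm = seq(0, 10, by = 0.1),
               a_cor_mm2 = 7, a_corr_mm2 = 7,
               theta_deg = 10, rel_err = re, flag = "ok")
  }
  same <- average_relative_error(list(mkp(0.1), mkp(0.1)))
  expect_true(all(same$sd_rel_err == 0))
  expect_true(all(abs(same$mean_rel_err - 0.1) < 1e-12))
  set.seed(4)
  profs <- lapply(1:10, function(i) mkp(runif(101, 0, 0.5)))
  avg <- average_relative_error(profs)
  env_min <- do.call(pmin, lapply(profs, function(p) p$rel_err))
  env_max <- do.call(pmax, lapply(profs, function(p) p$rel_err))
  expect_true(all(avg$mean_rel_err >= env_min - 1e-12 &
                    avg$mean_rel_err <= env_max + 1e-12))
  expect_error(average_relative_error(list()), "no profiles")
})

test_that("find_offset recovers planted offsets exactly on the 0.1 mm grid", {
  prof <- reference_profile()
  for (off in c(0, 0.3, 0.5, 0.7, 1.0)) {
    refs <- approx(prof$s_mm, prof$d_ce_mm, xout = off + c(0, 3, 5))$y
    r <- find_offset(prof, refs)
    expect_equal(r$offset, off)
    expect_lt(r$mae, 1e-9)
  }
  # ties prefer the smaller offset
  profc <- prof
  profc$d_ce_mm <- 3
  expect_equal(find_offset(profc, c(3, 3, 3))$offset, 0)
  short <- prof[prof$s_mm <= 4, ]
  expect_error(find_offset(short, c(3, 3, 3)), "5 mm")
  expect_error(find_offset(prof, c(3, 3)), "three")
})

test_that("agreement reproduces hand-computed statistics exactly", {
  a <- agreement(1:5, 1:5)
  expect_equal(a$mae, 0)
  expect_equal(a$icc, 1)
  expect_equal(a$bland_altman$mean_diff, 0)
  ac <- agreement(1:5 - 0.2, 1:5)
  expect_equal(ac$mae, 0.2)
  expect_equal(ac$bland_altman$mean_diff, -0.2)
  expect_lt(ac$bland_altman$sd_diff, 1e-12)
  # fixed 8-pair table against a spreadsheet-style computation
  auto <- c(3.1, 2.8, 3.6, 2.2, 4.0, 3.3, 2.9, 3.8)
  manual <- c(3.0, 3.0, 3.4, 2.5, 3.8, 3.2, 3.1, 3.6)
  g <- agreement(auto, manual)
  dif <- auto - manual
  expect_equal(g$mae, mean(abs(dif)), tolerance = 1e-12)
  expect_equal(g$bland_altman$mean_diff, mean(dif), tolerance = 1e-12)
  expect_equal(g$bland_altman$loa_upper, mean(dif) + 1.96 * sd(dif),
               tolerance = 1e-12)
  expect_equal(g$icc, oracle_icc_a1(manual, auto), tolerance = 1e-12)
  expect_error(agreement(1:4, 1:5), "length")
})

test_that("proportional bias shows the published Bland-Altman pattern", {
  manual <- seq(2, 5, length.out = 12)
  auto <- 0.9 * manual
  g <- agreement(auto, manual)
  dif <- auto - manual
  avg <- (auto + manual) / 2
  # difference decreases with the mean: smaller sizes over-, larger sizes
  # under-estimated relative to trend
  expect_lt(coef(lm(dif ~ avg))[2], 0)
  expect_lt(g$bland_altman$mean_diff, 0)
})

test_that("the radial intensity model recovers r_on with homogeneous CSF", {
  sl <- synth_coronal_slice(r_on = 1.5, r_csf = 2.5, blur_sigma = 0.3,
                            noise_sigma = 10, seed = 2)
  f <- fit_intensity_baseline(sl$patch, sl$spacing)
  expect_equal(f$r_on, 1.5, tolerance = 0.2)
  expect_false(f$quality_flag)
  # exact model class, noise- and blur-free: half-voxel accuracy
  sl0 <- synth_coronal_slice(r_on = 1.5, r_csf = 2.5, blur_sigma = 0,
                             noise_sigma = 0)
  f0 <- fit_intensity_baseline(sl0$patch, sl0$spacing)
  expect_equal(f0$r_on, 1.5, tolerance = 0.15)
})

test_that("absent or asymmetric CSF raises the quality flag", {
  flags_absent <- vapply(1:5, function(s) {
    sl <- synth_coronal_slice(r_on = 1.5, r_csf = 1.5, noise_sigma = 10,
                              seed = s)
    fit_intensity_baseline(sl$patch, sl$spacing)$quality_flag
  }, logical(1))
  expect_gte(mean(flags_absent), 0.8)
  flags_asym <- vapply(6:10, function(s) {
    sl <- synth_coronal_slice(r_on = 1.5, r_csf = 2.5, csf_arc = 0.6 * pi,
                              noise_sigma = 10, seed = s)
    fit_intensity_baseline(sl$patch, sl$spacing)$quality_flag
  }, logical(1))
  expect_gte(mean(flags_asym), 0.8)
})
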