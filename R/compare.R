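#' Coronal-plane area profile with orientation correction
#'
#' For each centerline sample, the in-plane connected area of the mask in the
#' coronal slice (normal `v_cor = (0, 1, 0)`, the anterior-posterior grid
#' axis) through the sample point is measured (`a_cor`).  Because an oblique
#' tube overestimates its true section by ~`1/cos(theta)`, the corrected area
#' `a_corr = a_cor * (c_i . v_cor)` and the centerline angle
#' `theta = arccos(c_i . v_cor)` are reported; samples with
#' `theta >= 85` degrees (centerline nearly parallel to the coronal plane)
#' are flagged and excluded from averages.  When a [cross_section_profile()]
#' is supplied, the relative error of the coronal equivalent diameter against
#' the cross-sectional CE diameter is included.
#'
#' @param mask a [binary_mask()].
#' @param cl a `centerline`.
#' @param profile optional `diameter_profile` on the same centerline.
#' @param theta_max flag threshold in degrees.
#' @return A `coronal_profile` data frame: `s_mm`, `a_cor_mm2`,
#'   `a_corr_mm2`, `theta_deg`, `rel_err`, `flag`.
#' @export
coronal_profile <- function(mask, cl, profile = NULL, theta_max = 85) {
  d <- dim(mask$voxels)
  vcor <- c(0, 1, 0)
  n <- nrow(cl$points)
  a_cor <- rep(NA_real_, n)
  costh <- pmin(1, pmax(-1, as.numeric(cl$tangents %*% vcor)))
  costh <- abs(costh)  # orientation-free angle
  theta <- acos(costh) * 180 / pi
  slice_area <- function(pt) {
    idx <- round(world_to_index(mask, matrix(pt, 1)))
    if (any(idx < 1) || any(idx > d)) return(NA_real_)
    sl <- mask$voxels[, idx[2], , drop = FALSE] != 0
    if (!any(sl)) return(NA_real_)
    lab <- cpp_label26(as.logical(sl), c(d[1], 1L, d[3]))
    lab <- array(lab, c(d[1], 1L, d[3]))
    l0 <- lab[idx[1], 1, idx[3]]
    if (l0 == 0) {
      # center voxel off-mask (thin sections): take the nearest component
      w <- which(lab != 0, arr.ind = TRUE)
      dd <- (w[, 1] - idx[1])^2 + (w[, 3] - idx[3])^2
      l0 <- lab[w[which.min(dd), , drop = FALSE]]
    }
    sum(lab == l0) * mask$spacing[1] * mask$spacing[3]
  }
  for (i in seq_len(n)) a_cor[i] <- slice_area(cl$points[i, ])
  a_corr <- a_cor * costh
  flag <- ifelse(theta >= theta_max, "parallel", "ok")
  flag[is.na(a_cor)] <- "invalid"
  rel_err <- rep(NA_real_, n)
  if (!is.null(profile)) {
    acs <- stats::approx(profile$s_mm, profile$area_mm2, xout = cl$s,
                         rule = 2)$y
    rel_err <- sqrt(a_cor / acs) - 1
    flag[flag == "ok" & (is.na(acs) | profile$flag[
      pmin(seq_len(n), nrow(profile))] %in% c("cap", "invalid"))] <- "cap"
  }
  out <- data.frame(s_mm = cl$s, a_cor_mm2 = a_cor, a_corr_mm2 = a_corr,
                    theta_deg = theta, rel_err = rel_err, flag = flag,
                    stringsAsFactors = FALSE)
  class(out) <- c("coronal_profile", class(out))
  out
}

#' Arc-length-aligned mean relative error across subjects
#'
#' Resamples each subject's coronal relative-error curve onto a common arc
#' length grid and averages, mirroring the cohort-level coronal-ablation
#' summary (mean with SD band as a function of distance along the nerve).
#'
#' @param profiles list of `coronal_profile` objects.
#' @param step common grid step, mm.
#' @return data frame `s_mm`, `mean_rel_err`, `sd_rel_err`, `n`.
#' @export
average_relative_error <- function(profiles, step = 0.1) {
  if (length(profiles) == 0) stop("no profiles supplied")
  ok <- lapply(profiles, function(p) p[p$flag == "ok" & !is.na(p$rel_err), ])
  lmax <- min(vapply(ok, function(p) max(p$s_mm), numeric(1)))
  s <- seq(0, lmax, by = step)
  M <- vapply(ok, function(p)
    stats::approx(p$s_mm, p$rel_err, xout = s, rule = 2)$y,
    numeric(length(s)))
  M <- matrix(M, nrow = length(s))
  data.frame(s_mm = s, mean_rel_err = rowMeans(M),
             sd_rel_err = apply(M, 1, stats::sd), n = ncol(M))
}

#' Align automatic and manual measurements by MAE-minimizing offset
#'
#' Manual reference measurements are taken at the most anteriorly located
#' CSF and at 3 and 5 mm posterior of it; the surface-model origin does not
#' coincide with that anatomical origin, so the offset in `[0, 1]` mm (grid
#' step = the profile step, 0.1 mm) minimizing the mean absolute error
#' between the profile values at `offset + {0, 3, 5}` mm and the three
#' references is found.  Ties prefer the smaller offset.
#'
#' @param profile a `diameter_profile`.
#' @param refs numeric length 3: reference values at 0, +3, +5 mm (same
#'   quantity and unit as `value_col`).
#' @param value_col which profile column to compare (`"d_ce_mm"`,
#'   `"d_mis_mm"` or `"area_mm2"`).
#' @param max_offset search range upper end, mm.
#' @return list with `offset` (mm), `mae` (at the chosen offset), and
#'   `mae_by_location` (length 3 absolute errors).
#' @export
find_offset <- function(profile, refs, value_col = "d_ce_mm",
                        max_offset = 1.0) {
  if (length(refs) != 3) stop("exactly three reference values are required")
  step <- stats::median(diff(profile$s_mm))
  L <- max(profile$s_mm)
  if (L < max_offset + 5) stop("profile must cover at least offset + 5 mm")
  vals <- profile[[value_col]]
  at <- function(s) stats::approx(profile$s_mm, vals, xout = s)$y
  offsets <- seq(0, max_offset, by = step)
  maes <- vapply(offsets, function(o) mean(abs(at(o + c(0, 3, 5)) - refs)),
                 numeric(1))
  best <- which.min(maes)  # which.min takes the first = smallest offset
  list(offset = offsets[best], mae = maes[best],
       mae_by_location = abs(at(offsets[best] + c(0, 3, 5)) - refs))
}

#' Agreement statistics between automatic and manual measurements
#'
#' Mean absolute error, ICC(A,1) (via [icc_a1()]) and Bland-Altman mean
#' difference with 95% limits of agreement (`mean +/- 1.96 SD` of the
#' differences, automatic minus manual).
#'
#' @param auto,manual paired numeric vectors, length >= 3.
#' @return An `agreement_report` list: `mae`, `icc`, `bland_altman`
#'   (`mean_diff`, `loa_lower`, `loa_upper`, `sd_diff`) and `n`.
#' @export
agreement <- function(auto, manual) {
  if (length(auto) != length(manual)) stop("paired vectors differ in length")
  if (length(auto) < 3) stop("need at least 3 pairs")
  dif <- auto - manual
  md <- mean(dif)
  sdd <- stats::sd(dif)
  structure(list(mae = mean(abs(dif)),
                 icc = icc_a1(manual, auto),
                 bland_altman = list(mean_diff = md, sd_diff = sdd,
                                     loa_lower = md - 1.96 * sdd,
                                     loa_upper = md + 1.96 * sdd),
                 n = length(auto)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "agreement over %d pairs: MAE %.4f, ICC(A,1) %.3f\n", x$n, x$mae, x$icc))
  cat(sprintf("Bland-Altman: mean diff %.4f, 95%% LoA [%.4f, %.4f]\n",
              x$bland_altman$mean_diff, x$bland_altman$loa_lower,
              x$bland_altman$loa_upper))
  invisible(x)
}

#' Radial intensity-model baseline for one coronal slice
#'
#' The intensity-model approach segments nerve and CSF from a coronal patch
#' alone: a radially symmetric forward model (dark nerve disc of radius
#' `r_on`, bright CSF annulus to `r_csf`, homogeneous background, convolved
#' with an isotropic Gaussian) is least-squares fitted to the patch.  The
#' model class is only identifiable when a reasonably homogeneous bright
#' annulus surrounds the nerve; the fit therefore raises a quality flag when
#' the fitted annulus contrast is weak relative to the nerve contrast or the
#' annulus intensity is angularly inhomogeneous, the documented failure mode
#' of purely intensity-based diameter estimation on high-resolution data.
#'
#' @param patch 2D numeric matrix (a coronal intensity patch).
#' @param spacing mm per patch axis (length 2 or scalar).
#' @param center patch-relative center of the nerve in mm (defaults to the
#'   patch midpoint).
#' @param init optional named list of starting values.
#' @return list with `r_on`, `r_csf` (mm), `levels` (nerve, csf, background),
#'   `sigma` (blur, mm), `fit_residual` (RMS), `quality_flag` (logical) and
#'   `flag_reason`.
#' @export
fit_intensity_baseline <- function(patch, spacing = c(0.3, 0.3),
                                   center = NULL, init = NULL) {
  if (length(spacing) == 1) spacing <- rep(spacing, 2)
  nx <- nrow(patch); nz <- ncol(patch)
  if (is.null(center))
    center <- c((nx - 1) / 2 * spacing[1], (nz - 1) / 2 * spacing[2])
  X <- (seq_len(nx) - 1) * spacing[1] - center[1]
  Z <- (seq_len(nz) - 1) * spacing[2] - center[2]
  RHO <- sqrt(outer(X^2, Z^2, "+"))
  bg0 <- stats::median(patch[RHO > 0.8 * max(abs(c(X, Z)))])
  if (!is.finite(bg0)) bg0 <- stats::median(patch)
  sm <- matrix(cpp_gauss3(as.numeric(patch), c(nx, 1L, nz), c(1, 0, 1)),
               nx, nz)
  dark0 <- min(sm)
  # radial profile initialization: nerve edge at the half-rise between the
  # dark center and the annulus peak; CSF edge at the half-fall to background
  rb <- cut(RHO, seq(0, max(RHO) + 0.3, by = 0.3 / 2), labels = FALSE)
  prof <- tapply(as.numeric(sm), rb, mean)
  rr <- (as.numeric(names(prof)) - 0.5) * 0.3 / 2
  pk <- max(prof, na.rm = TRUE)
  r_on0 <- 1.2
  half <- (prof[1] + pk) / 2
  above <- which(prof > half & rr > 0.2)
  if (length(above) && pk > prof[1]) r_on0 <- max(0.3, rr[above[1]])
  r_csf0 <- r_on0 + 0.8
  ipk <- which.max(prof)
  beyond <- which(prof < (pk + bg0) / 2 & seq_along(prof) > ipk)
  if (length(beyond)) r_csf0 <- max(rr[beyond[1]], r_on0 + 0.2)
  ini <- list(r_on = r_on0, dr = max(r_csf0 - r_on0, 0.15), nerve = dark0,
              csf = pk, bg = bg0, sigma = 0.3)
  if (!is.null(init)) ini[names(init)] <- init
  rho_max <- max(RHO)
  model_img <- function(par) {
    # clamp to the identifiable region; unconstrained Nelder-Mead otherwise
    # wanders into arbitrarily large radii/blurs
    r_on <- min(exp(par[1]), 0.8 * rho_max)
    dr <- min(exp(par[2]), 0.8 * rho_max)
    lev_n <- par[3]; lev_c <- par[4]; lev_b <- par[5]
    sigma <- min(max(exp(par[6]), 0.02), 0.25 * rho_max)
    img <- matrix(lev_b, nx, nz)
    img[RHO <= r_on + dr] <- lev_c
    img[RHO <= r_on] <- lev_n
    sv <- sigma / spacing
    matrix(cpp_gauss3(as.numeric(img), c(nx, 1L, nz), c(sv[1], 0, sv[2])),
           nx, nz)
  }
  lo_lev <- min(patch) - 3 * stats::sd(patch)
  hi_lev <- max(patch) + 3 * stats::sd(patch)
  obj <- function(par) {
    # soft box penalty keeps the three intensity levels in the data range;
    # without it the simplex can diverge on degenerate (annulus-free) input
    pen <- sum(pmax(0, par[3:5] - hi_lev)^2 + pmax(0, lo_lev - par[3:5])^2)
    sum((model_img(par) - patch)^2) + length(patch) * pen
  }
  # multi-start (the radius/blur trade-off has local minima) with simplex
  # restarts until the objective stops improving (degenerate, annulus-free
  # patches have a flat landscape)
  run_from <- function(p0) {
    fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-9))
    tv <- fit$value
    for (round in 1:4) {
      fit2 <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                           control = list(maxit = 2000, reltol = 1e-9))
      tv <- c(tv, fit2$value)
      improved <- (fit$value - fit2$value) / max(fit$value, 1e-12)
      fit <- fit2
      if (fit2$convergence == 0 || improved < 1e-3) break
    }
    fit$trace_vals <- tv
    fit
  }
  fits <- lapply(c(0.8, 1.0, 1.25), function(fac)
    run_from(c(log(ini$r_on * fac), log(ini$dr), ini$nerve, ini$csf, ini$bg,
               log(ini$sigma))))
  fit <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  trace_vals <- fit$trace_vals
  if (!is.finite(fit$value) ||
      (fit$convergence != 0 &&
       (trace_vals[length(trace_vals) - 1] - fit$value) /
         max(fit$value, 1e-12) > 0.05))
    stop("intensity-model fit did not converge; residual trace: ",
         paste(signif(trace_vals, 6), collapse = " "))
  par <- fit$par
  rho_cap <- 0.8 * rho_max
  r_on <- min(exp(par[1]), rho_cap)
  r_csf <- min(exp(par[1]), rho_cap) + min(exp(par[2]), rho_cap)
  lev_n <- par[3]; lev_c <- par[4]; lev_b <- par[5]
  rms <- sqrt(fit$value / length(patch))
  # quality assessment: annulus contrast and angular homogeneity
  ann <- RHO > r_on & RHO <= r_csf
  reason <- NULL
  # the model is only identifiable when a CSF ring distinctly brighter than
  # the nerve disc exists; otherwise the annulus term just absorbs the disc
  if (sum(ann) < 8 ||
      (lev_c - lev_n) < max(0.5 * abs(lev_n - lev_b), 3 * rms))
    reason <- c(reason, "weak or absent CSF annulus")
  if (sum(ann) >= 8) {
    ang <- atan2(outer(rep(1, nx), Z), outer(X, rep(1, nz)))
    quad <- floor((ang[ann] + pi) / (pi / 2)) %% 4
    qm <- tapply(patch[ann], quad, mean)
    spread <- (max(qm) - min(qm))
    if (length(qm) < 4 || spread > 0.6 * max(lev_c - lev_b, 1e-9))
      reason <- c(reason, "annulus not homogeneously distributed")
  }
  list(r_on = r_on, r_csf = r_csf,
       levels = c(nerve = lev_n, csf = lev_c, background = lev_b),
       sigma = exp(par[6]), fit_residual = rms,
       quality_flag = length(reason) > 0,
       flag_reason = paste(reason, collapse = "; "))
}

#' Synthetic coronal slice for the intensity-model baseline
#'
#' Renders a nerve disc with (optionally asymmetric or absent) CSF annulus on
#' a background, with Gaussian blur and noise; the generator behind the
#' baseline's unit and acceptance tests.
#'
#' @param nx,nz patch size in voxels.
#' @param spacing mm per axis.
#' @param r_on,r_csf nerve and CSF outer radii, mm (`r_csf = r_on` gives no
#'   annulus).
#' @param levels named numeric: `nerve`, `csf`, `background`.
#' @param blur_sigma Gaussian blur, mm.
#' @param noise_sigma additive noise SD.
#' @param csf_arc if < 2*pi, the annulus only spans this angular arc
#'   (asymmetric CSF).
#' @param seed RNG seed.
#' @return list with `patch` (matrix), `spacing`, `center` (mm).
#' @export
synth_coronal_slice <- function(nx = 40, nz = 40, spacing = c(0.3, 0.3),
                                r_on = 1.5, r_csf = 2.5,
                                levels = c(nerve = 100, csf = 300,
                                           background = 50),
                                blur_sigma = 0.3, noise_sigma = 10,
                                csf_arc = 2 * pi, seed = 1L) {
  center <- c((nx - 1) / 2 * spacing[1], (nz - 1) / 2 * spacing[2])
  X <- (seq_len(nx) - 1) * spacing[1] - center[1]
  Z <- (seq_len(nz) - 1) * spacing[2] - center[2]
  RHO <- sqrt(outer(X^2, Z^2, "+"))
  ANG <- atan2(outer(rep(1, nx), Z), outer(X, rep(1, nz)))
  img <- matrix(levels[["background"]], nx, nz)
  ann <- RHO > r_on & RHO <= r_csf & ((ANG + pi) %% (2 * pi)) <= csf_arc
  img[ann] <- levels[["csf"]]
  img[RHO <= r_on] <- levels[["nerve"]]
  if (blur_sigma > 0) {
    sv <- blur_sigma / spacing
    img <- matrix(cpp_gauss3(as.numeric(img), c(nx, 1L, nz),
                             c(sv[1], 0, sv[2])), nx, nz)
  }
  if (noise_sigma > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                       .GlobalEnv) else NULL
    set.seed(seed)
    img <- img + matrix(stats::rnorm(nx * nz, 0, noise_sigma), nx, nz)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  list(patch = img, spacing = spacing, center = center)
}
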