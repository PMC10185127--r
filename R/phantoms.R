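#' Synthetic optic-nerve phantom specification
#'
#' Describes a synthetic 3D T2-weighted-like volume: a curved dark tube (the
#' nerve) of varying radius, surrounded by a bright shell of variable
#' thickness (the CSF sheath), optionally one or two bright spheres (eye
#' globes), a homogeneous background, a smooth multiplicative polynomial bias
#' field and additive Gaussian noise.  Every phantom carries analytic ground
#' truth (centerline, radius and area profiles), so all downstream stages can
#' be validated without any acquired data.
#'
#' Radius and shell-thickness profiles are piecewise linear in relative arc
#' length: data frames with columns `frac` (0..1 along the curve) and `mm`.
#' Intensity levels default to the T2-like contrast the pipeline assumes:
#' dark nerve on a mid background with a bright CSF sheath and bright globe.
#'
#' @param grid_shape integer length-3, voxel counts per axis.
#' @param spacing mm per axis (scalar or length 3).
#' @param origin world mm of the first voxel center.
#' @param curve_control_points n x 3 matrix of ordered world points (mm)
#'   defining the nerve path, anterior to posterior.
#' @param radius_profile data frame (`frac`, `mm`): nerve radius r(s).
#' @param csf_thickness_profile data frame (`frac`, `mm`): shell thickness,
#'   may be 0 locally or everywhere.
#' @param globe_centers 0-2 world points (rows of a matrix), or `NULL`.
#' @param globe_radius globe radius in mm.
#' @param intensities named list: `background`, `nerve`, `csf`, `globe`.
#' @param noise_sigma additive Gaussian noise standard deviation.
#' @param bias_coeffs named numeric vector of low-order polynomial bias-field
#'   coefficients over coordinates normalized to \[-1, 1\]; names among
#'   `x, y, z, xx, yy, zz, xy, xz, yz`.  The field is `1 + sum(c_i * term_i)`.
#' @param seed RNG seed for the noise.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         spacing = 0.3,
                         origin = c(0, 0, 0),
                         curve_control_points = rbind(
                           c(9.45, 16.0, 9.45),
                           c(8.80, 12.0, 9.45),
                           c(9.50, 7.0, 9.80),
                           c(10.80, 2.8, 10.20)),
                         radius_profile = data.frame(
                           frac = c(0, 0.35, 1), mm = c(1.6, 1.25, 1.6)),
                         csf_thickness_profile = data.frame(
                           frac = c(0, 0.5, 1), mm = c(0.7, 0.45, 0.3)),
                         globe_centers = NULL,
                         globe_radius = 11,
                         intensities = list(background = 50, nerve = 100,
                                            csf = 300, globe = 280),
                         noise_sigma = 10,
                         bias_coeffs = c(x = 0, y = 0, z = 0),
                         seed = 1L) {
  spacing <- if (length(spacing) == 1L) rep(spacing, 3) else as.numeric(spacing)
  if (any(spacing <= 0)) stop("spacing must be > 0")
  if (any(radius_profile$mm <= 0)) stop("all nerve radii must be > 0")
  if (any(csf_thickness_profile$mm < 0)) stop("CSF thickness must be >= 0")
  if (!is.null(globe_centers)) {
    globe_centers <- matrix(globe_centers, ncol = 3)
    if (nrow(globe_centers) > 2) stop("at most two globe centers")
    if (globe_radius <= 0) stop("globe radius must be > 0")
  }
  spec <- structure(list(
    grid_shape = as.integer(grid_shape), spacing = spacing,
    origin = as.numeric(origin),
    curve_control_points = matrix(curve_control_points, ncol = 3),
    radius_profile = radius_profile,
    csf_thickness_profile = csf_thickness_profile,
    globe_centers = globe_centers, globe_radius = globe_radius,
    intensities = intensities, noise_sigma = noise_sigma,
    bias_coeffs = bias_coeffs, seed = as.integer(seed)),
    class = "phantom_spec")
  spec
}

profile_at <- function(profile, frac) {
  stats::approx(profile$frac, profile$mm, xout = pmin(pmax(frac, 0), 1),
                rule = 2)$y
}

#' Arc-length parameterized smooth curve through control points
#'
#' Fits a natural cubic spline through the ordered control points (chord-length
#' parameterization), reparameterizes by arc length and resamples at steps of
#' at most 0.05 mm.  Radius, shell and area profiles are evaluated along the
#' curve, yielding the phantom's analytic ground truth.
#'
#' @param spec a [phantom_spec()].
#' @param step resampling step in mm (<= 0.05).
#' @return A `phantom_truth` object: `centerline_points` (n x 3 world mm),
#'   `arclengths` (mm, strictly increasing), `tangents` (unit vectors),
#'   `radius_at_s`, `csf_outer_radius_at_s` (mm) and `area_at_s`
#'   (`pi * r(s)^2`, mm^2).
#' @export
build_curve <- function(spec, step = 0.05) {
  cp <- spec$curve_control_points
  if (nrow(cp) < 2) stop("need at least 2 control points")
  seglen <- sqrt(rowSums((cp[-1, , drop = FALSE] -
                            cp[-nrow(cp), , drop = FALSE])^2))
  if (any(seglen < 1e-9)) stop("coincident consecutive control points")
  u <- c(0, cumsum(seglen))
  dense_n <- max(200L, as.integer(ceiling(4 * u[length(u)] / step)))
  ud <- seq(0, u[length(u)], length.out = dense_n)
  interp1 <- function(y) {
    if (nrow(cp) == 2) stats::approx(u, y, xout = ud)$y
    else stats::spline(u, y, xout = ud, method = "natural")$y
  }
  P <- cbind(interp1(cp[, 1]), interp1(cp[, 2]), interp1(cp[, 3]))
  ds <- sqrt(rowSums((P[-1, ] - P[-nrow(P), ])^2))
  s_dense <- c(0, cumsum(ds))
  L <- s_dense[length(s_dense)]
  if (L <= 0) stop("curve arc length must be > 0")
  s <- seq(0, L, by = step)
  if (L - s[length(s)] > step / 4) s <- c(s, L) else s[length(s)] <- L
  Q <- cbind(stats::approx(s_dense, P[, 1], xout = s)$y,
             stats::approx(s_dense, P[, 2], xout = s)$y,
             stats::approx(s_dense, P[, 3], xout = s)$y)
  n <- nrow(Q)
  tg <- rbind(Q[2, ] - Q[1, ],
              Q[3:n, , drop = FALSE] - Q[1:(n - 2), , drop = FALSE],
              Q[n, ] - Q[n - 1, ])
  tg <- tg / sqrt(rowSums(tg^2))
  r <- profile_at(spec$radius_profile, s / L)
  th <- profile_at(spec$csf_thickness_profile, s / L)
  structure(list(centerline_points = Q, arclengths = s, tangents = tg,
                 radius_at_s = r, csf_outer_radius_at_s = r + th,
                 area_at_s = pi * r^2, length = L),
            class = "phantom_truth")
}

# maximal curvature of the truth centerline (1/mm), for the self-intersection
# invariant r + shell < bending radius
curve_max_curvature <- function(truth) {
  Q <- truth$centerline_points
  s <- truth$arclengths
  n <- nrow(Q)
  if (n < 3) return(0)
  i <- seq(2, n - 1, by = max(1L, n %/% 400))
  h1 <- s[i] - s[i - 1]; h2 <- s[i + 1] - s[i]
  dd <- (Q[i + 1, , drop = FALSE] - Q[i, , drop = FALSE]) / h2 -
    (Q[i, , drop = FALSE] - Q[i - 1, , drop = FALSE]) / h1
  kappa <- sqrt(rowSums((2 * dd / (h1 + h2))^2))
  max(kappa)
}

#' Rasterize a phantom onto its voxel grid
#'
#' Produces the noisy intensity volume together with the noise-free nerve and
#' CSF masks and the analytic truth.  A voxel belongs to the nerve when its
#' distance to the curve is at most `r(s)` at the nearest curve point; the
#' CSF mask is the shell between `r(s)` and `r(s) + thickness(s)`.  Intensity
#' composition order is background, globe, CSF, nerve (the nerve is drawn
#' last); the volume is multiplied by the polynomial bias field and seeded
#' Gaussian noise is added.  Masks are never noised.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` ([volume_grid()]), `nerve`, `csf`
#'   ([binary_mask()]) and `truth` (`phantom_truth`).
#' @export
rasterize_phantom <- function(spec) {
  truth <- build_curve(spec)
  kmax <- curve_max_curvature(truth)
  if (kmax > 0 && max(truth$csf_outer_radius_at_s) >= 1 / kmax)
    stop("radius + shell thickness exceeds the curve's minimum bending radius")
  d <- spec$grid_shape; sp <- spec$spacing; org <- spec$origin
  lo <- org - sp / 2
  hi <- org + (d - 1) * sp + sp / 2
  rout <- truth$csf_outer_radius_at_s
  for (ax in 1:3) {
    if (any(truth$centerline_points[, ax] - rout < lo[ax]) ||
        any(truth$centerline_points[, ax] + rout > hi[ax]))
      stop(sprintf("tube exits the grid along the %s axis",
                   c("x", "y", "z")[ax]))
  }
  td <- cpp_tube_distance(d, sp, org, truth$centerline_points,
                          truth$arclengths, rout + 2 * max(sp))
  # flat caps: project each candidate voxel onto the curve through its
  # nearest sample's tangent and keep only arc lengths within [0, L]
  cand <- which(!is.na(td$pmin))
  s_proj <- rep(NA_real_, length(td$smin))
  if (length(cand)) {
    Xw <- index_to_world(volume_grid(array(0, d), sp, org), arrayInd(cand, d))
    pi_ <- td$pmin[cand]
    Q <- truth$centerline_points[pi_, , drop = FALSE]
    Tg <- truth$tangents[pi_, , drop = FALSE]
    s_proj[cand] <- td$smin[cand] + rowSums((Xw - Q) * Tg)
  }
  inside <- !is.na(s_proj) & s_proj >= 0 & s_proj <= truth$length
  s_eval <- pmin(pmax(s_proj, 0), truth$length)
  r_near <- stats::approx(truth$arclengths, truth$radius_at_s,
                          xout = s_eval, rule = 2)$y
  rc_near <- stats::approx(truth$arclengths, truth$csf_outer_radius_at_s,
                           xout = s_eval, rule = 2)$y
  nerve <- inside & td$dmin <= r_near
  csf <- inside & !nerve & td$dmin <= rc_near
  iv <- spec$intensities
  vol <- rep(iv$background, prod(d))
  if (!is.null(spec$globe_centers)) {
    cx <- org[1] + (seq_len(d[1]) - 1) * sp[1]
    cy <- org[2] + (seq_len(d[2]) - 1) * sp[2]
    cz <- org[3] + (seq_len(d[3]) - 1) * sp[3]
    for (g in seq_len(nrow(spec$globe_centers))) {
      gc <- spec$globe_centers[g, ]
      d2 <- outer(outer((cx - gc[1])^2, (cy - gc[2])^2, "+"),
                  (cz - gc[3])^2, "+")
      vol[d2 <= spec$globe_radius^2] <- iv$globe
    }
  }
  vol[csf] <- iv$csf
  vol[nerve] <- iv$nerve
  vol <- vol * bias_field_values(spec)
  if (spec$noise_sigma > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                       .GlobalEnv) else NULL
    set.seed(spec$seed)
    vol <- vol + stats::rnorm(length(vol), 0, spec$noise_sigma)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  list(volume = volume_grid(array(vol, d), sp, org),
       nerve = binary_mask(array(nerve, d), sp, org),
       csf = binary_mask(array(csf, d), sp, org),
       truth = truth)
}

# evaluate the multiplicative bias field over the grid (unit level = 1)
bias_field_values <- function(spec) {
  d <- spec$grid_shape
  cf <- spec$bias_coeffs
  if (is.null(cf) || all(cf == 0)) return(1)
  u <- if (d[1] > 1) seq(-1, 1, length.out = d[1]) else 0
  v <- if (d[2] > 1) seq(-1, 1, length.out = d[2]) else 0
  w <- if (d[3] > 1) seq(-1, 1, length.out = d[3]) else 0
  U <- rep(u, times = d[2] * d[3])
  V <- rep(rep(v, each = d[1]), times = d[3])
  W <- rep(w, each = d[1] * d[2])
  terms <- list(x = U, y = V, z = W, xx = U * U, yy = V * V, zz = W * W,
                xy = U * V, xz = U * W, yz = V * W)
  f <- rep(1, prod(d))
  for (nm in names(cf)) {
    if (cf[[nm]] == 0) next
    if (is.null(terms[[nm]])) stop("unknown bias term: ", nm)
    f <- f + cf[[nm]] * terms[[nm]]
  }
  f
}

#' Two-globe head phantom specification
#'
#' A larger phantom emulating the head-level field of view the preprocessing
#' stage expects: two bright eye globes with one nerve running posteriorly
#' from each, on a homogeneous background.  The default geometry follows the
#' anatomy the pipeline assumes (globe radius ~11 mm, inter-ocular distance
#' ~60 mm, nerves converging toward a chiasm point).
#'
#' @param spacing isotropic voxel size in mm (coarser values keep the volume
#'   small for testing).
#' @param rotation_deg in-plane (axial) head rotation applied to all
#'   world-space landmarks.
#' @param globe_radius globe radius, mm.
#' @param noise_sigma additive noise level.
#' @param seed RNG seed.
#' @param single_globe generate only the right globe (degenerate input for
#'   detector error handling).
#' @return A [phantom_spec()].
#' @export
head_phantom_spec <- function(spacing = 0.6, rotation_deg = 0,
                              globe_radius = 11, noise_sigma = 10, seed = 1L,
                              single_globe = FALSE) {
  rot <- function(p) {
    a <- rotation_deg * pi / 180
    R <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
    t(R %*% t(matrix(p, ncol = 3)))
  }
  centers <- rbind(c(-30, 40, 0), c(30, 40, 0))
  if (single_globe) centers <- centers[2, , drop = FALSE]
  centers <- rot(centers)
  # right nerve: from behind the right globe toward the chiasm
  curve <- rot(rbind(c(30, 29.5, 0), c(25, 22, 0.5), c(15, 14, 1),
                     c(4, 9, 1.5)))
  lo <- c(-48, -2, -16)
  hi <- c(48, 56, 16)
  shape <- as.integer(ceiling((hi - lo) / spacing))
  phantom_spec(grid_shape = shape, spacing = spacing, origin = lo,
               curve_control_points = curve,
               radius_profile = data.frame(frac = c(0, 1), mm = c(1.8, 1.4)),
               csf_thickness_profile = data.frame(frac = c(0, 1),
                                                  mm = c(0.7, 0.4)),
               globe_centers = centers, globe_radius = globe_radius,
               noise_sigma = noise_sigma, seed = seed)
}

#' Write a phantom to disk
#'
#' Writes `volume.nii.gz`, `nerve.nii.gz`, `csf.nii.gz`, the analytic truth
#' as `truth.csv` (columns `s_mm, x, y, z, r_mm, area_mm2`) and a JSON dump
#' of the spec.
#'
#' @param spec a [phantom_spec()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ph <- rasterize_phantom(spec)
  write_nifti(ph$volume, file.path(dir, "volume.nii.gz"))
  write_nifti(ph$nerve, file.path(dir, "nerve.nii.gz"))
  write_nifti(ph$csf, file.path(dir, "csf.nii.gz"))
  tr <- ph$truth
  utils::write.csv(data.frame(
    s_mm = tr$arclengths, x = tr$centerline_points[, 1],
    y = tr$centerline_points[, 2], z = tr$centerline_points[, 3],
    r_mm = tr$radius_at_s, area_mm2 = tr$area_at_s),
    file.path(dir, "truth.csv"), row.names = FALSE)
  sp <- spec
  sp$curve_control_points <- unclass(sp$curve_control_points)
  writeLines(jsonlite::toJSON(unclass(sp), auto_unbox = TRUE, digits = NA,
                              null = "null"),
             file.path(dir, "spec.json"))
  invisible(dir)
}

#' Read a phantom spec from a JSON dump
#' @param path JSON file written by [write_phantom()] or by hand.
#' @return A [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  j <- jsonlite::fromJSON(path)
  phantom_spec(grid_shape = j$grid_shape, spacing = j$spacing,
               origin = j$origin,
               curve_control_points = matrix(j$curve_control_points, ncol = 3),
               radius_profile = as.data.frame(j$radius_profile),
               csf_thickness_profile = as.data.frame(j$csf_thickness_profile),
               globe_centers = if (is.null(j$globe_centers)) NULL else
                 matrix(j$globe_centers, ncol = 3),
               globe_radius = j$globe_radius %||% 11,
               intensities = j$intensities,
               noise_sigma = j$noise_sigma,
               bias_coeffs = unlist(j$bias_coeffs),
               seed = j$seed)
}
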