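#' @useDynLib onquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile rnorm runif sd var lm optim predict
#' @importFrom utils head read.csv tail write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' 3D scalar image on a regular grid
#'
#' A `volume_grid` couples a 3D numeric array with its world geometry: voxel
#' spacing (mm per axis), the world position of the center of voxel
#' `[1, 1, 1]` (`origin`, mm) and a 3x3 orthonormal `direction` matrix.  The
#' package works in an RAS world frame: +x right (lateral), +y anterior,
#' +z superior; the coronal plane has unit normal `(0, 1, 0)`.
#'
#' @param voxels 3D numeric array.
#' @param spacing numeric length-3, mm per axis; all > 0.
#' @param origin numeric length-3, world mm of the first voxel center.
#' @param direction 3x3 orthonormal matrix (defaults to identity).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(voxels, spacing, origin = c(0, 0, 0),
                        direction = diag(3)) {
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  if (any(spacing <= 0)) stop("spacing must be > 0 on all axes")
  direction <- as.matrix(direction)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("direction matrix must be orthonormal")
  structure(list(voxels = voxels, spacing = spacing,
                 origin = as.numeric(origin), direction = direction),
            class = "volume_grid")
}

#' Binary labelling on a volume grid
#'
#' @param voxels array whose non-zero entries mark foreground.
#' @inheritParams volume_grid
#' @return An object of class `c("binary_mask", "volume_grid")` whose voxels
#'   are stored as integer 0/1.
#' @export
binary_mask <- function(voxels, spacing, origin = c(0, 0, 0),
                        direction = diag(3)) {
  vg <- volume_grid(array(as.integer(voxels != 0), dim(voxels)), spacing,
                    origin, direction)
  class(vg) <- c("binary_mask", "volume_grid")
  vg
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin %s mm\n",
              class(x)[1], paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$voxels)

as_mask <- function(vg) {
  vg$voxels <- array(as.integer(vg$voxels != 0), dim(vg$voxels))
  class(vg) <- unique(c("binary_mask", class(vg)))
  vg
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol &&
    max(abs(a$direction - b$direction)) < tol
}

stopifnot_same_grid <- function(a, b) {
  if (!same_grid(a, b)) stop("masks are not defined on the same grid")
}

#' World coordinates of voxel indices
#'
#' @param vg a `volume_grid`.
#' @param idx n x 3 matrix of 1-based voxel indices (may be fractional).
#' @return n x 3 matrix of world mm.
#' @export
index_to_world <- function(vg, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(t(vg$direction %*% t(sweep(idx - 1, 2, vg$spacing, "*"))), 2,
        vg$origin, "+")
}

#' @rdname index_to_world
#' @param world n x 3 matrix of world mm.
#' @export
world_to_index <- function(vg, world) {
  world <- matrix(as.numeric(world), ncol = 3)
  sweep(t(t(vg$direction) %*% t(sweep(world, 2, vg$origin, "-"))), 2,
        vg$spacing, "/") + 1
}

# world coordinates of all foreground voxel centers of a mask
mask_points <- function(mask) {
  w <- which(mask$voxels != 0, arr.ind = TRUE)
  index_to_world(mask, w)
}

# trilinear sample of a volume at fractional 1-based indices; outside -> fill
interp_trilinear <- function(vox, idx, fill = 0) {
  d <- dim(vox)
  i <- idx[, 1]; j <- idx[, 2]; k <- idx[, 3]
  fi <- floor(i); fj <- floor(j); fk <- floor(k)
  ok <- fi >= 1 & fi + 1 <= d[1] & fj >= 1 & fj + 1 <= d[2] &
    fk >= 1 & fk + 1 <= d[3]
  out <- rep(fill, length(i))
  if (!any(ok)) return(out)
  ax <- i[ok] - fi[ok]; ay <- j[ok] - fj[ok]; az <- k[ok] - fk[ok]
  acc <- 0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) ax else 1 - ax) * (if (dy) ay else 1 - ay) *
      (if (dz) az else 1 - az)
    acc <- acc + w * vox[cbind(fi[ok] + dx, fj[ok] + dy, fk[ok] + dz)]
  }
  out[ok] <- acc
  out
}

# separable Gaussian smoothing, sigma in mm (scalar) converted per axis
smooth_gaussian <- function(vg, sigma_mm) {
  sv <- sigma_mm / vg$spacing
  out <- vg
  out$voxels <- array(cpp_gauss3(as.numeric(vg$voxels), dim(vg$voxels), sv),
                      dim(vg$voxels))
  out
}

# ---------------------------------------------------------------------------
# Minimal NIfTI-1 single-file I/O (.nii / .nii.gz).  No NIfTI reader exists in
# the dependency set, so the format is implemented here: 348-byte header,
# sform affine, little-endian by default with byte-swapped reading supported.
# Only 3D volumes and scalar datatypes are handled, which covers the
# pipeline's contract.

NIFTI_DT <- list(`2` = list(what = "integer", size = 1L, signed = FALSE),
                 `4` = list(what = "integer", size = 2L, signed = TRUE),
                 `8` = list(what = "integer", size = 4L, signed = TRUE),
                 `16` = list(what = "double", size = 4L, signed = TRUE),
                 `64` = list(what = "double", size = 8L, signed = TRUE),
                 `256` = list(what = "integer", size = 1L, signed = TRUE),
                 `512` = list(what = "integer", size = 2L, signed = FALSE))

#' Read a NIfTI-1 volume
#'
#' Reads single-file `.nii` or `.nii.gz` images.  If an sform affine is
#' present it must be axis-aligned up to orthonormal rotation; spacing,
#' origin and direction are taken from it, otherwise from `pixdim` with an
#' identity direction.
#'
#' @param path file path.
#' @return A [volume_grid()] (a [binary_mask()] if the data are 0/1 integers).
#' @export
read_nifti <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", 1L, 4L, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", 1L, 4L, endian = endian)
    if (sz != 348L) stop("not a NIfTI-1 file: ", path)
  }
  rint16 <- function(off, n) readBin(hdr[(off + 1):(off + 2 * n)], "integer",
                                     n, 2L, endian = endian)
  rfloat <- function(off, n) readBin(hdr[(off + 1):(off + 4 * n)], "double",
                                     n, 4L, endian = endian)
  dims <- rint16(40, 8)
  ndim <- dims[1]
  if (ndim < 3L) stop("expected a 3D NIfTI volume")
  nx <- dims[2]; ny <- dims[3]; nz <- dims[4]
  if (ndim > 3L && any(dims[5:(ndim + 1)] > 1L))
    stop("only 3D NIfTI volumes are supported")
  datatype <- rint16(70, 1)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", datatype)
  pixdim <- rfloat(76, 8)
  vox_offset <- rfloat(108, 1)
  scl_slope <- rfloat(112, 1)
  scl_inter <- rfloat(116, 1)
  sform_code <- rint16(254, 1)
  srow <- matrix(rfloat(280, 12), nrow = 3, byrow = TRUE)
  nvox <- as.numeric(nx) * ny * nz
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  vals <- readBin(con, dt$what, n = nvox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) < nvox) stop("truncated NIfTI data in ", path)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  vox <- array(vals, c(nx, ny, nz))
  if (sform_code > 0) {
    R <- srow[, 1:3]
    spacing <- sqrt(colSums(R^2))
    direction <- sweep(R, 2, spacing, "/")
    origin <- srow[, 4]
  } else {
    spacing <- pixdim[2:4]
    direction <- diag(3)
    origin <- c(0, 0, 0)
  }
  vg <- volume_grid(vox, spacing, origin, direction)
  if (is.integer(vals) && all(vals %in% c(0L, 1L))) vg <- as_mask(vg)
  vg
}

#' Write a NIfTI-1 volume
#'
#' @param vg a [volume_grid()] or [binary_mask()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param datatype `"auto"` (uint8 for masks, float32 otherwise),
#'   `"uint8"`, `"float32"` or `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vg, path, datatype = "auto") {
  if (datatype == "auto")
    datatype <- if (inherits(vg, "binary_mask")) "uint8" else "float32"
  code <- switch(datatype, uint8 = 2L, float32 = 16L, float64 = 64L,
                 stop("unsupported datatype: ", datatype))
  size <- switch(datatype, uint8 = 1L, float32 = 4L, float64 = 8L)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  d <- dim(vg$voxels)
  wi32 <- function(x) writeBin(as.integer(x), con, 4L, endian = "little")
  wi16 <- function(x) writeBin(as.integer(x), con, 2L, endian = "little")
  wf32 <- function(x) writeBin(as.numeric(x), con, 4L, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)
  wi32(348)                                  # sizeof_hdr
  wraw(36)                                   # data_type..dim_info
  wi16(c(3, d, 1, 1, 1, 1))                  # dim[8]
  wf32(c(0, 0, 0)); wi16(0)                  # intent
  wi16(code); wi16(size * 8L); wi16(0)       # datatype, bitpix, slice_start
  wf32(c(1, vg$spacing, 0, 0, 0, 0))         # pixdim
  wf32(352); wf32(1); wf32(0)                # vox_offset, scl
  wi16(0); wraw(2)                           # slice_end, slice_code, xyzt
  wf32(c(0, 0, 0, 0))                        # cal_max/min, slice_dur, toffset
  wi32(c(0, 0))                              # glmax, glmin
  wraw(104)                                  # descrip, aux_file
  wi16(0); wi16(1)                           # qform_code, sform_code
  wf32(rep(0, 6))                            # quatern, qoffset
  R <- vg$direction %*% diag(vg$spacing)
  wf32(c(R[1, ], vg$origin[1]))
  wf32(c(R[2, ], vg$origin[2]))
  wf32(c(R[3, ], vg$origin[3]))
  wraw(16)                                   # intent_name
  writeBin(charToRaw("n+1"), con); wraw(1)   # magic
  wraw(4)                                    # extension flag
  if (code == 2L) {
    writeBin(as.integer(vg$voxels), con, 1L)
  } else {
    writeBin(as.numeric(vg$voxels), con, size, endian = "little")
  }
  invisible(path)
}
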