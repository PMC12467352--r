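# Separable 1D Gaussian convolution along one array axis with reflective
# boundary handling; sigma in voxels.
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k / sum(k)
}

convolve_axis <- function(a, k, axis) {
  r <- (length(k) - 1L) / 2L
  if (r == 0L) return(a)
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  n <- dim(ap)[1]
  m <- matrix(ap, nrow = n)
  idx <- c(rev(seq_len(min(r, n))), seq_len(n),
           rev(n + 1 - seq_len(min(r, n))))   # reflect edges
  if (r > n) stop("smoothing kernel wider than the grid")
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k))
    out <- out + k[j] * mp[(j - 1L) + seq_len(n), , drop = FALSE]
  res <- array(out, dim(ap))
  aperm(res, order(perm))
}

gaussian_smooth3d <- function(a, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  for (ax in 1:3)
    if (sigma_vox[ax] > 0) a <- convolve_axis(a, gauss_kernel(sigma_vox[ax]), ax)
  a
}

# Trilinear interpolation of a 3D array at fractional voxel coordinates
# (1-based), clamped at the edges.
trilinear <- function(a, x, y, z) {
  d <- dim(a)
  cl <- function(v, n) pmin(pmax(v, 1), n)
  x <- cl(x, d[1]); y <- cl(y, d[2]); z <- cl(z, d[3])
  x0 <- pmin(floor(x), d[1] - 1L); y0 <- pmin(floor(y), d[2] - 1L)
  z0 <- pmin(floor(z), d[3] - 1L)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  at <- function(i, j, k) a[cbind(i, j, k)]
  v <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wgt <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    v <- v + wgt * at(x0 + dx, y0 + dy, z0 + dz)
  }
  v
}

#' Smooth and resample a gray-matter occupancy map
#'
#' Applies a Gaussian filter of the given full width at half maximum
#' (default 5 mm; sigma = FWHM / 2.3548, converted to voxels per axis) and
#' resamples the result to the target isotropic resolution (default 2 mm).
#' When the target spacing is an integer multiple of the input spacing on
#' every axis, non-overlapping block averaging is used; otherwise trilinear
#' interpolation at the new voxel centres. Input values are clipped into
#' `[0, 1]` (tolerating segmentation round-off up to `eps`), and so is the
#' output.
#'
#' @param occ_native a [vol3d()] occupancy map in native resolution.
#' @param fwhm_mm Gaussian full width at half maximum in mm.
#' @param target_mm target isotropic voxel size in mm.
#' @param eps tolerated out-of-range excursion of the input values.
#' @return a [vol3d()] occupancy map at `target_mm` resolution.
#' @export
prepare_occupancy <- function(occ_native, fwhm_mm = 5, target_mm = 2,
                              eps = 1e-3) {
  stopifnot(inherits(occ_native, "vol3d"))
  a <- occ_native$data
  if (min(a) < -eps || max(a) > 1 + eps)
    stop("occupancy values outside [0, 1] beyond tolerance")
  a <- pmin(pmax(a, 0), 1)
  vox <- occ_native$voxel_size_mm
  extent <- dim(a) * vox
  if (any(target_mm > extent))
    stop("target resolution coarser than the grid extent")
  sigma_vox <- (fwhm_mm / 2.3548) / vox
  a <- gaussian_smooth3d(a, sigma_vox)

  factor <- target_mm / vox
  if (all(abs(factor - round(factor)) < 1e-9)) {
    f <- as.integer(round(factor))
    dn <- dim(a) %/% f
    if (any(dn < 1L)) stop("target resolution coarser than the grid extent")
    a <- a[seq_len(dn[1] * f[1]), seq_len(dn[2] * f[2]),
           seq_len(dn[3] * f[3]), drop = FALSE]
    # block average: collapse each f-sized block to its mean
    dim(a) <- c(f[1], dn[1], f[2], dn[2], f[3], dn[3])
    out <- apply(a, c(2, 4, 6), mean)
  } else {
    dn <- pmax(1L, floor(extent / target_mm))
    # centres of the new voxels, expressed in input voxel coordinates
    coord <- function(ax) ((seq_len(dn[ax]) - 0.5) * target_mm) / vox[ax] + 0.5
    g <- expand.grid(x = coord(1), y = coord(2), z = coord(3))
    out <- array(trilinear(a, g$x, g$y, g$z), dn)
  }
  vol3d(pmin(pmax(out, 0), 1), voxel_size_mm = rep(target_mm, 3))
}
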