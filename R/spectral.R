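#' Eight-bin spectral band schema
#'
#' The default schema covers 0-0.64 Hz with eight contiguous 0.08 Hz bins
#' centred at 0.04, 0.12, 0.20, 0.28, 0.36, 0.44, 0.52 and 0.60 Hz. Bin
#' membership is half-open: a DFT ordinate at frequency f belongs to bin i
#' iff `low_i <= f < high_i`; the ordinate at exactly 0 Hz is excluded
#' (the series is demeaned anyway).
#'
#' @param midpoints_hz ordered bin midpoints in Hz.
#' @param bin_width_hz common bin width in Hz.
#' @return an object of class `"band_schema"` with derived `low`/`high`
#'   edges.
#' @export
band_schema <- function(midpoints_hz = c(0.04, 0.12, 0.20, 0.28,
                                         0.36, 0.44, 0.52, 0.60),
                        bin_width_hz = 0.08) {
  stopifnot(length(midpoints_hz) >= 1L, bin_width_hz > 0)
  if (is.unsorted(midpoints_hz, strictly = TRUE))
    stop("midpoints must be strictly increasing")
  low <- midpoints_hz - bin_width_hz / 2
  high <- midpoints_hz + bin_width_hz / 2
  if (any(low < -1e-12)) stop("bin edges must be nonnegative")
  if (any(diff(midpoints_hz) < bin_width_hz - 1e-12))
    stop("adjacent bins overlap")
  structure(list(midpoints_hz = midpoints_hz, bin_width_hz = bin_width_hz,
                 low = pmax(low, 0), high = high),
            class = "band_schema")
}

#' @export
print.band_schema <- function(x, ...) {
  cat(sprintf("<band_schema> %d bins, %g Hz wide, midpoints %s Hz\n",
              length(x$midpoints_hz), x$bin_width_hz,
              paste(x$midpoints_hz, collapse = ", ")))
  invisible(x)
}

# One-sided periodogram of a demeaned, linearly detrended series.
# Returns freq (Hz, excluding DC) and power, where sum(power) equals the
# detrended series' sum of squares (Parseval with the |X_k|^2 / T scaling).
periodogram_onesided <- function(x, tr_seconds) {
  n <- length(x)
  t0 <- seq_len(n) - (n + 1) / 2            # centred time index
  x <- x - mean(x) - t0 * sum(x * t0) / sum(t0 * t0)  # linear detrend
  X <- stats::fft(x)
  kmax <- floor(n / 2)
  k <- seq_len(kmax)
  w <- rep(2, kmax)
  if (n %% 2 == 0) w[kmax] <- 1            # Nyquist ordinate is unpaired
  list(freq = k / (n * tr_seconds), power = w * Mod(X[k + 1])^2 / n)
}

#' Spectral band powers of one voxel time series
#'
#' The series is linearly detrended (which also removes the mean), a
#' one-sided periodogram is computed on the raw DFT frequency grid, and
#' periodogram ordinates are summed within each bin's half-open
#' `[low, high)` interval.
#'
#' @param series numeric vector, length >= 16.
#' @param tr_seconds sampling interval (repetition time) in seconds.
#' @param schema a [band_schema()].
#' @param allow_partial if `FALSE` (default) an error is raised when the
#'   Nyquist frequency `1/(2 tr)` lies below the highest bin edge. If
#'   `TRUE`, bins lying entirely above Nyquist are returned as 0 and bins
#'   straddling Nyquist sum the ordinates that exist; the result carries a
#'   `"partial_bins"` attribute naming them.
#' @param average if `TRUE`, ordinates are averaged per bin rather than
#'   summed (a per-bin monotone rescaling).
#' @return numeric vector of nonnegative band powers, one per bin.
#' @export
band_powers <- function(series, tr_seconds, schema = band_schema(),
                        allow_partial = FALSE, average = FALSE) {
  n <- length(series)
  if (n < 16L) stop("series too short (need T >= 16, got ", n, ")")
  if (any(!is.finite(series))) stop("series contains non-finite values")
  nyq <- 1 / (2 * tr_seconds)
  if (max(schema$high) > nyq + 1e-12 && !allow_partial)
    stop(sprintf(paste0("Nyquist frequency %.4g Hz is below the highest bin ",
                        "edge %.4g Hz; set allow_partial = TRUE to proceed"),
                 nyq, max(schema$high)))
  pg <- periodogram_onesided(series, tr_seconds)
  nb <- length(schema$low)
  out <- numeric(nb)
  partial <- character(0)
  for (i in seq_len(nb)) {
    sel <- pg$freq >= schema$low[i] - 1e-12 & pg$freq < schema$high[i] - 1e-12
    if (schema$low[i] >= nyq - 1e-12) {           # fully above Nyquist
      out[i] <- 0
      partial <- c(partial, sprintf("bin%d_above_nyquist", i))
      next
    }
    if (!any(sel))
      stop(sprintf(paste0("series too short: no DFT ordinate falls in bin %d ",
                          "[%.3g, %.3g) Hz"), i, schema$low[i], schema$high[i]))
    out[i] <- if (average) mean(pg$power[sel]) else sum(pg$power[sel])
    if (schema$high[i] > nyq + 1e-12)
      partial <- c(partial, sprintf("bin%d_truncated_at_nyquist", i))
  }
  if (length(partial)) attr(out, "partial_bins") <- partial
  out
}

# Band powers for many series at once: X is a T x n matrix (columns =
# voxels). Same estimator as band_powers(), vectorised with mvfft.
band_powers_matrix <- function(X, tr_seconds, schema = band_schema(),
                               allow_partial = FALSE, average = FALSE) {
  n <- nrow(X)
  nyq <- 1 / (2 * tr_seconds)
  if (max(schema$high) > nyq + 1e-12 && !allow_partial)
    stop("Nyquist frequency below the highest bin edge; set allow_partial")
  t0 <- seq_len(n) - (n + 1) / 2
  X <- sweep(X, 2, colMeans(X))
  X <- X - outer(t0, colSums(X * t0) / sum(t0 * t0))
  F <- stats::mvfft(X)
  kmax <- floor(n / 2)
  w <- rep(2, kmax)
  if (n %% 2 == 0) w[kmax] <- 1
  P <- (Mod(F[1 + seq_len(kmax), , drop = FALSE])^2 / n) * w
  freq <- seq_len(kmax) / (n * tr_seconds)
  nb <- length(schema$low)
  out <- matrix(0, ncol(X), nb)
  for (i in seq_len(nb)) {
    sel <- freq >= schema$low[i] - 1e-12 & freq < schema$high[i] - 1e-12
    if (schema$low[i] >= nyq - 1e-12) next
    if (!any(sel)) stop("no DFT ordinate in bin ", i)
    out[, i] <- if (average) colMeans(P[sel, , drop = FALSE])
                else colSums(P[sel, , drop = FALSE])
  }
  out
}

neighbor_offsets <- c("xm", "xp", "ym", "yp", "zm", "zp")

#' Extract the 57-column voxel feature matrix
#'
#' For every in-mask voxel: columns 1-8 are the voxel's own band powers,
#' columns 9-56 the band powers of its six face-adjacent neighbours in the
#' fixed order x-, x+, y-, y+, z-, z+, and column 57 the gray-matter
#' occupancy. In `mode = "original"` the occupancy column is kept but set
#' to 0 for all voxels (the uncorrected model); in `mode = "pva_corrected"`
#' it carries the occupancy map value.
#'
#' Neighbours outside the grid or outside the mask are handled by
#' `neighbor_policy`: `"replicate"` (default) substitutes the centre
#' voxel's own band powers, `"zero"` fills zeros.
#'
#' @param bold a [vol4d()] of BOLD time series.
#' @param mask a [vol3d()] with nonzero values marking analysis voxels.
#' @param occupancy a [vol3d()] with gray-matter occupancy in `[0, 1]`;
#'   may be `NULL` when `mode = "original"`.
#' @param mode `"pva_corrected"` or `"original"`.
#' @param schema a [band_schema()].
#' @param neighbor_policy `"replicate"` or `"zero"`.
#' @param allow_partial passed to the band-power estimator (see
#'   [band_powers()]).
#' @param average passed to the band-power estimator.
#' @return an object of class `"cbf_features"`: list with `features`
#'   (n x 57 matrix), `voxel_index` (n x 3 integer matrix of 1-based array
#'   indices), `mode`, `schema`, `neighbor_policy`, `dim`, `voxel_size_mm`,
#'   `space_id`, `tr_seconds`.
#' @export
extract_features <- function(bold, mask, occupancy = NULL,
                             mode = c("pva_corrected", "original"),
                             schema = band_schema(),
                             neighbor_policy = c("replicate", "zero"),
                             allow_partial = FALSE, average = FALSE) {
  mode <- match.arg(mode)
  neighbor_policy <- match.arg(neighbor_policy)
  stopifnot(inherits(bold, "vol4d"), inherits(mask, "vol3d"))
  vols <- list(bold, mask)
  if (!is.null(occupancy)) vols <- c(vols, list(occupancy))
  check_aligned(vols)
  if (mode == "pva_corrected" && is.null(occupancy))
    stop("pva_corrected mode requires an occupancy map")
  if (!is.null(occupancy) &&
      (min(occupancy$data) < -1e-9 || max(occupancy$data) > 1 + 1e-9))
    stop("occupancy values must lie in [0, 1]")

  d <- dim(bold$data)[1:3]
  Tn <- dim(bold$data)[4]
  inmask <- which(mask$data != 0)
  if (!length(inmask)) stop("mask is empty")

  M <- matrix(bold$data, nrow = prod(d), ncol = Tn)
  bp <- band_powers_matrix(t(M[inmask, , drop = FALSE]), bold$tr_seconds,
                           schema, allow_partial = allow_partial,
                           average = average)
  nb <- ncol(bp)

  rowof <- integer(prod(d))
  rowof[inmask] <- seq_along(inmask)
  ai <- arrayInd(inmask, d)

  shift_index <- function(dx, dy, dz) {
    x <- ai[, 1] + dx; y <- ai[, 2] + dy; z <- ai[, 3] + dz
    ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
    flat <- rep(NA_integer_, nrow(ai))
    flat[ok] <- x[ok] + (y[ok] - 1L) * d[1] + (z[ok] - 1L) * d[1] * d[2]
    r <- rep(NA_integer_, nrow(ai))
    r[ok] <- rowof[flat[ok]]
    r[!is.na(r) & r == 0L] <- NA_integer_
    r
  }
  shifts <- list(xm = c(-1, 0, 0), xp = c(1, 0, 0), ym = c(0, -1, 0),
                 yp = c(0, 1, 0), zm = c(0, 0, -1), zp = c(0, 0, 1))

  feat <- matrix(0, nrow(ai), 7L * nb + 1L)
  feat[, seq_len(nb)] <- bp
  for (j in seq_along(shifts)) {
    r <- shift_index(shifts[[j]][1], shifts[[j]][2], shifts[[j]][3])
    block <- matrix(0, nrow(ai), nb)
    hit <- !is.na(r)
    block[hit, ] <- bp[r[hit], , drop = FALSE]
    if (neighbor_policy == "replicate" && any(!hit))
      block[!hit, ] <- bp[!hit, , drop = FALSE]
    feat[, nb * j + seq_len(nb)] <- block
  }
  occ_col <- if (mode == "pva_corrected") occupancy$data[inmask] else
    numeric(nrow(ai))
  feat[, 7L * nb + 1L] <- pmin(pmax(occ_col, 0), 1)
  colnames(feat) <- c(paste0("c_b", seq_len(nb)),
                      unlist(lapply(neighbor_offsets,
                                    function(o) paste0(o, "_b", seq_len(nb)))),
                      "occupancy")
  structure(list(features = feat, voxel_index = ai, mode = mode,
                 schema = schema, neighbor_policy = neighbor_policy,
                 dim = d, voxel_size_mm = bold$voxel_size_mm,
                 space_id = bold$space_id, tr_seconds = bold$tr_seconds),
            class = "cbf_features")
}

#' @export
print.cbf_features <- function(x, ...) {
  cat(sprintf("<cbf_features> %d voxels x %d features, mode = %s\n",
              nrow(x$features), ncol(x$features), x$mode))
  invisible(x)
}

#' Switch a feature matrix between occupancy modes
#'
#' The original and PVA-corrected feature matrices differ only in the
#' occupancy column, so the original-mode matrix is obtained from a
#' corrected one by zeroing column 57. Going the other way requires the
#' occupancy map.
#'
#' @param features a `cbf_features` object.
#' @param mode target mode.
#' @param occupancy occupancy [vol3d()], required when switching to
#'   `"pva_corrected"`.
#' @return a `cbf_features` in the requested mode.
#' @export
set_feature_mode <- function(features, mode = c("original", "pva_corrected"),
                             occupancy = NULL) {
  mode <- match.arg(mode)
  if (identical(features$mode, mode)) return(features)
  occ_ix <- ncol(features$features)
  if (mode == "original") {
    features$features[, occ_ix] <- 0
  } else {
    if (is.null(occupancy))
      stop("switching to pva_corrected requires an occupancy map")
    flat <- features$voxel_index[, 1] +
      (features$voxel_index[, 2] - 1L) * features$dim[1] +
      (features$voxel_index[, 3] - 1L) * features$dim[1] * features$dim[2]
    features$features[, occ_ix] <- pmin(pmax(occupancy$data[flat], 0), 1)
  }
  features$mode <- mode
  features
}
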