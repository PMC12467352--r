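#' Volumetric containers
#'
#' `vol3d()` and `vol4d()` wrap plain numeric arrays with the geometric
#' metadata the pipeline needs: voxel size in mm, repetition time (4D only)
#' and a `space_id` token identifying the aligned analysis space. All
#' cross-volume operations require identical grids; no implicit resampling
#' is performed anywhere except [prepare_occupancy()].
#'
#' @param data 3D (or 4D) numeric array; all values must be finite.
#' @param voxel_size_mm length-3 numeric vector of voxel edge lengths in mm.
#' @param tr_seconds repetition time in seconds (4D only; must be > 0).
#' @param space_id opaque alignment token; derived from the affine on read.
#'   Defaults to a token built from the voxel size.
#' @return an object of class `"vol3d"` or `"vol4d"`.
#' @export
vol3d <- function(data, voxel_size_mm = c(2, 2, 2), space_id = NULL) {
  data <- as.array(data)
  stopifnot(length(dim(data)) == 3L, length(voxel_size_mm) == 3L)
  check_finite(data)
  if (is.null(space_id)) space_id <- default_space_id(voxel_size_mm)
  structure(list(data = data, voxel_size_mm = as.numeric(voxel_size_mm),
                 space_id = space_id),
            class = "vol3d")
}

#' @rdname vol3d
#' @export
vol4d <- function(data, voxel_size_mm = c(2, 2, 2), tr_seconds,
                  space_id = NULL) {
  data <- as.array(data)
  stopifnot(length(dim(data)) == 4L, length(voxel_size_mm) == 3L)
  if (dim(data)[4] < 2L) stop("a 4D volume needs at least 2 time points")
  if (missing(tr_seconds) || is.null(tr_seconds) || !is.finite(tr_seconds) ||
      tr_seconds <= 0)
    stop("tr_seconds must be a positive scalar")
  check_finite(data)
  if (is.null(space_id)) space_id <- default_space_id(voxel_size_mm)
  structure(list(data = data, voxel_size_mm = as.numeric(voxel_size_mm),
                 tr_seconds = tr_seconds, space_id = space_id),
            class = "vol4d")
}

check_finite <- function(data) {
  bad <- sum(!is.finite(data))
  if (bad > 0L)
    stop(sprintf("volume contains %d non-finite voxel value(s)", bad))
  invisible(TRUE)
}

default_space_id <- function(voxel_size_mm) {
  paste0("vox:", paste(sprintf("%.4f", voxel_size_mm), collapse = "x"))
}

# space_id from an affine, rounded to 1e-4 mm so header rounding does not
# produce spurious mismatches.
space_id_from_affine <- function(affine) {
  paste(sprintf("%.4f", round(as.numeric(affine), 4)), collapse = ",")
}

#' @export
print.vol3d <- function(x, ...) {
  cat(sprintf("<vol3d> %s voxels, %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_size_mm, 4), collapse = "x")))
  invisible(x)
}

#' @export
print.vol4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vol4d> %s voxels x %d time points, TR = %g s\n",
              paste(d[1:3], collapse = "x"), d[4], x$tr_seconds))
  invisible(x)
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1/2 file into a [vol3d()] or [vol4d()] depending on its
#' dimensionality. Geometry comes from the header: voxel size from `pixdim`,
#' TR (4D) from the fourth `pixdim` slot, and `space_id` from the affine
#' (rounded at 1e-4 mm). Non-finite voxels are an error.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return a `vol3d` or `vol4d`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  data <- as.array(img)
  attributes(data) <- list(dim = dim(data))   # drop NIfTI header attributes
  nd <- length(dim(data))
  hdr <- RNifti::niftiHeader(img)
  vox <- abs(hdr$pixdim[2:4])
  sid <- space_id_from_affine(RNifti::xform(img))
  if (nd == 3L) {
    vol3d(data, voxel_size_mm = vox, space_id = sid)
  } else if (nd == 4L) {
    tr <- hdr$pixdim[5]
    if (!is.finite(tr) || tr <= 0)
      stop("4D image has no repetition time in its header (pixdim[4] = ",
           tr, ")")
    vol4d(data, voxel_size_mm = vox, tr_seconds = tr, space_id = sid)
  } else {
    stop("unsupported image dimensionality: ", nd)
  }
}

#' Write a volume to NIfTI
#'
#' @param vol a `vol3d` or `vol4d`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI on-disk datatype (default `"float"`, i.e. float32;
#'   round-trips float32 payloads bit-exactly).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = "float") {
  stopifnot(inherits(vol, "vol3d") || inherits(vol, "vol4d"))
  img <- RNifti::asNifti(vol$data)
  pd <- vol$voxel_size_mm
  if (inherits(vol, "vol4d")) pd <- c(pd, vol$tr_seconds)
  img <- RNifti::`pixdim<-`(img, pd)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Check that volumes share one grid
#'
#' Passes iff all inputs share X,Y,Z dimensions, voxel size (within 1e-4 mm)
#' and `space_id`. Accepts any mix of `vol3d`, `vol4d` and [label_atlas()]
#' objects.
#'
#' @param ... two or more volumes/atlases, or a single list of them.
#' @return `TRUE` invisibly; mismatches raise an error naming the field.
#' @export
check_aligned <- function(...) {
  vols <- list(...)
  if (length(vols) == 1L && is.list(vols[[1]]) && !inherits(vols[[1]], c("vol3d", "vol4d", "label_atlas")))
    vols <- vols[[1]]
  if (length(vols) < 2L) stop("check_aligned needs at least 2 volumes")
  geom <- function(v) {
    if (inherits(v, "label_atlas"))
      list(dim = dim(v$labels), vox = v$voxel_size_mm, sid = v$space_id)
    else
      list(dim = dim(v$data)[1:3], vox = v$voxel_size_mm, sid = v$space_id)
  }
  ref <- geom(vols[[1]])
  for (i in seq_along(vols)[-1]) {
    g <- geom(vols[[i]])
    if (!identical(ref$dim, g$dim))
      stop(sprintf("grid dimension mismatch (volume 1: %s, volume %d: %s)",
                   paste(ref$dim, collapse = "x"), i,
                   paste(g$dim, collapse = "x")))
    if (any(abs(ref$vox - g$vox) > 1e-4))
      stop(sprintf("voxel_size_mm mismatch (volume 1: %s, volume %d: %s)",
                   paste(ref$vox, collapse = "x"), i,
                   paste(g$vox, collapse = "x")))
    if (!identical(ref$sid, g$sid))
      stop(sprintf("space_id mismatch between volume 1 and volume %d", i))
  }
  invisible(TRUE)
}
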