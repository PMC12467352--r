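#' Integer-labelled cortical atlas
#'
#' A `label_atlas` pairs a 3D integer label grid with a lookup table (LUT)
#' mapping each label to a region name and hemisphere, in the style of a
#' bilateral Desikan-Killiany parcellation (34 named regions per hemisphere
#' in the standard atlas). Every nonzero label in the grid must appear in
#' the LUT and every region name must be present in both hemispheres.
#'
#' @param labels 3D integer array of region labels (0 = background).
#' @param lut data frame with columns `label`, `region_name`, `hemisphere`
#'   (values `"L"`/`"R"`).
#' @param voxel_size_mm,space_id geometry, as for [vol3d()].
#' @return an object of class `"label_atlas"`.
#' @export
label_atlas <- function(labels, lut, voxel_size_mm = c(2, 2, 2),
                        space_id = NULL) {
  labels <- as.array(labels)
  stopifnot(length(dim(labels)) == 3L)
  if (any(labels != round(labels))) stop("label grid must be integer-valued")
  storage.mode(labels) <- "integer"
  lut <- as.data.frame(lut)
  need <- c("label", "region_name", "hemisphere")
  if (!all(need %in% names(lut)))
    stop("LUT must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(lut$label)) stop("duplicate labels in LUT")
  if (!all(lut$hemisphere %in% c("L", "R")))
    stop("hemisphere must be 'L' or 'R'")
  present <- setdiff(unique(as.integer(labels)), 0L)
  missing_lab <- setdiff(present, lut$label)
  if (length(missing_lab))
    stop("grid label(s) absent from LUT: ", paste(missing_lab, collapse = ", "))
  tab <- table(lut$region_name, lut$hemisphere)
  oneside <- rownames(tab)[tab[, "L"] == 0 | tab[, "R"] == 0]
  if (length(oneside))
    stop("region(s) present in only one hemisphere: ",
         paste(oneside, collapse = ", "))
  if (is.null(space_id)) space_id <- default_space_id(voxel_size_mm)
  structure(list(labels = labels, lut = lut,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 space_id = space_id),
            class = "label_atlas")
}

#' @export
print.label_atlas <- function(x, ...) {
  cat(sprintf("<label_atlas> %s grid, %d labels, %d bilateral regions\n",
              paste(dim(x$labels), collapse = "x"), nrow(x$lut),
              length(region_names(x))))
  invisible(x)
}

#' @rdname label_atlas
#' @param atlas a `label_atlas`.
#' @return `region_names()`: sorted unique bilateral region names.
#' @export
region_names <- function(atlas) sort(unique(atlas$lut$region_name))

#' Load an atlas from a NIfTI label image and a TSV lookup table
#'
#' The LUT is a tab-separated table with a header row and columns
#' `label`, `region_name`, `hemisphere`. Label/LUT consistency and the
#' bilateral pairing of region names are validated on load.
#'
#' @param label_path NIfTI file of integer labels.
#' @param lut_path TSV lookup table.
#' @return a [label_atlas()].
#' @export
load_atlas <- function(label_path, lut_path) {
  vol <- read_volume(label_path)
  lut <- utils::read.delim(lut_path, stringsAsFactors = FALSE)
  label_atlas(round(vol$data), lut, voxel_size_mm = vol$voxel_size_mm,
              space_id = vol$space_id)
}

#' Write an atlas lookup table as TSV
#' @param atlas a `label_atlas`.
#' @param path output path.
#' @export
write_lut <- function(atlas, path) {
  utils::write.table(atlas$lut, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a subject manifest
#'
#' A manifest is a TSV with one row per subject and at least the columns
#' `subject_id`, `age` (years), `sex` (`"M"`/`"F"`), `group`
#' (`"case"`/`"control"`); additional columns typically hold file paths.
#'
#' @param path TSV path.
#' @param check_files if `TRUE`, verify that every value in columns ending
#'   in `_path` points to an existing file.
#' @return a data frame.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "sex", "group")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(m$subject_id)) stop("duplicate subject_id in manifest")
  if (!all(m$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  if (check_files) {
    pcols <- grep("_path$", names(m), value = TRUE)
    for (pc in pcols) {
      miss <- m[[pc]][!file.exists(m[[pc]])]
      if (length(miss))
        stop("manifest references missing file(s): ",
             paste(utils::head(miss, 3), collapse = ", "))
    }
  }
  m
}
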