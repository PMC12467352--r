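#' @keywords internal
"_PACKAGE"

# Deterministic substream seeds: one master seed fans out to named streams
# (split, subsample, folds, per-subject simulation) so that stages can be
# re-run independently with reproducible draws.
substream_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131)
  as.integer((abs(master) * 48271 + h) %% 2147483647)
}

# Evaluate expr under a temporary RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write a results table as TSV
#'
#' Tables are written with a header row, tab separation, no quoting, and
#' floats formatted at 6 significant digits so outputs diff cleanly.
#'
#' @param x a data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path) {
  stopifnot(is.data.frame(x))
  fmt <- x
  num <- vapply(fmt, is.double, logical(1))
  fmt[num] <- lapply(fmt[num], function(v) signif(v, 6))
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# JSON provenance sidecar written next to a pipeline artifact.
write_sidecar <- function(path, info) {
  jsonlite::write_json(info, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
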