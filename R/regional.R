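#' Average a voxel map over atlas regions
#'
#' Every region's value is the mean of the map over the in-mask voxels
#' carrying that region's labels. With `bilateral = TRUE` (default, the
#' granularity of a 34-region bilateral cortical table) the left and right
#' hemisphere voxels are pooled before averaging, so the bilateral mean is
#' the voxel-count-weighted mean of the two hemisphere means.
#'
#' @param map a [vol3d()].
#' @param atlas a [label_atlas()] aligned with `map`.
#' @param mask optional [vol3d()]; only voxels with nonzero mask enter.
#' @param bilateral pool hemispheres (TRUE) or keep them separate.
#' @return data frame with `region` (and `hemisphere` if unilateral),
#'   `mean`, `n_voxels`; one row per region, erroring on empty regions.
#' @export
regionalize <- function(map, atlas, mask = NULL, bilateral = TRUE) {
  stopifnot(inherits(map, "vol3d"), inherits(atlas, "label_atlas"))
  vols <- list(map, atlas)
  if (!is.null(mask)) vols <- c(vols, list(mask))
  check_aligned(vols)
  keep <- atlas$labels != 0L
  if (!is.null(mask)) keep <- keep & (mask$data != 0)
  lab <- atlas$labels[keep]
  val <- map$data[keep]
  lut <- atlas$lut
  key <- if (bilateral) lut$region_name else
    paste(lut$region_name, lut$hemisphere, sep = "|")
  grp <- key[match(lab, lut$label)]
  means <- tapply(val, grp, mean)
  counts <- tapply(val, grp, length)
  want <- if (bilateral) sort(unique(lut$region_name)) else
    sort(unique(key))
  empty <- setdiff(want, names(means))
  if (length(empty))
    stop("region(s) with no in-mask voxels: ", paste(empty, collapse = ", "))
  out <- data.frame(region = want, mean = as.numeric(means[want]),
                    n_voxels = as.integer(counts[want]),
                    stringsAsFactors = FALSE)
  if (!bilateral) {
    parts <- do.call(rbind, strsplit(out$region, "|", fixed = TRUE))
    out$region <- parts[, 1]
    out$hemisphere <- parts[, 2]
    out <- out[, c("region", "hemisphere", "mean", "n_voxels")]
  }
  rownames(out) <- NULL
  out
}

#' Mask-wide mean of a voxel map
#'
#' The whole-brain summary used alongside regional tables: mean of the map
#' over nonzero-mask voxels.
#'
#' @param map a [vol3d()].
#' @param mask a [vol3d()] analysis mask.
#' @return scalar mean.
#' @export
wholebrain_mean <- function(map, mask) {
  check_aligned(map, mask)
  mean(map$data[mask$data != 0])
}

#' Correlate predicted and measured regional CBF across subjects
#'
#' For each region, the Pearson correlation (across subjects) between
#' predicted and measured regional CBF, with a two-tailed p-value from the
#' exact t-transform with `n - 2` degrees of freedom. A `whole_brain` row
#' is added when per-subject mask-wide means are supplied.
#'
#' @param pred subjects x regions matrix of predicted regional CBF
#'   (rownames = subject ids, colnames = regions).
#' @param meas same shape, measured regional CBF; same subjects and
#'   regions.
#' @param pred_wholebrain,meas_wholebrain optional per-subject mask-wide
#'   means (same subject order).
#' @return data frame `region`, `r`, `p`, `n`.
#' @export
predicted_vs_measured <- function(pred, meas, pred_wholebrain = NULL,
                                  meas_wholebrain = NULL) {
  pred <- as.matrix(pred); meas <- as.matrix(meas)
  if (!identical(dim(pred), dim(meas)) ||
      !identical(colnames(pred), colnames(meas)) ||
      !identical(rownames(pred), rownames(meas)))
    stop("pred and meas must cover the same subjects and regions")
  n <- nrow(pred)
  if (n < 4L) stop("need at least 4 subjects")
  one <- function(a, b, label) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
      stop("zero-variance values for ", label)
    ct <- stats::cor.test(a, b)
    data.frame(region = label, r = unname(ct$estimate), p = ct$p.value,
               n = n, stringsAsFactors = FALSE)
  }
  rows <- lapply(colnames(pred), function(rg) one(pred[, rg], meas[, rg], rg))
  out <- do.call(rbind, rows)
  if (!is.null(pred_wholebrain)) {
    stopifnot(!is.null(meas_wholebrain),
              length(pred_wholebrain) == n, length(meas_wholebrain) == n)
    out <- rbind(one(pred_wholebrain, meas_wholebrain, "whole_brain"), out)
  }
  rownames(out) <- NULL
  out
}

#' Fisher r-to-z comparison of two independent correlations
#'
#' `Z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-tailed normal p-value. Antisymmetric under swapping the two
#' correlations. A dependent-correlations variant (Steiger's test, sharing
#' one sample of size `n1` with inter-correlation `r12`) is available via
#' `dependent = TRUE`.
#'
#' @param r1,r2 correlation coefficients, `|r| < 1`.
#' @param n1,n2 sample sizes behind each correlation (> 3).
#' @param dependent use Steiger's test for correlations measured on the
#'   same subjects.
#' @param r12 correlation between the two predictors (dependent case).
#' @return list with `Z` and `p`.
#' @export
fisher_z_difference <- function(r1, n1, r2, n2, dependent = FALSE,
                                r12 = 0) {
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("|r| = 1 gives an infinite z-transform")
  if (n1 <= 3 || n2 <= 3) stop("need n > 3")
  z1 <- atanh(r1); z2 <- atanh(r2)
  if (!dependent) {
    Z <- (z1 - z2) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  } else {
    # Steiger (1980): correlations r1 = cor(x1, y), r2 = cor(x2, y) on one
    # sample of size n1, with r12 = cor(x1, x2).
    rbar <- (r1 + r2) / 2
    cov <- (r12 * (1 - 2 * rbar^2) - 0.5 * rbar^2 *
              (1 - 2 * rbar^2 - r12^2)) / ((1 - rbar^2)^2)
    Z <- (z1 - z2) * sqrt((n1 - 3) / (2 - 2 * cov))
  }
  list(Z = Z, p = 2 * stats::pnorm(-abs(Z)))
}

#' Per-region model comparison via Fisher r-to-z
#'
#' @param r_original,r_corrected per-region correlations of the two models
#'   (equal-length named or unnamed vectors).
#' @param n sample size behind each correlation (scalar or per-region).
#' @param regions optional region names.
#' @return data frame `region`, `r_original`, `r_corrected`, `Z`, `p`.
#' @export
compare_models <- function(r_original, r_corrected, n, regions = NULL) {
  stopifnot(length(r_original) == length(r_corrected))
  n <- rep_len(n, length(r_original))
  if (is.null(regions))
    regions <- names(r_original) %||% paste0("region_", seq_along(r_original))
  rows <- mapply(function(ro, rc, ni) {
    fz <- fisher_z_difference(rc, ni, ro, ni)
    c(Z = fz$Z, p = fz$p)
  }, r_original, r_corrected, n)
  data.frame(region = regions, r_original = as.numeric(r_original),
             r_corrected = as.numeric(r_corrected),
             Z = as.numeric(rows["Z", ]), p = as.numeric(rows["p", ]),
             stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bonferroni significance mask
#'
#' Flags `p < alpha / m`. With the defaults (alpha 0.05, m = 34 bilateral
#' cortical regions) the threshold is 0.05/34 = 1.47e-3.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param alpha family-wise error rate.
#' @param m number of comparisons.
#' @return logical vector with attribute `"threshold"`.
#' @export
bonferroni_mask <- function(p_values, alpha = 0.05, m = 34) {
  if (length(p_values) &&
      (min(p_values) < 0 || max(p_values) > 1))
    stop("p-values must lie in [0, 1]")
  thr <- alpha / m
  structure(p_values < thr, threshold = thr)
}
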