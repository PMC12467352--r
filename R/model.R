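#' SVR model configuration
#'
#' Collects the tunable choices of the CBF decoder: the grids for the RBF
#' kernel's `C` (penalty) and `gamma` (kernel width), the epsilon tube
#' width on the standardized target scale, the number of cross-validation
#' folds, the per-subject voxel subsample used for training, and the seed.
#' Grids are searched by mean CV RMSE with ties broken toward smaller `C`,
#' then smaller `gamma`.
#'
#' @param C_grid positive penalty values to search.
#' @param gamma_grid positive kernel widths to search; the default centres
#'   on `1/57` (one over the feature dimension), the standard heuristic for
#'   z-scored features.
#' @param epsilon SVR tube width on the standardized target scale.
#' @param cv_folds number of cross-validation folds.
#' @param voxels_per_subject training voxels drawn per subject.
#' @param group_folds if `TRUE` (default) CV folds are grouped by subject so
#'   no subject contributes to both sides of a fold.
#' @param seed master seed; named substreams are derived from it.
#' @return an object of class `"model_config"`.
#' @export
model_config <- function(C_grid = c(0.1, 1, 10, 100),
                         gamma_grid = c(0.25, 1, 4) / 57,
                         epsilon = 0.1, cv_folds = 10,
                         voxels_per_subject = 2000,
                         group_folds = TRUE, seed = 1L) {
  stopifnot(length(C_grid) >= 1L, all(C_grid > 0),
            length(gamma_grid) >= 1L, all(gamma_grid > 0),
            cv_folds >= 2L, voxels_per_subject >= 1L, epsilon > 0)
  structure(list(C_grid = C_grid, gamma_grid = gamma_grid, epsilon = epsilon,
                 cv_folds = as.integer(cv_folds),
                 voxels_per_subject = as.integer(voxels_per_subject),
                 group_folds = isTRUE(group_folds), seed = as.integer(seed)),
            class = "model_config")
}

#' Split a cohort into balanced training and testing sets
#'
#' Draws a random `train_fraction` split of the manifest and re-draws (up
#' to `max_attempts` seeded attempts) until the two sides show no age or
#' sex difference: two-sample t-test p > 0.2 on age and a sex-proportion
#' test p > 0.2 (chi-square, or Fisher's exact test when any expected cell
#' count is small). Diagnosis/group is not considered.
#'
#' @param manifest data frame with `subject_id`, `age`, `sex` columns.
#' @param train_fraction fraction of subjects assigned to training.
#' @param seed integer seed.
#' @param p_threshold balance threshold on both tests.
#' @param max_attempts maximum number of re-draws.
#' @return an object of class `"cohort_split"`: list with `train_ids`,
#'   `test_ids`, `age_p`, `sex_p`, `attempts`.
#' @export
split_cohort <- function(manifest, train_fraction = 2 / 3, seed = 1L,
                         p_threshold = 0.2, max_attempts = 1000L) {
  stopifnot(is.data.frame(manifest), nrow(manifest) >= 6L || train_fraction == 1)
  ids <- manifest$subject_id
  n <- length(ids)
  if (train_fraction >= 1) {
    return(structure(list(train_ids = ids, test_ids = character(0),
                          age_p = NA_real_, sex_p = NA_real_, attempts = 0L),
                     class = "cohort_split"))
  }
  n_train <- round(n * train_fraction)
  sex_p_value <- function(tr) {
    tab <- table(factor(manifest$sex, c("M", "F")),
                 factor(tr, c(TRUE, FALSE)))
    if (any(tab == 0) || any(suppressWarnings(
      stats::chisq.test(tab)$expected) < 5))
      stats::fisher.test(tab)$p.value
    else stats::chisq.test(tab, correct = FALSE)$p.value
  }
  res <- with_seed(seed, {
    out <- NULL
    for (att in seq_len(max_attempts)) {
      tr <- logical(n)
      tr[sample.int(n, n_train)] <- TRUE
      ap <- stats::t.test(manifest$age[tr], manifest$age[!tr])$p.value
      sp <- sex_p_value(tr)
      if (ap > p_threshold && sp > p_threshold) {
        out <- list(tr = tr, ap = ap, sp = sp, att = att)
        break
      }
    }
    out
  })
  if (is.null(res))
    stop("could not balance the split on age/sex in ", max_attempts,
         " attempts")
  structure(list(train_ids = ids[res$tr], test_ids = ids[!res$tr],
                 age_p = res$ap, sex_p = res$sp, attempts = res$att),
            class = "cohort_split")
}

#' @export
print.cohort_split <- function(x, ...) {
  cat(sprintf("<cohort_split> %d train / %d test (age p = %.3g, sex p = %.3g)\n",
              length(x$train_ids), length(x$test_ids), x$age_p, x$sex_p))
  invisible(x)
}

#' Pool a seeded voxel subsample across subjects
#'
#' For every subject, draws `config$voxels_per_subject` in-mask voxels
#' uniformly without replacement (seeded per subject) from that subject's
#' feature matrix and pairs them with the subject's measured CBF at the
#' same voxels. A subject with fewer voxels than requested contributes all
#' of them (with a warning).
#'
#' @param features_list named list of `cbf_features`, one per subject.
#' @param cbf_list named list of [vol3d()] measured CBF maps, same names.
#' @param config a [model_config()].
#' @return list with `x` (pooled feature matrix), `y` (targets),
#'   `subject` (provenance factor).
#' @export
assemble_training_set <- function(features_list, cbf_list, config) {
  stopifnot(length(features_list) >= 1L,
            identical(names(features_list), names(cbf_list)))
  modes <- vapply(features_list, `[[`, "", "mode")
  if (length(unique(modes)) != 1L)
    stop("all subjects must share one feature mode")
  xs <- list(); ys <- list(); subj <- list()
  for (id in names(features_list)) {
    ft <- features_list[[id]]
    cbf <- cbf_list[[id]]
    flat <- ft$voxel_index[, 1] + (ft$voxel_index[, 2] - 1L) * ft$dim[1] +
      (ft$voxel_index[, 3] - 1L) * ft$dim[1] * ft$dim[2]
    y_all <- cbf$data[flat]
    nv <- nrow(ft$features)
    k <- config$voxels_per_subject
    if (k >= nv) {
      if (k > nv)
        warning(sprintf("subject %s has %d < %d in-mask voxels; using all",
                        id, nv, k))
      take <- seq_len(nv)
    } else {
      take <- with_seed(substream_seed(config$seed, paste0("subsample:", id)),
                        sample.int(nv, k))
    }
    xs[[id]] <- ft$features[take, , drop = FALSE]
    ys[[id]] <- y_all[take]
    subj[[id]] <- rep(id, length(take))
  }
  list(x = do.call(rbind, xs), y = unlist(ys, use.names = FALSE),
       subject = factor(unlist(subj, use.names = FALSE)))
}

assign_folds <- function(n, k, groups = NULL, seed = 1L) {
  if (is.null(groups)) {
    with_seed(seed, sample(rep_len(seq_len(k), n)))
  } else {
    g <- unique(as.character(groups))
    k_eff <- min(k, length(g))
    gf <- with_seed(seed, sample(rep_len(seq_len(k_eff), length(g))))
    names(gf) <- g
    unname(gf[as.character(groups)])
  }
}

#' Tune and train the RBF-kernel CBF regressor
#'
#' Features and targets are z-standardized with statistics computed from
#' the training rows only. Every `(C, gamma)` grid point is scored by mean
#' cross-validated RMSE (folds grouped by subject when provenance is
#' given); the minimizer is selected with ties broken toward smaller `C`
#' then smaller `gamma`, and the final epsilon-SVR is refit on all rows.
#'
#' @param x numeric feature matrix (rows = voxels).
#' @param y numeric target vector (CBF, mL/100g/min).
#' @param config a [model_config()].
#' @param groups optional subject provenance (used for grouped folds).
#' @param mode feature mode recorded in the model (`"pva_corrected"` or
#'   `"original"`).
#' @param schema the [band_schema()] recorded in the model.
#' @param fold_assign optional explicit fold assignment vector (overrides
#'   the seeded assignment; mainly for testing).
#' @return an object of class `"cbf_model"`.
#' @export
tune_and_train <- function(x, y, config = model_config(), groups = NULL,
                           mode = "pva_corrected", schema = band_schema(),
                           fold_assign = NULL) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y))
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite entries in features or targets")
  if (stats::sd(y) == 0) stop("degenerate target: zero variance")
  if (nrow(x) < 10L * config$cv_folds)
    stop("need at least 10 rows per CV fold")

  xm <- colMeans(x)
  xs <- apply(x, 2, stats::sd)
  xs[xs == 0] <- 1          # constant columns (e.g. zeroed occupancy)
  ym <- mean(y); ys <- stats::sd(y)
  xz <- sweep(sweep(x, 2, xm), 2, xs, "/")
  yz <- (y - ym) / ys

  if (is.null(fold_assign)) {
    fold_assign <- assign_folds(nrow(x), config$cv_folds,
                                groups = if (config$group_folds) groups,
                                seed = substream_seed(config$seed, "folds"))
  }
  grid <- expand.grid(C = sort(config$C_grid),
                      gamma = sort(config$gamma_grid))
  cv_rmse <- rep(NA_real_, nrow(grid))
  nfold <- length(unique(fold_assign))
  if (nrow(grid) == 1L) cv_rmse[1] <- 0   # nothing to select; skip CV
  for (gi in seq_len(nrow(grid))) {
    if (!is.na(cv_rmse[gi])) next
    errs <- numeric(nfold)
    ok <- TRUE
    for (f in seq_len(nfold)) {
      hold <- fold_assign == f
      fit <- e1071::svm(x = xz[!hold, , drop = FALSE], y = yz[!hold],
                        type = "eps-regression", kernel = "radial",
                        cost = grid$C[gi], gamma = grid$gamma[gi],
                        epsilon = config$epsilon, scale = FALSE)
      pr <- stats::predict(fit, xz[hold, , drop = FALSE])
      if (any(!is.finite(pr))) { ok <- FALSE; break }
      errs[f] <- sqrt(mean((pr - yz[hold])^2))
    }
    if (ok) cv_rmse[gi] <- mean(errs)
  }
  if (all(is.na(cv_rmse))) stop("every grid point produced non-finite CV loss")
  ord <- order(grid$C, grid$gamma)        # tie-break: smaller C, then gamma
  best <- ord[which(cv_rmse[ord] == min(cv_rmse, na.rm = TRUE))[1]]
  fit <- e1071::svm(x = xz, y = yz, type = "eps-regression",
                    kernel = "radial", cost = grid$C[best],
                    gamma = grid$gamma[best], epsilon = config$epsilon,
                    scale = FALSE)
  structure(list(fit = fit, C = grid$C[best], gamma = grid$gamma[best],
                 epsilon = config$epsilon,
                 cv = data.frame(grid, rmse = cv_rmse),
                 x_center = xm, x_scale = xs, y_center = ym, y_scale = ys,
                 mode = mode, schema = schema,
                 n_rows = nrow(x),
                 n_subjects = if (is.null(groups)) NA_integer_ else
                   length(unique(groups)),
                 seed = config$seed),
            class = "cbf_model")
}

#' @export
print.cbf_model <- function(x, ...) {
  cat(sprintf("<cbf_model> mode = %s, C = %g, gamma = %g, %d training rows\n",
              x$mode, x$C, x$gamma, x$n_rows))
  invisible(x)
}

# Predict on a raw feature matrix, returning values in target units.
predict_cbf_matrix <- function(model, x) {
  xz <- sweep(sweep(as.matrix(x), 2, model$x_center), 2, model$x_scale, "/")
  as.numeric(stats::predict(model$fit, xz)) * model$y_scale + model$y_center
}

#' Predict CBF voxel by voxel
#'
#' Applies a trained model to a feature matrix, writing one prediction per
#' in-mask voxel (de-standardized to CBF units) into a 3D map; voxels
#' outside the feature matrix's mask receive `background`.
#'
#' @param model a `cbf_model`.
#' @param features a `cbf_features` whose mode and band schema match the
#'   model's.
#' @param background value for out-of-mask voxels.
#' @return a [vol3d()] predicted CBF map.
#' @export
predict_voxelwise <- function(model, features, background = 0) {
  stopifnot(inherits(model, "cbf_model"), inherits(features, "cbf_features"))
  if (!identical(model$mode, features$mode))
    stop(sprintf("feature mode '%s' does not match model mode '%s'",
                 features$mode, model$mode))
  if (!isTRUE(all.equal(model$schema$midpoints_hz,
                        features$schema$midpoints_hz)) ||
      !isTRUE(all.equal(model$schema$bin_width_hz,
                        features$schema$bin_width_hz)))
    stop("band schema mismatch between model and features")
  pred <- predict_cbf_matrix(model, features$features)
  out <- array(background, features$dim)
  out[features$voxel_index] <- pred
  vol3d(out, voxel_size_mm = features$voxel_size_mm,
        space_id = features$space_id)
}

#' Write model metadata as JSON
#'
#' Persists everything needed to audit a trained model (mode, schema,
#' winning hyperparameters, scaler statistics, seeds, training size) as a
#' JSON file. The kernel state itself is an R object; keep it with
#' `saveRDS()` if it must outlive the session.
#'
#' @param model a `cbf_model`.
#' @param path output JSON path.
#' @export
write_model_metadata <- function(model, path) {
  meta <- list(mode = model$mode,
               band_midpoints_hz = model$schema$midpoints_hz,
               band_width_hz = model$schema$bin_width_hz,
               C = model$C, gamma = model$gamma, epsilon = model$epsilon,
               x_center = model$x_center, x_scale = model$x_scale,
               y_center = model$y_center, y_scale = model$y_scale,
               n_rows = model$n_rows, n_subjects = model$n_subjects,
               seed = model$seed)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
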