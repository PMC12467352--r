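make_manifest <- function(n, seed = 1) {
  withr::with_seed(seed, data.frame(
    subject_id = sprintf("s%03d", seq_len(n)),
    age = rnorm(n, 50, 12),
    sex = sample(c("M", "F"), n, replace = TRUE),
    group = "control", stringsAsFactors = FALSE))
}

test_that("cohort splitting balances age and sex and is reproducible", {
  m <- make_manifest(300)
  sp <- split_cohort(m, seed = 5)
  expect_length(sp$train_ids, 200L)
  expect_length(sp$test_ids, 100L)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0L)
  expect_setequal(c(sp$train_ids, sp$test_ids), m$subject_id)
  expect_gt(sp$age_p, 0.2)
  expect_gt(sp$sex_p, 0.2)
  expect_identical(split_cohort(m, seed = 5), sp)
  expect_false(identical(split_cohort(m, seed = 6)$train_ids, sp$train_ids))

  # train_fraction 1: everyone trains, no balance test
  sp1 <- split_cohort(m, train_fraction = 1, seed = 5)
  expect_length(sp1$test_ids, 0L)
  expect_true(is.na(sp1$age_p))

  # pathological cohort: age perfectly separates any large split rarely --
  # force failure with an impossible threshold
  expect_error(split_cohort(m, seed = 1, p_threshold = 0.999999,
                            max_attempts = 5), "balance")
})

test_that("training-set assembly draws the requested voxels per subject", {
  ph <- default_phantom()
  coh <- simulate_cohort(0, 3, ph, generative_params(), seed = 31,
                         with_bold = TRUE)
  feats <- lapply(coh$subjects, function(s)
    extract_features(s$bold, ph$mask, s$occupancy, allow_partial = TRUE))
  meas <- lapply(coh$subjects, `[[`, "measured_cbf")
  cfg <- model_config(voxels_per_subject = 100, seed = 9)
  pooled <- assemble_training_set(feats, meas, cfg)
  expect_identical(nrow(pooled$x), 300L)
  expect_equal(unname(table(pooled$subject)), rep(100L, 3),
               ignore_attr = TRUE)
  # determinism
  pooled2 <- assemble_training_set(feats, meas, cfg)
  expect_identical(pooled$x, pooled2$x)
  expect_identical(pooled$y, pooled2$y)
  # over-request falls back to every voxel with a warning
  cfg_big <- model_config(voxels_per_subject = 1e6, seed = 9)
  expect_warning(big <- assemble_training_set(feats[1], meas[1], cfg_big),
                 "using all")
  expect_identical(nrow(big$x), nrow(feats[[1]]$features))
})

test_that("a near-constant target is fit to within the epsilon tube", {
  set.seed(21)
  x <- matrix(rnorm(300 * 10), 300, 10)
  y <- 50 + rnorm(300, sd = 0.01)
  cfg <- model_config(C_grid = 1, gamma_grid = 0.1, cv_folds = 2,
                      seed = 1)
  mod <- tune_and_train(x, y, cfg)
  pr <- predict_cbf_matrix_for_test(mod, x)
  expect_lt(max(abs(pr - 50)), 2 * cfg$epsilon * mod$y_scale + 0.05)
  expect_error(tune_and_train(x, rep(1, 300), cfg), "zero variance")
})

test_that("grid selection agrees with an exhaustive re-computation", {
  set.seed(22)
  n <- 120
  x <- matrix(rnorm(n * 5), n, 5)
  y <- x[, 1] - 0.5 * x[, 3]^2 + rnorm(n, sd = 0.2)
  folds <- rep_len(1:4, n)
  cfg <- model_config(C_grid = c(0.5, 50), gamma_grid = 0.2, cv_folds = 4,
                      seed = 2)
  mod <- tune_and_train(x, y, cfg, fold_assign = folds)

  # independent oracle: z-score, run e1071 per fold, average RMSE
  xz <- scale(x); yz <- as.numeric(scale(y))
  rmse <- sapply(c(0.5, 50), function(C) {
    mean(sapply(1:4, function(f) {
      fit <- e1071::svm(x = xz[folds != f, ], y = yz[folds != f],
                        type = "eps-regression", kernel = "radial",
                        cost = C, gamma = 0.2, epsilon = 0.1, scale = FALSE)
      sqrt(mean((predict(fit, xz[folds == f, ]) - yz[folds == f])^2))
    }))
  })
  expect_equal(mod$C, c(0.5, 50)[which.min(rmse)])
  expect_equal(sort(mod$cv$rmse), sort(rmse), tolerance = 1e-10)
})

test_that("a linear feature-target mapping is recovered on held-out data", {
  set.seed(23)
  n <- 2000
  x <- matrix(runif(n * 57), n, 57)
  y <- 3 * x[, 2] - 2 * x[, 10] + 1.5 * x[, 57] + rnorm(n, sd = 0.1)
  tr <- seq_len(1500); te <- 1501:2000
  cfg <- model_config(C_grid = c(1, 10), gamma_grid = 1 / 57, cv_folds = 5,
                      seed = 3)
  mod <- tune_and_train(x[tr, ], y[tr], cfg)
  pr <- predict_cbf_matrix_for_test(mod, x[te, ])
  r2 <- 1 - sum((pr - y[te])^2) / sum((y[te] - mean(y[te]))^2)
  expect_gt(r2, 0.9)
})

test_that("standardization statistics come from training rows only", {
  set.seed(24)
  x_train <- matrix(rnorm(400 * 6), 400, 6)
  y_train <- rowSums(x_train) + rnorm(400, sd = 0.1)
  cfg <- model_config(C_grid = 1, gamma_grid = 0.2, cv_folds = 2, seed = 4)
  mod <- tune_and_train(x_train, y_train, cfg)
  expect_equal(mod$x_center, colMeans(x_train), ignore_attr = TRUE)
  expect_equal(mod$x_scale, apply(x_train, 2, sd), ignore_attr = TRUE)
  expect_equal(mod$y_center, mean(y_train))
  # the model object is independent of any test rows by construction;
  # predictions are stateless row-wise
  x_test <- matrix(rnorm(50 * 6), 50, 6)
  p1 <- predict_cbf_matrix_for_test(mod, x_test)
  perm <- sample(50)
  p2 <- predict_cbf_matrix_for_test(mod, x_test[perm, ])
  expect_equal(p2, p1[perm])
})

test_that("voxelwise prediction respects mode, schema and geometry", {
  ph <- default_phantom()
  coh <- simulate_cohort(0, 3, ph, generative_params(), seed = 32)
  feats <- lapply(coh$subjects, function(s)
    extract_features(s$bold, ph$mask, s$occupancy, allow_partial = TRUE))
  meas <- lapply(coh$subjects, `[[`, "measured_cbf")
  cfg <- model_config(C_grid = 10, gamma_grid = 1 / 57,
                      voxels_per_subject = 300, seed = 5)
  pooled <- assemble_training_set(feats[1:2], meas[1:2], cfg)
  mod <- tune_and_train(pooled$x, pooled$y, cfg, groups = pooled$subject)

  pv <- predict_voxelwise(mod, feats[[3]], background = -1)
  expect_identical(dim(pv$data), ph$spec$shape)
  expect_true(all(is.finite(pv$data)))
  expect_true(all(pv$data[ph$mask$data == 0] == -1))

  fo <- set_feature_mode(feats[[3]], "original")
  expect_error(predict_voxelwise(mod, fo), "mode")
  fs <- feats[[3]]
  fs$schema <- band_schema(midpoints_hz = c(0.04, 0.12), bin_width_hz = 0.08)
  expect_error(predict_voxelwise(mod, fs), "schema")

  # a pva_corrected model reacts to the occupancy column
  zeroed <- feats[[3]]
  zeroed$features[, 57] <- 0
  p_occ <- predict_cbf_matrix_for_test(mod, feats[[3]]$features)
  p_zero <- predict_cbf_matrix_for_test(mod, zeroed$features)
  expect_gt(mean(abs(p_occ - p_zero)), 0)
})
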