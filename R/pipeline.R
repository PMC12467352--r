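#' Run the full synthetic-cohort pipeline
#'
#' Orchestrates simulate -> features -> split -> train -> predict ->
#' regionalize -> statistics on one synthetic cohort and writes the
#' result tables (TSV), model metadata and provenance sidecars (JSON) to
#' an output directory. Every artifact's sidecar records the master seed
#' and the stage that produced it; reruns with the same config and seed
#' reproduce the same tables.
#'
#' @param config a list (or path to a YAML file) with any of:
#'   `seed` (master seed), `out_dir` (required), `n_case`, `n_control`,
#'   `train_fraction`, `phantom` (arguments for [phantom_spec()]),
#'   `params` (arguments for [generative_params()]; `effect_map` may be a
#'   named list), `model` (arguments for [model_config()]).
#' @return invisibly, a list with the split, both trained models, the
#'   prediction-accuracy tables, the model comparison, both effect-size
#'   tables and the agreement result.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$out_dir))
    stop("config must name an out_dir")
  seed <- config$seed %||% 1L
  n_case <- config$n_case %||% 8L
  n_control <- config$n_control %||% 8L
  if (n_case + n_control < 6L)
    stop("need at least 6 subjects for a balanced split")
  train_fraction <- config$train_fraction %||% (2 / 3)
  n_total <- n_case + n_control
  if (n_total - round(n_total * train_fraction) < 4L)
    stop("configuration leaves fewer than 4 test subjects; increase the ",
         "cohort or lower train_fraction")
  phantom <- make_phantom(do.call(phantom_spec, c(
    config$phantom %||% list(),
    if (is.null(config$phantom$seed)) list(seed = substream_seed(seed, "phantom")))))
  pargs <- config$params %||% list()
  if (!is.null(pargs$effect_map)) pargs$effect_map <- unlist(pargs$effect_map)
  params <- do.call(generative_params, pargs)
  mcfg <- do.call(model_config, c(config$model %||% list(),
                                  if (is.null(config$model$seed))
                                    list(seed = substream_seed(seed, "model"))))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  prov <- function(stage) list(stage = stage, master_seed = seed,
                               package_version =
                                 as.character(utils::packageVersion("rsfCBF")))

  cohort <- simulate_cohort(n_case, n_control, phantom, params,
                            seed = substream_seed(seed, "cohort"))
  utils::write.table(cohort$manifest, out("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_sidecar(out("manifest.tsv"), prov("simulate"))

  feats <- lapply(cohort$subjects, function(s)
    extract_features(s$bold, phantom$mask, s$occupancy,
                     mode = "pva_corrected", allow_partial = TRUE))

  split <- split_cohort(cohort$manifest, train_fraction,
                        seed = substream_seed(seed, "split"))
  jsonlite::write_json(list(train_ids = split$train_ids,
                            test_ids = split$test_ids,
                            age_p = split$age_p, sex_p = split$sex_p),
                       out("split.json"), auto_unbox = TRUE, digits = NA)

  meas <- lapply(cohort$subjects, `[[`, "measured_cbf")
  rnames <- region_names(phantom$atlas)
  reg_means <- function(map) {
    rt <- regionalize(map, phantom$atlas, phantom$mask)
    stats::setNames(rt$mean, rt$region)[rnames]
  }
  meas_reg <- t(vapply(split$test_ids, function(id) reg_means(meas[[id]]),
                       stats::setNames(numeric(length(rnames)), rnames)))
  mwb <- vapply(split$test_ids, function(id)
    wholebrain_mean(meas[[id]], phantom$mask), 0)

  models <- list(); acc <- list()
  for (mode in c("pva_corrected", "original")) {
    fts <- if (mode == "pva_corrected") feats else
      lapply(feats, set_feature_mode, mode = "original")
    pooled <- assemble_training_set(fts[split$train_ids],
                                    meas[split$train_ids], mcfg)
    models[[mode]] <- tune_and_train(pooled$x, pooled$y, mcfg,
                                     groups = pooled$subject, mode = mode)
    write_model_metadata(models[[mode]],
                         out(sprintf("model_%s.json", mode)))
    preds <- lapply(split$test_ids, function(id)
      predict_voxelwise(models[[mode]], fts[[id]]))
    names(preds) <- split$test_ids
    pred_reg <- t(vapply(preds, reg_means,
                         stats::setNames(numeric(length(rnames)), rnames)))
    pwb <- vapply(preds, wholebrain_mean, 0, mask = phantom$mask)
    acc[[mode]] <- predicted_vs_measured(pred_reg, meas_reg, pwb, mwb)
    f <- out(sprintf("prediction_accuracy_%s.tsv", mode))
    write_result_table(acc[[mode]], f)
    write_sidecar(f, prov(paste0("accuracy:", mode)))
  }

  cmp <- compare_models(
    r_original = acc$original$r[acc$original$region != "whole_brain"],
    r_corrected = acc$pva_corrected$r[acc$pva_corrected$region != "whole_brain"],
    n = length(split$test_ids),
    regions = acc$original$region[acc$original$region != "whole_brain"])
  write_result_table(cmp, out("model_comparison.tsv"))
  write_sidecar(out("model_comparison.tsv"), prov("compare"))

  # case-control effect sizes on predicted (corrected-mode) and measured
  # regional CBF over the whole cohort
  all_ids <- cohort$manifest$subject_id
  pred_all <- t(vapply(all_ids, function(id)
    reg_means(predict_voxelwise(models$pva_corrected, feats[[id]])),
    stats::setNames(numeric(length(rnames)), rnames)))
  meas_all <- t(vapply(all_ids, function(id) reg_means(meas[[id]]),
                       stats::setNames(numeric(length(rnames)), rnames)))
  is_case <- cohort$manifest$group == "case"
  d_res <- NULL; agree <- NULL
  if (sum(is_case) >= 2L && sum(!is_case) >= 2L) {
    d_pred <- cohens_d_table(pred_all[is_case, , drop = FALSE],
                             pred_all[!is_case, , drop = FALSE])
    d_meas <- cohens_d_table(meas_all[is_case, , drop = FALSE],
                             meas_all[!is_case, , drop = FALSE])
    write_result_table(d_pred, out("effect_sizes_predicted.tsv"))
    write_result_table(d_meas, out("effect_sizes_measured.tsv"))
    write_sidecar(out("effect_sizes_predicted.tsv"), prov("group"))
    write_sidecar(out("effect_sizes_measured.tsv"), prov("group"))
    agree <- effect_size_agreement(d_pred, d_meas)
    jsonlite::write_json(list(r = agree$r, p = agree$p,
                              n_regions = agree$n_regions),
                         out("agreement.json"), auto_unbox = TRUE,
                         digits = NA)
    d_res <- list(predicted = d_pred, measured = d_meas)
  }
  invisible(list(split = split, models = models, accuracy = acc,
                 comparison = cmp, effect_sizes = d_res,
                 agreement = agree, phantom = phantom))
}
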