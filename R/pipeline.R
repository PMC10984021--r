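#' Simulate a full assay campaign and write its input tables
#'
#' Convenience wrapper around the generator chain: slab, truth, plate
#' randomization, assay campaign, MRI metrics. When `out_dir` is given the
#' standard CSV artifacts (`voxels.csv`, `plates.csv`, `traces.csv`,
#' `respirometry.csv`, `qpcr.csv`, `mri.csv`, `truth.json`) are written.
#'
#' @param config A [slab_config()].
#' @param effects An [effect_config()].
#' @param noise A [noise_config()].
#' @param target_r2 MRI predictability target.
#' @param coupling Passed to [generate_truth()].
#' @param seed Master seed; stage seeds are derived from it.
#' @param n_plates,samples_per_plate Plate randomization parameters.
#' @param out_dir Optional output directory.
#' @return A list: `voxels`, `truth`, `assignments`, `assays`, `mri`.
#' @export
simulate_campaign <- function(config = slab_config(),
                              effects = effect_config(),
                              noise = noise_config(),
                              target_r2 = 0.3,
                              coupling = "independent",
                              seed = 1L, n_plates = 8L,
                              samples_per_plate = 90L,
                              out_dir = NULL) {
  voxels <- generate_slab(config)
  truth <- generate_truth(voxels, effects, seed = seed, coupling = coupling)
  assignments <- randomize_to_plates(voxels$voxel_id, n_plates,
                                     samples_per_plate, seed = seed)
  assays <- generate_assay_data(truth, voxels, assignments, noise,
                                seed = seed)
  mri <- generate_mri(truth, target_r2 = target_r2, seed = seed)
  out <- list(voxels = voxels, truth = truth, assignments = assignments,
              assays = assays, mri = mri)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(voxels, file.path(out_dir, "voxels.csv"), row.names = FALSE)
    write.csv(assignments, file.path(out_dir, "plates.csv"),
              row.names = FALSE)
    write.csv(assays$traces, file.path(out_dir, "traces.csv"),
              row.names = FALSE)
    write.csv(assays$respirometry, file.path(out_dir, "respirometry.csv"),
              row.names = FALSE)
    write.csv(assays$qpcr, file.path(out_dir, "qpcr.csv"), row.names = FALSE)
    write.csv(mri$metrics, file.path(out_dir, "mri.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(latent = truth$latent, raw = truth$raw,
           plate_factors = as.list(assays$plate_factors),
           mri_sigma = mri$sigma, seed = seed),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Run the analysis pipeline on a simulated or loaded campaign
#'
#' Executes the stages in dependency order: assay processing (colorimetry,
#' respirometry, qPCR), feature derivation, spatial feature volumes,
#' embedding + cluster accuracy, and the stepwise MRI models with
#' out-of-sample evaluation. Outputs are stamped with the config hash and
#' seed; re-running with identical inputs reproduces identical artifacts.
#'
#' @param campaign Output of [simulate_campaign()].
#' @param out_dir Output directory for artifacts (`features.csv`,
#'   `regions.csv`, `embedding.csv`, `accuracy.json`, `models.json`,
#'   `predictions.csv`, one NIfTI volume per derived feature, and
#'   `run_manifest.json`).
#' @param seed Seed for the split/embedding stages.
#' @param alpha Stepwise significance level.
#' @param k_clusters Embedding cluster count.
#' @return A list with the main stage outputs (invisible artifacts on disk).
#' @export
run_pipeline <- function(campaign, out_dir, seed = 1L, alpha = 0.05,
                         k_clusters = 3L) {
  stopifnot(is.list(campaign), !is.null(campaign$assays))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  colorim <- process_colorimetry(campaign$assays$traces,
                                 campaign$assignments)
  resp <- process_respirometry(campaign$assays$respirometry,
                               campaign$assignments)
  qp <- process_qpcr(campaign$assays$qpcr, campaign$assignments)
  features <- build_feature_table(colorim, resp, qp,
                                  voxel_ids = campaign$voxels$voxel_id)
  write.csv(features, file.path(out_dir, "features.csv"), row.names = FALSE)

  voxels <- campaign$voxels
  regions <- region_aggregate(features$trc, voxels$region)
  write.csv(regions, file.path(out_dir, "regions.csv"), row.names = FALSE)

  # feature volumes
  shape <- c(max(voxels$col) + 1L, max(voxels$row) + 1L, 1L)
  affine <- attr(voxels, "affine") %||% slab_affine()
  ijk <- cbind(voxels$col, voxels$row, 0L)
  for (feat in c("mito_d", "trc", "mrc", "ci", "cii", "civ")) {
    vol <- grid_to_volume(features[[feat]], ijk, shape, affine)
    write_volume(vol, file.path(out_dir, paste0(feat, ".nii.gz")))
  }

  # embedding on complete annotated voxels
  known <- voxels$tissue_class %in% c("GM", "WM", "mixed")
  emb_rows <- features$complete & known
  emb_mat <- as.matrix(features[emb_rows,
                                c("ci", "cii", "civ", "cs_n", "mtdna_n")])
  coords <- embed_features(emb_mat, seed = seed)
  clusters <- cluster_embedding(coords, k = k_clusters, seed = seed)
  accuracy <- cluster_class_accuracy(clusters,
                                     voxels$tissue_class[emb_rows])
  emb_df <- data.frame(voxel_id = features$voxel_id[emb_rows], coords,
                       cluster = clusters)
  write.csv(emb_df, file.path(out_dir, "embedding.csv"), row.names = FALSE)
  jsonlite::write_json(accuracy, file.path(out_dir, "accuracy.json"),
                       auto_unbox = TRUE, digits = NA)

  # stepwise models on filtered, complete voxels
  pv_keep <- partial_volume_filter(voxels$gm_prob, voxels$wm_prob)
  model_rows <- which(features$complete & pv_keep)
  X <- as.matrix(campaign$mri$metrics[model_rows, mri_metric_names()])
  split <- split_train_test(model_rows, seed = seed)
  train_idx <- match(split$train, model_rows)
  test_idx <- match(split$test, model_rows)
  responses <- c("ci", "cii", "civ", "mito_d", "trc", "mrc")
  models <- list()
  preds <- data.frame(voxel_id = features$voxel_id[model_rows][test_idx])
  eval_r2 <- c()
  for (r in responses) {
    y <- features[[r]][model_rows]
    m <- stepwise_backward(X[train_idx, , drop = FALSE], y[train_idx],
                           alpha = alpha)
    models[[r]] <- m
    p <- predict(m, X[test_idx, , drop = FALSE])
    preds[[r]] <- p
    eval_r2[r] <- evaluate_r2(y[test_idx], p)
  }
  write.csv(preds, file.path(out_dir, "predictions.csv"), row.names = FALSE)
  jsonlite::write_json(
    lapply(models, function(m) list(predictors = m$predictors,
                                    beta = as.list(m$beta),
                                    intercept = m$intercept,
                                    alpha = m$alpha,
                                    r_squared_train = m$r_squared)),
    file.path(out_dir, "models.json"), auto_unbox = TRUE, digits = NA)

  manifest <- list(config_hash = config_hash(campaign), seed = seed,
                   stages = c("assays", "features", "volumes", "embedding",
                              "models"),
                   n_voxels = nrow(voxels),
                   n_complete = sum(features$complete),
                   n_modeled = length(model_rows),
                   test_r2 = as.list(eval_r2))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(features = features, regions = regions,
                 accuracy = accuracy, models = models,
                 test_r2 = eval_r2, manifest = manifest))
}

# Stable hash of the campaign inputs (seed + dimensions + truth digest).
config_hash <- function(campaign) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(list(seed = campaign$truth$seed,
               n = nrow(campaign$voxels),
               latent_sum = sum(campaign$truth$latent[, -1])), tmp)
  unname(tools::md5sum(tmp))
}
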