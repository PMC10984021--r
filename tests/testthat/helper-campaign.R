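# Small slab + campaign builders shared across test files. Sizes are kept
# modest so the default suite stays fast; full-campaign checks live in
# test-acceptance.R.

tiny_slab_config <- function(seed = 1L, n_voxels = 40L) {
  slab_config(grid_rows = 6L, grid_cols = 8L, n_voxels = n_voxels,
              class_counts = c(WM = 8L, mixed = 10L, GM = 22L),
              seed = seed)
}

tiny_campaign <- function(seed = 1L, noise = noise_config(0, 0, 0),
                          batch_sdlog = 0, n_plates = 4L,
                          samples_per_plate = 12L) {
  cfg <- tiny_slab_config(seed)
  voxels <- generate_slab(cfg)
  truth <- generate_truth(voxels, seed = seed)
  assignments <- randomize_to_plates(voxels$voxel_id, n_plates,
                                     samples_per_plate, seed = seed)
  assays <- generate_assay_data(truth, voxels, assignments, noise,
                                batch_sdlog = batch_sdlog, seed = seed)
  list(config = cfg, voxels = voxels, truth = truth,
       assignments = assignments, assays = assays)
}

# Larger slab for stages that need n comfortably above the 22 MRI metrics
# (stepwise modeling, pipeline smoke runs).
medium_campaign <- function(seed = 1L, noise = noise_config(0, 0, 0),
                            batch_sdlog = 0) {
  cfg <- slab_config(grid_rows = 10L, grid_cols = 12L, n_voxels = 100L,
                     class_counts = c(WM = 20L, mixed = 25L, GM = 55L),
                     seed = seed)
  voxels <- generate_slab(cfg)
  truth <- generate_truth(voxels, seed = seed)
  assignments <- randomize_to_plates(voxels$voxel_id, n_plates = 2L,
                                     samples_per_plate = 50L, seed = seed)
  assays <- generate_assay_data(truth, voxels, assignments, noise,
                                batch_sdlog = batch_sdlog, seed = seed)
  list(config = cfg, voxels = voxels, truth = truth,
       assignments = assignments, assays = assays)
}

# Align a per-voxel vector with the truth table's raw column.
truth_lookup <- function(truth, feature, voxel_ids) {
  truth$raw[[feature]][match(voxel_ids, truth$raw$voxel_id)]
}
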