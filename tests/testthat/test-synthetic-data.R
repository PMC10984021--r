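test_that("slab generation is deterministic and respects the weight model", {
  cfg <- tiny_slab_config(seed = 11)
  v1 <- generate_slab(cfg)
  v2 <- generate_slab(cfg)
  expect_identical(v1, v2)

  # zero weight noise: every voxel at the predicted 27 mg
  v0 <- generate_slab(cfg, weight_sd = 0)
  expect_true(all(v0$weight == 27))

  # 2 x 2 all-GM grid
  lay <- matrix("GM", 2, 2)
  cfg2 <- slab_config(grid_rows = 2, grid_cols = 2, tissue_layout = lay)
  v <- generate_slab(cfg2)
  expect_equal(nrow(v), 4L)
  expect_true(all(v$tissue_class == "GM"))

  # degenerate grid rejected
  expect_error(slab_config(grid_rows = 2, grid_cols = 2,
                           tissue_layout = matrix("edge", 2, 2)),
               "degenerate")
})

test_that("default slab reproduces the campaign class composition", {
  v <- generate_slab(slab_config(seed = 1))
  expect_equal(nrow(v), 703L)
  tab <- table(v$tissue_class)
  expect_equal(unname(tab[["GM"]]), 325L)
  expect_equal(unname(tab[["WM"]]), 132L)
  expect_equal(unname(tab[["mixed"]]), 176L)
  expect_true(all(v$gm_prob >= 0 & v$gm_prob <= 1))
  expect_true(all(v$gm_prob + v$wm_prob <= 1 + 1e-12))
  # GM-class voxels carry high grey-matter probability
  expect_gt(min(v$gm_prob[v$tissue_class == "GM"] /
                  (v$gm_prob + v$wm_prob)[v$tissue_class == "GM"]), 0.8)
})

test_that("configured GM-WM effect sizes are realized on the latent scale", {
  v <- generate_slab(slab_config(seed = 2))
  cfg_g2 <- effect_config(g = c(cs = 2, mtdna = 2, ci = 2, cii = 2, civ = 2))
  truth <- generate_truth(v, cfg_g2, seed = 2)
  gm <- v$tissue_class == "GM"; wm <- v$tissue_class == "WM"
  for (f in c("cs", "ci", "civ")) {
    g_hat <- hedges_g(truth$latent[[f]][gm], truth$latent[[f]][wm])
    expect_gt(g_hat, 1.7)
    expect_lt(g_hat, 2.3)
  }

  cfg_g0 <- effect_config(g = c(cs = 0, mtdna = 0, ci = 0, cii = 0, civ = 0))
  truth0 <- generate_truth(v, cfg_g0, seed = 2)
  expect_lt(abs(hedges_g(truth0$latent$cs[gm], truth0$latent$cs[wm])), 0.1)

  # raw volume features (cubes of normals) are right-skewed
  expect_gt(e1071::skewness(truth$raw$cs[gm]), 0)
  expect_error(effect_config(sd = c(cs = -1, mtdna = 1, ci = 1, cii = 1,
                                    civ = 1)), "positive")
})

test_that("proportional coupling yields identical per-mitochondrion OxPhos", {
  v <- generate_slab(tiny_slab_config(seed = 3))
  truth <- generate_truth(v, seed = 3, coupling = "proportional")
  ratio <- truth$latent$ci / truth$latent$cs
  expect_lt(diff(range(ratio)), 1e-12)
})

test_that("assay forward model matches its construction", {
  cmp <- tiny_campaign(seed = 4, batch_sdlog = 0.3)
  w <- assay_windows()[assay_windows()$assay == "CS", ]
  tr <- cmp$assays$traces
  pid <- "CS-P01-r1"
  pf <- cmp$assays$plate_factors[[pid]]
  one <- tr[tr$plate_id == pid & tr$well == "A1", ]
  voxel <- cmp$assignments$voxel_id[cmp$assignments$plate_id == "P01" &
                                      cmp$assignments$well == "A1"]
  raw <- truth_lookup(cmp$truth, "cs", voxel)
  slope <- integrate_window(one$time_s, one$od,
                            c(w$late_start, w$late_end), w$direction) /
    (w$late_end - w$late_start)
  expect_equal(slope, pf * (raw + cmp$assays$ns_rates[["CS"]]),
               tolerance = 1e-9)

  # qPCR definition: halving the template amount costs exactly one cycle
  ct1 <- log2(1e12) - log2(raw)
  ct2 <- log2(1e12) - log2(raw / 2)
  expect_equal(ct2 - ct1, 1)
})

test_that("campaign generation is deterministic under a fixed seed", {
  c1 <- tiny_campaign(seed = 9, noise = noise_config())
  c2 <- tiny_campaign(seed = 9, noise = noise_config())
  expect_identical(c1$assays$traces, c2$assays$traces)
  expect_identical(c1$assays$qpcr, c2$assays$qpcr)
  expect_identical(c1$assays$respirometry, c2$assays$respirometry)
})

test_that("MRI metrics hit the configured predictability", {
  v <- generate_slab(slab_config(seed = 5))
  truth <- generate_truth(v, seed = 5)
  mri <- generate_mri(truth, target_r2 = 0.3, seed = 5)
  X <- as.matrix(mri$metrics[, mri_metric_names()])
  F_mat <- mri$features
  set.seed(42)
  idx <- sample(nrow(X))
  train <- idx[1:431]; test <- idx[432:539]
  r2 <- sapply(seq_len(5), function(f) {
    beta <- lm.fit(cbind(1, X[train, ]), F_mat[train, f])$coefficients
    pred <- drop(cbind(1, X[test, ]) %*% beta)
    cor(F_mat[test, f], pred)^2
  })
  expect_gt(mean(r2), 0.2)
  expect_lt(mean(r2), 0.4)

  expect_error(generate_mri(truth, target_r2 = 1.2), "target_r2")
  null_mri <- generate_mri(truth, target_r2 = 0.3,
                           coefficients = matrix(0, 5, 22), seed = 5)
  expect_equal(null_mri$sigma, 1)
})

test_that("expression generator encodes region and cell-type structure", {
  small_n <- c(MTg = 300, Hipp = 300, Put = 300, WM = 300)
  ex <- generate_expression(n_nuclei = small_n, seed = 6)
  expect_true(all(ex$matrix >= 0))
  grp <- paste(ex$metadata$voxel, ex$metadata$cell_type, sep = "|")
  scores <- pathway_score(pseudobulk(ex$matrix, grp), ex$annotation)
  vox_of <- sub("\\|.*", "", colnames(scores))
  cell_of <- sub(".*\\|", "", colnames(scores))

  cl_raw <- correlation_cluster(scores, k = 4)$clusters
  expect_gt(mclust::adjustedRandIndex(cl_raw, vox_of), 0.9)
  z <- zscore_matrix(scores, "within_voxel", voxel = vox_of)
  cl_z <- correlation_cluster(z, k = 9)$clusters
  expect_gt(mclust::adjustedRandIndex(cl_z, cell_of), 0.9)

  # all effects silenced: pathway scores constant across samples
  flat <- generate_expression(n_nuclei = small_n, region_scale = 0,
                              cell_scale = 0, noise_sd = 0, seed = 6)
  fs <- pathway_score(pseudobulk(flat$matrix,
                                 paste(flat$metadata$voxel,
                                       flat$metadata$cell_type, sep = "|")),
                      flat$annotation)
  expect_lt(max(apply(fs, 1, sd)), 1e-12)

  expect_error(generate_expression(regions = "one"), "regions")
  expect_error(generate_expression(pathway_annotation = NULL), "annotation")
})
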