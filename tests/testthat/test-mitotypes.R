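test_that("pseudobulk is a per-group gene mean", {
  m <- matrix(1:12, 3, 4, dimnames = list(paste0("g", 1:3), paste0("n", 1:4)))
  # one sample per group: identity
  pb1 <- pseudobulk(m, paste0("s", 1:4))
  expect_equal(unname(pb1), unname(m))

  pb <- pseudobulk(m, c("a", "a", "b", "b"))
  oracle <- cbind(a = rowMeans(m[, 1:2]), b = rowMeans(m[, 3:4]))
  expect_equal(pb, oracle)

  const <- pseudobulk(matrix(2, 3, 4), rep(c("a", "b"), 2))
  expect_true(all(const == 2))
  expect_error(pseudobulk(m, c("a", "a", NA, "b")), "group")
})

test_that("pathway scores are gene-set means with missing genes dropped", {
  pb <- matrix(1, 4, 3,
               dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  ann <- data.frame(pathway = c("P1", "P1", "P2"),
                    gene = c("g1", "g2", "g3"))
  sc <- pathway_score(pb, ann)
  expect_true(all(sc == 1))

  pb2 <- pb; pb2["g3", ] <- c(2, 4, 6)
  sc2 <- pathway_score(pb2, ann)
  expect_equal(unname(sc2["P2", ]), c(2, 4, 6))  # single-gene pathway

  set.seed(23)
  pbr <- matrix(rnorm(12), 4, 3, dimnames = dimnames(pb))
  scr <- pathway_score(pbr, ann)
  expect_equal(unname(scr["P1", ]), unname(colMeans(pbr[c("g1", "g2"), ])))

  expect_warning(pathway_score(pb, rbind(ann, data.frame(pathway = "P3",
                                                         gene = "absent"))),
                 "absent")
  expect_error(pathway_score(pb, ann[0, ]), "empty")
})

test_that("z-scoring modes standardize their intended units", {
  set.seed(24)
  m <- matrix(rnorm(60), 6, 10,
              dimnames = list(paste0("p", 1:6), paste0("s", 1:10)))
  within <- zscore_matrix(m, "within_sample")
  expect_equal(unname(colMeans(within)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(apply(within, 2, sd)), rep(1, 10), tolerance = 1e-12)

  # global mode keeps sample-level offsets visible
  shifted <- m; shifted[, 6:10] <- shifted[, 6:10] + 5
  glob <- zscore_matrix(shifted, "global")
  expect_gt(mean(glob[, 6:10]) - mean(glob[, 1:5]), 1)

  # constant row flagged and zeroed
  m2 <- m; m2[1, ] <- 7
  g2 <- zscore_matrix(m2, "global")
  expect_true(all(g2[1, ] == 0))
  expect_true(all(attr(g2, "zero_variance")[1, ]))

  # within-voxel mode removes per-gene voxel effects exactly
  voxel <- rep(c("v1", "v2"), each = 5)
  bump <- m; bump[, voxel == "v2"] <- bump[, voxel == "v2"] + 100
  wv_plain <- zscore_matrix(m, "within_voxel", voxel = voxel)
  wv_bump <- zscore_matrix(bump, "within_voxel", voxel = voxel)
  expect_equal(wv_plain, wv_bump, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(zscore_matrix(m, "within_voxel"), "voxel")
})

test_that("correlation clustering groups identical profiles together", {
  set.seed(25)
  base <- rnorm(8)
  m <- cbind(s1 = base, s2 = base, s3 = base)
  out <- correlation_cluster(m, k = 1)
  expect_lt(max(out$hclust$height), 1e-12)
  expect_true(all(out$clusters == 1))

  two <- cbind(a1 = base, a2 = base + rnorm(8, 0, 0.01),
               b1 = rev(base), b2 = rev(base) + rnorm(8, 0, 0.01))
  cl <- correlation_cluster(two, k = 2)$clusters
  expect_equal(cl[["a1"]], cl[["a2"]])
  expect_equal(cl[["b1"]], cl[["b2"]])
  expect_true(cl[["a1"]] != cl[["b1"]])
  expect_error(correlation_cluster(m[, 1:2]), ">= 3")
})

test_that("nucleus totals sum the per-voxel counts", {
  expect_equal(manifest_total(c(8945, 7044, 6176, 10350)), 32515)
  expect_equal(manifest_total(numeric(0)), 0)
  expect_equal(manifest_total(7), 7)
  expect_error(manifest_total(c(3, -1)), "negative")
})
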