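#' UMAP embedding of voxel mitochondrial profiles
#'
#' Features are z-scored per column before embedding. Rows with any missing
#' feature are rejected (use the feature table's completeness flag
#' upstream). Deterministic under a fixed seed (single-threaded SGD).
#'
#' @param features Numeric matrix or data frame (voxels x features).
#' @param n_neighbors,min_dist UMAP parameters.
#' @param seed Integer seed.
#' @return An n x 2 matrix of embedding coordinates.
#' @export
embed_features <- function(features, n_neighbors = 15, min_dist = 0.1,
                           seed = 1L) {
  x <- as.matrix(features)
  if (anyNA(x)) stopf("rows with missing features must be removed first")
  x <- scale(x)
  x[, colSums(is.na(x)) > 0] <- 0  # constant columns carry no signal
  set.seed(derive_seed(seed, 808L))
  coords <- uwot::umap(x, n_neighbors = min(n_neighbors, nrow(x) - 1),
                       min_dist = min_dist, n_threads = 1,
                       n_sgd_threads = 1, batch = FALSE)
  colnames(coords) <- c("dim1", "dim2")
  coords
}

#' Cluster an embedding with k-means
#'
#' Stands in for the visual cluster delineation of the original analysis;
#' k defaults to 3 for all-voxel embeddings (GM / WM / mixed) and 4 is the
#' convention for GM-only embeddings.
#'
#' @param coords Embedding coordinates (n x 2).
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @return Integer cluster labels `0..k-1`.
#' @export
cluster_embedding <- function(coords, k = 3L, seed = 1L) {
  coords <- as.matrix(coords)
  if (k > nrow(coords)) stopf("k exceeds the number of points")
  set.seed(derive_seed(seed, 909L))
  km <- kmeans(coords, centers = k, nstart = 10L)
  km$cluster - 1L
}

#' Cluster-to-tissue-class prediction accuracy
#'
#' Each cluster predicts its majority tissue class; per-class accuracy is
#' the fraction of that class's voxels landing in clusters that predict it.
#' Chance level is the class prevalence, in rounded percent.
#'
#' @param cluster_labels Cluster assignment per voxel.
#' @param tissue_classes Tissue class per voxel.
#' @return A `data.frame`: `class`, `accuracy_pct`, `chance_pct`, `n`.
#' @export
cluster_class_accuracy <- function(cluster_labels, tissue_classes) {
  stopifnot(length(cluster_labels) == length(tissue_classes))
  classes <- unique(tissue_classes)
  if (any(table(tissue_classes) == 0)) stopf("empty tissue class")
  tab <- table(cluster_labels, tissue_classes)
  majority <- colnames(tab)[apply(tab, 1, which.max)]
  predicted <- majority[match(as.character(cluster_labels),
                              rownames(tab))]
  n_total <- length(tissue_classes)
  out <- lapply(classes, function(cl) {
    in_class <- tissue_classes == cl
    data.frame(class = cl,
               accuracy_pct = round(100 * mean(predicted[in_class] == cl)),
               chance_pct = round(100 * sum(in_class) / n_total),
               n = sum(in_class), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
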