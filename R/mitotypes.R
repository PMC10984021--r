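#' Pseudobulk aggregation of a genes x nuclei matrix
#'
#' Mean expression per gene within each sample group (voxel, or voxel by
#' cell type), mimicking bulk RNA-seq of the group.
#'
#' @param expr Genes x nuclei numeric matrix.
#' @param groups Group label per nucleus (length = ncol(expr)).
#' @return Genes x groups matrix of means.
#' @export
pseudobulk <- function(expr, groups) {
  stopifnot(ncol(expr) == length(groups))
  groups <- as.character(groups)
  levels <- unique(groups)
  if (any(!nzchar(levels)) || anyNA(groups)) stopf("empty group label")
  out <- vapply(levels, function(g)
    rowMeans(expr[, groups == g, drop = FALSE]), numeric(nrow(expr)))
  dimnames(out) <- list(rownames(expr), levels)
  out
}

#' Pathway scores from pseudobulk expression
#'
#' Mean expression of each pathway's genes, per sample. Annotation genes
#' absent from the matrix are dropped with a warning; a pathway with no
#' remaining genes is an error.
#'
#' @param pb Genes x samples pseudobulk matrix.
#' @param annotation Two-column `data.frame` (`pathway`, `gene`).
#' @return Pathways x samples score matrix.
#' @export
pathway_score <- function(pb, annotation) {
  if (is.null(annotation) || !nrow(annotation)) stopf("empty pathway annotation")
  missing <- setdiff(unique(annotation$gene), rownames(pb))
  if (length(missing)) {
    warning(sprintf("%d annotation gene(s) absent from the matrix",
                    length(missing)))
    annotation <- annotation[!annotation$gene %in% missing, ]
  }
  pathways <- unique(annotation$pathway)
  out <- t(vapply(pathways, function(p) {
    genes <- annotation$gene[annotation$pathway == p]
    if (!length(genes)) stopf("pathway '%s' has no genes in the matrix", p)
    colMeans(pb[genes, , drop = FALSE])
  }, numeric(ncol(pb))))
  dimnames(out) <- list(pathways, colnames(pb))
  out
}

#' Z-score a score or expression matrix
#'
#' * `global`: each row (gene/pathway) standardized across all samples;
#'   sample-level offsets (e.g. region effects) remain visible.
#' * `within_sample`: each column standardized across rows (mean 0, SD 1
#'   per sample).
#' * `within_voxel`: each row standardized within each voxel's group of
#'   samples (requires `voxel`); removes any per-gene effect that is
#'   constant within a voxel — region effects vanish exactly, exposing
#'   cell-type structure.
#'
#' Zero-variance standardization units are flagged (attribute
#' `zero_variance`) and set to 0.
#'
#' @param mat Numeric matrix (rows = genes/pathways, columns = samples).
#' @param mode One of `"global"`, `"within_sample"`, `"within_voxel"`.
#' @param voxel Voxel label per column (required for `"within_voxel"`).
#' @return Z-scored matrix with attribute `zero_variance`.
#' @export
zscore_matrix <- function(mat,
                          mode = c("global", "within_sample", "within_voxel"),
                          voxel = NULL) {
  mode <- match.arg(mode)
  zs <- function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) rep(NA_real_, length(x))
    else (x - mean(x)) / s
  }
  out <- mat
  if (mode == "global") {
    out <- t(apply(mat, 1, zs))
  } else if (mode == "within_sample") {
    out <- apply(mat, 2, zs)
  } else {
    if (is.null(voxel) || length(voxel) != ncol(mat))
      stopf("within_voxel mode needs one voxel label per column")
    for (v in unique(voxel)) {
      cols <- voxel == v
      if (sum(cols) < 2L) stopf("voxel '%s' has < 2 samples", v)
      out[, cols] <- t(apply(mat[, cols, drop = FALSE], 1, zs))
    }
  }
  zero_var <- is.na(out) & !is.na(mat)
  out[zero_var] <- 0
  dimnames(out) <- dimnames(mat)
  attr(out, "zero_variance") <- zero_var
  out
}

#' Hierarchical clustering of sample score profiles
#'
#' Average-linkage hierarchical clustering with 1 - Pearson correlation
#' distance (or Euclidean), returning the leaf order and flat clusters at k.
#'
#' @param scores Pathways x samples matrix (>= 3 columns).
#' @param k Number of flat clusters.
#' @param distance `"correlation"` (1 - Pearson, default) or `"euclidean"`.
#' @return A list: `order` (leaf order), `clusters` (named integer vector),
#'   `hclust` (the tree).
#' @export
correlation_cluster <- function(scores, k = 2L,
                                distance = c("correlation", "euclidean")) {
  distance <- match.arg(distance)
  if (ncol(scores) < 3L) stopf("need >= 3 samples")
  if (distance == "correlation") {
    sds <- apply(scores, 2, sd)
    if (any(sds == 0)) stopf("constant sample column(s)")
    d <- as.dist(1 - cor(scores))
  } else {
    d <- dist(t(scores))
  }
  tree <- hclust(d, method = "average")
  clusters <- cutree(tree, k = k)
  list(order = tree$order, clusters = clusters, hclust = tree)
}

#' Total count across groups
#'
#' @param per_group_counts Non-negative counts (e.g. recovered nuclei per
#'   voxel).
#' @return Their sum.
#' @export
manifest_total <- function(per_group_counts) {
  if (!length(per_group_counts)) return(0)
  if (any(per_group_counts < 0)) stopf("negative count")
  sum(per_group_counts)
}
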