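#' Place per-voxel feature values into a 3-D volume
#'
#' Writes each voxel's value at its 0-based `(i, j, k)` lattice cell;
#' unvisited cells keep the background value. Two voxels claiming one cell
#' is an error.
#'
#' @param values Numeric vector of feature values.
#' @param ijk Integer matrix (n x 3) of 0-based voxel indices.
#' @param shape Length-3 lattice dimensions.
#' @param affine 4 x 4 voxel-to-world (RAS mm) affine.
#' @param background Value for empty cells (default 0).
#' @return A list of class `brain_volume`: `data` (3-D array), `affine`,
#'   `background`.
#' @export
grid_to_volume <- function(values, ijk, shape, affine = slab_affine(),
                           background = 0) {
  ijk <- as.matrix(ijk)
  stopifnot(ncol(ijk) == 3L, length(values) == nrow(ijk),
            length(shape) == 3L)
  if (any(shape < 1)) stopf("lattice shape must be positive")
  if (abs(det(affine)) < 1e-12) stopf("affine must be invertible")
  out_of_range <- any(ijk < 0) ||
    any(ijk[, 1] > shape[1] - 1) || any(ijk[, 2] > shape[2] - 1) ||
    any(ijk[, 3] > shape[3] - 1)
  if (out_of_range) stopf("voxel indices outside lattice shape")
  lin <- 1L + ijk[, 1] + shape[1] * (ijk[, 2] + shape[2] * ijk[, 3])
  if (anyDuplicated(lin)) stopf("index collision: two voxels map to one cell")
  data <- array(background, dim = shape)
  data[lin] <- values
  structure(list(data = data, affine = affine, background = background),
            class = "brain_volume")
}

#' Write a brain volume to a NIfTI-1 file
#'
#' Data are stored as float64 so lattice values round-trip bit-exactly; the
#' affine is stored in the sform/qform (single precision in the NIfTI-1
#' header, so affines with single-precision-representable entries round-trip
#' exactly).
#'
#' @param volume A `brain_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$data, datatype = "double")
  img <- RNifti::`sform<-`(img, structure(volume$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a NIfTI-1 file back into a brain volume
#'
#' @param path NIfTI file path.
#' @param background Background value recorded on the returned object.
#' @return A `brain_volume`.
#' @export
read_volume <- function(path, background = 0) {
  img <- RNifti::readNifti(path)
  affine <- structure(RNifti::xform(img), class = "matrix")
  shape3 <- c(dim(img), 1L, 1L)[1:3]  # NIfTI readers drop trailing singletons
  structure(list(data = array(as.numeric(img), dim = shape3),
                 affine = matrix(as.numeric(affine), 4, 4),
                 background = background),
            class = "brain_volume")
}

#' Partial-volume filter
#'
#' Voxels whose combined GM and WM probability falls below the threshold are
#' contaminated by non-tissue (CSF) signal and discarded; the boundary is
#' inclusive (a sum of exactly 0.70 is kept).
#'
#' @param gm_prob,wm_prob Probabilities in \[0, 1\].
#' @param threshold Minimal GM+WM probability (default 0.70).
#' @return Logical vector: `TRUE` = keep.
#' @export
partial_volume_filter <- function(gm_prob, wm_prob, threshold = 0.70) {
  if (any(gm_prob < 0 | gm_prob > 1 | wm_prob < 0 | wm_prob > 1,
          na.rm = TRUE))
    stopf("probabilities must be in [0, 1]")
  gm_prob + wm_prob >= threshold
}

#' Aggregate voxel features by region
#'
#' @param values Numeric vector of per-voxel values.
#' @param regions Region labels aligned with `values`.
#' @param statistic `"mean"` or `"median"`.
#' @return A `data.frame`: `region`, `value`, `n`.
#' @export
region_aggregate <- function(values, regions, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  if (!length(regions) || !length(values)) stopf("empty region set")
  fun <- if (statistic == "mean") mean else median
  keep <- is.finite(values)
  agg <- tapply(values[keep], regions[keep], fun)
  n <- tapply(values[keep], regions[keep], length)
  data.frame(region = names(agg), value = as.numeric(agg),
             n = as.integer(n), stringsAsFactors = FALSE)
}

#' Default phylogenic ranks of the slab regions
#'
#' Ordinal phylogenic age, oldest (pallidal/striatal) to newest (frontal
#' cortex), for the default slab region labels.
#' @return Named integer vector (1 = oldest).
#' @export
default_phylo_ranks <- function() {
  c(ePal = 1L, iPal = 2L, Put = 3L, H = 4L, Ins = 5L, MTg = 6L, IFg = 7L,
    SFg = 8L, MFg = 9L)
}

#' Correlation of region feature summaries with phylogenic rank
#'
#' Spearman rank correlation (midranks for ties) between per-region feature
#' summaries and an ordinal phylogenic-age ranking.
#'
#' @param region_summaries Output of [region_aggregate()] (or a named
#'   vector of per-region values).
#' @param phylo_ranks Named numeric vector of phylogenic ranks.
#' @return A list: `rho`, `p_value`, `n_regions`.
#' @export
phylo_correlation <- function(region_summaries, phylo_ranks = default_phylo_ranks()) {
  if (is.data.frame(region_summaries)) {
    vals <- setNames(region_summaries$value, region_summaries$region)
  } else {
    vals <- region_summaries
  }
  common <- intersect(names(vals), names(phylo_ranks))
  if (length(common) < 5L) stopf("need >= 5 regions with both values")
  ct <- suppressWarnings(cor.test(vals[common], phylo_ranks[common],
                                  method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n_regions = length(common))
}
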