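#' Configuration for a voxelized tissue slab
#'
#' Describes the milling grid laid over a frozen coronal brain slab: grid
#' dimensions, voxel edge length, and per-cell tissue class and region
#' layouts. When `tissue_layout`/`region_layout` are omitted, a deterministic
#' anatomically flavoured default is built: cells outside an ellipse
#' inscribed in the grid are `edge` (no tissue collected), the innermost
#' cells form a white-matter core (corpus callosum-like), a ring of `mixed`
#' cells surrounds it, and the outer shell is grey matter split into cortical
#' and subcortical region labels by angular sector.
#'
#' With the default 20 x 43 grid and `n_voxels = 703`, the default layout
#' reproduces the class composition of the annotated campaign: 325 GM, 132 WM
#' and 176 mixed voxels among the 633 voxels that are classed GM/WM/mixed
#' plus 70 additional voxels flagged `unknown` (emulating voxels lacking a
#' confident class annotation).
#'
#' @param grid_rows,grid_cols Grid dimensions (positive integers).
#' @param voxel_side Voxel edge length in mm (default 3).
#' @param n_voxels Number of tissue (non-edge) cells for the default layout.
#' @param tissue_layout Optional `grid_rows x grid_cols` character matrix with
#'   entries in `c("GM", "WM", "mixed", "unknown", "edge")`.
#' @param region_layout Optional character matrix of region labels (ignored
#'   for `edge` cells).
#' @param class_counts Named counts used by the default layout,
#'   `c(WM, mixed, GM)` assigned from the slab centre outward; remaining
#'   tissue cells are classed `unknown`.
#' @param seed Integer seed (layout defaults are deterministic; the seed is
#'   carried along for downstream generators).
#' @return An object of class `slab_config`.
#' @export
slab_config <- function(grid_rows = 20L, grid_cols = 43L, voxel_side = 3,
                        n_voxels = 703L, tissue_layout = NULL,
                        region_layout = NULL,
                        class_counts = c(WM = 132L, mixed = 176L, GM = 325L),
                        seed = 1L) {
  if (grid_rows < 1 || grid_cols < 1) stopf("grid dimensions must be positive")
  check_scalar_positive(voxel_side, "voxel_side")
  n_cells <- grid_rows * grid_cols
  if (is.null(tissue_layout)) {
    if (n_voxels < 1 || n_voxels > n_cells)
      stopf("n_voxels must be in [1, %d]", n_cells)
    lay <- default_layout(grid_rows, grid_cols, n_voxels, class_counts)
    tissue_layout <- lay$tissue
    region_layout <- region_layout %||% lay$region
  } else {
    tissue_layout <- as.matrix(tissue_layout)
    if (!all(dim(tissue_layout) == c(grid_rows, grid_cols)))
      stopf("tissue_layout dimensions must match the grid")
    bad <- setdiff(unique(as.vector(tissue_layout)),
                   c("GM", "WM", "mixed", "unknown", "edge"))
    if (length(bad)) stopf("unknown tissue classes: %s", paste(bad, collapse = ", "))
    if (is.null(region_layout)) {
      region_layout <- matrix("slab", grid_rows, grid_cols)
    }
  }
  if (!any(tissue_layout != "edge")) stopf("degenerate grid: no tissue cells")
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 voxel_side = voxel_side,
                 tissue_layout = tissue_layout,
                 region_layout = region_layout,
                 seed = as.integer(seed)),
            class = "slab_config")
}

# Deterministic elliptical slab layout. Cells are ranked by normalized
# elliptical radius; the closest `n_voxels` are tissue, ordered WM core ->
# mixed ring -> GM shell -> unknown rim, with GM/subcortical region labels
# assigned by radius and angular sector.
default_layout <- function(nr, nc, n_voxels, class_counts) {
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  r <- sqrt(((rows - cy) / (nr / 2))^2 + ((cols - cx) / (nc / 2))^2)
  ord <- order(r)
  tissue <- matrix("edge", nr, nc)
  idx <- ord[seq_len(n_voxels)]
  n_wm <- min(class_counts[["WM"]], n_voxels)
  n_mx <- min(class_counts[["mixed"]], max(n_voxels - n_wm, 0))
  n_gm <- min(class_counts[["GM"]], max(n_voxels - n_wm - n_mx, 0))
  cls <- rep("unknown", n_voxels)
  cls[seq_len(n_wm)] <- "WM"
  if (n_mx > 0) cls[n_wm + seq_len(n_mx)] <- "mixed"
  if (n_gm > 0) cls[n_wm + n_mx + seq_len(n_gm)] <- "GM"
  tissue[idx] <- cls

  # Region labels: WM core is corpus callosum; inner GM/mixed cells take
  # subcortical labels, outer cells cortical labels, both by angular sector.
  ang <- atan2(rows - cy, cols - cx)  # (-pi, pi]
  subcortical <- c("Put", "ePal", "iPal", "H")
  cortical <- c("Ins", "MTg", "IFg", "SFg", "MFg")
  sector <- function(a, labels) {
    labels[pmin(length(labels),
                1L + floor((a + pi) / (2 * pi + 1e-9) * length(labels)))]
  }
  region <- matrix("edge", nr, nc)
  inner <- r <= stats::quantile(r[idx], 0.55)
  region[idx] <- ifelse(tissue[idx] == "WM", "CC",
                        ifelse(inner[idx], sector(ang[idx], subcortical),
                               sector(ang[idx], cortical)))
  list(tissue = tissue, region = region)
}

#' Expected voxel mass from its dimensions
#'
#' @param side Voxel edge length in mm.
#' @param density Tissue density in mg/mm^3 (aqueous tissue is ~1).
#' @return Expected mass in mg (`side^3 * density`); 27 mg for a 3 mm voxel.
#' @export
expected_voxel_mass <- function(side = 3, density = 1) {
  check_scalar_positive(side, "side")
  check_scalar_positive(density, "density")
  side^3 * density
}

#' Default slab affine (grid indices to world mm, RAS)
#'
#' Maps 0-based `(col, row, slice)` indices of the coronal slab grid to MNI-like
#' mm coordinates: x increases with column, z decreases with row, y is the
#' fixed coronal plane of the slab. Entries are chosen to be exactly
#' representable in single precision so NIfTI round trips are bit-exact.
#'
#' @param voxel_side Voxel edge length in mm.
#' @param origin Length-3 world coordinate of cell `(0, 0, 0)`.
#' @return A 4 x 4 affine matrix.
#' @export
slab_affine <- function(voxel_side = 3, origin = c(-64, -15.5, 28)) {
  affine <- diag(c(voxel_side, voxel_side, -voxel_side, 1))
  affine[1:3, 4] <- origin
  affine
}

#' Generate voxel records for a slab
#'
#' One record per non-edge grid cell: identifiers, 0-based grid indices,
#' tissue mass (mean `voxel_side^3 * density` mg with Gaussian noise),
#' protein concentration, relative nuclear DNA content, tissue class and
#' region annotations, GM/WM partial-volume probabilities consistent with the
#' class, and MNI mm coordinates from the slab affine.
#'
#' @param config A [slab_config()].
#' @param density Tissue density in mg/mm^3.
#' @param weight_sd SD of voxel mass in mg (0 gives exactly the predicted
#'   mass; campaign default 4.5 mg mirrors observed voxel-to-voxel spread).
#' @param protein_mean,protein_sd Protein concentration (ug/uL).
#' @param ndna_mean Named per-class means of relative nuclear DNA content
#'   (cellularity proxy; GM > mixed > WM).
#' @param ndna_cv Coefficient of variation of nuclear DNA within class.
#' @param csf_shape2 Second shape parameter of the Beta(1, shape2) draw of the
#'   non-tissue (CSF) partial-volume fraction; the default leaves roughly 15%
#'   of voxels below the 0.70 GM+WM threshold, as in the annotated campaign.
#' @param affine 4 x 4 grid-to-world affine.
#' @return A `data.frame` of voxel records (class `voxel_table`).
#' @export
generate_slab <- function(config, density = 1, weight_sd = 4.5,
                          protein_mean = 2, protein_sd = 0.2,
                          ndna_mean = c(GM = 1200, mixed = 1000, WM = 800,
                                        unknown = 1000),
                          ndna_cv = 0.12,
                          csf_shape2 = 5,
                          affine = slab_affine(config$voxel_side)) {
  stopifnot(inherits(config, "slab_config"))
  set.seed(derive_seed(config$seed, 101L))
  keep <- which(config$tissue_layout != "edge", arr.ind = TRUE)
  if (nrow(keep) == 0L) stopf("degenerate grid: no tissue cells")
  n <- nrow(keep)
  cls <- config$tissue_layout[keep]
  region <- config$region_layout[keep]
  row0 <- keep[, 1] - 1L
  col0 <- keep[, 2] - 1L
  mass <- expected_voxel_mass(config$voxel_side, density) +
    rnorm(n, 0, weight_sd)
  mass <- pmax(mass, 1)
  protein <- pmax(rnorm(n, protein_mean, protein_sd), 0.05)
  ndna <- pmax(rnorm(n, ndna_mean[cls], ndna_cv * ndna_mean[cls]), 1)

  csf <- rbeta(n, 1, csf_shape2)
  gm_share <- ifelse(cls == "GM", runif(n, 0.85, 0.98),
              ifelse(cls == "WM", runif(n, 0.02, 0.15),
                     runif(n, 0.4, 0.6)))
  gm_prob <- (1 - csf) * gm_share
  wm_prob <- (1 - csf) * (1 - gm_share)

  ijk <- cbind(col0, row0, 0L)
  world <- t(affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]

  out <- data.frame(
    voxel_id = sprintf("V%04d", seq_len(n)),
    row = row0, col = col0,
    weight = mass,
    protein = protein,
    ndna = ndna,
    tissue_class = cls,
    region = region,
    gm_prob = gm_prob,
    wm_prob = wm_prob,
    mni_x = world[, 1], mni_y = world[, 2], mni_z = world[, 3],
    stringsAsFactors = FALSE
  )
  attr(out, "voxel_side") <- config$voxel_side
  attr(out, "affine") <- affine
  class(out) <- c("voxel_table", "data.frame")
  out
}
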