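#' Toy mitochondrial pathway annotation
#'
#' A small stand-in gene-set annotation (10 pathways x 15 genes each,
#' synthetic gene identifiers) with the two-column layout a user-supplied
#' pathway file must have. Real curated pathway content can be loaded with
#' [load_pathway_annotation()].
#'
#' @param n_pathways,genes_per_pathway Annotation size.
#' @return A `data.frame` with columns `pathway`, `gene`.
#' @export
toy_pathway_annotation <- function(n_pathways = 10L, genes_per_pathway = 15L) {
  pathways <- c("OxPhos_CI", "OxPhos_CII", "OxPhos_CIII", "OxPhos_CIV",
                "ATP_synthase", "TCA_cycle", "FA_oxidation", "Mito_dynamics",
                "mtDNA_maintenance", "Protein_import")
  pathways <- pathways[seq_len(min(n_pathways, length(pathways)))]
  if (n_pathways > length(pathways))
    pathways <- c(pathways, sprintf("Pathway_%02d",
                                    seq_len(n_pathways - length(pathways))))
  data.frame(
    pathway = rep(pathways, each = genes_per_pathway),
    gene = paste0(rep(pathways, each = genes_per_pathway), "_g",
                  sprintf("%02d", sequence(rep(genes_per_pathway,
                                               n_pathways)))),
    stringsAsFactors = FALSE
  )
}

#' Load a two-column pathway/gene annotation file
#'
#' @param path Path to a TSV with columns `pathway` and `gene`.
#' @return A `data.frame` with columns `pathway`, `gene`.
#' @export
load_pathway_annotation <- function(path) {
  ann <- read.csv(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("pathway", "gene") %in% names(ann)))
    stopf("annotation file needs columns `pathway` and `gene`")
  ann[, c("pathway", "gene")]
}

#' Default cell-type composition of the four sequenced voxels
#'
#' Nine broad cell types; grey-matter voxels are neuron-enriched and the
#' white-matter voxel oligodendrocyte-enriched.
#' @return A regions x cell-types matrix of proportions (rows sum to 1).
#' @export
default_cell_composition <- function() {
  types <- c("Exc", "Inh", "Ast", "Oli", "OPC", "Mic", "End", "Per", "Epe")
  comp <- rbind(
    MTg  = c(0.40, 0.12, 0.16, 0.12, 0.05, 0.06, 0.04, 0.03, 0.02),
    Hipp = c(0.32, 0.10, 0.20, 0.16, 0.06, 0.07, 0.04, 0.03, 0.02),
    Put  = c(0.14, 0.18, 0.20, 0.24, 0.07, 0.08, 0.04, 0.03, 0.02),
    WM   = c(0.03, 0.02, 0.16, 0.58, 0.09, 0.07, 0.02, 0.02, 0.01)
  )
  colnames(comp) <- types
  comp / rowSums(comp)
}

#' Generate a synthetic genes x nuclei expression matrix
#'
#' Expression on an additive (log-like) scale:
#' `x[g, i] = baseline[g] + region_scale * alpha[g, region(i)] +
#' cell_scale * gamma[g, cell(i)] + noise`, with standard-normal
#' gene-by-region and gene-by-cell-type effect patterns. Because the region
#' effect is constant across every nucleus of a voxel, gene-wise
#' standardization within a voxel removes it exactly — the mechanism behind
#' the region-to-cell-type clustering flip (see [zscore_matrix()]).
#'
#' @param regions Region (voxel) labels; >= 2 required. Defaults to the four
#'   sequenced voxels.
#' @param cell_types Cell-type labels; >= 2 required.
#' @param pathway_annotation Two-column pathway/gene `data.frame`; the genes
#'   of the matrix are the annotation genes.
#' @param n_nuclei Named nuclei counts per region; the defaults reproduce the
#'   recovered campaign counts (MTg 8,945; Hipp 7,044; Put 6,176; WM 10,350).
#' @param composition Regions x cell-types proportion matrix.
#' @param region_scale,cell_scale Effect SDs (region default 3x cell).
#' @param noise_sd Per-nucleus measurement noise SD.
#' @param baseline_mean,baseline_sd Gene baseline distribution.
#' @param seed Integer seed.
#' @return A list of class `expression_sim`: `matrix` (genes x nuclei),
#'   `metadata` (`nucleus_id`, `voxel`, `cell_type`), `annotation`, `effects`
#'   (the drawn region/cell effect matrices), and the scales used.
#' @export
generate_expression <- function(regions = c("MTg", "Hipp", "Put", "WM"),
                                cell_types = colnames(default_cell_composition()),
                                pathway_annotation = toy_pathway_annotation(),
                                n_nuclei = c(MTg = 8945, Hipp = 7044,
                                             Put = 6176, WM = 10350),
                                composition = default_cell_composition(),
                                region_scale = 1.5, cell_scale = 0.5,
                                noise_sd = 0.5,
                                baseline_mean = 8, baseline_sd = 1,
                                seed = 1L) {
  if (length(regions) < 2L) stopf("need >= 2 regions")
  if (length(cell_types) < 2L) stopf("need >= 2 cell types")
  if (is.null(pathway_annotation) || !nrow(pathway_annotation))
    stopf("empty pathway annotation")
  set.seed(derive_seed(seed, 707L))
  genes <- unique(pathway_annotation$gene)
  ng <- length(genes)

  alpha <- matrix(rnorm(ng * length(regions)), ng,
                  dimnames = list(genes, regions))
  gamma <- matrix(rnorm(ng * length(cell_types)), ng,
                  dimnames = list(genes, cell_types))
  baseline <- rnorm(ng, baseline_mean, baseline_sd)

  meta <- do.call(rbind, lapply(regions, function(r) {
    n <- n_nuclei[[r]]
    comp <- composition[r, cell_types]
    comp <- comp / sum(comp)
    data.frame(voxel = r,
               cell_type = sample(cell_types, n, replace = TRUE, prob = comp),
               stringsAsFactors = FALSE)
  }))
  meta$nucleus_id <- sprintf("N%05d", seq_len(nrow(meta)))

  expr <- baseline +
    region_scale * alpha[, meta$voxel] +
    cell_scale * gamma[, meta$cell_type] +
    matrix(rnorm(ng * nrow(meta), 0, noise_sd), ng)
  expr <- pmax(expr, 0)
  dimnames(expr) <- list(genes, meta$nucleus_id)

  structure(list(matrix = expr, metadata = meta,
                 annotation = pathway_annotation,
                 effects = list(region = alpha, cell = gamma,
                                baseline = baseline),
                 region_scale = region_scale, cell_scale = cell_scale,
                 noise_sd = noise_sd),
            class = "expression_sim")
}
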