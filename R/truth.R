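#' Effect-size configuration for the latent mitochondrial features
#'
#' Latent activities are normal within tissue class on the latent scale; the
#' raw observables are powers of the latents (squares for the surface-like
#' OxPhos activities CI/CII/CIV, cubes for the volume-like content markers CS
#' and mtDNA), so square-/cube-root transforms exactly normalize them.
#' GM means sit `g` pooled SDs above WM means; mixed voxels are halfway,
#' `unknown` voxels follow the mixed distribution.
#'
#' @param g Named GM-vs-WM standardized mean differences (Hedges' g on the
#'   latent scale) for `cs`, `mtdna`, `ci`, `cii`, `civ`. Defaults span the
#'   1.8-2.6 range observed for annotated voxels.
#' @param wm_mean,sd Named WM-class latent means and common within-class SDs.
#'   mtDNA latents are large so qPCR Ct values land in the 18-26 range.
#' @param batch_sdlog SD (log scale) of the multiplicative log-normal plate
#'   factors applied to every well of an assay plate (default 0.2).
#' @param nonspecific_frac Nonspecific (background) colorimetric activity as
#'   a fraction of the cohort-mean specific activity of each assay.
#' @return A list of class `effect_config`.
#' @export
effect_config <- function(g = c(cs = 2.2, mtdna = 1.8, ci = 2.6, cii = 2.4,
                                civ = 2.0),
                          wm_mean = c(cs = 4, mtdna = 80, ci = 5, cii = 5,
                                      civ = 6),
                          sd = c(cs = 0.6, mtdna = 12, ci = 0.7, cii = 0.7,
                                 civ = 0.8),
                          batch_sdlog = 0.2,
                          nonspecific_frac = 0.1) {
  for (f in MITO_FEATURES) {
    if (!f %in% names(g) || !f %in% names(wm_mean) || !f %in% names(sd))
      stopf("effect_config: missing parameters for feature '%s'", f)
    if (sd[[f]] <= 0) stopf("effect_config: SD for '%s' must be positive", f)
  }
  if (batch_sdlog < 0) stopf("batch_sdlog must be >= 0")
  structure(list(g = g[MITO_FEATURES], wm_mean = wm_mean[MITO_FEATURES],
                 sd = sd[MITO_FEATURES], batch_sdlog = batch_sdlog,
                 nonspecific_frac = nonspecific_frac),
            class = "effect_config")
}

latent_class_means <- function(cfg, feature) {
  wm <- cfg$wm_mean[[feature]]
  gm <- wm + cfg$g[[feature]] * cfg$sd[[feature]]
  c(GM = gm, WM = wm, mixed = (gm + wm) / 2, unknown = (gm + wm) / 2)
}

#' Generate per-voxel ground truth
#'
#' Draws latent mitochondrial features per voxel from class-conditional
#' normals and forms the raw observables as powers of the latents (`L^2` for
#' CI/CII/CIV, `L^3` for CS/mtDNA). Also derives the pooled loading-control
#' truth (mean latent of 30 synthetic voxels per tissue class, mirroring the
#' pooled occipital-lobe reference samples) used to seed control wells.
#'
#' @param voxels A voxel table from [generate_slab()].
#' @param config An [effect_config()].
#' @param seed Integer seed.
#' @param coupling `"independent"` draws each feature's latent independently;
#'   `"proportional"` draws a single per-voxel latent and scales it by each
#'   feature's class mean ratio, so every mitochondrion has identical OxPhos
#'   capacity and MRC is constant across voxels (the MRC null).
#' @return A list of class `synthetic_truth` with elements `latent` and `raw`
#'   (data frames keyed by `voxel_id`), `controls` (per-class pooled raw and
#'   latent values), `config`, `coupling` and `seed`.
#' @export
generate_truth <- function(voxels, config = effect_config(), seed = 1L,
                           coupling = c("independent", "proportional")) {
  coupling <- match.arg(coupling)
  stopifnot(is.data.frame(voxels), "tissue_class" %in% names(voxels))
  set.seed(derive_seed(seed, 202L))
  n <- nrow(voxels)
  cls <- voxels$tissue_class
  latent <- data.frame(voxel_id = voxels$voxel_id, stringsAsFactors = FALSE)

  if (coupling == "independent") {
    for (f in MITO_FEATURES) {
      mu <- latent_class_means(config, f)[cls]
      latent[[f]] <- truncated_normal(n, mu, config$sd[[f]])
    }
  } else {
    # One shared per-voxel latent scaled per feature: raw transforms recover
    # proportional profiles, hence constant TRC/MitoD ratio.
    base_mu <- latent_class_means(config, "cs")[cls]
    shared <- truncated_normal(n, base_mu, config$sd[["cs"]])
    rel <- shared / config$wm_mean[["cs"]]
    for (f in MITO_FEATURES) latent[[f]] <- config$wm_mean[[f]] * rel
  }

  raw <- latent
  for (f in SURFACE_FEATURES) raw[[f]] <- latent[[f]]^2
  for (f in VOLUME_FEATURES) raw[[f]] <- latent[[f]]^3

  controls <- control_truth(config, seed)

  structure(list(latent = latent, raw = raw, controls = controls,
                 config = config, coupling = coupling,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

# Latents must stay positive for the power observables to be invertible by
# root transforms; the class means sit >= 4 SDs above zero so truncation is
# a rare-event guard, not a distributional feature.
truncated_normal <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  bad <- x <= 0
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean[bad], sd)
    bad <- x <= 0
  }
  x
}

# Pooled loading controls: mean latent of 30 synthetic voxels per class.
control_truth <- function(config, seed, n_pool = 30L) {
  set.seed(derive_seed(seed, 303L))
  classes <- c("GM", "WM", "mixed")
  latent <- sapply(MITO_FEATURES, function(f) {
    mu <- latent_class_means(config, f)[classes]
    vapply(mu, function(m) mean(truncated_normal(n_pool, rep(m, n_pool),
                                                 config$sd[[f]])), 0)
  })
  rownames(latent) <- classes
  raw <- latent
  raw[, SURFACE_FEATURES] <- latent[, SURFACE_FEATURES]^2
  raw[, VOLUME_FEATURES] <- latent[, VOLUME_FEATURES]^3
  # Control aliquots carry nominal protein and nDNA close to cohort centres.
  list(latent = latent, raw = raw,
       protein = c(GM = 2, WM = 2, mixed = 2),
       ndna = c(GM = 1200, WM = 800, mixed = 1000))
}
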