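#' Volumetric power transform
#'
#' Raw mitochondrial metrics arise as powers of approximately normal latent
#' sizes: surface-area-like activities (CI, CII, CIV) scale as the square of
#' the latent and are normalized by a square root; volume-like content
#' markers (CS, mtDNA) scale as the cube and are normalized by a cube root.
#'
#' @param values Non-negative numeric vector.
#' @param kind `"surface"` (square root) or `"volume"` (cube root).
#' @return Transformed values.
#' @export
volumetric_transform <- function(values, kind = c("surface", "volume")) {
  kind <- match.arg(kind)
  if (any(values < 0, na.rm = TRUE)) stopf("negative values cannot be transformed")
  if (kind == "surface") sqrt(values) else values^(1 / 3)
}

#' Distribution diagnostics: CV, skewness, and K-S distance to normality
#'
#' @param values Numeric vector, n >= 8.
#' @return A list: `cv` (sd/mean), `skewness` (moment-ratio sample
#'   skewness), `ks_distance` (Kolmogorov-Smirnov statistic against a normal
#'   with the sample's mean and SD), `degenerate` (TRUE for constant input,
#'   where skewness and K-S are undefined and returned as `NA`).
#' @export
distribution_diagnostics <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 8L) stopf("need n >= 8 finite values")
  m <- mean(values)
  if (m == 0) stopf("zero mean: CV undefined")
  s <- sd(values)
  if (s == 0) {
    return(list(cv = 0, skewness = NA_real_, ks_distance = NA_real_,
                degenerate = TRUE))
  }
  ks <- suppressWarnings(ks.test(values, "pnorm", mean = m, sd = s))
  list(cv = s / m, skewness = sample_skewness(values),
       ks_distance = unname(ks$statistic), degenerate = FALSE)
}

#' Scale values to a cohort mean of one
#'
#' @param values Numeric vector with positive mean (NAs ignored for the mean
#'   and preserved in the output).
#' @return `values / mean(values)`; the output mean is exactly 1.
#' @export
mean_normalize <- function(values) {
  m <- mean(values, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) stopf("cohort mean must be positive")
  values / m
}

#' Integrate colorimetric and respirometric estimates of one complex
#'
#' Arithmetic mean of the available mean-normalized transformed estimates.
#' Colorimetric CI is excluded by default (its colorimetric readings are not
#' used for respiratory-capacity integration); the respirometric value then
#' passes through.
#'
#' @param colorimetric,respirometric Mean-normalized transformed values
#'   (vectors; `NA` = missing).
#' @param use_colorimetric Include the colorimetric estimate.
#' @return Per-voxel combined values (`NA` where neither assay is available).
#' @export
integrate_complex <- function(colorimetric, respirometric,
                              use_colorimetric = TRUE) {
  if (!use_colorimetric) colorimetric <- rep(NA_real_, length(respirometric))
  rowMeans(cbind(colorimetric, respirometric), na.rm = TRUE) |>
    (\(x) ifelse(is.nan(x), NA_real_, x))()
}

#' Mitochondrial tissue density (MitoD)
#'
#' Mean of the mean-normalized cube-root CS activity and mtDNA density.
#'
#' @param cs_norm,mtdna_norm Mean-normalized cube-root values.
#' @return MitoD per voxel (`NA` when both are missing).
#' @export
compute_mito_d <- function(cs_norm, mtdna_norm) {
  integrate_complex(cs_norm, mtdna_norm)
}

#' Tissue respiratory capacity (TRC)
#'
#' Mean of the integrated, mean-normalized square-root CI, CII and CIV
#' activities: OxPhos capacity per tissue unit.
#'
#' @param ci,cii,civ Integrated complex values.
#' @return TRC per voxel.
#' @export
compute_trc <- function(ci, cii, civ) {
  out <- rowMeans(cbind(ci, cii, civ), na.rm = TRUE)
  ifelse(is.nan(out), NA_real_, out)
}

#' Mitochondrial respiratory capacity (MRC)
#'
#' OxPhos capacity per mitochondrion: `MRC = TRC / MitoD`. Undefined
#' (missing) where MitoD is not positive. If every mitochondrion had the
#' same OxPhos capacity, MRC would be constant across the brain; variation
#' in MRC indicates tissue-specific mitochondrial specialization.
#'
#' @param trc,mito_d Per-voxel TRC and MitoD.
#' @return MRC per voxel.
#' @export
compute_mrc <- function(trc, mito_d) {
  ifelse(is.na(mito_d) | mito_d <= 0, NA_real_, trc / mito_d)
}

#' Hedges' g standardized mean difference
#'
#' `(mean(a) - mean(b)) / s_pooled`, multiplied by the small-sample
#' correction `J = 1 - 3 / (4 (nA + nB) - 9)`.
#'
#' @param group_a,group_b Numeric vectors, each n >= 2.
#' @return Hedges' g (positive when `group_a` has the larger mean).
#' @export
hedges_g <- function(group_a, group_b) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stopf("each group needs n >= 2")
  sp2 <- ((na - 1) * var(group_a) + (nb - 1) * var(group_b)) / (na + nb - 2)
  if (sp2 <= 0) stopf("zero pooled SD")
  j <- 1 - 3 / (4 * (na + nb) - 9)
  (mean(group_a) - mean(group_b)) / sqrt(sp2) * j
}

#' Two-component Gaussian deconvolution
#'
#' Maximum-likelihood fit of a two-component normal mixture (unequal
#' variances, via finite-mixture EM), used to separate the GM- and WM-like
#' modes of a transformed mitochondrial feature. Components are sorted by
#' mean.
#'
#' @param values Numeric vector, n >= 20.
#' @return A list: `means`, `sds`, `weights` (component-sorted), and
#'   `converged`.
#' @export
mixture_deconvolution <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 20L) stopf("need n >= 20 values")
  fit <- tryCatch(
    Mclust(values, G = 2, modelNames = c("V", "E"), verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(means = c(NA_real_, NA_real_), sds = c(NA_real_, NA_real_),
                weights = c(NA_real_, NA_real_), converged = FALSE))
  }
  means <- fit$parameters$mean
  sds <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sds) == 1L) sds <- rep(sds, 2L)
  ord <- order(means)
  list(means = unname(means[ord]), sds = unname(sds[ord]),
       weights = unname(fit$parameters$pro[ord]), converged = TRUE)
}

#' Assemble the per-voxel mitochondrial feature table
#'
#' Merges the assay-level results into one row per voxel, applies the
#' volumetric transforms, mean-normalizes every transformed column,
#' integrates the colorimetric and respirometric complex estimates
#' (colorimetric CI excluded by default), and derives MitoD, TRC and MRC.
#' The completeness flag requires all five base features (CS, mtDNA and the
#' three complexes, each from at least one assay route).
#'
#' @param colorimetry Output of [process_colorimetry()] (or `NULL`).
#' @param respirometry Output of [process_respirometry()] (or `NULL`).
#' @param qpcr Output of [process_qpcr()] (or `NULL`).
#' @param voxel_ids Optional id vector fixing row order.
#' @param use_colorimetric_ci Include colorimetric CI in the integrated CI.
#' @return A `data.frame` (class `mito_feature_table`): raw columns
#'   (`cs_raw`, `mtdna_raw`, `ci_col_raw`, `ci_resp_raw`, ...), transformed
#'   and mean-normalized columns (`cs_t`, ..., `*_n`), integrated `ci`,
#'   `cii`, `civ`, derived `mito_d`, `trc`, `mrc`, and `complete`.
#' @export
build_feature_table <- function(colorimetry = NULL, respirometry = NULL,
                                qpcr = NULL, voxel_ids = NULL,
                                use_colorimetric_ci = FALSE) {
  ids <- voxel_ids %||% unique(c(colorimetry$voxel_id,
                                 respirometry$voxel_id, qpcr$voxel_id))
  ft <- data.frame(voxel_id = ids, stringsAsFactors = FALSE)
  pick_col <- function(assay) {
    if (is.null(colorimetry)) return(rep(NA_real_, length(ids)))
    sub <- colorimetry[colorimetry$assay == assay, ]
    sub$activity[match(ids, sub$voxel_id)]
  }
  pick_resp <- function(col) {
    if (is.null(respirometry)) return(rep(NA_real_, length(ids)))
    respirometry[[col]][match(ids, respirometry$voxel_id)]
  }
  ft$cs_raw <- pick_col("CS")
  ft$ci_col_raw <- pick_col("CI")
  ft$cii_col_raw <- pick_col("CII")
  ft$civ_col_raw <- pick_col("CIV")
  ft$ci_resp_raw <- pick_resp("ci")
  ft$cii_resp_raw <- pick_resp("cii")
  ft$civ_resp_raw <- pick_resp("civ")
  ft$mtdna_raw <- if (is.null(qpcr)) rep(NA_real_, length(ids)) else
    qpcr$mtdna_density[match(ids, qpcr$voxel_id)]

  surf <- c("ci_col", "cii_col", "civ_col", "ci_resp", "cii_resp", "civ_resp")
  for (s in surf)
    ft[[paste0(s, "_t")]] <- volumetric_transform(ft[[paste0(s, "_raw")]],
                                                  "surface")
  for (v in c("cs", "mtdna"))
    ft[[paste0(v, "_t")]] <- volumetric_transform(ft[[paste0(v, "_raw")]],
                                                  "volume")
  for (col in c(surf, "cs", "mtdna"))
    ft[[paste0(col, "_n")]] <- mean_normalize(ft[[paste0(col, "_t")]])

  ft$ci <- integrate_complex(ft$ci_col_n, ft$ci_resp_n, use_colorimetric_ci)
  ft$cii <- integrate_complex(ft$cii_col_n, ft$cii_resp_n, TRUE)
  ft$civ <- integrate_complex(ft$civ_col_n, ft$civ_resp_n, TRUE)
  ft$mito_d <- compute_mito_d(ft$cs_n, ft$mtdna_n)
  ft$trc <- compute_trc(ft$ci, ft$cii, ft$civ)
  ft$mrc <- compute_mrc(ft$trc, ft$mito_d)
  ft$complete <- !is.na(ft$cs_raw) & !is.na(ft$mtdna_raw) &
    !is.na(ft$ci) & !is.na(ft$cii) & !is.na(ft$civ)
  class(ft) <- c("mito_feature_table", "data.frame")
  ft
}

#' Feature table straight from generator truth
#'
#' Bypasses the simulated assays: treats the raw truth observables as
#' perfectly measured and derives the transformed, normalized and integrated
#' features. Used for forward-model identities (e.g. the constant-MRC null).
#'
#' @param truth A `synthetic_truth`.
#' @return A `mito_feature_table`.
#' @export
features_from_truth <- function(truth) {
  raw <- truth$raw
  assay_map <- c(CS = "cs", CI = "ci", CII = "cii", CIV = "civ")
  col_tab <- do.call(rbind, lapply(names(assay_map), function(a) {
    data.frame(voxel_id = raw$voxel_id, assay = a,
               activity = raw[[assay_map[[a]]]],
               qc = "ok", stringsAsFactors = FALSE)
  }))
  resp_tab <- data.frame(voxel_id = raw$voxel_id, ci = raw$ci, cii = raw$cii,
                         civ = raw$civ, stringsAsFactors = FALSE)
  qpcr_tab <- data.frame(voxel_id = raw$voxel_id, mtdna_density = raw$mtdna,
                         stringsAsFactors = FALSE)
  build_feature_table(col_tab, resp_tab, qpcr_tab,
                      voxel_ids = raw$voxel_id)
}
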