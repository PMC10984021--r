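#' Names of the 22 neuroimaging metrics
#'
#' Structural, diffusion and functional metrics used as predictors of the
#' mitochondrial features (axial/radial/mean diffusivity, FA, NODDI ICVF and
#' isotropic fraction, orientation dispersion, streamline density, T1-/T2-
#' weighted intensities and ratio, FLAIR, cortical thickness, cross-sectional
#' areas, GM/WM probabilities, and resting-state measures).
#'
#' @return Character vector of length 22.
#' @export
mri_metric_names <- function() {
  c("AD", "FA", "RD", "StreDensity", "ICVF", "ISOCF", "MD", "OD",
    "T1W", "T2W", "T1w_T2w", "FLAIR", "CT", "inner_CSA", "plial_CSA",
    "GM", "WM", "Max_activity", "Reho", "Entropy", "ALFF", "fALFF")
}

#' Generate synthetic MRI metrics coupled to the mitochondrial truth
#'
#' Each metric is a linear combination of the five standardized latent
#' mitochondrial features plus Gaussian noise:
#' `X = F C + E`, `E ~ N(0, sigma^2)`. The common noise SD `sigma` is
#' calibrated analytically so that the population R-squared of the best
#' linear predictor of a latent feature from all 22 metrics, averaged over
#' the five features, equals `target_r2`:
#' `R^2_f = c_f' (C' S C + sigma^2 I)^{-1} c_f` with `S` the empirical
#' feature covariance and `c_f = C' S e_f`, solved for `sigma` by
#' root-finding (the noise-for-a-target-R2 relation
#' `sigma^2 = Var(signal) (1 - R^2) / R^2` in the single-predictor case).
#'
#' @param truth A `synthetic_truth` from [generate_truth()].
#' @param target_r2 Target out-of-sample predictability in (0, 1).
#' @param coefficients Optional 5 x 22 coefficient matrix (rows =
#'   `cs, mtdna, ci, cii, civ`); drawn N(0, 1) when `NULL`. An all-zero
#'   matrix yields pure-noise metrics (sigma = 1) for null experiments.
#' @param seed Integer seed.
#' @return A list of class `mri_sim`: `metrics` (`voxel_id` + 22 columns),
#'   `coefficients`, `sigma`, `target_r2`, `features` (the standardized
#'   latent features used).
#' @export
generate_mri <- function(truth, target_r2 = 0.3, coefficients = NULL,
                         seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (target_r2 <= 0 || target_r2 >= 1) stopf("target_r2 must be in (0, 1)")
  set.seed(derive_seed(seed, 606L))
  F_mat <- scale(as.matrix(truth$latent[MITO_FEATURES]))
  n <- nrow(F_mat)
  if (is.null(coefficients)) {
    coefficients <- matrix(rnorm(5L * 22L), 5L, 22L,
                           dimnames = list(MITO_FEATURES, mri_metric_names()))
  }
  stopifnot(all(dim(coefficients) == c(5L, 22L)))

  sigma <- if (all(coefficients == 0)) 1 else
    calibrate_mri_noise(coefficients, stats::cov(F_mat), target_r2)

  X <- F_mat %*% coefficients +
    matrix(rnorm(n * 22L, 0, sigma), n, 22L)
  metrics <- data.frame(voxel_id = truth$latent$voxel_id, X,
                        stringsAsFactors = FALSE)
  names(metrics) <- c("voxel_id", mri_metric_names())
  structure(list(metrics = metrics, coefficients = coefficients,
                 sigma = sigma, target_r2 = target_r2,
                 features = F_mat),
            class = "mri_sim")
}

# Mean over the five latent features of the population R^2 of the best
# linear predictor from the 22 metrics, as a function of the noise SD.
mri_population_r2 <- function(C, S, sigma) {
  Sx <- t(C) %*% S %*% C + sigma^2 * diag(ncol(C))
  Cx <- t(C) %*% S  # 22 x 5, Cov(X, F)
  sol <- solve(Sx, Cx)
  r2 <- colSums(Cx * sol) / diag(S)
  mean(r2)
}

calibrate_mri_noise <- function(C, S, target_r2) {
  f <- function(log_sigma) mri_population_r2(C, S, exp(log_sigma)) - target_r2
  uniroot(f, lower = log(1e-6), upper = log(1e6), tol = 1e-10)$root |> exp()
}
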