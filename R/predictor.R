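#' Seeded train/test split
#'
#' @param ids Vector of ids (n >= 2).
#' @param train_fraction Fraction in (0, 1); train size is
#'   `floor(train_fraction * n)` (539 voxels at 0.8 give 431 / 108).
#' @param seed Integer seed.
#' @return A list with disjoint, exhaustive `train` and `test` id vectors.
#' @export
split_train_test <- function(ids, train_fraction = 0.8, seed = 1L) {
  n <- length(ids)
  if (n < 2L) stopf("need n >= 2 ids")
  if (train_fraction <= 0 || train_fraction >= 1)
    stopf("train_fraction must be in (0, 1)")
  set.seed(derive_seed(seed, 111L))
  shuffled <- sample(ids)
  n_train <- floor(train_fraction * n)
  list(train = shuffled[seq_len(n_train)],
       test = shuffled[(n_train + 1L):n])
}

# least-squares helpers on a design matrix with intercept --------------------

ls_fit <- function(Xi, y) {
  q <- qr(Xi)
  if (q$rank < ncol(Xi)) stopf("rank-deficient predictor matrix")
  coef <- qr.coef(q, y)
  rss <- sum((y - Xi %*% coef)^2)
  list(coef = coef, rss = rss, df = length(y) - ncol(Xi), qr = q)
}

ls_pvalues <- function(fit) {
  xtx_inv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(pmax(diag(xtx_inv), 0) * fit$rss / fit$df)
  t_stat <- fit$coef / se
  2 * pt(abs(t_stat), fit$df, lower.tail = FALSE)
}

#' Stepwise backward elimination of neuroimaging predictors
#'
#' Predictors and response are standardized internally, so coefficients are
#' reported on the standardized (beta) scale. At each step the least
#' significant remaining predictor (largest partial-t p-value) is the
#' removal candidate; the candidate reduced model is compared by an F-change
#' test against a baseline and the candidate is removed while that
#' comparison is non-significant at `alpha`. With the default
#' `baseline = "full"` the comparison is a running joint test of everything
#' removed so far against the initial full model, which keeps the
#' family-wise rate of retaining pure-noise predictors near `alpha`;
#' `baseline = "single"` compares only the two consecutive models (the
#' candidate's partial F), the textbook single-term variant.
#'
#' @param X Predictor matrix or data frame (n x p, named columns).
#' @param y Response vector.
#' @param alpha Significance level of the F-change test (default 0.05).
#' @param baseline `"full"` (default) or `"single"`.
#' @return An object of class `stepwise_model`: `predictors` (retained
#'   names), `beta` (standardized coefficients), `intercept` (standardized
#'   scale, ~0), `trace` (`data.frame` of eliminated predictors in order,
#'   with the removal-candidate p and the F-change p at removal), `alpha`,
#'   `r_squared` (training), scaling attributes for prediction on raw data,
#'   and `intercept_only`.
#' @export
stepwise_backward <- function(X, y, alpha = 0.05,
                              baseline = c("full", "single")) {
  baseline <- match.arg(baseline)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep_rows <- complete.cases(X) & is.finite(y)
  X <- X[keep_rows, , drop = FALSE]
  y <- y[keep_rows]
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 2L) stopf("need n > p + 2 observations")

  x_center <- colMeans(X); x_scale <- apply(X, 2, sd)
  if (any(x_scale == 0)) stopf("constant predictor column(s)")
  y_center <- mean(y); y_scale <- sd(y)
  if (y_scale == 0) stopf("constant response")
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  ys <- (y - y_center) / y_scale

  full <- ls_fit(cbind(1, Xs), ys)
  keep <- colnames(Xs)
  trace <- data.frame(predictor = character(0), p_candidate = numeric(0),
                      p_fchange = numeric(0))
  repeat {
    if (!length(keep)) break
    cur <- ls_fit(cbind(1, Xs[, keep, drop = FALSE]), ys)
    pv <- ls_pvalues(cur)[-1]
    worst <- keep[which.max(pv)]
    cand <- setdiff(keep, worst)
    red <- if (length(cand)) ls_fit(cbind(1, Xs[, cand, drop = FALSE]), ys)
      else list(rss = sum((ys - mean(ys))^2), df = n - 1L)
    base_fit <- if (baseline == "full") full else cur
    ddf <- red$df - base_fit$df
    f_stat <- ((red$rss - base_fit$rss) / ddf) / (base_fit$rss / base_fit$df)
    p_f <- pf(f_stat, ddf, base_fit$df, lower.tail = FALSE)
    if (!is.na(p_f) && p_f < alpha) break
    trace <- rbind(trace, data.frame(predictor = worst,
                                     p_candidate = max(pv),
                                     p_fchange = p_f))
    keep <- cand
  }

  if (length(keep)) {
    final <- ls_fit(cbind(1, Xs[, keep, drop = FALSE]), ys)
    beta <- final$coef[-1]
    names(beta) <- keep
    intercept <- final$coef[1]
    r2 <- 1 - final$rss / sum((ys - mean(ys))^2)
  } else {
    beta <- numeric(0); intercept <- 0; r2 <- 0
  }
  structure(list(predictors = keep, beta = beta, intercept = intercept,
                 trace = trace, alpha = alpha, baseline = baseline,
                 r_squared = r2, intercept_only = !length(keep),
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, y_scale = y_scale),
            class = "stepwise_model")
}

#' Predict from a stepwise model
#'
#' @param object A `stepwise_model`.
#' @param newdata Matrix or data frame containing the retained predictor
#'   columns on the raw scale.
#' @param ... Unused.
#' @return Predicted response on the raw scale.
#' @export
predict.stepwise_model <- function(object, newdata, ...) {
  newdata <- as.matrix(as.data.frame(newdata))
  miss <- setdiff(object$predictors, colnames(newdata))
  if (length(miss)) stopf("missing predictors: %s", paste(miss, collapse = ", "))
  ys <- rep(object$intercept, nrow(newdata))
  for (p in object$predictors) {
    xs <- (newdata[, p] - object$x_center[[p]]) / object$x_scale[[p]]
    ys <- ys + object$beta[[p]] * xs
  }
  unname(ys * object$y_scale + object$y_center)
}

#' Squared Pearson correlation of observed and predicted values
#'
#' The prediction-accuracy convention of the observed-vs-predicted
#' scatterplots: r^2 of the correlation, not regression R^2 (a
#' `regression = TRUE` switch gives 1 - SSE/SST instead).
#'
#' @param observed,predicted Numeric vectors.
#' @param regression Use the regression R^2 convention.
#' @return r^2 in \[0, 1\] (regression R^2 may be negative).
#' @export
evaluate_r2 <- function(observed, predicted, regression = FALSE) {
  keep <- is.finite(observed) & is.finite(predicted)
  observed <- observed[keep]; predicted <- predicted[keep]
  if (sd(observed) == 0) stopf("constant observed vector")
  if (regression) {
    return(1 - sum((observed - predicted)^2) /
             sum((observed - mean(observed))^2))
  }
  if (sd(predicted) == 0) return(0)
  cor(observed, predicted)^2
}

#' Scrambled-pairing null distribution of prediction accuracy
#'
#' Permutes the observed-predicted pairing to estimate the accuracy expected
#' with no voxel-level correspondence. Under independence the expected r^2
#' is approximately `1 / (n - 1)`.
#'
#' @param observed,predicted Numeric vectors (n >= 10).
#' @param n_permutations Number of permutations.
#' @param seed Integer seed.
#' @return A list: `null_r2` (vector), `mean_null_r2`, `real_r2`,
#'   `p_value` (fraction of null >= real, with +1 smoothing).
#' @export
scrambled_null <- function(observed, predicted, n_permutations = 1000L,
                           seed = 1L) {
  if (length(observed) < 10L) stopf("need n >= 10")
  set.seed(derive_seed(seed, 222L))
  real <- evaluate_r2(observed, predicted)
  null_r2 <- vapply(seq_len(n_permutations), function(i)
    evaluate_r2(sample(observed), predicted), 0)
  list(null_r2 = null_r2, mean_null_r2 = mean(null_r2), real_r2 = real,
       p_value = (sum(null_r2 >= real) + 1) / (n_permutations + 1))
}

#' Apply stepwise models to whole-brain metric volumes
#'
#' Evaluates each fitted model at every lattice cell of the supplied metric
#' volumes; cells where any retained metric is missing (background/NA) stay
#' at the background value.
#'
#' @param models Named list of `stepwise_model`s (one per mitochondrial
#'   feature).
#' @param mri_volumes Named list of `brain_volume`s, one per metric; all
#'   shapes and affines must agree.
#' @param mask Optional logical array marking cells to predict; defaults to
#'   cells where all retained metrics differ from their volume's background.
#' @return Named list of `brain_volume`s with predicted features.
#' @export
whole_volume_predict <- function(models, mri_volumes, mask = NULL) {
  shapes <- lapply(mri_volumes, function(v) dim(v$data))
  if (length(unique(vapply(shapes, paste, "", collapse = "x"))) != 1L)
    stopf("metric volume shapes differ")
  affs <- vapply(mri_volumes, function(v) paste(signif(v$affine, 10),
                                                collapse = ","), "")
  if (length(unique(affs)) != 1L) stopf("metric volume affines differ")
  shape <- shapes[[1]]
  lapply(models, function(model) {
    needed <- model$predictors
    miss <- setdiff(needed, names(mri_volumes))
    if (length(miss)) stopf("no volume for metric(s): %s",
                            paste(miss, collapse = ", "))
    use <- if (is.null(mask)) {
      ok <- array(TRUE, dim = shape)
      for (p in needed) {
        v <- mri_volumes[[p]]
        ok <- ok & is.finite(v$data) & (v$data != v$background)
      }
      ok
    } else mask
    if (!length(needed)) {
      pred_vals <- rep(model$y_center + model$intercept * model$y_scale,
                       sum(use))
    } else {
      X <- vapply(needed, function(p) mri_volumes[[p]]$data[use],
                  numeric(sum(use)))
      X <- matrix(X, ncol = length(needed),
                  dimnames = list(NULL, needed))
      pred_vals <- predict(model, X)
    }
    bg <- mri_volumes[[1]]$background
    out <- array(bg, dim = shape)
    out[use] <- pred_vals
    structure(list(data = out, affine = mri_volumes[[1]]$affine,
                   background = bg), class = "brain_volume")
  })
}

#' Consistency of directly predicted and recomputed derived metrics
#'
#' TRC and MRC can either be predicted directly from the MRI metrics or
#' recomputed from the predicted CI, CII, CIV and MitoD; their agreement is
#' a consistency check of the model family.
#'
#' @param predicted A `data.frame` with columns `ci`, `cii`, `civ`,
#'   `mito_d`, `trc`, `mrc` of predicted values.
#' @return A list: `trc_r`, `mrc_r` (Pearson correlations between direct and
#'   recomputed values).
#' @export
derived_consistency <- function(predicted) {
  need <- c("ci", "cii", "civ", "mito_d", "trc", "mrc")
  miss <- setdiff(need, names(predicted))
  if (length(miss)) stopf("missing component predictions: %s",
                          paste(miss, collapse = ", "))
  trc_re <- compute_trc(predicted$ci, predicted$cii, predicted$civ)
  mrc_re <- compute_mrc(trc_re, predicted$mito_d)
  keep <- complete.cases(cbind(predicted$trc, trc_re, predicted$mrc, mrc_re))
  list(trc_r = cor(predicted$trc[keep], trc_re[keep]),
       mrc_r = cor(predicted$mrc[keep], mrc_re[keep]))
}
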