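sim_design <- function(n, p, beta = NULL, noise_sd = 1, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  y <- if (is.null(beta)) rnorm(n, 0, noise_sd)
  else drop(X %*% beta) + rnorm(n, 0, noise_sd)
  list(X = X, y = y)
}

test_that("train/test split is a seeded partition with floor sizing", {
  s <- split_train_test(1:539, 0.8, seed = 1)
  expect_length(s$train, 431)
  expect_length(s$test, 108)

  s2 <- split_train_test(1:10, 0.8, seed = 2)
  expect_length(s2$train, 8)
  expect_length(s2$test, 2)

  set.seed(3)
  for (i in 1:20) {
    n <- sample(5:200, 1)
    s <- split_train_test(seq_len(n), runif(1, 0.3, 0.9), seed = i)
    expect_length(intersect(s$train, s$test), 0)
    expect_setequal(c(s$train, s$test), seq_len(n))
  }
  expect_identical(split_train_test(1:50, seed = 9),
                   split_train_test(1:50, seed = 9))
  expect_error(split_train_test(1, 0.5), "n >= 2")
})

test_that("single significant predictor reduces to ordinary least squares", {
  d <- sim_design(100, 1, beta = 2, noise_sd = 0.5, seed = 4)
  m <- stepwise_backward(d$X, d$y)
  expect_equal(m$predictors, "x1")
  ols <- lm(scale(d$y) ~ scale(d$X))
  expect_equal(unname(m$beta), unname(coef(ols)[2]), tolerance = 1e-8)
  expect_equal(predict(m, d$X), unname(fitted(lm(d$y ~ d$X))),
               tolerance = 1e-8)
})

test_that("single-term elimination path matches an lm/drop1 oracle", {
  d <- sim_design(120, 8, beta = c(0.8, 0.5, rep(0, 6)), seed = 5)
  m <- stepwise_backward(d$X, d$y, baseline = "single")

  # independent route: iterative lm on standardized data
  Xs <- scale(d$X); ys <- as.numeric(scale(d$y))
  keep <- colnames(Xs)
  repeat {
    fit <- lm(ys ~ Xs[, keep, drop = FALSE] - 1 + 1)
    pv <- summary(fit)$coefficients[-1, 4]
    names(pv) <- keep
    if (max(pv) < 0.05) break
    keep <- setdiff(keep, names(which.max(pv)))
    if (!length(keep)) break
  }
  expect_setequal(m$predictors, keep)
  fit <- lm(ys ~ Xs[, keep, drop = FALSE] - 1 + 1)
  expect_equal(unname(m$beta[keep]), unname(coef(fit)[-1]),
               tolerance = 1e-8)
})

test_that("backward elimination recovers known support and controls noise", {
  hits <- 0; nulls <- 0
  for (i in 1:10) {
    d <- sim_design(300, 10, beta = c(rep(0.5, 3), rep(0, 7)),
                    noise_sd = sqrt(1 - 3 * 0.25), seed = 100 + i)
    m <- stepwise_backward(d$X, d$y)
    if (setequal(m$predictors, c("x1", "x2", "x3"))) hits <- hits + 1
    d0 <- sim_design(300, 10, seed = 200 + i)
    m0 <- stepwise_backward(d0$X, d0$y)
    if (m0$intercept_only) nulls <- nulls + 1
  }
  expect_gte(hits, 8)
  expect_gte(nulls, 8)

  # elimination trace covers the removed set
  d <- sim_design(150, 6, beta = c(1, rep(0, 5)), seed = 6)
  m <- stepwise_backward(d$X, d$y)
  expect_setequal(c(m$predictors, m$trace$predictor), colnames(d$X))
  expect_error(stepwise_backward(d$X[1:5, ], d$y[1:5]), "n > p")
})

test_that("prediction accuracy is the squared observed-predicted correlation", {
  set.seed(7)
  y <- rnorm(50); yhat <- 2 * y + 3
  expect_equal(evaluate_r2(y, yhat), 1)
  orth <- rnorm(50)
  expect_lt(evaluate_r2(y, orth), 0.2)
  a <- rnorm(30); b <- a + rnorm(30)
  expect_equal(evaluate_r2(a, b), cor(a, b)^2)
  expect_equal(evaluate_r2(a, b, regression = TRUE),
               1 - sum((a - b)^2) / sum((a - mean(a))^2))
  expect_error(evaluate_r2(rep(1, 10), rnorm(10)), "constant")
})

test_that("scrambled-pairing null behaves like independent data", {
  set.seed(8)
  y <- rnorm(108); yhat <- y + rnorm(108, 0, 0.5)
  out <- scrambled_null(y, yhat, n_permutations = 1000, seed = 1)
  expect_lte(out$p_value, 2 / 1001)
  expect_lt(out$mean_null_r2, 3 / 107)
  expect_gt(out$mean_null_r2, 1 / (3 * 107))
  out2 <- scrambled_null(y, yhat, n_permutations = 1000, seed = 1)
  expect_identical(out$null_r2, out2$null_r2)
})

test_that("whole-volume prediction matches the per-voxel oracle", {
  d <- sim_design(200, 3, beta = c(1, -0.5, 0.8), noise_sd = 0.3, seed = 9)
  m <- stepwise_backward(d$X, d$y)
  shape <- c(4, 4, 2)
  set.seed(10)
  vols <- lapply(m$predictors, function(p) {
    grid_to_volume(runif(30, -1, 1),
                   cbind(rep(0:3, length.out = 30),
                         rep(rep(0:3, each = 4), length.out = 30)[1:30],
                         rep(0:1, each = 16)[1:30]),
                   shape, background = 0)
  })
  names(vols) <- m$predictors
  pred <- whole_volume_predict(list(y = m), vols)$y
  filled <- which(vols[[1]]$data != 0 & vols[[2]]$data != 0 &
                    vols[[3]]$data != 0)
  Xcell <- sapply(m$predictors, function(p) vols[[p]]$data[filled])
  expect_equal(pred$data[filled], unname(predict(m, Xcell)),
               tolerance = 1e-10)
  # cells lacking any metric stay at background
  empty <- which(vols[[1]]$data == 0)
  expect_true(all(pred$data[empty] == 0))
})

test_that("derived metrics recomputed from components agree when linear", {
  set.seed(11)
  n <- 200
  ci <- runif(n, 0.5, 1.5); cii <- runif(n, 0.5, 1.5)
  civ <- runif(n, 0.5, 1.5); mito <- runif(n, 0.5, 1.5)
  trc <- compute_trc(ci, cii, civ)
  mrc <- compute_mrc(trc, mito)
  tab <- data.frame(ci = ci, cii = cii, civ = civ, mito_d = mito,
                    trc = trc, mrc = mrc)
  out <- derived_consistency(tab)
  expect_equal(out$trc_r, 1)
  expect_equal(out$mrc_r, 1)

  # decorrelated components: agreement collapses
  tab2 <- tab
  tab2$ci <- sample(ci); tab2$cii <- sample(cii); tab2$civ <- sample(civ)
  out2 <- derived_consistency(tab2)
  expect_lt(abs(out2$trc_r), 0.5)
  expect_error(derived_consistency(tab[, -1]), "missing")
})
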