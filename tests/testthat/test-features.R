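test_that("volumetric transforms invert the power observables", {
  expect_equal(volumetric_transform(27, "volume"), 3)
  expect_equal(volumetric_transform(16, "surface"), 4)
  expect_error(volumetric_transform(-1, "surface"), "negative")

  set.seed(8)
  lat <- rnorm(10000, 5, 1)
  cubes <- lat^3
  expect_gt(e1071::skewness(cubes), 0.5)
  expect_lt(abs(e1071::skewness(volumetric_transform(cubes, "volume"))), 0.05)
})

test_that("distribution diagnostics separate skewed from normal data", {
  set.seed(9)
  sym <- rnorm(5000)
  d_sym <- distribution_diagnostics(sym)
  expect_lt(abs(d_sym$skewness), 0.1)

  d_const <- distribution_diagnostics(rep(2, 10))
  expect_equal(d_const$cv, 0)
  expect_true(d_const$degenerate)

  expo <- rexp(5000)
  d_expo <- distribution_diagnostics(expo)
  gauss <- rnorm(5000, 1, 0.5)
  d_gauss <- distribution_diagnostics(gauss)
  expect_gt(d_expo$cv, d_gauss$cv)
  expect_gt(d_expo$skewness, d_gauss$skewness)
  expect_gt(d_expo$ks_distance, d_gauss$ks_distance)
  expect_error(distribution_diagnostics(1:5), "n >= 8")
})

test_that("mean normalization fixes the cohort mean at one", {
  set.seed(10)
  x <- runif(100, 1, 5)
  expect_equal(mean(mean_normalize(x)), 1)
  expect_equal(mean_normalize(rep(3, 5)), rep(1, 5))
  expect_equal(mean_normalize(x), x / mean(x))
  expect_error(mean_normalize(c(-2, 0, 2)), "positive")
})

test_that("complex integration averages available routes", {
  expect_equal(integrate_complex(1, 1), 1)
  expect_equal(integrate_complex(0.8, 1.2), 1)
  # colorimetric CI excluded: respirometry passes through
  expect_equal(integrate_complex(0.7, 1.3, use_colorimetric = FALSE), 1.3)
  expect_true(is.na(integrate_complex(NA_real_, NA_real_)))
})

test_that("MitoD, TRC and MRC compose as documented", {
  expect_equal(compute_mito_d(1, 1), 1)
  expect_equal(compute_mito_d(0.5, 1.5), 1)
  expect_equal(compute_trc(1, 1, 1), 1)
  expect_equal(compute_mrc(1, 1), 1)
  expect_equal(compute_mrc(2, 1), 2 * compute_mrc(1, 1))
  expect_true(is.na(compute_mrc(1, 0)))
})

test_that("Hedges g matches an independent t-statistic route", {
  expect_equal(hedges_g(c(1, 2, 3), c(1, 2, 3)), 0)

  a <- c(0, 1); b <- c(2, 3)
  # by hand: means 0.5/2.5, pooled SD sqrt(0.5), J = 1 - 3/7
  expect_equal(hedges_g(a, b), (0.5 - 2.5) / sqrt(0.5) * (1 - 3 / 7))

  set.seed(12)
  for (i in 1:1000) {
    na <- sample(3:30, 1); nb <- sample(3:30, 1)
    x <- rnorm(na, runif(1, -1, 1)); y <- rnorm(nb)
    tt <- t.test(x, y, var.equal = TRUE)
    d <- unname(tt$statistic) * sqrt(1 / na + 1 / nb)
    j <- 1 - 3 / (4 * (na + nb) - 9)
    expect_equal(hedges_g(x, y), d * j, tolerance = 1e-12)
  }

  # large-n limit approaches Cohen's d (J -> 1)
  set.seed(13)
  x <- rnorm(5000, 0.5); y <- rnorm(5000)
  d <- (mean(x) - mean(y)) /
    sqrt(((5000 - 1) * var(x) + (5000 - 1) * var(y)) / (2 * 5000 - 2))
  expect_equal(hedges_g(x, y), d, tolerance = 1e-3)
  expect_error(hedges_g(1, c(1, 2)), "n >= 2")
  expect_error(hedges_g(rep(1, 5), rep(1, 5)), "pooled")
})

test_that("two-Gaussian deconvolution recovers separated components", {
  set.seed(14)
  x <- c(rnorm(200, 0, 1), rnorm(200, 5, 1))
  fit <- mixture_deconvolution(x)
  expect_true(fit$converged)
  expect_lt(abs(fit$means[1] - 0), 0.2)
  expect_lt(abs(fit$means[2] - 5), 0.2)
  expect_true(fit$means[1] < fit$means[2])  # sorting contract
  expect_equal(sum(fit$weights), 1, tolerance = 1e-6)

  single <- mixture_deconvolution(rnorm(200))
  expect_true(is.logical(single$converged))
  expect_error(mixture_deconvolution(rnorm(10)), "n >= 20")
})

test_that("feature table derived from truth is proportional to latents", {
  v <- generate_slab(tiny_slab_config(seed = 15))
  truth <- generate_truth(v, seed = 15)
  ft <- features_from_truth(truth)
  lat <- truth$latent
  # transform + mean-normalization recovers normalized latents exactly
  for (f in c("cs", "mtdna")) {
    expect_equal(ft[[paste0(f, "_n")]], lat[[f]] / mean(lat[[f]]),
                 tolerance = 1e-9)
  }
  mito_oracle <- rowMeans(cbind(lat$cs / mean(lat$cs),
                                lat$mtdna / mean(lat$mtdna)))
  expect_equal(ft$mito_d, mito_oracle, tolerance = 1e-6)
  trc_oracle <- rowMeans(cbind(lat$ci / mean(lat$ci),
                               lat$cii / mean(lat$cii),
                               lat$civ / mean(lat$civ)))
  expect_equal(ft$trc, trc_oracle, tolerance = 1e-6)
  expect_equal(ft$mrc, trc_oracle / mito_oracle, tolerance = 1e-6)
  expect_true(all(ft$complete))
})
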