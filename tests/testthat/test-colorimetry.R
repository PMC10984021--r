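test_that("window integration matches direct endpoint evaluation", {
  t <- seq(0, 600, 10)
  expect_equal(integrate_window(t, rep(1, length(t)), c(100, 200)), 0)
  expect_equal(integrate_window(t, 0.001 * t, c(100, 200)), 0.1)

  # saturating exponential: compare against the closed-form OD at the edges
  od <- 1 - exp(-t / 150)
  expect_equal(integrate_window(t, od, c(50, 300)),
               stats::approx(t, od, 300)$y - stats::approx(t, od, 50)$y,
               tolerance = 1e-9)

  # decreasing reporter measured with direction = -1
  expect_equal(integrate_window(t, 2 - 0.001 * t, c(0, 100), direction = -1),
               0.1)
  expect_error(integrate_window(t, od, c(-50, 100)), "outside")
  expect_error(integrate_window(t, od, c(200, 100)), "window")
  expect_error(integrate_window(c(1, 1, 2), c(1, 2, 3), c(1, 2)),
               "increasing")
})

test_that("window selection takes the higher value", {
  expect_equal(pick_window(0.2, 0.5), 0.5)
  expect_equal(pick_window(0.5, 0.5), 0.5)
  set.seed(1)
  a <- rnorm(200); b <- rnorm(200)
  expect_equal(pick_window(a, b), pmax(a, b))
  expect_error(pick_window(NA, 1), "finite")
})

test_that("two-closest replicate selection agrees with pair enumeration", {
  sel <- select_two_closest(c(1, 2, 10))
  expect_equal(sort(sel$pair), c(1L, 2L))
  expect_equal(sel$mean, 1.5)

  # tie: keep the lowest-index pair
  tie <- select_two_closest(c(5, 5, 5))
  expect_equal(sort(tie$pair), c(1L, 2L))
  expect_equal(tie$mean, 5)

  set.seed(42)
  for (i in 1:1000) {
    v <- rnorm(3)
    pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
    gaps <- abs(v[pairs[, 1]] - v[pairs[, 2]])
    best <- pairs[which.min(gaps), ]
    sel <- select_two_closest(v)
    expect_identical(sort(sel$pair), sort(as.integer(best)))
    expect_equal(sel$mean, mean(v[best]))
  }

  partial <- select_two_closest(c(1, NA, 3))
  expect_equal(partial$qc, "incomplete_triplicate")
  expect_equal(partial$mean, 2)
  expect_error(select_two_closest(c(NA_real_, NA, NA)), "finite")
})

test_that("nonspecific subtraction clips at the detection limit", {
  ok <- specific_activity(1.0, 0.2)
  expect_equal(ok$activity, 0.8)
  expect_equal(ok$qc, "ok")
  low <- specific_activity(0.1, 0.3)
  expect_equal(low$activity, 0)
  expect_equal(low$qc, "below_detection")
})

test_that("OD-to-activity conversion follows the scaling formula", {
  expect_equal(od_to_activity(0.5, 1, 1, 1), 0.5)
  expect_equal(od_to_activity(0.5, 1, 2, 1), 2 * od_to_activity(0.5, 1, 1, 1))
  set.seed(3)
  for (i in 1:20) {
    d <- runif(1); e <- runif(1, 0.5, 2); dil <- runif(1, 1, 60)
    p <- runif(1, 0.5, 1.5)
    expect_equal(od_to_activity(d, e, dil, p), d * dil / (e * p))
  }
  expect_error(od_to_activity(1, 0), "positive")
})

test_that("trace scaling propagates linearly into activities", {
  t <- seq(0, 600, 10)
  base <- integrate_window(t, 0.002 * t, c(100, 400))
  doubled <- integrate_window(t, 0.004 * t, c(100, 400))
  expect_equal(doubled, 2 * base)
})

test_that("zero-noise colorimetry pipeline returns the generator truth", {
  cmp <- tiny_campaign(seed = 21)
  acts <- process_colorimetry(cmp$assays$traces, cmp$assignments)
  for (a in c("CS", "CI", "CII", "CIV")) {
    f <- c(CS = "cs", CI = "ci", CII = "cii", CIV = "civ")[[a]]
    sub <- acts[acts$assay == a, ]
    expect_equal(nrow(sub), nrow(cmp$voxels))
    rel <- abs(sub$activity / truth_lookup(cmp$truth, f, sub$voxel_id) - 1)
    expect_lt(max(rel), 1e-9)
    expect_true(all(sub$qc == "ok"))
  }
})
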