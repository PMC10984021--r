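make_controls <- function(plate_values) {
  # plate_values: list plate -> named per-type duplicate means
  do.call(rbind, lapply(names(plate_values), function(p) {
    v <- plate_values[[p]]
    data.frame(plate_id = p, control_type = rep(names(v), each = 2),
               value = rep(unname(v), each = 2), stringsAsFactors = FALSE)
  }))
}

test_that("control grand means average duplicates then plates", {
  same <- make_controls(list(P1 = c(GM = 2, WM = 1, mixed = 1.5),
                             P2 = c(GM = 2, WM = 1, mixed = 1.5)))
  expect_equal(control_grand_means(same),
               c(GM = 2, WM = 1, mixed = 1.5))

  two <- make_controls(list(P1 = c(GM = 1), P2 = c(GM = 3)))
  expect_equal(unname(control_grand_means(two)[["GM"]]), 2)

  set.seed(7)
  rnd <- data.frame(plate_id = rep(c("P1", "P2", "P3"), each = 6),
                    control_type = rep(rep(c("GM", "WM", "mixed"), each = 2), 3),
                    value = runif(18, 1, 3))
  gm <- control_grand_means(rnd)
  oracle <- sapply(split(rnd, rnd$control_type), function(d)
    mean(tapply(d$value, d$plate_id, mean)))
  expect_equal(gm[names(oracle)], oracle)
  expect_error(control_grand_means(rnd[0, ]), "empty")
})

test_that("plate factors are mean control ratios", {
  grand <- c(GM = 2, WM = 1, mixed = 1.5)
  on_target <- data.frame(control_type = rep(c("GM", "WM", "mixed"), each = 2),
                          value = rep(c(2, 1, 1.5), each = 2))
  expect_equal(plate_factor(on_target, grand), 1)

  doubled <- on_target; doubled$value <- doubled$value * 2
  expect_equal(plate_factor(doubled, grand), 2)

  mixed_ratios <- data.frame(control_type = c("GM", "WM", "mixed"),
                             value = c(2 * 1, 1 * 2, 1.5 * 4))
  expect_equal(plate_factor(mixed_ratios, grand), mean(c(1, 2, 4)))
  expect_error(plate_factor(on_target, c(GM = 0, WM = 1, mixed = 1)),
               "positive")
})

test_that("normalization direction corrects rather than amplifies", {
  expect_equal(apply_normalization(c(1, 4), 1), c(1, 4))
  expect_equal(apply_normalization(4, 2), 2)
  expect_equal(apply_normalization(4, 2, "multiply"), 8)
  expect_error(apply_normalization(1, 0), "positive")
})

test_that("log-normal batch effects are removed exactly at zero noise", {
  set.seed(11)
  plates <- sprintf("P%02d", 1:8)
  factors <- rlnorm(8, 0, 0.2)
  truth_ctrl <- c(GM = 2, WM = 0.8, mixed = 1.4)
  truth_samp <- runif(20, 0.5, 3)
  df <- do.call(rbind, lapply(seq_along(plates), function(i) {
    rbind(
      data.frame(plate_id = plates[i],
                 content = rep(paste0("control_", names(truth_ctrl)), 2),
                 value = rep(truth_ctrl, 2) * factors[i]),
      data.frame(plate_id = plates[i], content = "sample",
                 value = truth_samp * factors[i])
    )
  }))
  out <- normalize_plates(df)
  ctrl <- out[grepl("^control", out$content), ]
  cv_by_type <- sapply(split(ctrl, ctrl$content), function(d) {
    per_plate <- tapply(d$value, d$plate_id, mean)
    sd(per_plate) / mean(per_plate)
  })
  expect_lt(max(cv_by_type), 1e-9)

  # corrected samples beat uncorrected ones (mean-normalized scale)
  samp <- out[out$content == "sample", ]
  corrected <- matrix(samp$value, nrow = 20)
  uncorr <- outer(truth_samp, factors)
  rmse <- function(m) sqrt(mean((mean_normalize(as.vector(m)) -
                                   rep(mean_normalize(truth_samp), 8))^2))
  expect_lt(rmse(corrected), rmse(uncorr) / 5)

  expect_error(normalize_plates(df[df$content == "sample", ]), "control")
})

test_that("residual control scatter shrinks with duplicate count", {
  set.seed(13)
  run_cv <- function(n_dup) {
    mean(replicate(30, {
      factors <- rlnorm(6, 0, 0.2)
      df <- do.call(rbind, lapply(1:6, function(i) {
        data.frame(plate_id = sprintf("P%d", i),
                   content = rep(paste0("control_", c("GM", "WM", "mixed")),
                                 each = n_dup),
                   value = rep(c(2, 0.8, 1.4), each = n_dup) * factors[i] *
                     (1 + rnorm(3 * n_dup, 0, 0.1)))
      }))
      out <- normalize_plates(df)
      per_plate <- tapply(out$value[out$content == "control_GM"],
                          out$plate_id[out$content == "control_GM"], mean)
      sd(per_plate) / mean(per_plate)
    }))
  }
  cvs <- sapply(c(2, 4, 8), run_cv)
  expect_true(all(diff(cvs) < 0))
})
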