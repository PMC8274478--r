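test_that("binocular mean averages eyes and falls back to the available eye", {
  tr <- pupil_trace(1:4 / 60, c(4.0, 4.0, NA, 3), c(4.2, NA, NA, 5))
  expect_equal(binocular_mean(tr), c(4.1, 4.0, NA, 4))
})

test_that("low-outlier gate removes exactly the far-below-mean samples", {
  s <- c(rep(4, 100), rep(0, 5))
  # hand-computed trial statistics
  m <- sum(s) / 105
  sdev <- sqrt(sum((s - m)^2) / 104)
  expect_equal(m, 400 / 105)
  expect_true(abs((m - 2 * sdev) - 2.0977) < 1e-3)
  mask <- gate_low_outliers(s)
  expect_identical(which(mask), 101:105)
})

test_that("low-outlier gate is one-sided and strict at the boundary", {
  # constant series: nothing below the mean
  expect_false(any(gate_low_outliers(rep(4, 50))))
  # high outliers are never gated here
  expect_false(any(gate_low_outliers(c(rep(4, 50), 9, 9))[51:52]))
  # c(0, 4, 2 x 7): mean 2, SD exactly 1, so the 0 sits exactly at
  # mean - 2 SD and must be retained under the strict rule
  x <- c(0, 4, rep(2, 7))
  expect_equal(mean(x), 2)
  expect_equal(stats::sd(x), 1)
  expect_false(any(gate_low_outliers(x)))
})

test_that("velocity gate flags the post-edge sample of a step and spares ramps", {
  t <- (0:19) / 60
  ramp <- seq(3, 4, length.out = 20)
  expect_false(any(gate_velocity_outliers(ramp, t)))

  s <- c(rep(4, 10), rep(5, 10))
  v <- diff(s) / diff(t)               # 18 zeros and one spike of 300
  keep <- abs(v - mean(v)) <= 2 * stats::sd(v)
  expect_identical(which(!keep), 10L)  # hand enumeration: only the step
  mask <- gate_velocity_outliers(s, t)
  expect_identical(which(mask), 11L)   # assigned to the later sample
})

test_that("velocity gate skips excluded gaps when forming differences", {
  t <- (0:9) / 60
  s <- c(4, 4, 0.1, 4, 4, 4, 4, 4, 4, 4)
  excl <- s < 1
  mask <- gate_velocity_outliers(s, t, exclude = excl)
  expect_false(any(mask))              # 4 -> 4 across the gap: no velocity
})

test_that("gap filling interpolates interior gaps and edge-fills the ends", {
  t <- 0:2
  expect_equal(fill_gaps(c(2, NA, 4), c(FALSE, TRUE, FALSE), t), c(2, 3, 4))
  expect_equal(fill_gaps(c(1, 2, 3), rep(FALSE, 3), t), c(1, 2, 3))
  expect_equal(fill_gaps(c(NA, 5, 5), c(TRUE, FALSE, FALSE), t), c(5, 5, 5))
  expect_error(fill_gaps(c(NA, NA), c(TRUE, TRUE), 0:1), "all samples")
})

test_that("interpolated values stay within their bracketing retained values", {
  set.seed(4)
  for (rep in 1:20) {
    n <- 50
    x <- cumsum(rnorm(n))
    mask <- rep(FALSE, n)
    mask[sample(2:(n - 1), 12)] <- TRUE
    filled <- fill_gaps(ifelse(mask, NA, x), mask, seq_len(n))
    keep_idx <- which(!mask)
    for (i in which(mask)) {
      lo <- max(keep_idx[keep_idx < i], -Inf)
      hi <- min(keep_idx[keep_idx > i], Inf)
      if (is.finite(lo) && is.finite(hi)) {
        expect_gte(filled[i], min(x[lo], x[hi]) - 1e-12)
        expect_lte(filled[i], max(x[lo], x[hi]) + 1e-12)
      }
    }
  }
})

test_that("baseline statistics gate blinks before averaging", {
  t <- (0:19) / 60
  vals <- c(rep(4, 19), 0)
  bl <- baseline_stats(pupil_trace(t, vals, vals, "s1", "rest"))
  expect_equal(bl$mean_diameter, 4)    # the zero is gated, 19 samples remain
  expect_equal(bl$n_samples, 19L)
  expect_equal(bl$sd_diameter, 0)

  b2 <- const_baseline(4.0)
  expect_equal(b2$mean_diameter, 4.0)
  expect_equal(b2$sd_diameter, 0)
})

test_that("full cleaning chain zeroes a constant trace against an equal baseline", {
  t <- (0:299) / 60
  tr <- pupil_trace(t, rep(4, 300), rep(4, 300), "s1", "perf")
  cl <- preprocess_trace(tr, const_baseline(4))
  expect_s3_class(cl, "clean_trace")
  expect_equal(length(cl$diameter), 300L)
  expect_lt(max(abs(cl$diameter)), 1e-9)
  expect_false(any(cl$gap_mask))
})

test_that("baseline differencing is shift-equivariant", {
  set.seed(8)
  t <- (0:499) / 60
  base <- 4 + 0.1 * sin(t) + rnorm(500, 0, 0.01)
  tr1 <- pupil_trace(t, base, base + 0.02, "s", "a")
  tr2 <- pupil_trace(t, base + 1.5, base + 0.02 + 1.5, "s", "a")
  cl1 <- preprocess_trace(tr1, const_baseline(4))
  cl2 <- preprocess_trace(tr2, const_baseline(5.5))
  expect_equal(cl1$diameter, cl2$diameter, tolerance = 1e-10)
  expect_identical(cl1$gap_mask, cl2$gap_mask)
})

test_that("a constructed blink is fully covered by the gap mask, edges included", {
  set.seed(3)
  t <- (0:599) / 60
  x <- 4 + rnorm(600, 0, 0.02)
  blink <- 300:315
  x[blink] <- c(2.2, 0.6, rep(0.08, 12), 0.45, 1.3)  # partial edges + hold
  tr <- pupil_trace(t, x, x, "s", "a")
  cl <- preprocess_trace(tr, const_baseline(4))
  expect_true(all(cl$gap_mask[blink]))
  expect_lt(mean(cl$gap_mask), 0.1)
  # the reconstruction bridges the blink near the surrounding level
  expect_lt(max(abs(cl$diameter[blink])), 0.15)
})

test_that("cleaned output tracks the generator's clean reference below noise level", {
  tl <- make_timeline(20)
  truth <- synth_truth(seed = 5)
  pred <- gen_bar_predictors(20, seed = 5)
  names(pred)[names(pred) == "qom_head_target"] <- "qom_head"
  pred$cloud <- runif(20, 0, 3)
  pred$sound <- runif(20, 0.1, 0.3)
  gp <- gen_pupil(tl, pred, truth, seed = 6)
  cl <- preprocess_trace(gp$raw, const_baseline(truth$baseline_mean))
  rmse <- sqrt(mean((cl$diameter + truth$baseline_mean - gp$reference)^2))
  expect_lt(rmse, truth$noise_sd)
})
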