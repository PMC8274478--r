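test_that("truth record validates its parameters", {
  expect_error(synth_truth(rho = 1), "rho")
  expect_error(synth_truth(sigma_ar = -1), "non-negative")
  expect_error(synth_truth(blink_rate = -2), "blink_rate")
  expect_error(synth_truth(beta = c(0.1, 0.2)), "named")
})

test_that("score generation is seeded, covers every bar, and spells pitches", {
  one <- gen_score(1, 1, seed = 7)
  expect_s3_class(one$notes, "note_events")
  expect_gte(nrow(one$notes), 1L)
  expect_false(anyNA(one$notes))
  expect_identical(gen_score(1, 1, seed = 7)$notes, one$notes)

  sc <- gen_score(16, 4, seed = 1)
  expect_setequal(unique(sc$notes$bar), 1:16)
  for (p in unique(sc$notes$part)) {
    expect_setequal(unique(sc$notes$bar[sc$notes$part == p]), 1:16)
  }
  expect_error(gen_score(0, 1), "positive")
  expect_error(gen_score(4, 0), "positive")
})

test_that("per-bar score clouds match the brute-force geometry oracle", {
  sc <- gen_score(16, 4, seed = 1)
  for (b in c(1, 5, 9, 16)) {
    expect_equal(cloud_diameter(sc$clouds[[b]]),
                 brute_cloud_diameter(sc$clouds[[b]]), tolerance = 1e-12)
  }
})

test_that("bar predictors respect ranges and are independent across measures", {
  p <- gen_bar_predictors(5, seed = 3)
  expect_true(all(p$technical %in% 1:7))
  expect_true(all(p$harmonic %in% 1:7))
  expect_true(all(p$expressive %in% 1:7))
  expect_true(all(p$qom_head_target > 0))
  expect_true(all(p$rms_target > 0 & p$rms_target <= 0.5))
  expect_identical(nrow(gen_bar_predictors(1, seed = 1)), 1L)

  big <- gen_bar_predictors(10000, seed = 4)
  expect_lt(abs(cor(big$technical, big$harmonic)), 0.05)
  expect_lt(abs(cor(big$harmonic, big$expressive)), 0.05)
})

test_that("a degenerate truth yields a constant noiseless trace", {
  tl <- make_timeline(6)
  truth <- synth_truth(beta = c(technical = 0), rho = 0, sigma_ar = 0,
                       sigma_e = 0, sigma_subject = 0, sigma_piece = 0,
                       blink_rate = 0, noise_sd = 0)
  pred <- data.frame(bar = 1:6, technical = sample(1:7, 6, replace = TRUE))
  gp <- gen_pupil(tl, pred, truth, seed = 2)
  expect_equal(gp$reference, rep(4, length(gp$reference)))
  expect_equal(gp$raw$left, gp$reference)
  expect_equal(gp$raw$right, gp$reference)
  expect_equal(gp$bar_means, rep(4, 6))
})

test_that("missing predictor bars raise an error naming the bar", {
  tl <- make_timeline(4)
  truth <- synth_truth(beta = c(technical = 0.01))
  pred <- data.frame(bar = c(1, 2, 4), technical = c(3, 3, 3))
  expect_error(gen_pupil(tl, pred, truth), "3")
})

test_that("blink counts fall in the Poisson 99% interval at the requested rate", {
  tl <- make_timeline(30)                      # 60 s at 2 s/bar
  truth <- synth_truth(blink_rate = 10, seed = 1)
  pred <- data.frame(bar = 1:30,
                     matrix(1, 30, length(truth$beta),
                            dimnames = list(NULL, names(truth$beta))))
  counts <- vapply(1:8, function(s) {
    gen_pupil(tl, pred, truth, seed = s)$n_blinks
  }, 0)
  lo <- qpois(0.005, 10)
  hi <- qpois(0.995, 10)
  expect_true(all(counts >= lo & counts <= hi))
  expect_gt(stats::sd(counts), 0)
})

test_that("per-bar latent means regress on a known coefficient", {
  tl <- make_timeline(200)
  truth <- synth_truth(beta = c(technical = 0.03), rho = 0, sigma_ar = 0.002,
                       sigma_e = 0.002, blink_rate = 0, noise_sd = 0)
  set.seed(33)
  pred <- data.frame(bar = 1:200, technical = sample(1:7, 200, TRUE))
  gp <- gen_pupil(tl, pred, truth, seed = 3)
  slope <- coef(lm(gp$bar_means ~ pred$technical))[2]
  expect_lt(abs(slope - 0.03), 0.005)
})

test_that("pupil generation is byte-deterministic per seed", {
  tl <- make_timeline(8)
  truth <- synth_truth()
  pred <- gen_bar_predictors(8, seed = 5)
  names(pred)[names(pred) == "qom_head_target"] <- "qom_head"
  pred$cloud <- 1
  pred$sound <- 0.2
  a <- gen_pupil(tl, pred, truth, seed = 4)
  b <- gen_pupil(tl, pred, truth, seed = 4)
  expect_identical(a$raw$left, b$raw$left)
  expect_identical(a$bar_means, b$bar_means)
  c <- gen_pupil(tl, pred, truth, seed = 5)
  expect_false(identical(a$raw$left, c$raw$left))
})

test_that("mocap hits QoM targets, supports stillness, and is seeded", {
  tl <- make_timeline(10)
  targ <- rep(800, 10)
  tracks <- gen_mocap(tl, targ, seed = 6)
  q <- qom(segment_speed(tracks, "head"), tl)
  expect_lt(stats::sd(q) / mean(q), 0.1)       # constant targets: low CV
  expect_lt(max(abs(q - targ) / targ), 0.1)

  set.seed(34)
  vary <- exp(rnorm(10, log(1000), 0.25))
  q2 <- qom(segment_speed(gen_mocap(tl, vary, seed = 7), "head"), tl)
  expect_lt(max(abs(q2 - vary) / vary), 0.1)

  still <- gen_mocap(tl, rep(0, 10), seed = 8)
  sp <- segment_speed(still, "head")$speed
  expect_lt(max(sp), 1e-6)

  t1 <- gen_mocap(tl, targ, seed = 9)
  t2 <- gen_mocap(tl, targ, seed = 9)
  expect_identical(t1[[1]]$x, t2[[1]]$x)
})

test_that("audio hits per-bar RMS targets through the extraction chain", {
  tl <- make_timeline(10)
  clip <- gen_audio(tl, rep(0.2, 10), seed = 10)
  sl <- sound_level_per_bar(smooth_envelope(rms_frames(clip)), tl)
  expect_lt(max(abs(sl - 0.2) / 0.2), 0.1)

  set.seed(35)
  targ <- pmin(0.5, exp(rnorm(10, log(0.15), 0.3)))
  clip2 <- gen_audio(tl, targ, seed = 11)
  sl2 <- sound_level_per_bar(smooth_envelope(rms_frames(clip2)), tl)
  expect_lt(max(abs(sl2 - targ) / targ), 0.1)

  quiet <- gen_audio(tl, rep(1e-5, 10), seed = 12)
  expect_lt(max(rms_frames(quiet)$rms), 1e-3)

  expect_error(gen_audio(tl, rep(1.2, 10)), "clip")
  a <- gen_audio(tl, targ, seed = 13)
  b <- gen_audio(tl, targ, seed = 13)
  expect_identical(a$samples, b$samples)
})

test_that("substream seeds are deterministic, distinct, and 32-bit safe", {
  s1 <- substream_seed(42, "pupil:p1:piece1")
  expect_identical(s1, substream_seed(42, "pupil:p1:piece1"))
  expect_false(s1 == substream_seed(42, "pupil:p1:piece2"))
  expect_false(s1 == substream_seed(43, "pupil:p1:piece1"))
  expect_true(s1 >= 0 && s1 < 2^31)
})

test_that("a minimal study writes the full tree and reproduces checksums per seed", {
  cfg <- synth_config(n_performers = 2, n_listeners = 0, n_pieces = 1,
                      n_bars = 8, baseline_dur = 10)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  gen_full_study(cfg, seed = 11, dir = d1)
  for (sub in c("pupil", "baseline", "mocap", "audio", "score", "ratings",
                "timelines")) {
    expect_true(length(list.files(file.path(d1, sub))) > 0)
  }
  truth <- jsonlite::read_json(file.path(d1, "truth.json"))
  expect_equal(truth$rho, 0.6)
  expect_true(all(c("cloud", "technical") %in% names(truth$beta)))

  gen_full_study(cfg, seed = 11, dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  sum1 <- unname(tools::md5sum(file.path(d1, f1)))
  sum2 <- unname(tools::md5sum(file.path(d2, f2)))
  expect_identical(sum1, sum2)
})
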