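test_that("line-of-fifths indices anchor at C and distinguish spellings", {
  expect_identical(fifths_index("C"), 0L)
  expect_identical(fifths_index("G"), 1L)
  expect_identical(fifths_index("F"), -1L)
  expect_identical(fifths_index("F", 1L), 6L)
  expect_identical(fifths_index("G", -1L), -6L)
  expect_identical(fifths_index(c("B", "B"), c(0L, -1L)), c(5L, -2L))
  expect_error(fifths_index("H"), "step")
  expect_error(fifths_index("C", 3L), "alter")
  # agreement with a first-principles derivation over all spellings
  grid <- expand.grid(step = LETTERS[1:7], alter = -2:2,
                      stringsAsFactors = FALSE)
  expect_identical(fifths_index(grid$step, grid$alter),
                   brute_fifths(grid$step, grid$alter))
})

test_that("helix positions follow the quarter-turn geometry", {
  cfg <- spiral_config()
  expect_equal(spiral_position(0, cfg)[1, ], c(x = 0, y = 1, z = 0))
  p4 <- spiral_position(4, cfg)[1, ]
  expect_equal(p4, c(x = 0, y = 1, z = 4 * cfg$h), tolerance = 1e-12)
  # adjacent-fifth distance is sqrt(2 r^2 + h^2) for every k
  cfg2 <- spiral_config(r = 1.7, h = 0.9)
  for (k in -6:6) {
    d <- sqrt(sum((spiral_position(k, cfg2) -
                     spiral_position(k + 1, cfg2))^2))
    expect_equal(d, sqrt(2 * 1.7^2 + 0.9^2), tolerance = 1e-12)
  }
})

test_that("cloud diameter is 0 for singletons and exactly 1 for a fifth", {
  expect_equal(cloud_diameter(data.frame(step = "D", alter = 1)), 0)
  set.seed(12)
  for (i in 1:10) {
    cfg <- spiral_config(r = runif(1, 0.2, 3), h = runif(1, 0.05, 2))
    expect_equal(cloud_diameter(data.frame(step = c("C", "G"),
                                           alter = c(0, 0)), cfg), 1)
  }
  # duplicate pitch classes collapse (octave is ignored)
  expect_equal(cloud_diameter(data.frame(step = c("C", "C", "G"),
                                         alter = 0)), 1)
  expect_error(cloud_diameter(data.frame(step = character(0),
                                         alter = integer(0))), "empty")
})

test_that("cloud diameter equals brute-force pairwise enumeration for small clouds", {
  cfg <- spiral_config()
  expect_equal(cloud_diameter(c(0L, 1L, 2L), cfg),
               brute_cloud_diameter(c(0, 1, 2)), tolerance = 1e-12)
  set.seed(13)
  for (i in 1:40) {
    ks <- sample(-12:14, sample(2:8, 1))
    expect_equal(cloud_diameter(ks, cfg), brute_cloud_diameter(ks),
                 tolerance = 1e-12)
  }
})

test_that("cloud diameter is transposition invariant and monotone under growth", {
  set.seed(14)
  cfg <- spiral_config()
  for (i in 1:25) {
    ks <- sample(-10:12, sample(2:8, 1))
    shift <- sample(-7:7, 1)
    expect_equal(cloud_diameter(ks + shift, cfg), cloud_diameter(ks, cfg),
                 tolerance = 1e-12)
    extra <- sample(setdiff(-15:15, ks), 1)
    expect_gte(cloud_diameter(c(ks, extra), cfg) + 1e-12,
               cloud_diameter(ks, cfg))
  }
})

test_that("per-bar clouds pool onsets, include sustains, and respect the flag", {
  notes <- note_events(part = c("P1", "P1", "P1", "P1"),
                       bar = c(1, 1, 1, 2), beat = c(0, 0, 0, 0),
                       duration = c(1, 1, 1.5, 1),
                       step = c("C", "E", "G", "C"),
                       alter = c(0, 0, 0, 0), octave = 4)
  cfg <- spiral_config()
  d_triad <- brute_cloud_diameter(brute_fifths(c("C", "E", "G"), c(0, 0, 0)))
  with_sus <- cloud_diameter_per_bar(notes, 2, cfg)
  expect_equal(with_sus[1], d_triad, tolerance = 1e-12)
  # the G sustains into bar 2, joining the C there
  expect_equal(with_sus[2], brute_cloud_diameter(c(0, 1)), tolerance = 1e-12)
  onsets_only <- cloud_diameter_per_bar(notes, 2, cfg,
                                        include_sustained = FALSE)
  expect_equal(onsets_only[2], 0)

  # a repeated chord gives a constant series; transposition leaves it intact
  rep_notes <- note_events(part = "P1", bar = rep(1:8, each = 3),
                           beat = 0, duration = 1 / 3,
                           step = rep(c("C", "E", "G"), 8), alter = 0L,
                           octave = 4L)
  v <- cloud_diameter_per_bar(rep_notes, 8, cfg)
  expect_equal(v, rep(d_triad, 8), tolerance = 1e-12)
  transposed <- rep_notes
  transposed$step <- rep(c("D", "F", "A"), 8)
  transposed$alter <- rep(c(0L, 1L, 0L), 8)      # up a major second
  expect_equal(cloud_diameter_per_bar(transposed, 8, cfg), v,
               tolerance = 1e-12)
})

test_that("empty bars warn and yield missing cloud diameters", {
  notes <- note_events("P1", 1, 0, 1, "C", 0L, 4L)
  expect_warning(v <- cloud_diameter_per_bar(notes, 3), "NA")
  expect_equal(v, c(0, NA, NA))
})

test_that("rating averaging collapses performers bar-wise", {
  expect_equal(average_ratings(list(c(2, 4), c(4, 2))), c(3, 3))
  expect_equal(average_ratings(list(one = c(5, 6, 7))), c(5, 6, 7))
  four <- lapply(1:4, function(i) rep(i, 6))
  expect_equal(average_ratings(four), rep(2.5, 6))
  df <- data.frame(performer = rep(c("a", "b"), each = 3),
                   measure = "technical", bar = rep(1:3, 2),
                   value = c(1, 2, 3, 3, 2, 1))
  expect_equal(average_ratings(df, "technical"), c(2, 2, 2))
  bad <- list(a = 1:3, b = 1:2, c = 1:3)
  expect_error(average_ratings(bad), "b")
})

test_that("musicXML scores round-trip through write and read", {
  sc <- gen_score(10, 3, seed = 21)
  f <- withr::local_tempfile(fileext = ".musicxml")
  write_musicxml(sc$notes, f)
  back <- read_musicxml(f)
  expect_equal(nrow(back), nrow(sc$notes))
  key <- function(d) {
    d <- d[order(d$part, d$bar, d$beat, d$step, d$alter, d$octave), ]
    paste(d$part, d$bar, round(d$beat, 6), d$step, d$alter, d$octave)
  }
  expect_identical(key(back), key(sc$notes))
  expect_equal(cloud_diameter_per_bar(back, 10),
               cloud_diameter_per_bar(sc$notes, 10), tolerance = 1e-12)
})

test_that("note validation enforces spelling and positivity", {
  expect_error(note_events("P1", 0, 0, 1, "C", 0L, 4L), "1-based")
  expect_error(note_events("P1", 1, 0, 0, "C", 0L, 4L), "positive")
  expect_error(note_events("P1", 1, 0, 1, "X", 0L, 4L), "step")
  expect_error(note_events("P1", 1, 0, 1, "C", 3L, 4L), "alter")
})
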