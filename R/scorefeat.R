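#' Note events
#'
#' Spelled notes of a score on a 1-based bar grid. `beat` is the onset
#' position within its bar as a fraction of the bar in `[0, 1)`; `duration`
#' is in fractional bars. Pitch spelling (`step` A-G plus `alter` in -2..2)
#' is an input contract: enharmonic spellings are tonally distinct, so
#' unspelled (MIDI-style) pitches are rejected.
#'
#' @param part part identifier.
#' @param bar 1-based bar number.
#' @param beat onset within bar, fraction in `[0, 1)`.
#' @param duration duration in fractional bars, `> 0`.
#' @param step letter name, one of `A`-`G`.
#' @param alter accidental, integer in `-2..2`.
#' @param octave scientific octave number.
#' @return data frame of class `note_events`.
#' @export
note_events <- function(part, bar, beat, duration, step, alter, octave) {
  d <- data.frame(part = as.character(part), bar = as.integer(bar),
                  beat = as.numeric(beat), duration = as.numeric(duration),
                  step = as.character(step), alter = as.integer(alter),
                  octave = as.integer(octave), stringsAsFactors = FALSE)
  if (any(d$bar < 1L)) stop("bar numbers are 1-based")
  if (any(d$beat < 0 | d$beat >= 1)) stop("`beat` must lie in [0, 1)")
  if (any(d$duration <= 0)) stop("durations must be positive")
  if (!all(d$step %in% LETTERS[1:7])) stop("invalid pitch step")
  if (any(abs(d$alter) > 2L)) stop("`alter` must be in -2..2")
  class(d) <- c("note_events", "data.frame")
  d
}

#' Line-of-fifths index of a spelled pitch
#'
#' C natural is 0 and each sharpward perfect fifth adds 1 (G = 1, D = 2, ...,
#' F = -1, B-flat = -2, F-sharp = 6). Octave is ignored: the tonal model
#' places pitch classes. Distinct spellings of the same sounding pitch map to
#' distinct indices by construction.
#'
#' @param step character vector of letter names `A`-`G`.
#' @param alter integer accidentals in `-2..2` (default 0).
#' @return integer vector of fifths indices.
#' @export
fifths_index <- function(step, alter = 0L) {
  base <- c(F = -1L, C = 0L, G = 1L, D = 2L, A = 3L, E = 4L, B = 5L)
  step <- as.character(step)
  if (!all(step %in% names(base))) stop("invalid pitch step")
  alter <- as.integer(alter)
  if (any(abs(alter) > 2L)) stop("`alter` must be an integer in -2..2")
  unname(base[step] + 7L * alter)
}

#' Spiral (helix) configuration
#'
#' The line of fifths is wound onto a helix with one quarter turn per fifth:
#' radius `r` and rise `h` per fifth. Defaults use the calibrated aspect
#' ratio `h/r = sqrt(2/15)`, under which adjacent fifths, major thirds and
#' minor thirds obtain their standard relative distances.
#'
#' @param r helix radius (dimensionless, `> 0`).
#' @param h vertical rise per fifth (dimensionless, `> 0`).
#' @export
spiral_config <- function(r = 1, h = sqrt(2 / 15)) {
  if (r <= 0 || h <= 0) stop("`r` and `h` must be positive")
  structure(list(r = r, h = h), class = "spiral_config")
}

#' Helix position of a fifths index
#'
#' `(r sin(k pi/2), r cos(k pi/2), k h)`: a quarter turn and a rise of `h`
#' per sharpward fifth, so tonally close pitch classes are spatially close.
#'
#' @param k integer fifths index (vectorised).
#' @param cfg a [spiral_config()].
#' @return matrix with one row per index and columns x, y, z.
#' @export
spiral_position <- function(k, cfg = spiral_config()) {
  stopifnot(inherits(cfg, "spiral_config"))
  cbind(x = cfg$r * sin(k * pi / 2),
        y = cfg$r * cos(k * pi / 2),
        z = k * cfg$h)
}

#' Cloud diameter of a set of spelled pitches
#'
#' The largest pairwise Euclidean distance among the distinct helix
#' positions of the pitch classes, expressed in units of one perfect fifth
#' (the adjacent-fifth distance `sqrt(2 r^2 + h^2)`). A harmonic-tension /
#' dissonance measure: a single pitch class has diameter 0 and `{C, G}` has
#' diameter exactly 1 for any helix shape. Duplicated pitch classes
#' collapse.
#'
#' @param pitches a data frame with `step` and `alter` columns (e.g. rows of
#'   [note_events()]), or an integer vector of fifths indices.
#' @param cfg a [spiral_config()].
#' @return non-negative scalar in perfect-fifth units.
#' @export
cloud_diameter <- function(pitches, cfg = spiral_config()) {
  k <- if (is.data.frame(pitches)) {
    if (nrow(pitches) == 0L) stop("empty pitch cloud")
    fifths_index(pitches$step,
                 if (is.null(pitches$alter)) 0L else pitches$alter)
  } else {
    if (length(pitches) == 0L) stop("empty pitch cloud")
    as.integer(pitches)
  }
  k <- unique(k)
  if (length(k) == 1L) return(0)
  p <- spiral_position(k, cfg)
  d <- max(stats::dist(p))
  d / sqrt(2 * cfg$r^2 + cfg$h^2)
}

#' Per-bar cloud diameters of a score
#'
#' Bar `b`'s cloud contains every pitch with onset in bar `b`, plus (by
#' default) pitches from earlier bars still sounding through bar `b`. Parts
#' are pooled: the piece yields one series. Bars left empty produce `NA`
#' with a warning.
#'
#' @param notes a [note_events()] data frame.
#' @param n_bars number of bars of the piece.
#' @param cfg a [spiral_config()].
#' @param include_sustained include notes sustained into later bars (default
#'   `TRUE`); if `FALSE` only onsets count.
#' @return numeric vector of length `n_bars`.
#' @export
cloud_diameter_per_bar <- function(notes, n_bars, cfg = spiral_config(),
                                   include_sustained = TRUE) {
  n_bars <- as.integer(n_bars)
  if (n_bars < 1L) stop("`n_bars` must be positive")
  first <- notes$bar
  last <- if (include_sustained) {
    pmin(n_bars, floor(notes$bar + notes$beat + notes$duration - 1e-9))
  } else {
    notes$bar
  }
  last <- pmax(first, last)
  reps <- last - first + 1L
  bar_of <- sequence(reps) - 1L + rep(first, reps)
  k <- rep(fifths_index(notes$step, notes$alter), reps)
  out <- rep(NA_real_, n_bars)
  for (b in unique(bar_of)) {
    if (b >= 1L && b <= n_bars) {
      out[b] <- cloud_diameter(unique(k[bar_of == b]), cfg)
    }
  }
  if (anyNA(out)) {
    warning("bars without notes yield NA cloud diameter: ",
            paste(which(is.na(out)), collapse = ", "))
  }
  out
}

#' Average per-bar ratings across performers
#'
#' Collapses each performer's 1-7 per-bar rating series for one measure into
#' a single series by the arithmetic mean at each bar — the predictor used
#' when modelling listeners.
#'
#' @param ratings data frame with columns `performer`, `measure`, `bar`,
#'   `value`, or a list of equal-length numeric vectors.
#' @param measure which rating measure to average (`"technical"`,
#'   `"harmonic"`, `"expressive"`); ignored for list input.
#' @return numeric vector indexed by bar.
#' @export
average_ratings <- function(ratings, measure = NULL) {
  if (is.data.frame(ratings)) {
    if (!is.null(measure)) ratings <- ratings[ratings$measure == measure, ]
    if (nrow(ratings) == 0L) stop("no ratings for measure `", measure, "`")
    series <- split(ratings, ratings$performer)
    series <- lapply(series, function(d) d$value[order(d$bar)])
  } else {
    series <- ratings
  }
  n <- vapply(series, length, 0L)
  if (length(unique(n)) != 1L) {
    bad <- names(series)[n != stats::median(n)]
    stop("rating series length mismatch for: ", paste(bad, collapse = ", "))
  }
  rowMeans(do.call(cbind, series))
}

#' Read a ratings CSV (`performer,measure,bar,value`)
#' @param path CSV path.
#' @return data frame with ratings in long format.
#' @export
read_ratings_csv <- function(path) {
  d <- utils::read.csv(path)
  req <- c("performer", "measure", "bar", "value")
  if (!all(req %in% names(d))) {
    stop("ratings CSV must have columns ", paste(req, collapse = ","))
  }
  if (any(d$value < 1 | d$value > 7)) stop("ratings must lie in [1, 7]")
  d
}
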