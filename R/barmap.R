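#' Bar timeline
#'
#' Maps wall-clock time to 1-based musical bars. Bar `b` occupies the
#' half-open interval `[onsets[b], onsets[b+1])`; the last bar runs to
#' `end_time`.
#'
#' @param onsets numeric vector of bar onset times (s), strictly increasing.
#' @param end_time end of the last bar (s), greater than the last onset.
#' @param piece piece identifier.
#' @return object of class `bar_timeline` with fields `piece`, `n_bars`,
#'   `onsets`, `end_time`.
#' @export
bar_timeline <- function(onsets, end_time, piece = NA_character_) {
  onsets <- as.numeric(onsets)
  if (length(onsets) < 1L) stop("need at least one bar onset")
  if (any(diff(onsets) <= 0)) stop("bar onsets must be strictly increasing")
  if (end_time <= onsets[length(onsets)]) {
    stop("`end_time` must exceed the last bar onset")
  }
  structure(list(piece = piece, n_bars = length(onsets), onsets = onsets,
                 end_time = as.numeric(end_time)),
            class = "bar_timeline")
}

#' @export
print.bar_timeline <- function(x, ...) {
  cat(sprintf("<bar_timeline> %s: %d bars over [%.2f, %.2f] s\n",
              x$piece, x$n_bars, x$onsets[1], x$end_time))
  invisible(x)
}

#' Interpolate bar onsets from audio anchors
#'
#' The bar grid is anchored at a few `(bar, time)` points read off the audio
#' recording; bars between consecutive anchors are assumed evenly spaced in
#' time, and bars beyond the last anchor continue at the final span's rate.
#' With exactly two anchors (start and end) this reduces to a globally even
#' spacing.
#'
#' @param anchors two-column matrix or data frame `(bar, time_sec)`; at least
#'   two anchors, the first at bar 1, bars and times strictly increasing.
#' @param n_bars total number of bars of the piece.
#' @param end_time end of the last bar (s).
#' @param piece piece identifier.
#' @return a [bar_timeline()].
#' @export
interpolate_onsets <- function(anchors, n_bars, end_time,
                               piece = NA_character_) {
  a <- as.data.frame(anchors)
  if (ncol(a) < 2L || nrow(a) < 2L) {
    stop("`anchors` needs >= 2 rows of (bar, time)")
  }
  bars <- as.numeric(a[[1L]])
  times <- as.numeric(a[[2L]])
  if (bars[1L] != 1) stop("first anchor must be at bar 1")
  if (any(diff(bars) <= 0) || any(diff(times) <= 0)) {
    stop("anchor bars and times must be strictly increasing")
  }
  n_bars <- as.integer(n_bars)
  if (n_bars < 1L) stop("`n_bars` must be positive")
  k <- length(bars)
  rate <- (times[k] - times[k - 1L]) / (bars[k] - bars[k - 1L])
  b <- seq_len(n_bars)
  onsets <- numeric(n_bars)
  inside <- b <= bars[k]
  if (any(inside)) {
    onsets[inside] <- stats::approx(bars, times, xout = b[inside])$y
  }
  if (any(!inside)) {
    onsets[!inside] <- times[k] + (b[!inside] - bars[k]) * rate
  }
  bar_timeline(onsets, end_time, piece = piece)
}

#' Assign samples to bars
#'
#' Half-open assignment: a timestamp maps to bar `b` iff
#' `onsets[b] <= t < onsets[b+1]` (last bar up to `end_time`). Timestamps
#' before bar 1 or at/after `end_time` map to 0 ("outside the piece").
#'
#' @param time numeric timestamps (s).
#' @param timeline a [bar_timeline()].
#' @return integer vector of bar indices (0 = outside piece).
#' @export
assign_bars <- function(time, timeline) {
  stopifnot(inherits(timeline, "bar_timeline"))
  breaks <- c(timeline$onsets, timeline$end_time)
  idx <- findInterval(time, breaks)
  idx[idx > timeline$n_bars] <- 0L
  as.integer(idx)
}

#' Aggregate a sample stream per bar
#'
#' Per-bar mean (pupil diameter, RMS envelope) or sum (quantity of motion)
#' over the samples assigned to each bar. Bars containing no samples yield
#' `NA` — they are never zero-filled; downstream model rows drop them with a
#' logged count.
#'
#' @param series numeric sample values.
#' @param time numeric timestamps (s), same length as `series`.
#' @param timeline a [bar_timeline()].
#' @param stat `"mean"` or `"sum"`.
#' @param na.rm drop missing sample values within a bar (default `TRUE`).
#' @return numeric vector of length `n_bars`.
#' @export
per_bar_aggregate <- function(series, time, timeline,
                              stat = c("mean", "sum"), na.rm = TRUE) {
  stat <- match.arg(stat)
  if (length(series) != length(time)) {
    stop("`series` and `time` must have the same length")
  }
  b <- assign_bars(time, timeline)
  f <- if (stat == "mean") mean else sum
  out <- rep(NA_real_, timeline$n_bars)
  inb <- b > 0L
  if (!any(inb)) return(out)
  agg <- tapply(series[inb], b[inb], function(v) {
    v <- if (na.rm) v[!is.na(v)] else v
    if (length(v) == 0L) NA_real_ else f(v)
  })
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

#' Read a bar timeline CSV (`bar,onset_sec` rows plus a final `end,<sec>` row)
#' @param path CSV path.
#' @param piece piece identifier.
#' @export
read_timeline_csv <- function(path, piece = NA_character_) {
  d <- utils::read.csv(path, colClasses = c("character", "numeric"))
  is_end <- d[[1L]] == "end"
  if (sum(is_end) != 1L) stop("timeline CSV needs exactly one `end` row")
  bar_timeline(d[[2L]][!is_end][order(as.integer(d[[1L]][!is_end]))],
               d[[2L]][is_end], piece = piece)
}

#' Write a bar timeline CSV
#' @param timeline a [bar_timeline()].
#' @param path output path.
#' @export
write_timeline_csv <- function(timeline, path) {
  d <- data.frame(bar = c(as.character(seq_len(timeline$n_bars)), "end"),
                  onset_sec = c(timeline$onsets, timeline$end_time))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
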