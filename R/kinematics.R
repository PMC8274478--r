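#' Motion-capture marker track
#'
#' One reflective marker's 3-D trajectory. The study layout places one marker
#' on the head, one on the upper back, and two on each arm; only `head` and
#' arm segments feed the models.
#'
#' @param time timestamps (s), strictly increasing, nominally 120 Hz.
#' @param x,y,z positions in mm (`NA` = tracking dropout).
#' @param marker marker name.
#' @param segment one of `"head"`, `"arm_upper"`, `"arm_lower"`, `"back"`.
#' @param performer performer identifier.
#' @export
marker_track <- function(time, x, y, z, marker = NA_character_,
                         segment = c("head", "arm_upper", "arm_lower", "back"),
                         performer = NA_character_) {
  segment <- match.arg(segment)
  time <- as.numeric(time)
  n <- length(time)
  if (n == 0L) stop("empty marker track")
  if (any(diff(time) <= 0)) stop("timestamps must be strictly increasing")
  if (length(x) != n || length(y) != n || length(z) != n) {
    stop("position columns must match `time` length")
  }
  structure(list(time = time, x = as.numeric(x), y = as.numeric(y),
                 z = as.numeric(z), marker = marker, segment = segment,
                 performer = performer),
            class = "marker_track")
}

#' @export
print.marker_track <- function(x, ...) {
  cat(sprintf("<marker_track> %s (%s) %s: %d samples\n",
              x$marker, x$segment, x$performer, length(x$time)))
  invisible(x)
}

#' Smoothed marker speed via Savitzky-Golay differentiation
#'
#' Per-axis smoothed first derivatives (Savitzky-Golay, default order 3,
#' window 41) scaled by the sampling interval, combined as the Euclidean norm
#' into a scalar speed in mm/s. Samples with missing position are masked
#' before filtering; the filter runs on each contiguous valid segment of at
#' least `window` samples, and shorter segments are dropped (speed `NA`).
#'
#' @param track a [marker_track()].
#' @param order,window Savitzky-Golay parameters (defaults 3, 41).
#' @param rel_tol maximum relative deviation of sampling intervals from their
#'   median before the track is rejected as irregular.
#' @return object of class `velocity_series`: `time`, `speed` (mm/s),
#'   `markers`.
#' @export
sg_velocity <- function(track, order = 3L, window = 41L, rel_tol = 0.01) {
  stopifnot(inherits(track, "marker_track"))
  dt <- diff(track$time)
  if (length(dt) == 0L) stop("track too short")
  dt0 <- stats::median(dt)
  if (any(abs(dt - dt0) > rel_tol * dt0)) {
    stop("irregular sampling detected; resample the track to a uniform grid ",
         "before differentiation")
  }
  n <- length(track$time)
  ok <- is.finite(track$x) & is.finite(track$y) & is.finite(track$z)
  speed <- rep(NA_real_, n)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  dropped <- 0L
  for (i in seq_along(runs$values)) {
    if (!runs$values[i]) next
    seg <- starts[i]:ends[i]
    if (length(seg) < window) {
      dropped <- dropped + length(seg)
      next
    }
    vx <- savgol_smooth(track$x[seg], order, window, deriv = 1L, delta = dt0)
    vy <- savgol_smooth(track$y[seg], order, window, deriv = 1L, delta = dt0)
    vz <- savgol_smooth(track$z[seg], order, window, deriv = 1L, delta = dt0)
    speed[seg] <- sqrt(vx^2 + vy^2 + vz^2)
  }
  if (dropped > 0L) {
    message("sg_velocity: dropped ", dropped, " samples in segments shorter ",
            "than the filter window (marker ", track$marker, ")")
  }
  structure(list(time = track$time, speed = speed, markers = track$marker),
            class = "velocity_series")
}

#' @export
print.velocity_series <- function(x, ...) {
  cat("<velocity_series>", paste(x$markers, collapse = "+"), ":",
      length(x$time), "samples\n")
  invisible(x)
}

#' Combine marker speeds into a body-segment speed
#'
#' The head predictor is the single head marker's speed. The arm predictor is
#' the arithmetic mean of the available arm-marker speeds at each timestamp —
#' a mean rather than a sum so that unequal marker dropout across performers
#' does not rescale the predictor (`combine = "sum"` is available).
#'
#' @param tracks list of [marker_track()]s for one performer (all on a common
#'   time grid).
#' @param segment `"head"` or `"arms"` (arms = `arm_upper` + `arm_lower`).
#' @param combine `"mean"` (default) or `"sum"` across markers.
#' @param ... passed to [sg_velocity()].
#' @return a `velocity_series`.
#' @export
segment_speed <- function(tracks, segment = c("head", "arms"),
                          combine = c("mean", "sum"), ...) {
  segment <- match.arg(segment)
  combine <- match.arg(combine)
  want <- if (segment == "head") "head" else c("arm_upper", "arm_lower")
  sel <- Filter(function(tr) tr$segment %in% want, tracks)
  if (length(sel) == 0L) stop("no tracks for segment `", segment, "`")
  vs <- lapply(sel, sg_velocity, ...)
  t0 <- vs[[1L]]$time
  for (v in vs[-1L]) {
    if (length(v$time) != length(t0) || max(abs(v$time - t0)) > 1e-9) {
      stop("marker tracks are not on a common time grid")
    }
  }
  sp <- do.call(cbind, lapply(vs, `[[`, "speed"))
  agg <- if (combine == "mean") rowMeans(sp, na.rm = TRUE)
         else rowSums(sp, na.rm = TRUE)
  agg[!is.finite(agg)] <- NA_real_
  all_na <- rowSums(!is.na(sp)) == 0L
  agg[all_na] <- NA_real_
  structure(list(time = t0, speed = agg,
                 markers = vapply(sel, `[[`, "", "marker")),
            class = "velocity_series")
}

#' Quantity of motion per bar
#'
#' QoM is the sum of (smoothed) marker speeds over the samples of each bar —
#' a per-bar proxy for the mechanical energy a performer expends.
#'
#' @param series a `velocity_series` (see [sg_velocity()], [segment_speed()]).
#' @param timeline a [bar_timeline()].
#' @return numeric vector of length `n_bars` (mm/s summed per bar).
#' @export
qom <- function(series, timeline) {
  stopifnot(inherits(series, "velocity_series"))
  per_bar_aggregate(series$speed, series$time, timeline, stat = "sum")
}

#' Read long-format mocap TSV (`t_sec,marker,x_mm,y_mm,z_mm`)
#'
#' @param path TSV path.
#' @param segment_map named character vector mapping marker names to segments
#'   (`head`, `arm_upper`, `arm_lower`, `back`).
#' @param performer performer identifier.
#' @return list of [marker_track()]s.
#' @export
read_mocap_tsv <- function(path, segment_map, performer = NA_character_) {
  d <- as.data.frame(data.table::fread(path, sep = "\t"))
  req <- c("t_sec", "marker", "x_mm", "y_mm", "z_mm")
  if (!all(req %in% names(d))) {
    stop("mocap TSV must have columns ", paste(req, collapse = ","))
  }
  lapply(split(d, d$marker), function(dd) {
    mk <- dd$marker[1L]
    seg <- segment_map[[mk]]
    if (is.null(seg)) stop("marker `", mk, "` missing from segment map")
    dd <- dd[order(dd$t_sec), ]
    marker_track(dd$t_sec, dd$x_mm, dd$y_mm, dd$z_mm, marker = mk,
                 segment = seg, performer = performer)
  })
}

#' Write marker tracks as long-format TSV
#' @param tracks list of [marker_track()]s.
#' @param path output path.
#' @export
write_mocap_tsv <- function(tracks, path) {
  d <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(t_sec = tr$time, marker = tr$marker, x_mm = tr$x,
               y_mm = tr$y, z_mm = tr$z)
  }))
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}
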