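#' Raw binocular pupil trace
#'
#' Container for an eye-tracker sample stream: timestamps plus left/right
#' pupil diameters in mm. Missing samples (tracking loss) are `NA`.
#'
#' @param time numeric vector of timestamps in seconds, strictly increasing.
#' @param left,right pupil diameters in mm; `NA` where the eye was not
#'   captured. Values must be non-negative where present.
#' @param subject subject identifier.
#' @param trial trial identifier (performance or baseline occasion).
#' @return an object of class `pupil_trace`.
#' @export
pupil_trace <- function(time, left, right, subject = NA_character_,
                        trial = NA_character_) {
  time <- as.numeric(time)
  left <- as.numeric(left)
  right <- as.numeric(right)
  if (length(time) == 0L) stop("empty pupil trace")
  if (length(left) != length(time) || length(right) != length(time)) {
    stop("`left` and `right` must have the same length as `time`")
  }
  if (any(diff(time) <= 0)) stop("timestamps must be strictly increasing")
  if (any(left < 0, na.rm = TRUE) || any(right < 0, na.rm = TRUE)) {
    stop("pupil diameters must be non-negative")
  }
  structure(list(time = time, left = left, right = right,
                 subject = subject, trial = trial),
            class = "pupil_trace")
}

#' @export
print.pupil_trace <- function(x, ...) {
  cat("<pupil_trace>", length(x$time), "samples,",
      sprintf("%.1f s", diff(range(x$time))),
      "| subject:", x$subject, "| trial:", x$trial, "\n")
  invisible(x)
}

#' Read a pupil trace from CSV
#'
#' Expects columns `t_sec,left_mm,right_mm`; empty fields are missing samples.
#'
#' @param path CSV file path.
#' @inheritParams pupil_trace
#' @export
read_pupil_csv <- function(path, subject = NA_character_,
                           trial = NA_character_) {
  d <- as.data.frame(data.table::fread(path))
  req <- c("t_sec", "left_mm", "right_mm")
  if (!all(req %in% names(d))) {
    stop("pupil CSV must have columns ", paste(req, collapse = ","))
  }
  pupil_trace(d$t_sec, d$left_mm, d$right_mm, subject = subject, trial = trial)
}

#' Write a pupil trace to CSV
#' @param trace a [pupil_trace()].
#' @param path output file path.
#' @export
write_pupil_csv <- function(trace, path) {
  d <- data.frame(t_sec = trace$time, left_mm = trace$left,
                  right_mm = trace$right)
  data.table::fwrite(d, path, na = "")
  invisible(path)
}

#' Binocular mean diameter
#'
#' Averages left- and right-eye diameters sample by sample. If only one eye
#' was captured at a sample, that eye's value is used; if neither, the sample
#' is missing. Binocular averaging damps outliers confined to one eye (e.g.
#' at extreme gaze angles).
#'
#' @param trace a [pupil_trace()].
#' @return numeric vector of diameters (mm) with `NA` where both eyes are
#'   missing.
#' @export
binocular_mean <- function(trace) {
  stopifnot(inherits(trace, "pupil_trace"))
  m <- rowMeans(cbind(trace$left, trace$right), na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  m
}

#' Gate low outliers (blink elimination)
#'
#' Flags samples whose diameter is more than 2 standard deviations *below*
#' the trial mean — the closed/half-closed eye readings that blinks produce.
#' The rule is one-sided (large diameters are never gated here) and strict
#' (a value exactly at mean - 2 SD is retained). Mean and SD are the sample
#' statistics over all finite samples of the trial.
#'
#' @param series numeric vector of diameters (mm), `NA` allowed.
#' @param n_sd gating threshold in standard deviations (default 2).
#' @return logical mask, `TRUE` where the sample is discarded. Missing
#'   samples are `FALSE` (they are gaps already, not gated values).
#' @export
gate_low_outliers <- function(series, n_sd = 2) {
  fin <- is.finite(series)
  if (sum(fin) < 2L) stop("need at least 2 finite samples to estimate spread")
  m <- mean(series[fin])
  s <- stats::sd(series[fin])
  mask <- fin & (series < m - n_sd * s)
  mask
}

#' Gate velocity outliers (blink-edge elimination)
#'
#' Blink gaps are flanked by samples where the eye was captured partially
#' closed; these show up as extreme diameter-change velocities. Velocity is
#' the first difference of diameter over the first difference of time across
#' retained samples (gaps are skipped), assigned to the later sample of each
#' pair. Samples whose velocity deviates from the trial mean velocity by more
#' than 2 SD (two-sided, strict) are flagged. Only the later sample of an
#' outlying velocity pair is gated.
#'
#' @param series numeric diameters (mm).
#' @param time numeric timestamps (s), strictly increasing.
#' @param exclude logical mask of samples to skip when forming velocities
#'   (typically the low-outlier gaps); default none.
#' @param n_sd threshold in standard deviations (default 2).
#' @return logical mask, `TRUE` where the sample is discarded.
#' @export
gate_velocity_outliers <- function(series, time, exclude = NULL, n_sd = 2) {
  n <- length(series)
  if (length(time) != n) stop("`series` and `time` lengths differ")
  if (is.null(exclude)) exclude <- rep(FALSE, n)
  keep <- is.finite(series) & !exclude
  idx <- which(keep)
  if (length(idx) < 3L) stop("need at least 3 retained samples")
  dt <- diff(time[idx])
  if (any(dt <= 0)) stop("timestamps must be strictly increasing (zero dt)")
  v <- diff(series[idx]) / dt
  m <- mean(v)
  s <- stats::sd(v)
  mask <- rep(FALSE, n)
  if (s > 0) {
    bad <- abs(v - m) > n_sd * s
    mask[idx[-1L][bad]] <- TRUE
  }
  mask
}

#' Fill gaps by linear interpolation
#'
#' Interior gaps are interpolated linearly against time between the nearest
#' retained samples; leading/trailing gaps take the nearest retained value.
#' Interpolated values therefore never leave the range of their bracketing
#' retained values.
#'
#' @param series numeric vector with values at retained samples (`NA`
#'   elsewhere is fine).
#' @param gap_mask logical, `TRUE` where the sample was discarded.
#' @param time numeric timestamps (s).
#' @return numeric vector with all gaps filled.
#' @export
fill_gaps <- function(series, gap_mask, time) {
  keep <- !gap_mask & !is.na(series)
  if (!any(keep)) stop("all samples are gated; nothing to interpolate from")
  if (all(keep)) return(series)
  if (sum(keep) == 1L) return(rep(series[keep], length(series)))
  stats::approx(time[keep], series[keep], xout = time, rule = 2)$y
}

#' Baseline summary statistics
#'
#' Applies binocular averaging and low-outlier (blink) gating to a resting
#' baseline recording, then summarises the retained samples. The baseline
#' mean is what performance traces are differenced against.
#'
#' @param baseline a [pupil_trace()] of the baseline occasion.
#' @param n_sd blink-gating threshold (default 2 SD).
#' @return list of class `baseline_stat` with `subject`, `occasion`,
#'   `mean_diameter`, `sd_diameter`, `n_samples`.
#' @export
baseline_stats <- function(baseline, n_sd = 2) {
  em <- binocular_mean(baseline)
  mask <- gate_low_outliers(em, n_sd = n_sd)
  kept <- em[is.finite(em) & !mask]
  if (length(kept) < 1L) stop("no retained baseline samples")
  structure(list(subject = baseline$subject, occasion = baseline$trial,
                 mean_diameter = mean(kept),
                 sd_diameter = if (length(kept) > 1L) stats::sd(kept) else 0,
                 n_samples = length(kept)),
            class = "baseline_stat")
}

#' @export
print.baseline_stat <- function(x, ...) {
  cat(sprintf("<baseline_stat> %s/%s: M = %.3f mm, SD = %.3f mm, n = %d\n",
              x$subject, x$occasion, x$mean_diameter, x$sd_diameter,
              x$n_samples))
  invisible(x)
}

#' Full pupil cleaning chain
#'
#' Runs, in order: binocular averaging, low-outlier gating, velocity-outlier
#' gating, Savitzky-Golay smoothing of the retained samples, linear gap
#' interpolation, and differencing against the baseline mean diameter. The
#' result keeps the original sampling grid; `gap_mask` records every sample
#' that was discarded (or originally missing) and then interpolated.
#'
#' @param trace a [pupil_trace()] of the performance.
#' @param baseline a `baseline_stat` (see [baseline_stats()]), or `NULL` to
#'   skip baseline differencing.
#' @param order,window Savitzky-Golay parameters (defaults 3 and 11).
#' @param n_sd gating threshold in SD for both gates (default 2).
#' @param velocity_on_raw if `TRUE`, velocity statistics are computed on the
#'   series before low-outlier removal (default `FALSE`: blink zeros would
#'   otherwise dominate the velocity SD).
#' @return object of class `clean_trace`: `time`, `diameter`
#'   (baseline-differenced mm), `gap_mask`, `provenance`, `subject`, `trial`.
#' @export
preprocess_trace <- function(trace, baseline = NULL, order = 3L, window = 11L,
                             n_sd = 2, velocity_on_raw = FALSE) {
  stopifnot(inherits(trace, "pupil_trace"))
  if (!is.null(baseline) && !inherits(baseline, "baseline_stat")) {
    stop("`baseline` must be a baseline_stat (see baseline_stats())")
  }
  em <- binocular_mean(trace)
  miss <- !is.finite(em)
  low <- gate_low_outliers(em, n_sd = n_sd)
  vel_excl <- if (velocity_on_raw) miss else (miss | low)
  vel <- gate_velocity_outliers(em, trace$time, exclude = vel_excl, n_sd = n_sd)
  gap <- miss | low | vel

  sm <- rep(NA_real_, length(em))
  idx <- which(!gap)
  if (length(idx) < window) {
    stop("fewer retained samples (", length(idx), ") than the smoothing ",
         "window (", window, ")")
  }
  sm[idx] <- savgol_smooth(em[idx], order = order, window = window)
  filled <- fill_gaps(sm, gap, trace$time)
  diam <- if (is.null(baseline)) filled else filled - baseline$mean_diameter

  prov <- c("binocular_mean",
            sprintf("gate_low_outliers(n_sd=%g)", n_sd),
            sprintf("gate_velocity_outliers(n_sd=%g, on_raw=%s)", n_sd,
                    velocity_on_raw),
            sprintf("savgol_smooth(order=%d, window=%d)", order, window),
            "fill_gaps",
            if (is.null(baseline)) "no_baseline"
            else sprintf("subtract_baseline(%.4f)", baseline$mean_diameter))
  structure(list(time = trace$time, diameter = diam, gap_mask = gap,
                 provenance = prov, subject = trace$subject,
                 trial = trace$trial),
            class = "clean_trace")
}

#' @export
print.clean_trace <- function(x, ...) {
  cat("<clean_trace>", length(x$time), "samples,",
      sum(x$gap_mask), "interpolated |", x$subject, "/", x$trial, "\n")
  invisible(x)
}

#' Write a cleaned trace to CSV (`t_sec,diameter_mm,gap`)
#' @param clean a `clean_trace`.
#' @param path output path.
#' @export
write_clean_csv <- function(clean, path) {
  utils::write.csv(data.frame(t_sec = clean$time,
                              diameter_mm = clean$diameter,
                              gap = as.integer(clean$gap_mask)),
                   path, row.names = FALSE)
  invisible(path)
}
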