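# Synthetic study generator: scores, ratings, motion capture, audio, and
# pupil traces with known ground truth, so that every pipeline stage can be
# verified without access to any recordings.

# run expr with a temporary RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE)) {
            rm(".Random.seed", envir = globalenv())
          })
  set.seed(seed)
  force(expr)
}

#' Derive a named substream seed
#'
#' All randomness in the generator flows from one root seed through named
#' substreams (one per subject/piece/stream), so each stream is reproducible
#' in isolation. The derivation is a small deterministic string hash folded
#' with the root seed, kept within the 32-bit integer range.
#'
#' @param seed integer root seed.
#' @param name substream name.
#' @return integer seed.
#' @export
substream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147480009
  as.integer((h + (as.numeric(seed) %% 2147480009) * 2654435) %% 2147480009)
}

#' Ground-truth parameters of the synthetic study
#'
#' The generative counterpart of the fitted model: fixed-effect coefficients
#' `beta` (mm per predictor unit), AR(1) parameters for the bar-level serial
#' process, crossed random-intercept SDs for subject and piece, the resting
#' baseline diameter, blink contamination parameters, and the eye-tracker
#' measurement noise (a free parameter, not an estimate of any device).
#'
#' @param beta named numeric vector of coefficients (mm per predictor unit).
#' @param rho AR(1) correlation, in `[0, 1)`.
#' @param sigma_ar SD of the AR(1) process (mm).
#' @param sigma_e iid per-bar residual SD (mm).
#' @param sigma_subject,sigma_piece random-intercept SDs (mm).
#' @param baseline_mean resting pupil diameter (mm).
#' @param blink_rate blinks per minute.
#' @param blink_dur blink hold duration (s).
#' @param noise_sd sample-level measurement noise SD (mm).
#' @param seed integer root seed.
#' @export
synth_truth <- function(beta = c(cloud = -0.0192, harmonic = -0.0120,
                                 qom_head = 3e-4, sound = 0,
                                 technical = 0.0316, expressive = 0.0098),
                        rho = 0.6, sigma_ar = 0.08, sigma_e = 0.04,
                        sigma_subject = 0.15, sigma_piece = 0.10,
                        baseline_mean = 4.0, blink_rate = 15, blink_dur = 0.2,
                        noise_sd = 0.02, seed = 1L) {
  if (rho < 0 || rho >= 1) stop("`rho` must lie in [0, 1)")
  sds <- c(sigma_ar, sigma_e, sigma_subject, sigma_piece, noise_sd)
  if (any(sds < 0)) stop("all SDs must be non-negative")
  if (blink_rate < 0) stop("`blink_rate` must be non-negative")
  if (is.null(names(beta)) || any(!nzchar(names(beta)))) {
    stop("`beta` must be a named vector")
  }
  structure(list(beta = beta, rho = rho, sigma_ar = sigma_ar,
                 sigma_e = sigma_e, sigma_subject = sigma_subject,
                 sigma_piece = sigma_piece, baseline_mean = baseline_mean,
                 blink_rate = blink_rate, blink_dur = blink_dur,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_truth")
}

#' Generate a spelled multi-part score
#'
#' Each part performs a bounded random walk on the line of fifths, emitting
#' one to three notes per bar on a regular beat grid (plus occasional
#' whole-bar notes that sustain), so every bar of every part contains at
#' least one note and all pitches carry explicit spelling.
#'
#' @param n_bars,n_parts positive integers.
#' @param seed integer seed.
#' @return list with `notes` (a [note_events()] data frame) and `clouds`
#'   (per-bar list of distinct fifths indices by onset).
#' @export
gen_score <- function(n_bars, n_parts, seed = 1L) {
  n_bars <- as.integer(n_bars)
  n_parts <- as.integer(n_parts)
  if (n_bars < 1L || n_parts < 1L) {
    stop("`n_bars` and `n_parts` must be positive")
  }
  step_of <- c("F", "C", "G", "D", "A", "E", "B")
  with_seed(substream_seed(seed, "score"), {
    rows <- vector("list", n_bars * n_parts)
    ri <- 0L
    for (p in seq_len(n_parts)) {
      centre <- sample(-3:3, 1L)
      for (b in seq_len(n_bars)) {
        centre <- max(-8L, min(10L, centre + sample(-1:1, 1L)))
        whole <- stats::runif(1) < 0.15
        if (whole) {
          nn <- 1L
          beats <- 0
          durs <- stats::runif(1, 1, 1.75)   # sustains into the next bar
        } else {
          nn <- sample(1:3, 1L)
          beats <- (seq_len(nn) - 1L) / nn
          durs <- rep(1 / nn, nn)
        }
        k <- centre + sample(-2:2, nn, replace = TRUE)
        alter <- floor((k + 1) / 7)
        base <- k - 7L * alter
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          part = sprintf("P%d", p), bar = b, beat = beats, duration = durs,
          step = step_of[base + 2L], alter = alter,
          octave = sample(3:5, nn, replace = TRUE),
          stringsAsFactors = FALSE)
      }
    }
    d <- do.call(rbind, rows[seq_len(ri)])
    notes <- note_events(d$part, d$bar, d$beat, d$duration, d$step, d$alter,
                         d$octave)
    clouds <- lapply(seq_len(n_bars), function(b) {
      nb <- notes[notes$bar == b, ]
      unique(fifths_index(nb$step, nb$alter))
    })
    list(notes = notes, clouds = clouds)
  })
}

#' Generate per-bar predictor targets
#'
#' Independent per-bar series: three integer rating measures on the 1-7
#' scale (a discretised normal centred on 4), strictly positive target
#' quantities of motion for head and arms (mm/s summed per bar), and target
#' per-bar RMS sound levels in `(0, 0.5]`.
#'
#' @param n_bars positive integer.
#' @param seed integer seed.
#' @return data frame with columns `bar`, `technical`, `harmonic`,
#'   `expressive`, `qom_head_target`, `qom_arms_target`, `rms_target`.
#' @export
gen_bar_predictors <- function(n_bars, seed = 1L) {
  n_bars <- as.integer(n_bars)
  if (n_bars < 1L) stop("`n_bars` must be positive")
  with_seed(substream_seed(seed, "predictors"), {
    rating <- function() {
      pmin(7L, pmax(1L, as.integer(round(stats::rnorm(n_bars, 4, 1.5)))))
    }
    data.frame(
      bar = seq_len(n_bars),
      technical = rating(), harmonic = rating(), expressive = rating(),
      qom_head_target = exp(stats::rnorm(n_bars, log(1000), 0.25)),
      qom_arms_target = exp(stats::rnorm(n_bars, log(1500), 0.25)),
      rms_target = pmin(0.5, exp(stats::rnorm(n_bars, log(0.15), 0.3))))
  })
}

#' Generate a raw binocular pupil trace from known predictors
#'
#' The per-bar latent response is
#' `baseline_mean + sum(beta * predictor) + subject/piece offsets + AR(1) +
#' iid noise`. The sample-level reference trace holds each bar's latent mean
#' piecewise-constant and low-pass smooths it (the models only consume
#' per-bar means, so finer temporal structure is a free choice); the raw
#' trace adds per-eye measurement noise and blink dropouts in both eyes,
#' each ramping to near zero over two samples, holding for `blink_dur`, and
#' ramping back — giving the velocity gate realistic partially-closed edge
#' samples to remove.
#'
#' @param timeline a [bar_timeline()].
#' @param predictors data frame with a `bar` column and one column per name
#'   of `truth$beta`, covering every bar of the timeline.
#' @param truth a [synth_truth()].
#' @param fs sampling rate in Hz (default 60).
#' @param seed integer seed.
#' @param subject_offset,piece_offset random-intercept values in mm
#'   (defaults 0; drawn by [gen_full_study()]).
#' @return list with `raw` (a [pupil_trace()]), `reference` (the clean
#'   sample-level series, mm), `bar_means` (latent per-bar means, mm),
#'   `time`, and `n_blinks`.
#' @export
gen_pupil <- function(timeline, predictors, truth, fs = 60, seed = 1L,
                      subject_offset = 0, piece_offset = 0) {
  stopifnot(inherits(timeline, "bar_timeline"), inherits(truth, "synth_truth"))
  if (fs <= 0) stop("`fs` must be positive")
  nb <- timeline$n_bars
  need <- names(truth$beta)
  miss <- setdiff(c("bar", need), names(predictors))
  if (length(miss)) {
    stop("predictors missing columns: ", paste(miss, collapse = ", "))
  }
  pb <- predictors[match(seq_len(nb), predictors$bar), , drop = FALSE]
  if (anyNA(pb$bar)) {
    stop("predictors missing bar(s): ",
         paste(setdiff(seq_len(nb), predictors$bar), collapse = ", "))
  }
  with_seed(substream_seed(seed, "pupil"), {
    X <- as.matrix(pb[need])
    ar <- numeric(nb)
    if (truth$sigma_ar > 0) {
      ar[1L] <- stats::rnorm(1, 0, truth$sigma_ar)
      innov_sd <- truth$sigma_ar * sqrt(1 - truth$rho^2)
      for (b in seq_len(nb)[-1L]) {
        ar[b] <- truth$rho * ar[b - 1L] + stats::rnorm(1, 0, innov_sd)
      }
    }
    bar_means <- truth$baseline_mean + subject_offset + piece_offset +
      as.numeric(X %*% truth$beta) + ar +
      stats::rnorm(nb, 0, truth$sigma_e)

    t <- seq(timeline$onsets[1L], timeline$end_time - 1e-9, by = 1 / fs)
    bidx <- assign_bars(t, timeline)
    bidx[bidx == 0L] <- 1L
    lp <- max(3L, 2L * as.integer(round(fs / 8)) + 1L)   # ~0.25 s low-pass
    lp_kern <- signal::hamming(lp)
    # pre-compensate the per-bar levels for the smoothing the signal will
    # undergo (the generator's low-pass plus the analysis Savitzky-Golay),
    # so that per-bar means extracted downstream equal the latent means
    # rather than a neighbour-leaked version of them
    levels <- compensate_bar_levels(bar_means, bidx, t, timeline, lp_kern)
    ref <- conv_same_renorm(levels[bidx], lp_kern)

    left <- ref + stats::rnorm(length(ref), 0, truth$noise_sd)
    right <- ref + stats::rnorm(length(ref), 0, truth$noise_sd)
    dur_min <- (timeline$end_time - timeline$onsets[1L]) / 60
    n_blinks <- if (truth$blink_rate > 0) {
      stats::rpois(1, truth$blink_rate * dur_min)
    } else 0L
    hold <- max(1L, as.integer(round(truth$blink_dur * fs)))
    if (n_blinks > 0L) {
      starts <- sort(sample.int(length(t) - hold - 4L, n_blinks))
      for (s in starts) {
        idx_ramp_in <- s + 0:1
        idx_hold <- s + 2:(1L + hold)
        idx_ramp_out <- s + (2L + hold):(3L + hold)
        # entry edge: first sample only partially closed, so it passes the
        # low gate and must be caught by its extreme entry velocity; the
        # exit ramp reopens from below the low-outlier threshold so the
        # whole episode ends up in the gap mask
        shape_in <- c(0.55, 0.15)
        shape_out <- c(0.10, 0.30)
        for (eye in c("left", "right")) {
          v <- get(eye)
          v[idx_ramp_in] <- v[idx_ramp_in] * shape_in
          v[idx_hold] <- 0.02 * v[idx_hold] +
            abs(stats::rnorm(length(idx_hold), 0, 0.01))
          v[idx_ramp_out] <- v[idx_ramp_out] * shape_out
          assign(eye, v)
        }
      }
    }
    left <- pmax(left, 0)
    right <- pmax(right, 0)
    list(raw = pupil_trace(t, left, right), reference = ref,
         bar_means = bar_means, time = t, n_blinks = n_blinks)
  })
}

# Solve for per-bar sample levels such that, after the generator's low-pass
# and the default pupil Savitzky-Golay smoothing, the per-bar means of the
# smoothed trace equal `bar_means`. The combined kernel is unit-sum, so its
# bar-mixing matrix M has unit row sums and the system is well conditioned;
# with (near-)uniform bars M is Toeplitz and one indicator column yields the
# whole stencil.
compensate_bar_levels <- function(bar_means, bidx, t, timeline, lp_kern,
                                  sg_order = 3L, sg_window = 11L) {
  nb <- timeline$n_bars
  if (nb == 1L) return(bar_means)
  sg <- savgol_coefficients(sg_order, sg_window, 0L)
  comb <- conv_full(lp_kern / sum(lp_kern), sg)
  counts <- tabulate(bidx, nb)
  uniform <- max(counts) - min(counts) <= 1L
  if (uniform && nb >= 5L) {
    b0 <- nb %/% 2L
    sm <- conv_same_renorm(as.numeric(bidx == b0), comb)
    col <- per_bar_aggregate(sm, t, timeline, stat = "mean")
    col[is.na(col)] <- 0
    M <- matrix(0, nb, nb)
    for (b in seq_len(nb)) {
      shifted <- col[pmax(pmin(seq_len(nb) - b + b0, nb), 1L)]
      shifted[seq_len(nb) - b + b0 < 1L | seq_len(nb) - b + b0 > nb] <- 0
      M[, b] <- shifted
    }
    # renormalise rows: edge truncation makes the shifted stencil lossy
    M <- M / rowSums(M)
  } else {
    M <- matrix(0, nb, nb)
    for (b in seq_len(nb)) {
      sm <- conv_same_renorm(as.numeric(bidx == b), comb)
      M[, b] <- per_bar_aggregate(sm, t, timeline, stat = "mean")
    }
    M[!is.finite(M)] <- 0
  }
  g <- try(solve(M, bar_means), silent = TRUE)
  if (inherits(g, "try-error") || !all(is.finite(g))) return(bar_means)
  g
}

#' Generate marker trajectories with controllable per-bar speed
#'
#' Each marker moves on a large circle at a per-bar angular rate chosen so
#' that the per-bar sum of speeds equals the requested quantity-of-motion
#' target; the path is smooth, so Savitzky-Golay differentiation with the
#' analysis settings recovers the targets to within a few percent. The six
#' markers mirror the study layout (head, upper back, two per arm); head
#' markers are calibrated to `qom_targets` and arm markers to `arm_targets`.
#'
#' @param timeline a [bar_timeline()].
#' @param qom_targets per-bar head QoM targets (mm/s summed per bar,
#'   `>= 0`).
#' @param fs sampling rate (default 120 Hz).
#' @param seed integer seed.
#' @param arm_targets per-bar arm QoM targets (default `qom_targets`).
#' @param performer performer identifier.
#' @return list of [marker_track()]s.
#' @export
gen_mocap <- function(timeline, qom_targets, fs = 120, seed = 1L,
                      arm_targets = qom_targets,
                      performer = NA_character_) {
  stopifnot(inherits(timeline, "bar_timeline"))
  if (fs <= 0) stop("`fs` must be positive")
  if (length(qom_targets) != timeline$n_bars ||
      length(arm_targets) != timeline$n_bars) {
    stop("targets must have length n_bars")
  }
  if (any(qom_targets < 0) || any(arm_targets < 0)) {
    stop("QoM targets must be non-negative")
  }
  t <- seq(timeline$onsets[1L], timeline$end_time - 1e-9, by = 1 / fs)
  bidx <- assign_bars(t, timeline)
  bidx[bidx == 0L] <- 1L
  n_per_bar <- tabulate(bidx, timeline$n_bars)
  markers <- data.frame(
    marker = c("head", "back", "arm_upper_L", "arm_lower_L",
               "arm_upper_R", "arm_lower_R"),
    segment = c("head", "back", "arm_upper", "arm_lower",
                "arm_upper", "arm_lower"),
    stringsAsFactors = FALSE)
  with_seed(substream_seed(seed, paste0("mocap:", performer)), {
    lapply(seq_len(nrow(markers)), function(i) {
      seg <- markers$segment[i]
      targ <- if (seg == "head") qom_targets
              else if (seg == "back") qom_targets
              else arm_targets
      v_bar <- ifelse(n_per_bar > 0, targ / pmax(n_per_bar, 1L), 0)
      v <- v_bar[bidx]                       # mm/s, piecewise per bar
      radius <- stats::runif(1, 150, 250)
      phase <- stats::runif(1, 0, 2 * pi)
      theta <- phase + cumsum(v) / (radius * fs)
      centre <- stats::runif(3, -500, 500)
      marker_track(t,
                   x = centre[1L] + radius * cos(theta),
                   y = centre[2L] + radius * sin(theta),
                   z = centre[3L] + 0 * t,
                   marker = markers$marker[i], segment = seg,
                   performer = performer)
    })
  })
}

#' Generate noise-carrier audio with controllable per-bar RMS
#'
#' Uniform-noise audio with a piecewise-constant per-bar gain. The gains are
#' calibrated against the extraction chain itself: the bar-to-bar mixing
#' induced by framing and Hamming smoothing (at the analysis settings) is
#' measured on per-bar indicator envelopes, and the resulting linear system
#' is solved so that the smoothed per-bar sound level recovers the requested
#' targets. A target above 1 is unreachable without clipping and raises an
#' error. The clip starts at the timeline's first bar onset.
#'
#' @param timeline a [bar_timeline()].
#' @param rms_targets per-bar RMS targets in `(0, 1]`.
#' @param sr sample rate in Hz (`>= 8000`).
#' @param seed integer seed.
#' @param frame,overlap,smooth_window extraction settings the gains are
#'   calibrated for (defaults: frame 2048, 50% overlap, 50-sample Hamming).
#' @return an [audio_clip()].
#' @export
gen_audio <- function(timeline, rms_targets, sr = 22050, seed = 1L,
                      frame = 2048L, overlap = 0.5, smooth_window = 50L) {
  stopifnot(inherits(timeline, "bar_timeline"))
  if (sr < 8000) stop("`sr` must be at least 8000 Hz")
  if (length(rms_targets) != timeline$n_bars) {
    stop("targets must have length n_bars")
  }
  if (any(rms_targets > 1)) {
    stop("RMS target above 1 would clip the normalised signal")
  }
  if (any(rms_targets < 0)) stop("RMS targets must be non-negative")
  t <- seq(timeline$onsets[1L], timeline$end_time - 1e-9, by = 1 / sr)
  bidx <- assign_bars(t, timeline)
  bidx[bidx == 0L] <- 1L

  nb <- timeline$n_bars
  gains <- rms_targets
  if (nb > 1L) {
    # frame-centre grid exactly as rms_frames() lays it out
    hop <- max(1L, as.integer(round(frame * (1 - overlap))))
    starts <- seq.int(1L, length(t) - frame + 1L, by = hop)
    centres <- timeline$onsets[1L] + (starts - 1 + frame / 2) / sr
    fbar <- assign_bars(centres, timeline)
    kern <- signal::hamming(smooth_window)
    mix <- matrix(0, nb, nb)
    for (b in seq_len(nb)) {
      sm <- conv_same_renorm(as.numeric(fbar == b), kern)
      mix[, b] <- per_bar_aggregate(sm, centres, timeline, stat = "mean")
    }
    mix[!is.finite(mix)] <- 0
    g <- try(solve(mix, rms_targets), silent = TRUE)
    if (!inherits(g, "try-error") && all(is.finite(g))) {
      gains <- pmin(pmax(g, 0), 1)
    }
  }

  gain <- gains[bidx]
  with_seed(substream_seed(seed, "audio"), {
    u <- stats::runif(length(t), -1, 1)
    peak <- max(gain) * sqrt(3)
    x <- if (peak <= 1) {
      gain * sqrt(3) * u                    # uniform carrier, RMS = gain
    } else {
      p <- (1 / pmax(gain, 1e-12)^2 - 1) / 2
      pmax(-1, pmin(1, sign(u) * abs(u)^p)) # peaky carrier, RMS = gain
    }
    audio_clip(x, sr)
  })
}

#' Default synthetic-study configuration
#'
#' The study conditions: four performers and four pieces (with per-trial
#' baselines plus first-rehearsal and pre-concert baseline occasions),
#' sixteen listeners, 60 Hz pupil sampling, 120 Hz motion capture, 22.05 kHz
#' audio, and two-second bars.
#'
#' @param n_performers,n_listeners,n_pieces,n_bars study dimensions.
#' @param bar_dur bar duration in seconds.
#' @param fs_pupil,fs_mocap,sr_audio sampling rates (Hz).
#' @param baseline_dur baseline recording duration (s).
#' @param truth a [synth_truth()].
#' @export
synth_config <- function(n_performers = 4L, n_listeners = 16L, n_pieces = 4L,
                         n_bars = 96L, bar_dur = 2, fs_pupil = 60,
                         fs_mocap = 120, sr_audio = 22050, baseline_dur = 60,
                         truth = synth_truth()) {
  list(n_performers = as.integer(n_performers),
       n_listeners = as.integer(n_listeners),
       n_pieces = as.integer(n_pieces), n_bars = as.integer(n_bars),
       bar_dur = bar_dur, fs_pupil = fs_pupil, fs_mocap = fs_mocap,
       sr_audio = sr_audio, baseline_dur = baseline_dur, truth = truth)
}

gen_baseline_trace <- function(subject, occasion, truth, fs, dur, seed) {
  with_seed(substream_seed(seed, paste0("baseline:", subject, ":", occasion)), {
    t <- seq(0, dur - 1e-9, by = 1 / fs)
    # the resting level is the truth baseline itself: per-subject departures
    # from rest live in the subject random intercept of the performance
    # trace, so baseline differencing isolates exactly the latent predictor
    level <- truth$baseline_mean
    left <- level + stats::rnorm(length(t), 0, truth$noise_sd)
    right <- level + stats::rnorm(length(t), 0, truth$noise_sd)
    nb <- stats::rpois(1, truth$blink_rate * dur / 60)
    hold <- max(1L, as.integer(round(truth$blink_dur * fs)))
    if (nb > 0) {
      for (s in sort(sample.int(length(t) - hold - 4L, nb))) {
        idx <- s:(s + 3L + hold)
        left[idx] <- left[idx] * 0.05
        right[idx] <- right[idx] * 0.05
      }
    }
    pupil_trace(t, pmax(left, 0), pmax(right, 0), subject = subject,
                trial = occasion)
  })
}

#' Generate and write a complete synthetic study
#'
#' Builds scores, timelines, ratings, motion capture, audio, and performer
#' and listener pupil traces for a whole study, writes them as the on-disk
#' tree the pipeline consumes, and records the ground truth as JSON. The
#' per-bar predictors that drive each pupil trace are the features actually
#' extracted from the generated streams by the package's own feature modules
#' (with the analysis settings), so model fits on pipeline output estimate
#' the very coefficients stored in the truth record. Listener traces are
#' driven by the performer-averaged predictors.
#'
#' @param config a [synth_config()].
#' @param seed integer root seed (overrides `config$truth$seed`).
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the truth record, per-piece timelines and
#'   the per-(subject, piece) predictor tables used.
#' @export
gen_full_study <- function(config = synth_config(), seed = config$truth$seed,
                           dir) {
  if (missing(dir)) stop("`dir` is required")
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory ", dir)
  for (sub in c("pupil", "baseline", "mocap", "audio", "score", "ratings",
                "timelines")) {
    dir.create(file.path(dir, sub), showWarnings = FALSE)
  }
  truth <- config$truth
  truth$seed <- as.integer(seed)
  performers <- sprintf("p%d", seq_len(config$n_performers))
  listeners <- if (config$n_listeners > 0) {
    sprintf("l%02d", seq_len(config$n_listeners))
  } else character(0)
  pieces <- sprintf("piece%d", seq_len(config$n_pieces))

  offs_subj <- with_seed(substream_seed(seed, "offsets:subject"),
    stats::setNames(stats::rnorm(length(c(performers, listeners)), 0,
                                 truth$sigma_subject),
                    c(performers, listeners)))
  offs_piece <- with_seed(substream_seed(seed, "offsets:piece"),
    stats::setNames(stats::rnorm(length(pieces), 0, truth$sigma_piece),
                    pieces))

  seg_map <- c(head = "head", back = "back",
               arm_upper_L = "arm_upper", arm_lower_L = "arm_lower",
               arm_upper_R = "arm_upper", arm_lower_R = "arm_lower")
  predictor_tables <- list()
  listener_pred <- list()

  for (pc in pieces) {
    tl <- bar_timeline(seq(0, by = config$bar_dur,
                           length.out = config$n_bars),
                       config$n_bars * config$bar_dur, piece = pc)
    write_timeline_csv(tl, file.path(dir, "timelines",
                                     paste0(pc, ".csv")))
    sc <- gen_score(config$n_bars, 4L, substream_seed(seed, paste0("score:", pc)))
    write_musicxml(sc$notes, file.path(dir, "score",
                                       paste0(pc, ".musicxml")))
    cloud <- cloud_diameter_per_bar(sc$notes, config$n_bars)

    # one audio stream per piece
    pp0 <- gen_bar_predictors(config$n_bars,
                              substream_seed(seed, paste0("piecepred:", pc)))
    clip <- gen_audio(tl, pp0$rms_target, sr = config$sr_audio,
                      seed = substream_seed(seed, paste0("audio:", pc)))
    write_wav(clip, file.path(dir, "audio", paste0(pc, ".wav")))
    env <- smooth_envelope(rms_frames(clip))
    sound <- sound_level_per_bar(env, tl)

    per_perf <- list()
    for (pf in performers) {
      pp <- gen_bar_predictors(config$n_bars,
                               substream_seed(seed, paste0("pred:", pf, ":", pc)))
      tracks <- gen_mocap(tl, pp$qom_head_target, fs = config$fs_mocap,
                          seed = substream_seed(seed, paste0("mocap:", pf, ":", pc)),
                          arm_targets = pp$qom_arms_target, performer = pf)
      write_mocap_tsv(tracks, file.path(dir, "mocap",
                                        paste0(pf, "_", pc, ".tsv")))
      qh <- qom(segment_speed(tracks, "head"), tl)
      qa <- qom(segment_speed(tracks, "arms"), tl)
      pred <- data.frame(bar = pp$bar, cloud = cloud,
                         harmonic = pp$harmonic, technical = pp$technical,
                         expressive = pp$expressive, qom_head = qh,
                         qom_arms = qa, sound = sound)
      gp <- gen_pupil(tl, pred, truth, fs = config$fs_pupil,
                      seed = substream_seed(seed, paste0("pupil:", pf, ":", pc)),
                      subject_offset = offs_subj[[pf]],
                      piece_offset = offs_piece[[pc]])
      write_pupil_csv(gp$raw, file.path(dir, "pupil",
                                        paste0(pf, "_", pc, ".csv")))
      write_pupil_csv(
        gen_baseline_trace(pf, pc, truth, config$fs_pupil,
                           config$baseline_dur, seed),
        file.path(dir, "baseline", paste0(pf, "_", pc, ".csv")))
      per_perf[[pf]] <- pred
      predictor_tables[[paste0(pf, "_", pc)]] <- pred
    }

    # listener predictors: performer-averaged ratings and QoM
    avg <- function(col) {
      rowMeans(do.call(cbind, lapply(per_perf, `[[`, col)))
    }
    lp <- data.frame(bar = seq_len(config$n_bars), cloud = cloud,
                     harmonic = avg("harmonic"), technical = avg("technical"),
                     expressive = avg("expressive"),
                     qom_head = avg("qom_head"), qom_arms = avg("qom_arms"),
                     sound = sound)
    listener_pred[[pc]] <- lp
    for (ls in listeners) {
      gp <- gen_pupil(tl, lp, truth, fs = config$fs_pupil,
                      seed = substream_seed(seed, paste0("pupil:", ls, ":", pc)),
                      subject_offset = offs_subj[[ls]],
                      piece_offset = offs_piece[[pc]])
      write_pupil_csv(gp$raw, file.path(dir, "pupil",
                                        paste0(ls, "_", pc, ".csv")))
      write_pupil_csv(
        gen_baseline_trace(ls, pc, truth, config$fs_pupil,
                           config$baseline_dur, seed),
        file.path(dir, "baseline", paste0(ls, "_", pc, ".csv")))
    }
  }

  # ratings files (long format, integer 1-7 values used as predictors)
  for (pf in performers) {
    rows <- list()
    for (pc in pieces) {
      pred <- predictor_tables[[paste0(pf, "_", pc)]]
      for (m in c("technical", "harmonic", "expressive")) {
        rows[[length(rows) + 1L]] <- data.frame(
          performer = pf, piece = pc, measure = m, bar = pred$bar,
          value = pred[[m]])
      }
    }
    utils::write.csv(do.call(rbind, rows),
                     file.path(dir, "ratings", paste0(pf, ".csv")),
                     row.names = FALSE)
  }

  # occasion-level baselines for the rehearsal-vs-concert comparison
  for (pf in performers) {
    for (occ in c("first_rehearsal", "pre_concert")) {
      write_pupil_csv(
        gen_baseline_trace(pf, occ, truth, config$fs_pupil,
                           config$baseline_dur, seed),
        file.path(dir, "baseline", paste0(pf, "_", occ, ".csv")))
    }
  }

  manifest <- list(performers = performers, listeners = listeners,
                   pieces = pieces, n_bars = config$n_bars,
                   bar_dur = config$bar_dur, fs_pupil = config$fs_pupil,
                   fs_mocap = config$fs_mocap, sr_audio = config$sr_audio,
                   segment_map = as.list(seg_map))
  yaml::write_yaml(manifest, file.path(dir, "config.yaml"))
  truth_rec <- c(truth[setdiff(names(truth), "beta")],
                 list(beta = as.list(truth$beta),
                      subject_offsets = as.list(offs_subj),
                      piece_offsets = as.list(offs_piece)))
  jsonlite::write_json(truth_rec, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(truth = truth, performers = performers,
                 listeners = listeners, pieces = pieces,
                 predictors = predictor_tables,
                 listener_predictors = listener_pred, dir = dir))
}
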