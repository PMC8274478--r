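#' Mono audio clip
#'
#' Normalised-amplitude audio samples in `[-1, 1]` at a fixed sample rate.
#'
#' @param samples numeric vector, `|samples| <= 1`.
#' @param sr sample rate in Hz.
#' @export
audio_clip <- function(samples, sr) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("empty audio clip")
  if (sr <= 0) stop("sample rate must be positive")
  if (max(abs(samples)) > 1 + 1e-9) {
    stop("samples must be normalised to [-1, 1]")
  }
  structure(list(samples = samples, sr = as.numeric(sr)),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %.2f s at %g Hz (%d samples)\n",
              length(x$samples) / x$sr, x$sr, length(x$samples)))
  invisible(x)
}

#' Framed RMS envelope
#'
#' Root-mean-square amplitude over sliding frames — the sound-level measure.
#' Defaults follow the analysis settings: 2048-sample frames with 50%
#' overlap. Frame times are anchored at frame centres so that a frame's
#' energy is attributed symmetrically when assigned to bars.
#'
#' @param clip an [audio_clip()].
#' @param frame frame size in samples (default 2048).
#' @param overlap fractional overlap in `[0, 1)` (default 0.5).
#' @return object of class `envelope`: `time` (frame centres, s), `rms`,
#'   `frame`, `hop`.
#' @export
rms_frames <- function(clip, frame = 2048L, overlap = 0.5) {
  stopifnot(inherits(clip, "audio_clip"))
  frame <- as.integer(frame)
  if (overlap < 0 || overlap >= 1) stop("`overlap` must be in [0, 1)")
  n <- length(clip$samples)
  if (n < frame) stop("clip shorter than one frame")
  hop <- max(1L, as.integer(round(frame * (1 - overlap))))
  starts <- seq.int(1L, n - frame + 1L, by = hop)
  cs <- c(0, cumsum(clip$samples^2))
  rms <- sqrt((cs[starts + frame] - cs[starts]) / frame)
  structure(list(time = (starts - 1 + frame / 2) / clip$sr, rms = rms,
                 frame = frame, hop = hop),
            class = "envelope")
}

#' @export
print.envelope <- function(x, ...) {
  cat(sprintf("<envelope> %d frames (frame %d, hop %d)\n",
              length(x$rms), x$frame, x$hop))
  invisible(x)
}

#' Smooth an RMS envelope with a Hamming window
#'
#' Convolution with a Hamming kernel normalised to unit sum (so the envelope
#' keeps its RMS units); output has the same length as the input and edges
#' use the renormalised truncated kernel. Default window: 50 envelope
#' samples.
#'
#' @param env an `envelope` (see [rms_frames()]).
#' @param window Hamming window length in envelope samples (default 50).
#' @return an `envelope` with smoothed `rms`.
#' @export
smooth_envelope <- function(env, window = 50L) {
  stopifnot(inherits(env, "envelope"))
  window <- as.integer(window)
  if (window < 1L) stop("`window` must be >= 1")
  if (length(env$rms) < window) stop("envelope shorter than the window")
  kern <- if (window == 1L) 1 else signal::hamming(window)
  env$rms <- conv_same_renorm(env$rms, kern)
  env
}

#' Per-bar sound level
#'
#' Mean of the (smoothed) RMS envelope over the frames whose centres fall in
#' each bar. Bars containing no frame centres yield `NA`.
#'
#' @param env an `envelope`.
#' @param timeline a [bar_timeline()].
#' @return numeric vector of length `n_bars`.
#' @export
sound_level_per_bar <- function(env, timeline) {
  stopifnot(inherits(env, "envelope"))
  per_bar_aggregate(env$rms, env$time, timeline, stat = "mean")
}

#' Write an envelope CSV (`t_sec,rms`)
#' @param env an `envelope`.
#' @param path output path.
#' @export
write_envelope_csv <- function(env, path) {
  utils::write.csv(data.frame(t_sec = env$time, rms = env$rms), path,
                   row.names = FALSE)
  invisible(path)
}
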