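# Minimal RIFF/WAVE reader and writer: 16/24-bit integer PCM and 32-bit
# float, mono or stereo (stereo is collapsed to mono by channel mean on
# read). Amplitudes are normalised to [-1, 1].

#' Read a WAV file
#'
#' Supports PCM 16/24-bit and IEEE float 32-bit; multi-channel input is
#' collapsed to mono by channel mean.
#'
#' @param path WAV file path.
#' @return an [audio_clip()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1L, 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", size)
      fmt <- list(
        format = readBin(raw_fmt[1:2], "integer", 1L, 2L, endian = "little"),
        channels = readBin(raw_fmt[3:4], "integer", 1L, 2L, endian = "little"),
        sr = readBin(raw_fmt[5:8], "integer", 1L, 4L, endian = "little"),
        bits = readBin(raw_fmt[15:16], "integer", 1L, 2L, endian = "little"))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt chunk")
      if (fmt$format == 1L && fmt$bits == 16L) {
        v <- readBin(con, "integer", size / 2L, 2L, signed = TRUE,
                     endian = "little")
        samples <- v / 32768
      } else if (fmt$format == 1L && fmt$bits == 24L) {
        b <- readBin(con, "raw", size)
        i1 <- as.integer(b[seq(1L, length(b), 3L)])
        i2 <- as.integer(b[seq(2L, length(b), 3L)])
        i3 <- as.integer(b[seq(3L, length(b), 3L)])
        v <- i1 + 256 * i2 + 65536 * i3
        v <- ifelse(v >= 8388608, v - 16777216, v)
        samples <- v / 8388608
      } else if (fmt$format == 3L && fmt$bits == 32L) {
        samples <- readBin(con, "numeric", size / 4L, 4L, endian = "little")
      } else {
        stop("unsupported WAV encoding: format ", fmt$format, ", ",
             fmt$bits, " bits")
      }
      if (size %% 2L == 1L) invisible(readBin(con, "raw", 1L))
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  if (fmt$channels > 1L) {
    samples <- colMeans(matrix(samples, nrow = fmt$channels))
  }
  audio_clip(samples, fmt$sr)
}

#' Write an audio clip as 16-bit PCM WAV
#'
#' @param clip an [audio_clip()].
#' @param path output path.
#' @export
write_wav <- function(clip, path) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- pmax(-1, pmin(1, clip$samples))
  v <- pmin(as.integer(round(x * 32768)), 32767L)   # symmetric /32768 scale
  n <- length(v)
  data_size <- 2L * n
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")              # PCM
  writeBin(1L, con, 2L, endian = "little")              # mono
  writeBin(as.integer(clip$sr), con, 4L, endian = "little")
  writeBin(as.integer(clip$sr * 2L), con, 4L, endian = "little")
  writeBin(2L, con, 2L, endian = "little")              # block align
  writeBin(16L, con, 2L, endian = "little")             # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, 4L, endian = "little")
  writeBin(v, con, 2L, endian = "little")
  invisible(path)
}
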