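#' Savitzky-Golay smoothing and differentiation
#'
#' Local least-squares polynomial smoothing. For each sample a polynomial of
#' degree `order` is fitted over a centred window of `window` samples and
#' evaluated (or differentiated) at the sample position. Interior samples use
#' the classical fixed convolution coefficients; at the series edges the
#' polynomial is fitted on the truncated asymmetric window (all samples of the
#' full window that fall inside the series), so the output has the same length
#' as the input and no samples are discarded.
#'
#' @param x numeric vector, no missing values.
#' @param order polynomial order (default 3).
#' @param window odd window length, must exceed `order` (default 11).
#' @param deriv derivative order to return (0 = smoothing, 1 = first
#'   derivative).
#' @param delta sampling interval used to scale derivatives (seconds per
#'   sample; ignored for `deriv = 0`).
#' @return numeric vector of `length(x)`.
#' @examples
#' t <- seq(-1, 1, length.out = 51)
#' y <- t^3 - 2 * t
#' max(abs(savgol_smooth(y) - y)) < 1e-10   # cubics are fixed points
#' @export
savgol_smooth <- function(x, order = 3L, window = 11L, deriv = 0L, delta = 1) {
  order <- as.integer(order)
  window <- as.integer(window)
  deriv <- as.integer(deriv)
  if (window <= order) {
    stop("`window` (", window, ") must be greater than `order` (", order, ")")
  }
  if (window %% 2L == 0L) stop("`window` must be odd")
  if (deriv < 0L || deriv > order) stop("`deriv` must be in [0, order]")
  if (anyNA(x)) stop("`x` must not contain missing values")
  n <- length(x)
  if (n < window) {
    stop("series length (", n, ") must be at least `window` (", window, ")")
  }
  h <- (window - 1L) %/% 2L
  scale <- factorial(deriv) / delta^deriv

  # interior: one coefficient vector from the normal equations, applied as a
  # centred moving filter (C-level convolution)
  coef <- savgol_coefficients(order, window, deriv)
  out <- as.numeric(stats::filter(x, rev(coef), method = "convolution",
                                  sides = 2)) * scale

  # edges: refit on the truncated window
  edge_fit <- function(i) {
    off <- max(1L - i, -h):min(n - i, h)
    if (length(off) < order + 1L) {
      extra <- order + 1L - length(off)
      hi <- min(n - i, max(off) + extra)
      off <- min(off):hi
    }
    A <- outer(off, 0:order, `^`)
    beta <- qr.solve(A, x[i + off])
    beta[deriv + 1L] * scale
  }
  for (i in seq_len(h)) out[i] <- edge_fit(i)
  for (i in (n - h + 1L):n) out[i] <- edge_fit(i)
  out
}

#' Savitzky-Golay convolution coefficients
#'
#' Interior-point coefficients obtained from the polynomial least-squares
#' normal equations over a symmetric window. `sum(coef * x[i + (-h:h)])`
#' estimates the `deriv`-th derivative (up to `factorial(deriv)/delta^deriv`)
#' of the underlying signal at sample `i`.
#'
#' @inheritParams savgol_smooth
#' @return numeric vector of length `window` (offsets `-h:h`).
#' @export
savgol_coefficients <- function(order = 3L, window = 11L, deriv = 0L) {
  h <- (window - 1L) %/% 2L
  A <- outer(-h:h, 0:order, `^`)
  C <- solve(crossprod(A), t(A))
  C[deriv + 1L, ]
}

# full linear convolution via FFT on a padded (highly composite) length
conv_full <- function(x, w) {
  n <- length(x)
  m <- length(w)
  N <- stats::nextn(n + m - 1L)
  y <- Re(stats::fft(stats::fft(c(x, numeric(N - n))) *
                       stats::fft(c(w, numeric(N - m))), inverse = TRUE)) / N
  y[seq_len(n + m - 1L)]
}

# unit-sum windowed convolution with 'same' length and renormalised
# truncated kernel at the edges; kernel centre follows the floor(n/2)+1
# convention so odd kernels are symmetric.
conv_same_renorm <- function(x, kernel) {
  n <- length(x)
  m <- length(kernel)
  w <- kernel / sum(kernel)
  num <- conv_full(x, w)
  # ones convolved with w: ramp of kernel partial sums, flat middle
  cw <- cumsum(w)
  den <- if (n >= m) {
    c(cw, rep(1, n - m), 1 - cw[seq_len(m - 1L)])
  } else {
    conv_full(rep(1, n), w)
  }
  c0 <- m %/% 2L + 1L
  idx <- c0:(c0 + n - 1L)
  num[idx] / den[idx]
}
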