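# IIR filter design and zero-phase filtering.
#
# No DSP package is assumed: the Butterworth low-pass (analog prototype +
# bilinear transform) and a constrained second-order notch are designed here,
# and applied forward-backward for zero phase. Designs are validated in the
# test suite against their analytic magnitude responses.

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0i) - c(0i, p * rt)
  p
}

#' Butterworth low-pass filter design
#'
#' Designs a digital Butterworth low-pass via the bilinear transform with
#' frequency prewarping. DC gain is exactly 1.
#'
#' @param order Filter order (>= 1).
#' @param cutoff_hz -3 dB cutoff frequency in Hz.
#' @param rate Sampling rate in Hz; must exceed `2 * cutoff_hz`.
#' @return List with numerator `b` and denominator `a` coefficient vectors.
#' @export
butter_lowpass <- function(order, cutoff_hz, rate) {
  if (order < 1) stop("order must be >= 1")
  if (cutoff_hz <= 0 || cutoff_hz >= rate / 2)
    stop("cutoff_hz must lie in (0, rate/2); got ", cutoff_hz,
         " at rate ", rate)
  fs2 <- 2 * rate
  wc <- fs2 * tan(pi * cutoff_hz / rate)      # prewarped analog cutoff
  k <- seq_len(order)
  s <- wc * exp(1i * pi * (2 * k + order - 1) / (2 * order))  # LHP poles
  z <- (fs2 + s) / (fs2 - s)                  # bilinear transform
  a <- Re(poly_from_roots(z))
  b <- Re(poly_from_roots(rep(-1 + 0i, order)))
  b <- b * sum(a) / sum(b)                    # unit DC gain
  list(b = b, a = a)
}

#' Second-order IIR notch filter design
#'
#' Places a zero pair exactly on the unit circle at `notch_hz` with poles at
#' radius set by the -3 dB bandwidth, so the notch frequency is annihilated
#' while the passband is left essentially untouched.
#'
#' @param notch_hz Notch centre frequency in Hz.
#' @param rate Sampling rate in Hz.
#' @param bw_hz Approximate -3 dB bandwidth in Hz (default 2).
#' @return List with `b` and `a` coefficient vectors.
#' @export
iir_notch <- function(notch_hz, rate, bw_hz = 2) {
  if (notch_hz <= 0 || notch_hz >= rate / 2)
    stop("notch_hz must lie in (0, rate/2)")
  w0 <- 2 * pi * notch_hz / rate
  r <- 1 - pi * bw_hz / rate
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * r * cos(w0), r^2)
  g <- sum(a) / sum(b)                        # unit DC gain
  list(b = b * g, a = a)
}

# single-pass IIR filter, zero initial conditions
apply_iir <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v[nb:length(v)])
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

#' Zero-phase (forward-backward) IIR filtering
#'
#' Applies the filter forward then backward, cancelling phase distortion and
#' squaring the magnitude response. The series is extended at both ends by
#' odd reflection to suppress edge transients.
#'
#' @param b,a Filter coefficients.
#' @param x Numeric vector.
#' @param pad Reflection pad length; default adapts to the series length.
#' @return Filtered vector, same length as `x`.
#' @export
filtfilt_ba <- function(b, a, x, pad = NULL) {
  n <- length(x)
  if (n < 3) return(x)
  if (is.null(pad)) pad <- min(n - 1, 600L)
  pre <- 2 * x[1] - x[seq(pad + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - pad)]
  xx <- c(pre, x, post)
  y <- apply_iir(b, a, xx)
  y <- rev(apply_iir(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Analytic complex frequency response of a digital filter
#'
#' @param b,a Filter coefficients.
#' @param f Frequencies in Hz at which to evaluate.
#' @param rate Sampling rate in Hz.
#' @return Complex vector `H(e^{i 2 pi f / rate})`.
#' @export
filter_response <- function(b, a, f, rate) {
  w <- 2 * pi * f / rate
  num <- vapply(w, function(wi)
    sum(b * exp(-1i * wi * (seq_along(b) - 1))), complex(1))
  den <- vapply(w, function(wi)
    sum(a * exp(-1i * wi * (seq_along(a) - 1))), complex(1))
  num / den
}

# integer-factor decimation with Butterworth anti-alias low-pass
decimate_signal <- function(x, rate, new_rate, order = 4) {
  if (rate == new_rate) return(x)
  fac <- rate / new_rate
  if (abs(fac - round(fac)) > 1e-9)
    stop("rate (", rate, ") must be an integer multiple of analysis rate (",
         new_rate, ")")
  fac <- as.integer(round(fac))
  d <- butter_lowpass(order, 0.45 * new_rate, rate)
  y <- filtfilt_ba(d$b, d$a, x)
  y[seq(1, length(y), by = fac)]
}
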