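# Morlet continuous wavelet band envelopes.
#
# Each band envelope is the magnitude of complex Morlet coefficients,
# averaged over a small set of log-spaced centre frequencies inside the
# band. The transform is computed in the frequency domain: an analytic
# Gaussian kernel of relative width 1/n_cycles around each centre frequency,
# scaled so a unit-amplitude sinusoid at the centre has unit envelope.

#' Morlet band envelope of an epoch
#'
#' @param samples Numeric matrix, channels x time, at the raw sampling rate.
#' @param rate Sampling rate in Hz.
#' @param band Band name (see [eeg_bands()]) or a `c(lo, hi)` pair in Hz.
#' @param n_cycles Morlet cycle count (time-frequency trade-off, default 6).
#' @param n_scales Centre frequencies per band (default 4, log-spaced).
#' @return Matrix channels x time of nonnegative envelope amplitudes, with
#'   attribute `band`.
#' @export
band_envelope <- function(samples, rate, band, n_cycles = 6, n_scales = 4) {
  if (is.character(band)) {
    rng <- band_range(band)
    name <- band
  } else {
    rng <- c(lo = band[1], hi = band[2])
    name <- paste0(rng[1], "-", rng[2], "Hz")
  }
  if (rng["hi"] >= rate / 2)
    stop("band upper edge ", rng["hi"], " Hz at or above Nyquist (",
         rate / 2, " Hz)")
  samples <- as.matrix(samples)
  n <- ncol(samples)
  freqs <- exp(seq(log(rng["lo"]), log(rng["hi"]), length.out = n_scales))
  fax <- (seq_len(n) - 1) / n * rate            # 0 .. rate
  X <- stats::mvfft(t(samples))                  # time x channels
  acc <- matrix(0, nrow(samples), n)
  for (fc in freqs) {
    sigma_f <- fc / n_cycles
    g <- exp(-((fax - fc)^2) / (2 * sigma_f^2))
    g[fax > rate / 2] <- 0                       # analytic: positive freqs
    g <- 2 * g
    Y <- stats::mvfft(X * g, inverse = TRUE) / n
    acc <- acc + t(Mod(Y))
  }
  # normalize by the bank's response at the band's geometric centre so a
  # unit-amplitude mid-band sinusoid has an envelope near 1 (edge-of-band
  # tones see the bank's ripple; see the methods vignette)
  fmid <- sqrt(rng["lo"] * rng["hi"])
  resp <- mean(exp(-((fmid - freqs)^2) / (2 * (freqs / n_cycles)^2)))
  env <- acc / (n_scales * resp)
  attr(env, "band") <- name
  env
}

#' Band envelopes for all configured bands
#'
#' @param samples Channels x time matrix at the raw rate.
#' @param rate Sampling rate in Hz.
#' @param bands Character vector of band names (default all eight).
#' @inheritParams band_envelope
#' @return Named list of envelope matrices.
#' @export
band_envelopes <- function(samples, rate, bands = band_names(),
                           n_cycles = 6, n_scales = 4) {
  out <- lapply(bands, function(b)
    band_envelope(samples, rate, b, n_cycles, n_scales))
  names(out) <- bands
  out
}
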