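# Internal numeric helpers shared across modules.

rms <- function(x) sqrt(mean(x^2))

#' Rolling sample standard deviation
#'
#' Sample SD (denominator n - 1) over a centered window of `n` samples.
#' For even `n` the window at index i covers samples
#' (i - n/2) .. (i + n/2 - 1); edges where the full window does not fit
#' are returned as NA.
#'
#' @param x numeric vector.
#' @param n window length in samples (>= 2).
#' @return numeric vector the length of `x`, NA at the edges.
#' @keywords internal
#' @noRd
rolling_sd <- function(x, n) {
  len <- length(x)
  if (n > len) {
    stop("rolling window (", n, " samples) is longer than the waveform (",
         len, " samples)")
  }
  if (n < 2) stop("rolling window must span at least 2 samples")
  s1 <- cumsum(x)
  s2 <- cumsum(x * x)
  w1 <- s1[n:len] - c(0, s1[seq_len(len - n)])
  w2 <- s2[n:len] - c(0, s2[seq_len(len - n)])
  v <- (w2 - w1 * w1 / n) / (n - 1)
  v[v < 0] <- 0  # guard against catastrophic cancellation
  out <- rep(NA_real_, len)
  h <- floor(n / 2)
  out[(h + 1):(len - (n - 1 - h))] <- sqrt(v)
  out
}

# Vertex of the parabola through (-1, y1), (0, y2), (1, y3).
# Returns the sub-sample offset (in [-1, 1] for a true extremum at the
# middle sample) and the interpolated extremal value.
parabolic_vertex <- function(y1, y2, y3) {
  d <- y1 - 2 * y2 + y3
  if (d == 0) return(list(offset = 0, value = y2))
  off <- 0.5 * (y1 - y3) / d
  list(offset = off, value = y2 - 0.25 * (y1 - y3) * off)
}

# Spectrally shaped Gaussian noise with power spectral density ~ 1/f above
# `corner` Hz (flat below it). Amplitude is arbitrary; callers rescale.
pink_noise <- function(n, sampling_rate, corner = 0.5) {
  m <- stats::nextn(n, 2)
  k <- m / 2
  f <- seq_len(k) * sampling_rate / m
  shape <- 1 / sqrt(pmax(f, corner))
  z <- complex(real = stats::rnorm(k), imaginary = stats::rnorm(k)) * shape
  spec <- c(0 + 0i, z, Conj(rev(z[seq_len(k - 1)])))
  Re(stats::fft(spec, inverse = TRUE))[seq_len(n)]
}

# Round-trip through IEEE 754 single precision (the storage format of
# recording payloads), so in-memory and on-disk samples are identical.
float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
          what = "numeric", n = length(x), size = 4L, endian = "little")
}

# Zero-phase Butterworth bandpass on a bare numeric vector.
band_filter <- function(x, sampling_rate, low, high, order = 2) {
  nyq <- sampling_rate / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop("band edges must satisfy 0 < low < high < Nyquist (",
         nyq, " Hz); got [", low, ", ", high, "]")
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  signal::filtfilt(bf, x)
}

high_filter <- function(x, sampling_rate, cutoff, order = 2) {
  nyq <- sampling_rate / 2
  if (!(cutoff > 0 && cutoff < nyq)) {
    stop("highpass cutoff must lie in (0, Nyquist); got ", cutoff)
  }
  bf <- signal::butter(order, cutoff / nyq, type = "high")
  signal::filtfilt(bf, x)
}
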