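# Shared DSP primitives: zero-phase FFT filtering, Hilbert analytic signal,
# Welch periodogram. Kept internal except welchPSD and analyticSignal, which
# other modules' users also need.

# Zero-phase filter by applying a real, even gain in the frequency domain.
# gain(f) is evaluated on folded frequencies [0, fs/2]. Mirror padding limits
# circular edge artifacts; pad is in samples per side.
.fftFilter <- function(x, fs, gain, pad = 0L) {
  n0 <- length(x)
  pad <- min(as.integer(pad), n0 - 1L)
  if (pad > 0L) {
    x <- c(2 * x[1] - rev(x[2:(pad + 1L)]), x,
           2 * x[n0] - rev(x[(n0 - pad):(n0 - 1L)]))
  }
  n <- length(x)
  f <- (seq_len(n) - 1L) / n * fs
  f <- pmin(f, fs - f)
  y <- Re(stats::fft(stats::fft(x) * gain(f), inverse = TRUE)) / n
  if (pad > 0L) y <- y[(pad + 1L):(pad + n0)]
  y
}

# Raised-cosine low-pass gain: unity up to `pass`, cosine rolloff to zero at
# `stop`, zero beyond.
.lpGain <- function(pass, stop) {
  force(pass); force(stop)
  function(f) {
    g <- as.numeric(f <= pass)
    tr <- f > pass & f < stop
    g[tr] <- 0.5 * (1 + cos(pi * (f[tr] - pass) / (stop - pass)))
    g
  }
}

.lowpass <- function(x, fs, pass, stop, pad = 0L)
  .fftFilter(x, fs, .lpGain(pass, stop), pad = pad)

# Gaussian low-pass (gain exp(-f^2 / (2 sigmaF^2))): positive impulse
# response, hence no ringing on sharp-cornered waveforms — used where a
# derivative is taken afterwards.
.gaussLowpass <- function(x, fs, sigmaF, pad = 0L) {
  force(sigmaF)
  .fftFilter(x, fs, function(f) exp(-0.5 * (f / sigmaF)^2), pad = pad)
}

# Band-pass with raised-cosine transitions of width `trans` on either side.
.bandpass <- function(x, fs, low, high, trans = NULL, pad = NULL) {
  if (is.null(trans)) trans <- 0.25 * low
  if (is.null(pad)) pad <- min(length(x) - 1L, round(3 * fs / low))
  lo1 <- max(low - trans, 0); lo2 <- low
  hi1 <- high; hi2 <- high + trans
  gain <- function(f) {
    g <- as.numeric(f >= lo2 & f <= hi1)
    up <- f > lo1 & f < lo2
    g[up] <- 0.5 * (1 - cos(pi * (f[up] - lo1) / (lo2 - lo1)))
    dn <- f > hi1 & f < hi2
    g[dn] <- 0.5 * (1 + cos(pi * (f[dn] - hi1) / (hi2 - hi1)))
    g
  }
  .fftFilter(x - mean(x), fs, gain, pad = pad)
}

#' Discrete-time analytic signal
#'
#' Computes the analytic equivalent of a real series via the FFT Hilbert
#' transform: negative frequencies are zeroed, positive doubled, so the real
#' part equals the input and the imaginary part is its Hilbert transform.
#'
#' @param x numeric vector or [FWaveSignal-class].
#' @return complex vector of the same length.
#' @export
analyticSignal <- function(x) {
  if (is(x, "FWaveSignal")) x <- x@x
  stopifnot(is.numeric(x), length(x) >= 4L)
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Welch periodogram
#'
#' Averaged modified periodogram with Hamming-windowed segments, per-segment
#' mean removal, and zero padding for finer frequency interpolation.
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param segSeconds segment length in seconds (default 10).
#' @param overlap fractional segment overlap (default 0.5).
#' @param nfft FFT length; default next power of two of the segment length
#'   times `padFactor`.
#' @param padFactor zero-padding factor (default 4).
#' @param detrend remove a linear trend per segment instead of just the mean.
#' @return list with `freq` (Hz, one-sided) and `power` (spectral density).
#' @export
welchPSD <- function(x, fs, segSeconds = 10, overlap = 0.5, nfft = NULL,
                     padFactor = 4, detrend = FALSE) {
  stopifnot(is.numeric(x), fs > 0)
  seg <- min(length(x), max(8L, round(segSeconds * fs)))
  hop <- max(1L, round(seg * (1 - overlap)))
  starts <- seq(1L, length(x) - seg + 1L, by = hop)
  if (is.null(nfft)) nfft <- 2^ceiling(log2(seg)) * padFactor
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(seg - 1L)) / (seg - 1L))
  u <- sum(w^2)
  acc <- numeric(nfft)
  idx0 <- seq_len(seg)
  tt <- idx0 - (seg + 1) / 2
  for (s in starts) {
    xs <- x[s + idx0 - 1L]
    xs <- xs - mean(xs)
    if (detrend) xs <- xs - tt * sum(xs * tt) / sum(tt^2)
    X <- stats::fft(c(xs * w, numeric(nfft - seg)))
    acc <- acc + Mod(X)^2
  }
  acc <- acc / (length(starts) * u * fs)
  nh <- floor(nfft / 2) + 1L
  list(freq = (seq_len(nh) - 1L) / nfft * fs, power = acc[seq_len(nh)])
}

# Largest run of TRUE in a logical vector; returns c(start, end) or NULL.
.longestRun <- function(ok) {
  r <- rle(ok)
  if (!any(r$values)) return(NULL)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- which(r$values)[which.max(r$lengths[r$values])]
  c(starts[i], ends[i])
}

# Convert a time window (seconds, relative to series start) to sample indices
# on a uniform grid where sample m corresponds to time (m - 1) / fs.
.windowIndices <- function(window, fs, n) {
  i1 <- max(1L, floor(window[1] * fs) + 1L)
  i2 <- min(n, floor(window[2] * fs))
  if (i2 < i1) integer() else i1:i2
}
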