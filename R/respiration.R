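# ECG-derived respiration: per-lead QRS slope-range series interpolated to a
# uniform 50 Hz grid, combined into a joint-lead respiration signal r(m) by
# periodic component analysis (piCA), which also yields the respiration rate
# FRR as the most periodic candidate period.

#' Per-beat QRS slope-range series
#'
#' For each non-ectopic beat, the first difference of the waveform over
#' R +- `halfWindow` is computed and the slope range is its maximum minus
#' minimum (mV/s). The waveform is smoothed first with a Gaussian low-pass
#' (sd 25 Hz) — its positive impulse response cannot overshoot the true
#' slopes, unlike a sharp-cutoff filter. Respiratory QRS-morphology variation
#' shows up as beat-to-beat modulation of this series.
#'
#' @param record an [ECGRecord-class].
#' @param beats a [BeatSet-class].
#' @param lead lead name.
#' @param halfWindow half-width of the derivative window around R (s),
#'   default 0.05.
#' @return list with `times` (beat times, s), `values` (slope range, mV/s)
#'   and `lead`.
#' @export
slopeRangeSeries <- function(record, beats, lead, halfWindow = 0.05) {
  stopifnot(is(record, "ECGRecord"), is(beats, "BeatSet"))
  if (!lead %in% colnames(record@samples)) stop("unknown lead: ", lead)
  keep <- !beats@ectopic
  if (!any(keep)) stop("no non-ectopic beats available")
  fs <- record@fs
  xl <- .gaussLowpass(record@samples[, lead], fs, sigmaF = 25,
                      pad = round(fs))
  d <- c(diff(xl), 0) * fs
  n <- length(d)
  half <- round(halfWindow * fs)
  r <- beats@rPeaks[keep]
  vals <- vapply(r, function(p) {
    seg <- max(1L, p - half):min(n, p + half)
    max(d[seg]) - min(d[seg])
  }, numeric(1))
  list(times = (r - 1L) / fs, values = vals, lead = lead)
}

#' Interpolate a beat-domain series to a uniform 50 Hz respiration series
#'
#' Cubic-spline interpolation of per-beat values onto the 50 Hz analysis grid
#' over the span covered by beats, followed by a zero-phase band-pass
#' (default 0.08-0.5 Hz) and mean removal. Samples outside the beat span are
#' NA.
#'
#' @param values per-beat values.
#' @param times beat times (s), >= 10 beats spanning >= 30 s.
#' @param n length of the 50 Hz analysis grid (sample m is time (m-1)/fs).
#' @param fs grid rate, default 50 Hz.
#' @param band band-pass corner frequencies (Hz).
#' @return numeric vector of length `n`, zero-mean over its finite span.
#' @export
interpolateResp <- function(values, times, n, fs = 50, band = c(0.08, 0.5)) {
  stopifnot(length(values) == length(times))
  if (length(values) < 10L) stop("need >= 10 beats")
  if (diff(range(times)) < 30) stop("beats must span >= 30 s")
  out <- rep(NA_real_, n)
  idx <- which((seq_len(n) - 1L) / fs >= min(times) &
                 (seq_len(n) - 1L) / fs <= max(times))
  if (length(idx) < 2L) stop("beat span does not cover the analysis grid")
  y <- stats::spline(times, values, xout = (idx - 1L) / fs)$y
  y <- .bandpass(y, fs, band[1], band[2])
  out[idx] <- y - mean(y)
  out
}

#' Joint-lead respiration by periodic component analysis
#'
#' Scans candidate periods tau over a frequency band (0.01 Hz grid) and, for
#' each, minimizes the periodicity objective
#' `eps(tau) = w' A_tau w / w' C w` over lead-combination weights w, where C
#' is the lead-series covariance and A_tau the covariance of the tau-lagged
#' difference (generalized eigenvalue problem). The respiration rate FRR is
#' the frequency of the global minimum and `r(m)` the corresponding weighted
#' combination, scaled to unit variance with its lag-tau autocovariance
#' positive.
#'
#' @param series list of per-lead 50 Hz series (equal length, NA outside the
#'   common valid span) or a matrix with one column per lead.
#' @param fs sampling rate, default 50 Hz.
#' @param band scanned frequency band (Hz), default 0.08-0.5.
#' @param gridStep frequency grid step (Hz).
#' @param ridgeCondition condition-number threshold above which C is
#'   ridge-regularized (with a warning).
#' @return a [RespirationEstimate-class].
#' @export
jointRespiration <- function(series, fs = 50, band = c(0.08, 0.5),
                             gridStep = 0.01, ridgeCondition = 1e8) {
  if (is.list(series)) series <- do.call(cbind, series)
  stopifnot(is.matrix(series), ncol(series) >= 2L)
  nFull <- nrow(series)
  ok <- rowSums(!is.finite(series)) == 0L
  run <- .longestRun(ok)
  if (is.null(run)) stop("no common valid span across lead series")
  Z <- series[run[1]:run[2], , drop = FALSE]
  n <- nrow(Z)
  Z <- sweep(Z, 2, colMeans(Z))
  C <- crossprod(Z) / n
  # Solve the GEP in the principal subspace of C: directions with (near-)zero
  # lead-series variance are pure cancellation directions (numerator and
  # denominator both ~0) and must not compete; moderate ill-conditioning is
  # ridge-regularized instead.
  ec <- eigen(C, symmetric = TRUE)
  keep <- ec$values > max(ec$values) * 1e-8
  if (!all(keep))
    warning("rank-deficient lead covariance; ",
            "restricted to its principal subspace")
  if (max(ec$values[keep]) / min(ec$values[keep]) > ridgeCondition) {
    warning("ill-conditioned lead covariance; ridge regularization applied")
    C <- C + diag(1e-6 * sum(diag(C)) / ncol(C), ncol(C))
    ec <- eigen(C, symmetric = TRUE)
    keep <- rep(TRUE, ncol(C))
  }
  # whitening map W: w = W y with y in the kept subspace
  Rinv <- ec$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(ec$values[keep]), sum(keep))
  freqs <- seq(band[1], band[2], by = gridStep)
  taus <- sort(unique(round(fs / freqs)))
  taus <- taus[taus >= 2L & taus < n / 2L]
  eps <- rep(Inf, length(taus))
  ws <- vector("list", length(taus))
  for (i in seq_along(taus)) {
    tau <- taus[i]
    D <- Z[(tau + 1L):n, , drop = FALSE] - Z[1:(n - tau), , drop = FALSE]
    A <- crossprod(D) / (n - tau)
    B <- t(Rinv) %*% A %*% Rinv
    ee <- eigen((B + t(B)) / 2, symmetric = TRUE)
    k <- ncol(B)
    eps[i] <- ee$values[k]
    ws[[i]] <- as.numeric(Rinv %*% ee$vectors[, k])
  }
  if (!any(is.finite(eps))) stop("piCA scan failed on all candidate periods")
  # A T-periodic signal is also kT-periodic, and the longest lags also
  # absorb the slowest in-band noise, so the global minimum can land on a
  # subharmonic. Disambiguate by checking the exact divisors of the winning
  # lag: a genuinely long-period signal has a far larger objective at half
  # its period, so the tolerance below only collapses true subharmonics.
  iBest <- which.min(eps)
  for (k in c(3L, 2L)) {
    iDiv <- which.min(abs(taus - taus[iBest] / k))
    if (abs(taus[iDiv] - taus[iBest] / k) <= 2 &&
        eps[iDiv] <= 2 * eps[iBest] + 0.05) {
      iBest <- iDiv
      break
    }
  }
  best <- list(eps = eps[iBest], tau = taus[iBest], w = ws[[iBest]])
  w <- best$w
  r <- as.numeric(Z %*% w)
  # sign so the lag-tau* autocovariance is positive (flip if needed)
  tau <- best$tau
  if (sum(r[1:(n - tau)] * r[(tau + 1L):n]) < 0) { r <- -r; w <- -w }
  r <- r / stats::sd(r)
  rFull <- rep(NA_real_, nFull)
  rFull[run[1]:run[2]] <- r
  new("RespirationEstimate", r = rFull, fs = fs, frr = fs / tau,
      weights = w / sqrt(sum(w^2)), epsilon = best$eps)
}
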