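# Activation-time analysis for simulated atrial activity: per-point
# instantaneous frequency at 10 Hz, spectral peak-conditioned point
# selection, the mean frequency trend fs(m) with its median Ffs, and the
# respiratory modulation dFfs against a fixed 0.14 Hz reference sinusoid.

#' Instantaneous activation frequency of one point
#'
#' Converts activation times to a uniform 10 Hz rate series: each cycle's
#' rate `1 / (t_{i+1} - t_i)` is attributed to the interval midpoint and
#' linearly interpolated onto a 10 Hz grid spanning the point's activation
#' span.
#'
#' @param times strictly increasing activation times (s), >= 3 activations.
#' @param fs output rate (Hz), default 10.
#' @return list with `time` (grid, s), `fcs` (Hz) — or NULL (with a warning)
#'   for points with fewer than 3 activations.
#' @export
instantaneousFrequency <- function(times, fs = 10) {
  if (length(times) < 3L) {
    warning("point dropped: fewer than 3 activations")
    return(NULL)
  }
  stopifnot(all(diff(times) > 0))
  rate <- 1 / diff(times)
  mid <- (times[-1] + times[-length(times)]) / 2
  t0 <- ceiling(mid[1] * fs) / fs
  t1 <- floor(mid[length(mid)] * fs) / fs
  if (t1 <= t0) {
    warning("point dropped: activation span too short")
    return(NULL)
  }
  grid <- seq(t0, t1, by = 1 / fs)
  list(time = grid, fcs = stats::approx(mid, rate, xout = grid)$y)
}

#' Spectral peak-conditioned point selection
#'
#' A point's rate series is retained when its (linearly detrended) Welch
#' spectrum is sufficiently peaked: the fraction of total power within
#' `+-halfBand` of the spectral peak must reach `minFraction`. Broadband
#' series — points without a coherent periodic rate component — are
#' discarded.
#'
#' @param fcsList list of `instantaneousFrequency()` results (NULL entries
#'   count as discarded).
#' @param fs series rate (Hz), default 10.
#' @param minFraction concentration threshold (default 0.25).
#' @param halfBand half-width of the band around the peak (Hz), default 0.05.
#' @return logical retained mask, one entry per point. Errors when every
#'   point is discarded.
#' @export
peakConditionedSelection <- function(fcsList, fs = 10, minFraction = 0.25,
                                     halfBand = 0.05) {
  stopifnot(length(fcsList) >= 1L)
  retained <- vapply(fcsList, function(p) {
    if (is.null(p) || length(p$fcs) < 8 * fs) return(FALSE)
    ps <- welchPSD(p$fcs, fs, segSeconds = min(30, length(p$fcs) / fs),
                   overlap = 0.5, detrend = TRUE)
    sel <- ps$freq > 0
    pk <- ps$freq[sel][which.max(ps$power[sel])]
    inBand <- sel & abs(ps$freq - pk) <= halfBand
    sum(ps$power[inBand]) / sum(ps$power[sel]) >= minFraction
  }, logical(1))
  if (!any(retained)) stop("no peaked series: all points discarded")
  retained
}

#' Mean activation-frequency trend and its summary
#'
#' `fs(m)`: the mean over the retained per-point rate series at each 10 Hz
#' sample (points not covering a sample are excluded there); `Ffs`: the
#' median of `fs(m)` over time.
#'
#' @param fcsList list of `instantaneousFrequency()` results.
#' @param retained logical mask from [peakConditionedSelection()].
#' @param fs series rate (Hz), default 10.
#' @return list with `time`, `fs` (mean trend, Hz), `nContributing` (points
#'   per sample) and `ffs` (median, Hz).
#' @export
meanActivationTrend <- function(fcsList, retained, fs = 10) {
  stopifnot(length(fcsList) == length(retained))
  keep <- which(retained & !vapply(fcsList, is.null, logical(1)))
  if (!length(keep)) stop("no retained points")
  t0 <- min(vapply(fcsList[keep], function(p) p$time[1], numeric(1)))
  t1 <- max(vapply(fcsList[keep], function(p) max(p$time), numeric(1)))
  grid <- seq(round(t0 * fs) / fs, round(t1 * fs) / fs, by = 1 / fs)
  acc <- numeric(length(grid))
  cnt <- integer(length(grid))
  for (p in fcsList[keep]) {
    i0 <- round((p$time[1] - grid[1]) * fs) + 1L
    sel <- i0:(i0 + length(p$fcs) - 1L)
    acc[sel] <- acc[sel] + p$fcs
    cnt[sel] <- cnt[sel] + 1L
  }
  fsm <- ifelse(cnt > 0L, acc / pmax(cnt, 1L), NA_real_)
  list(time = grid, fs = fsm, nContributing = cnt,
       ffs = stats::median(fsm[cnt > 0L]))
}

#' Respiratory modulation of the simulated frequency trend
#'
#' Applies the orthogonal-subspace-projection machinery to `fs(m)` with a
#' reference respiration signal fixed to a sinusoid (default 0.14 Hz, the
#' cohort-average respiration rate): detrend by mean subtraction, project
#' onto the delayed-sinusoid subspace, and compute
#' `dFfs = sqrt(2 fr'fr / (M - q))`.
#'
#' @param fsm mean trend `fs(m)` (list from [meanActivationTrend()] or a
#'   numeric series).
#' @param respRate reference sinusoid frequency (Hz), default 0.14.
#' @param q delay count; default a quarter period, `round(fs/(4*respRate))`.
#' @param fs series rate (Hz), default 10.
#' @param minSeconds minimum series length (s), default 10 (one simulation
#'   analysis window).
#' @return list with `deltaFfs` (Hz), `pr` (percent), `fr`, `q`, `m`.
#' @export
deltaFfs <- function(fsm, respRate = 0.14, q = NULL, fs = 10,
                     minSeconds = 10) {
  if (is.list(fsm)) fsm <- fsm$fs
  fsm <- fsm[is.finite(fsm)]
  M <- length(fsm)
  if (M < minSeconds * fs) {
    warning("trend shorter than ", minSeconds, " s; dFfs missing")
    return(list(deltaFfs = NA_real_, pr = NA_real_, fr = numeric(),
                q = NA_integer_, m = M))
  }
  if (is.null(q)) q <- max(1L, round(fs / (4 * respRate)))
  r <- sin(2 * pi * respRate * (0:(M - 1L)) / fs)
  ftilde <- (fsm - mean(fsm))[1:(M - q)]
  fr <- ospProject(ftilde, buildDelayMatrix(r, q))
  pr <- if (sum(ftilde^2) == 0) NA_real_ else
    100 * sum(fr^2) / sum(ftilde^2)
  list(deltaFfs = deltaFf(fr), pr = pr, fr = fr, q = q, m = M)
}
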