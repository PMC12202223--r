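# Respiratory f-wave frequency modulation by orthogonal subspace projection:
# the detrended frequency trend is projected onto the span of delayed copies
# of the respiration signal; the projected series fr yields the modulation
# magnitude dFf (average peak amplitude) and its relative power Pr.

#' Build the respiratory delay matrix
#'
#' From `r(m)` over a window of M samples, builds the (M - q) x (q + 1)
#' matrix V whose column d (d = 0..q) is the delayed segment
#' `r(1 + d), ..., r(M - q + d)`.
#'
#' @param r numeric respiration series of length M.
#' @param q number of delays; requires `q < M / 2`.
#' @return the delay matrix V.
#' @export
buildDelayMatrix <- function(r, q) {
  M <- length(r)
  if (q < 0 || q >= M / 2) stop("require 0 <= q < M/2")
  rows <- M - q
  V <- matrix(0, rows, q + 1L)
  for (d in 0:q) V[, d + 1L] <- r[(1L + d):(rows + d)]
  V
}

#' Project a detrended trend window onto the respiratory subspace
#'
#' Computes `fr = V (V'V)^-1 V' ftilde` via a rank-revealing SVD: singular
#' values below `max(dim(V)) * eps * s_max` are truncated, so rank-deficient
#' V (e.g. constant or strictly narrowband r) falls back to the
#' pseudo-inverse projection onto the effective subspace.
#'
#' @param ftilde detrended (mean-subtracted) frequency-trend segment of
#'   length `nrow(V)`.
#' @param V delay matrix from [buildDelayMatrix()].
#' @return the projected series fr (same length as `ftilde`).
#' @export
ospProject <- function(ftilde, V) {
  stopifnot(length(ftilde) == nrow(V))
  sv <- svd(V)
  tol <- max(dim(V)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  if (rank == 0L) return(numeric(length(ftilde)))
  U <- sv$u[, seq_len(rank), drop = FALSE]
  as.numeric(U %*% crossprod(U, ftilde))
}

#' Respiratory modulation magnitude
#'
#' The average peak amplitude of the respiratory component:
#' `dFf = sqrt(2 fr'fr / (M - q))`, the root-mean-square of fr scaled to the
#' peak amplitude of an equivalent sinusoid.
#'
#' @param fr projected series of length M - q.
#' @param m,q optional window length and delay count; when given, the length
#'   of `fr` is checked against `m - q`.
#' @return dFf in the units of the trend (Hz).
#' @export
deltaFf <- function(fr, m = NULL, q = NULL) {
  if (!is.null(m) && !is.null(q) && length(fr) != m - q)
    stop("fr must have length m - q")
  sqrt(2 * sum(fr^2) / length(fr))
}

#' Relative power of the respiratory component
#'
#' `Pr = 100 * fr'fr / ftilde'ftilde` (percent): the share of the detrended
#' trend's energy captured by the respiratory subspace.
#'
#' @param fr projected series.
#' @param ftilde detrended trend segment of the same length.
#' @return Pr in percent, or NA (with a warning) for a zero-energy ftilde.
#' @export
relativePower <- function(fr, ftilde) {
  stopifnot(length(fr) == length(ftilde))
  den <- sum(ftilde^2)
  if (den == 0) {
    warning("zero-energy detrended trend; Pr undefined")
    return(NA_real_)
  }
  100 * sum(fr^2) / den
}

# Bridge short invalid gaps (<= maxGap s) in a masked series by linear
# interpolation; returns the series, the updated mask, and the fraction of
# bridged samples.
.bridgeGaps <- function(x, ok, fs, maxGap = 5) {
  if (all(ok) || !any(ok)) return(list(x = x, ok = ok, frac = 0))
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  bridged <- 0L
  for (i in which(!r$values)) {
    if (r$lengths[i] > maxGap * fs) next
    if (i == 1L || i == length(r$values)) next   # edge gaps cannot be bridged
    a <- starts[i]; b <- ends[i]
    x0 <- x[a - 1L]; x1 <- x[b + 1L]
    x[a:b] <- x0 + (x1 - x0) * seq_len(b - a + 1L) / (b - a + 2L)
    ok[a:b] <- TRUE
    bridged <- bridged + (b - a + 1L)
  }
  list(x = x, ok = ok, frac = bridged / length(x))
}

#' Per-phase respiratory modulation by OSP
#'
#' Extracts the phase window from the quality-gated frequency trend and the
#' respiration estimate, bridges invalid trend gaps up to `maxGap` seconds by
#' linear interpolation (longer gaps restrict the analysis to the longest
#' contiguous valid run), detrends by mean subtraction, projects onto the
#' respiratory delay subspace and computes dFf and Pr.
#'
#' @param trend a [FrequencyTrend-class] (gated, see [qualityIndex()]).
#' @param resp a [RespirationEstimate-class] on the same 50 Hz grid.
#' @param window numeric length-2 phase window (s).
#' @param q number of delays. The default (2) is the smallest count whose
#'   delay span covers both quadratures of the narrowband respiratory
#'   reference; because every additional delayed copy of a *noisy* r adds a
#'   broadband direction to the projection subspace, the estimator's noise
#'   floor grows with q while the captured respiratory signal does not.
#'   `q = NA` selects a quarter respiratory period,
#'   `round(fs / (4 * FRR))`.
#' @param maxGap largest bridgeable gap (s).
#' @param minRun minimum usable run length (s); shorter yields NA with a
#'   warning.
#' @return list with `deltaFf` (Hz), `pr` (percent), `fr`, `q`, `m` (window
#'   length used), `interpFraction` (fraction of bridged samples).
#' @export
phaseModulation <- function(trend, resp, window, q = 2L, maxGap = 5,
                            minRun = 60) {
  stopifnot(is(trend, "FrequencyTrend"), is(resp, "RespirationEstimate"))
  fs <- trend@fs
  idx <- .windowIndices(window, fs, length(trend@f))
  empty <- list(deltaFf = NA_real_, pr = NA_real_, fr = numeric(),
                q = NA_integer_, m = NA_integer_, interpFraction = NA_real_)
  if (!length(idx)) {
    warning("empty phase window; modulation missing")
    return(empty)
  }
  f <- trend@f[idx]
  ok <- trend@valid[idx] & is.finite(f) & is.finite(resp@r[idx])
  f[!ok] <- NA_real_
  br <- .bridgeGaps(f, ok, fs, maxGap)
  run <- .longestRun(br$ok & is.finite(resp@r[idx]))
  if (is.null(run) || run[2] - run[1] + 1L < minRun * fs) {
    warning("longest valid run shorter than ", minRun,
            " s; modulation missing")
    return(empty)
  }
  sel <- run[1]:run[2]
  fSeg <- br$x[sel]
  rSeg <- resp@r[idx][sel]
  M <- length(fSeg)
  if (is.null(q) || is.na(q)) q <- max(1L, round(fs / (4 * resp@frr)))
  q <- as.integer(q)
  if (q >= M / 2) q <- floor(M / 2) - 1L
  ftilde <- (fSeg - mean(fSeg))[1:(M - q)]
  V <- buildDelayMatrix(rSeg, q)
  fr <- ospProject(ftilde, V)
  pr <- if (sum(ftilde^2) == 0) {
    warning("constant trend in phase; Pr undefined")
    NA_real_
  } else 100 * sum(fr^2) / sum(ftilde^2)
  list(deltaFf = deltaFf(fr), pr = pr, fr = fr, q = q, m = M,
       interpFraction = br$frac)
}
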