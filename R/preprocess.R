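# ECG preprocessing: R-peak detection, template-based ectopic classification,
# average-beat-subtraction QRST cancellation, 50 Hz f-wave extraction, and
# per-phase heart rate with ectopic exclusion.

# QRS-band energy envelope used for detection: band-pass 5-25 Hz, square,
# 120 ms moving average.
.qrsEnvelope <- function(x, fs) {
  d <- .bandpass(x, fs, 5, 25, trans = 2, pad = round(fs))
  k <- max(3L, round(0.12 * fs))
  as.numeric(stats::filter(d^2, rep(1 / k, k), sides = 2))
}

# Pick the detection lead: largest median per-beat QRS-band energy, proxied
# by the 99th percentile of the envelope.
.detectionLead <- function(record) {
  e <- apply(record@samples, 2, function(x)
    stats::quantile(.qrsEnvelope(x, record@fs), 0.99, na.rm = TRUE))
  colnames(record@samples)[which.max(e)]
}

#' Detect R peaks
#'
#' Energy-envelope QRS detector: the designated lead is band-passed to the
#' QRS band (5-25 Hz), squared and smoothed; supra-threshold runs give beat
#' candidates, a 200 ms refractory period is enforced, and each R location is
#' refined to the largest absolute excursion of the low-passed waveform near
#' the envelope peak.
#'
#' @param record an [ECGRecord-class] (>= 10 s of signal).
#' @param lead detection lead name; default the lead with the largest
#'   QRS-band energy.
#' @param refractory minimum beat separation (s).
#' @return integer vector of R-peak sample indices.
#' @export
detectBeats <- function(record, lead = NULL, refractory = 0.2) {
  stopifnot(is(record, "ECGRecord"))
  fs <- record@fs
  n <- nrow(record@samples)
  if (n < 10 * fs) stop("need at least 10 s of signal")
  if (is.null(lead)) lead <- .detectionLead(record)
  x <- record@samples[, lead]
  if (stats::sd(x) < 1e-9) stop("no beats detected: flat signal")
  e <- .qrsEnvelope(x, fs)
  e[is.na(e)] <- 0
  thr <- 0.2 * stats::quantile(e, 0.99)
  if (!is.finite(thr) || thr <= 0) stop("no beats detected")
  above <- e > thr
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (!length(runs)) stop("no beats detected")
  peaks <- vapply(runs, function(i) {
    seg <- starts[i]:ends[i]
    seg[which.max(e[seg])]
  }, integer(1))
  amps <- e[peaks]
  # refractory: greedy by envelope amplitude
  ord <- order(amps, decreasing = TRUE)
  keep <- logical(length(peaks))
  taken <- numeric(0)
  minGap <- refractory * fs
  for (i in ord) {
    if (!length(taken) || all(abs(taken - peaks[i]) >= minGap)) {
      keep[i] <- TRUE
      taken <- c(taken, peaks[i])
    }
  }
  peaks <- sort(peaks[keep])
  # refine on the low-passed waveform (largest |deflection| within +-60 ms)
  xl <- .lowpass(x - stats::median(x), fs, 40, 45, pad = round(fs))
  half <- round(0.06 * fs)
  vapply(peaks, function(p) {
    seg <- max(1L, p - half):min(n, p + half)
    seg[which.max(abs(xl[seg]))]
  }, integer(1))
}

#' Classify ectopic beats against a normal template
#'
#' Iteratively builds a median normal-beat template on the (low-passed)
#' classification lead and flags a beat as ectopic when its correlation with
#' the template falls below `corrThreshold` *or* its preceding RR interval
#' deviates from the local median RR by more than `rrTol`. The template is
#' recomputed from unflagged beats over `passes` passes. Per-lead raw-signal
#' templates for cancellation are computed from the final normal set.
#'
#' The shape-consistency correlation is evaluated on the QRS core of the
#' template window (R +- `corrWindow`), where beat morphology discriminates;
#' at fibrillatory heart rates the full QRST window of one beat overlaps the
#' onset of the next, which would deflate correlations for perfectly normal
#' beats.
#'
#' @param record an [ECGRecord-class].
#' @param rPeaks integer R-peak indices (>= 10 beats).
#' @param lead classification lead; default the detection lead.
#' @param corrThreshold template-correlation threshold (default 0.9).
#' @param rrTol fractional RR deviation threshold (default 0.4).
#' @param window beat window around R in seconds (default -0.25..+0.45).
#' @param corrWindow half-width (s) of the QRS core used for the correlation.
#' @param passes template refinement passes (default 2).
#' @return a [BeatSet-class].
#' @export
classifyEctopic <- function(record, rPeaks, lead = NULL, corrThreshold = 0.9,
                            rrTol = 0.4, window = c(-0.25, 0.45),
                            corrWindow = 0.15, passes = 2) {
  stopifnot(is(record, "ECGRecord"))
  if (length(rPeaks) < 10L) stop("insufficient beats (need >= 10)")
  fs <- record@fs
  n <- nrow(record@samples)
  if (is.null(lead)) lead <- .detectionLead(record)
  win <- as.integer(round(window * fs))
  offs <- win[1]:win[2]
  xl <- .lowpass(record@samples[, lead] - stats::median(record@samples[, lead]),
                 fs, 40, 45, pad = round(fs))
  nb <- length(rPeaks)
  idx <- outer(offs, as.integer(rPeaks), "+")
  inside <- idx >= 1L & idx <= n
  idx[!inside] <- 1L
  beatMat <- matrix(xl[idx], nrow = length(offs))
  beatMat[!inside] <- NA_real_
  full <- colSums(!inside) == 0L
  core <- which(offs >= -round(corrWindow * fs) &
                  offs <= round(corrWindow * fs))
  rr <- diff(rPeaks) / fs
  localMed <- if (length(rr) >= 9L) stats::runmed(rr, 9L) else
    rep(stats::median(rr), length(rr))
  rrDev <- c(FALSE, abs(rr - localMed) / localMed > rrTol)
  flagged <- rep(FALSE, nb)
  corr <- rep(NA_real_, nb)
  ectSupport <- round(0.6 * fs)   # ectopic complexes extend ~0.6 s past R
  for (pass in seq_len(passes)) {
    use <- full & !flagged
    if (!any(use)) use <- full
    tpl <- apply(beatMat[, use, drop = FALSE], 1, stats::median)
    corr <- suppressWarnings(
      as.numeric(stats::cor(beatMat[core, , drop = FALSE], tpl[core],
                            use = "pairwise.complete.obs")))
    # beats following a morphology-deviant beat: drop the window prefix its
    # wide complex intrudes on, provided the QRS itself stays in view — a
    # contaminated but normal beat must not inherit the flag
    corrFlag <- is.finite(corr) & corr < corrThreshold
    for (i in which(c(FALSE, corrFlag[-nb]))) {
      cut <- rPeaks[i - 1L] + ectSupport - rPeaks[i]
      sub <- core[offs[core] > cut]
      if (cut <= -0.03 * fs && length(sub) >= round(0.1 * fs))
        corr[i] <- suppressWarnings(stats::cor(beatMat[sub, i], tpl[sub]))
    }
    corr[!is.finite(corr)] <- 1  # zero-variance beats: identical to template
    flagged <- (corr < corrThreshold) | rrDev
  }
  # raw per-lead templates for cancellation, from the final normal beats
  use <- full & !flagged
  if (!any(use)) use <- full
  template <- vapply(colnames(record@samples), function(ld) {
    m <- matrix(record@samples[idx, ld], nrow = length(offs))
    m[!inside] <- NA_real_
    apply(m[, use, drop = FALSE], 1, stats::median)
  }, numeric(length(offs)))
  new("BeatSet", rPeaks = as.integer(rPeaks), ectopic = flagged,
      corr = corr, template = template, window = win, fs = fs,
      detectionLead = lead)
}

#' Cancel QRST complexes by average beat subtraction
#'
#' For each non-ectopic beat the per-lead normal template, amplitude-scaled by
#' least squares, is subtracted over its window. The subtracted template is
#' restricted to the beat's own support — QRS onset (default 120 ms before R)
#' to the end of the T wave — with short cosine tapers: during AF there is no
#' P wave, so earlier samples carry only the previous beat's T tail, which
#' that beat's own (overlapping) subtraction removes. Ectopic beat windows
#' are replaced by linear interpolation between the surrounding residual
#' samples. Samples outside any beat window are untouched.
#'
#' @param record an [ECGRecord-class].
#' @param beats a [BeatSet-class]; may be empty, in which case the lead is
#'   returned unchanged.
#' @param lead lead to cancel.
#' @param onset QRS onset relative to R (s) bounding the template support.
#' @param ectopicPad extra seconds appended to an ectopic beat's replacement
#'   window: ectopic complexes are wider than the normal template window.
#' @return numeric residual waveform at the source rate (mV).
#' @export
cancelQRST <- function(record, beats, lead, onset = -0.12,
                       ectopicPad = 0.15) {
  stopifnot(is(record, "ECGRecord"), is(beats, "BeatSet"))
  if (!lead %in% colnames(record@samples)) stop("unknown lead: ", lead)
  x <- record@samples[, lead]
  nb <- length(beats@rPeaks)
  if (nb == 0L) return(x)
  win <- beats@window
  fs <- beats@fs
  offs <- win[1]:win[2]
  # support-restricted, tapered template
  mask <- as.numeric(offs >= round(onset * fs))
  rampIn <- which(offs >= round(onset * fs) &
                    offs < round((onset + 0.02) * fs))
  if (length(rampIn))
    mask[rampIn] <- 0.5 * (1 - cos(pi * seq_along(rampIn) /
                                     (length(rampIn) + 1L)))
  rampOut <- which(offs > win[2] - round(0.03 * fs))
  if (length(rampOut))
    mask[rampOut] <- mask[rampOut] *
      0.5 * (1 + cos(pi * seq_along(rampOut) / (length(rampOut) + 1L)))
  tpl <- beats@template[, lead] * mask
  supp <- which(mask > 0.5)
  n <- length(x)
  res <- x
  r <- beats@rPeaks
  for (i in seq_len(nb)) {
    if (beats@ectopic[i]) next
    a <- r[i] + win[1]
    k <- which(a + offs - win[1] >= 1L & a + offs - win[1] <= n)
    if (!length(k)) next
    ks <- intersect(k, supp)
    tk <- tpl[ks]
    den <- sum(tk^2)
    s <- if (den > 0) sum(res[a + ks - 1L] * tk) / den else 0
    res[a + k - 1L] <- res[a + k - 1L] - s * tpl[k]
  }
  segA <- pmax(1L, r + round(onset * fs))
  segB <- pmin(n, r + win[2] + round(ectopicPad * fs))
  # ectopic windows: bridge the residual by linear interpolation; the
  # replaced intervals are reported so downstream trend samples there can be
  # invalidated (the atrial signal is destroyed, not merely noisy)
  replaced <- matrix(numeric(), 0L, 2L)
  for (i in which(beats@ectopic)) {
    a <- segA[i]; b <- segB[i]
    if (b < a) next
    v0 <- if (a > 1L) res[a - 1L] else res[b + 1L]
    v1 <- if (b < n) res[b + 1L] else res[a - 1L]
    if (!length(v0) || !length(v1)) { res[a:b] <- 0; next }
    res[a:b] <- v0 + (v1 - v0) * seq_len(b - a + 1L) / (b - a + 2L)
    replaced <- rbind(replaced, c((a - 1L) / fs, b / fs))
  }
  attr(res, "replaced") <- replaced
  res
}

#' Invalidate trend samples over replaced signal intervals
#'
#' Marks trend samples whose fit windows overlap intervals where the f-wave
#' signal was replaced (ectopic beat windows bridged by interpolation during
#' QRST cancellation) as invalid: the frequency estimate there tracks an
#' artifact, not atrial activity. Each interval is padded by half a fit
#' window on both sides.
#'
#' @param trend a [FrequencyTrend-class].
#' @param windows two-column matrix of interval start/end times (s), e.g. the
#'   `"replaced"` attribute of [cancelQRST()]'s result.
#' @param pad padding on each side (s), default half a fit window plus one
#'   sample.
#' @return the trend with the affected samples marked invalid.
#' @export
maskTrendGaps <- function(trend, windows, pad = 0.26) {
  stopifnot(is(trend, "FrequencyTrend"))
  if (is.null(windows) || nrow(windows) == 0L) return(trend)
  valid <- trend@valid
  n <- length(valid)
  for (i in seq_len(nrow(windows))) {
    a <- max(1L, floor((windows[i, 1] - pad) * trend@fs) + 1L)
    b <- min(n, ceiling((windows[i, 2] + pad) * trend@fs))
    if (b >= a) valid[a:b] <- FALSE
  }
  initialize(trend, valid = valid)
}

#' Resample a residual to the 50 Hz f-wave rate
#'
#' Applies a zero-phase anti-aliasing low-pass (raised-cosine cutoff at
#' 24-25 Hz) and resamples to exactly 50 Hz. Output length is
#' `floor(duration * 50)`.
#'
#' @param x numeric residual waveform.
#' @param sourceFs source sampling rate (Hz), >= 100.
#' @param lead lead name recorded as provenance.
#' @return an [FWaveSignal-class].
#' @export
resampleTo50Hz <- function(x, sourceFs, lead = "V1") {
  if (sourceFs < 100) stop("sourceFs must be >= 100 Hz")
  xl <- .lowpass(x, sourceFs, 24, 25, pad = round(sourceFs))
  nOut <- floor(length(x) / sourceFs * 50)
  step <- sourceFs / 50
  if (abs(step - round(step)) < 1e-9) {
    y <- xl[1L + (seq_len(nOut) - 1L) * round(step)]
  } else {
    y <- stats::spline(x = (seq_along(xl) - 1L) / sourceFs, y = xl,
                       xout = (seq_len(nOut) - 1L) / 50)$y
  }
  new("FWaveSignal", x = y, fs = 50, lead = lead, sourceFs = sourceFs)
}

#' Mean heart rate over a phase window
#'
#' Average heart rate from RR intervals whose both beats lie inside the
#' window, excluding every interval adjacent to an ectopic beat:
#' `FHR = 60 / mean(RR)`.
#'
#' @param beats a [BeatSet-class].
#' @param window numeric length-2, start/end of the phase (s).
#' @return heart rate in bpm, or NA (with a warning) when fewer than two
#'   usable beats remain.
#' @export
meanHeartRate <- function(beats, window) {
  stopifnot(is(beats, "BeatSet"), length(window) == 2L)
  tb <- (beats@rPeaks - 1L) / beats@fs
  inside <- tb >= window[1] & tb <= window[2]
  if (sum(inside) < 2L) {
    warning("fewer than 2 beats in window; FHR missing")
    return(NA_real_)
  }
  tb <- tb[inside]; ect <- beats@ectopic[inside]
  rr <- diff(tb)
  ok <- !(ect[-length(ect)] | ect[-1])
  if (!any(ok)) {
    warning("no usable RR intervals in window; FHR missing")
    return(NA_real_)
  }
  60 / mean(rr[ok])
}
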