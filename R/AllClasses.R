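#' @import methods
NULL

#' Multi-lead sampled ECG record
#'
#' Container for a multi-lead ECG waveform together with its sampling rate and
#' the tilt-phase timeline. Samples are stored as a time-by-lead matrix in mV;
#' the timeline gives start/end (seconds from record start) of each protocol
#' phase (B1, B2, HDT1, HDT2, HUT1, HUT2 for the standard tilt protocol).
#'
#' @slot samples numeric matrix, rows = samples, named columns = leads (mV).
#' @slot fs sampling rate in Hz.
#' @slot phases data.frame with columns `phase`, `start`, `end` (seconds),
#'   non-overlapping and ordered; may have zero rows.
#' @export
setClass("ECGRecord",
  representation(samples = "matrix", fs = "numeric", phases = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@samples)) msg <- c(msg, "samples must be numeric")
    if (is.null(colnames(object@samples)) ||
        anyDuplicated(colnames(object@samples)))
      msg <- c(msg, "samples must have unique lead names as colnames")
    if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
      msg <- c(msg, "fs must be a single positive number")
    ph <- object@phases
    if (nrow(ph) > 0L) {
      if (!all(c("phase", "start", "end") %in% names(ph)))
        msg <- c(msg, "phases needs columns phase, start, end")
      else {
        if (any(ph$end <= ph$start)) msg <- c(msg, "phase end must exceed start")
        if (nrow(ph) > 1L && any(ph$start[-1] < ph$end[-nrow(ph)] - 1e-9))
          msg <- c(msg, "phases must be ordered and non-overlapping")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Construct an ECGRecord
#'
#' @param samples time-by-lead numeric matrix (mV) with lead names as colnames.
#' @param fs sampling rate (Hz).
#' @param phases optional data.frame (`phase`, `start`, `end` in seconds).
#' @return An [ECGRecord-class] object.
#' @export
ECGRecord <- function(samples, fs, phases = NULL) {
  if (is.null(phases))
    phases <- data.frame(phase = character(), start = numeric(),
                         end = numeric(), stringsAsFactors = FALSE)
  new("ECGRecord", samples = samples, fs = fs, phases = phases)
}

#' Detected beats with ectopic labels and normal templates
#'
#' R-peak sample indices on an [ECGRecord-class], per-beat ectopic flags and
#' template correlations, and the per-lead average normal (median) beat over a
#' fixed window around R.
#'
#' @slot rPeaks integer sample indices, strictly increasing.
#' @slot ectopic logical per beat.
#' @slot corr per-beat correlation with the normal template (NA where the beat
#'   window falls off the record).
#' @slot template window-by-lead matrix of the normal median beat (mV).
#' @slot window integer length-2 sample offsets of the beat window around R
#'   (default -250..+450 ms at the record's rate).
#' @slot fs sampling rate of the source record (Hz).
#' @slot detectionLead lead the beats were detected/classified on.
#' @export
setClass("BeatSet",
  representation(rPeaks = "integer", ectopic = "logical", corr = "numeric",
                 template = "matrix", window = "integer", fs = "numeric",
                 detectionLead = "character"),
  validity = function(object) {
    msg <- character()
    n <- length(object@rPeaks)
    if (n > 1L && any(diff(object@rPeaks) <= 0L))
      msg <- c(msg, "rPeaks must be strictly increasing")
    if (length(object@ectopic) != n) msg <- c(msg, "ectopic length mismatch")
    if (length(object@corr) != n) msg <- c(msg, "corr length mismatch")
    if (length(object@window) != 2L || object@window[1] >= object@window[2])
      msg <- c(msg, "window must be two increasing sample offsets")
    if (length(msg)) msg else TRUE
  })

#' Extracted f-wave signal at 50 Hz
#'
#' The atrial (f-wave) residual of one lead after QRST cancellation,
#' anti-alias filtered and resampled to exactly 50 Hz.
#'
#' @slot x numeric samples (mV) at 50 Hz.
#' @slot fs sampling rate, fixed at 50 Hz.
#' @slot lead source lead name.
#' @slot sourceFs sampling rate of the source record (Hz).
#' @export
setClass("FWaveSignal",
  representation(x = "numeric", fs = "numeric", lead = "character",
                 sourceFs = "numeric"),
  validity = function(object) {
    if (abs(object@fs - 50) > 1e-9) "fs must be exactly 50 Hz" else TRUE
  })

#' F-wave frequency trend with quality gating
#'
#' The fundamental-frequency series f(m) at 50 Hz from sliding-window harmonic
#' fits, a per-sample validity mask, the per-5-s signal quality index S, the
#' model reconstruction used for S, and the Welch anchor frequency f0 that
#' centres the +-1.5 Hz search interval.
#'
#' @slot f numeric frequency series (Hz), aligned sample-by-sample with the
#'   source f-wave signal; NA at window edges.
#' @slot valid logical mask; FALSE at edges and in blocks failing the S gate.
#' @slot sBlocks per-block quality index S (non-overlapping 5-s blocks).
#' @slot blockLength block length in samples.
#' @slot f0 Welch anchor frequency (Hz).
#' @slot fs trend sampling rate (50 Hz).
#' @slot recon complex model reconstruction of the analytic signal (NA at
#'   edges), used by the quality index.
#' @export
setClass("FrequencyTrend",
  representation(f = "numeric", valid = "logical", sBlocks = "numeric",
                 blockLength = "integer", f0 = "numeric", fs = "numeric",
                 recon = "complex"),
  validity = function(object) {
    msg <- character()
    if (length(object@valid) != length(object@f))
      msg <- c(msg, "valid mask length mismatch")
    if (length(object@recon) != length(object@f))
      msg <- c(msg, "recon length mismatch")
    ok <- object@valid & is.finite(object@f)
    if (any(ok) && length(object@f0) == 1L &&
        any(abs(object@f[ok] - object@f0) > 1.5 + 1e-6))
      msg <- c(msg, "valid samples must lie within [f0 - 1.5, f0 + 1.5]")
    if (any(is.finite(object@sBlocks) & object@sBlocks > 1 + 1e-12))
      msg <- c(msg, "S must not exceed 1")
    if (length(msg)) msg else TRUE
  })

#' Joint-lead ECG-derived respiration estimate
#'
#' Unit-variance respiration surrogate r(m) at 50 Hz from periodic component
#' analysis of per-lead QRS slope-range series, with the estimated respiration
#' rate FRR and the lead-combination weights.
#'
#' @slot r numeric series at 50 Hz aligned with the analysis grid; NA outside
#'   the span covered by beats.
#' @slot fs sampling rate (50 Hz).
#' @slot frr estimated respiration rate (Hz).
#' @slot weights per-lead combination vector (unit Euclidean norm).
#' @slot epsilon periodicity objective at the optimum (dimensionless; smaller
#'   means more periodic).
#' @export
setClass("RespirationEstimate",
  representation(r = "numeric", fs = "numeric", frr = "numeric",
                 weights = "numeric", epsilon = "numeric"),
  validity = function(object) {
    v <- stats::var(object@r[is.finite(object@r)])
    if (is.finite(v) && abs(v - 1) > 1e-6)
      "r must have unit variance over its finite span" else TRUE
  })

#' Per-point activation-time series from simulated atrial activity
#'
#' Activation times (s) of each extracted tissue point, as produced by
#' post-processing simulated transmembrane voltages (time of maximum upstroke
#' velocity per action potential).
#'
#' @slot times list of strictly increasing numeric vectors (seconds).
#' @slot ids character point identifiers.
#' @slot duration total covered duration (seconds).
#' @export
setClass("ActivationSet",
  representation(times = "list", ids = "character", duration = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@times) != length(object@ids))
      msg <- c(msg, "times/ids length mismatch")
    bad <- vapply(object@times, function(tt) {
      length(tt) < 2L || any(diff(tt) <= 0.03)
    }, logical(1))
    if (any(bad))
      msg <- c(msg, paste0(sum(bad), " point(s) violate the 30 ms ",
                           "refractoriness floor or have < 2 activations"))
    if (length(msg)) msg else TRUE
  })

#' Construct an ActivationSet
#'
#' @param times list of strictly increasing activation-time vectors (s).
#' @param ids optional point identifiers (default "p1", "p2", ...).
#' @param duration optional total duration; defaults to the latest activation.
#' @return An [ActivationSet-class] object.
#' @export
ActivationSet <- function(times, ids = NULL, duration = NULL) {
  if (is.null(ids)) ids <- paste0("p", seq_along(times))
  if (is.null(duration)) duration <- max(vapply(times, max, numeric(1)))
  new("ActivationSet", times = times, ids = as.character(ids),
      duration = duration)
}
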