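#' @rdname ECGRecord-class
setMethod("ecgSamples", "ECGRecord", function(x) x@samples)
#' @rdname ECGRecord-class
setMethod("samplingRate", "ECGRecord", function(x) x@fs)
#' @rdname ECGRecord-class
setMethod("leadNames", "ECGRecord", function(x) colnames(x@samples))
#' @rdname ECGRecord-class
setMethod("phaseTimeline", "ECGRecord", function(x) x@phases)

#' @rdname BeatSet-class
setMethod("rPeaks", "BeatSet", function(x) x@rPeaks)
#' @rdname BeatSet-class
setMethod("isEctopic", "BeatSet", function(x) x@ectopic)
#' @rdname BeatSet-class
setMethod("beatTemplate", "BeatSet", function(x) x@template)
#' @rdname BeatSet-class
setMethod("templateCorrelation", "BeatSet", function(x) x@corr)
#' @rdname BeatSet-class
setMethod("samplingRate", "BeatSet", function(x) x@fs)

#' @rdname FWaveSignal-class
setMethod("fwaveSamples", "FWaveSignal", function(x) x@x)
#' @rdname FWaveSignal-class
setMethod("samplingRate", "FWaveSignal", function(x) x@fs)

#' @rdname FrequencyTrend-class
setMethod("trendSeries", "FrequencyTrend", function(x) x@f)
#' @rdname FrequencyTrend-class
setMethod("trendValid", "FrequencyTrend", function(x) x@valid)
#' @rdname FrequencyTrend-class
setMethod("qualityBlocks", "FrequencyTrend", function(x) x@sBlocks)
#' @rdname FrequencyTrend-class
setMethod("anchorFrequency", "FrequencyTrend", function(x) x@f0)
#' @rdname FrequencyTrend-class
setMethod("samplingRate", "FrequencyTrend", function(x) x@fs)

#' @rdname RespirationEstimate-class
setMethod("respSeries", "RespirationEstimate", function(x) x@r)
#' @rdname RespirationEstimate-class
setMethod("respRate", "RespirationEstimate", function(x) x@frr)
#' @rdname RespirationEstimate-class
setMethod("respWeights", "RespirationEstimate", function(x) x@weights)
#' @rdname RespirationEstimate-class
setMethod("samplingRate", "RespirationEstimate", function(x) x@fs)

#' @rdname ActivationSet-class
setMethod("activationTimes", "ActivationSet", function(x) x@times)
#' @rdname ActivationSet-class
setMethod("pointIds", "ActivationSet", function(x) x@ids)

setMethod("show", "ECGRecord", function(object) {
  n <- nrow(object@samples)
  cat("ECGRecord:", ncol(object@samples), "lead(s) [",
      paste(colnames(object@samples), collapse = ", "), "],",
      n, "samples at", object@fs, "Hz (",
      sprintf("%.1f", n / object@fs), "s )\n")
  if (nrow(object@phases))
    cat("  phases:", paste(object@phases$phase, collapse = " "), "\n")
})

setMethod("show", "BeatSet", function(object) {
  cat("BeatSet:", length(object@rPeaks), "beats,",
      sum(object@ectopic), "ectopic; window",
      paste(object@window, collapse = ".."), "samples at",
      object@fs, "Hz, detection lead", object@detectionLead, "\n")
})

setMethod("show", "FWaveSignal", function(object) {
  cat("FWaveSignal: lead", object@lead, ",", length(object@x),
      "samples at 50 Hz (source", object@sourceFs, "Hz)\n")
})

setMethod("show", "FrequencyTrend", function(object) {
  cat("FrequencyTrend:", length(object@f), "samples at", object@fs,
      "Hz; f0 =", sprintf("%.2f", object@f0), "Hz;",
      sprintf("%.1f%%", 100 * mean(object@valid)), "valid;",
      length(object@sBlocks), "quality blocks\n")
})

setMethod("show", "RespirationEstimate", function(object) {
  cat("RespirationEstimate: FRR =", sprintf("%.3f", object@frr), "Hz;",
      length(object@weights), "lead weights\n")
})

setMethod("show", "ActivationSet", function(object) {
  nact <- vapply(object@times, length, integer(1))
  cat("ActivationSet:", length(object@times), "points,",
      sum(nact), "activations over", sprintf("%.1f", object@duration), "s\n")
})
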