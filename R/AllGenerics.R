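# Accessor generics for the signal containers. Slot access outside the
# package should go through these.

#' @rdname ECGRecord-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("ecgSamples", function(x) standardGeneric("ecgSamples"))
#' @rdname ECGRecord-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname ECGRecord-class
#' @export
setGeneric("leadNames", function(x) standardGeneric("leadNames"))
#' @rdname ECGRecord-class
#' @export
setGeneric("phaseTimeline", function(x) standardGeneric("phaseTimeline"))

#' @rdname BeatSet-class
#' @param x a `BeatSet`.
#' @export
setGeneric("rPeaks", function(x) standardGeneric("rPeaks"))
#' @rdname BeatSet-class
#' @export
setGeneric("isEctopic", function(x) standardGeneric("isEctopic"))
#' @rdname BeatSet-class
#' @export
setGeneric("beatTemplate", function(x) standardGeneric("beatTemplate"))
#' @rdname BeatSet-class
#' @export
setGeneric("templateCorrelation", function(x) standardGeneric("templateCorrelation"))

#' @rdname FWaveSignal-class
#' @param x an `FWaveSignal`.
#' @export
setGeneric("fwaveSamples", function(x) standardGeneric("fwaveSamples"))

#' @rdname FrequencyTrend-class
#' @param x a `FrequencyTrend`.
#' @export
setGeneric("trendSeries", function(x) standardGeneric("trendSeries"))
#' @rdname FrequencyTrend-class
#' @export
setGeneric("trendValid", function(x) standardGeneric("trendValid"))
#' @rdname FrequencyTrend-class
#' @export
setGeneric("qualityBlocks", function(x) standardGeneric("qualityBlocks"))
#' @rdname FrequencyTrend-class
#' @export
setGeneric("anchorFrequency", function(x) standardGeneric("anchorFrequency"))

#' @rdname RespirationEstimate-class
#' @param x a `RespirationEstimate`.
#' @export
setGeneric("respSeries", function(x) standardGeneric("respSeries"))
#' @rdname RespirationEstimate-class
#' @export
setGeneric("respRate", function(x) standardGeneric("respRate"))
#' @rdname RespirationEstimate-class
#' @export
setGeneric("respWeights", function(x) standardGeneric("respWeights"))

#' @rdname ActivationSet-class
#' @export
setGeneric("activationTimes", function(x) standardGeneric("activationTimes"))
#' @rdname ActivationSet-class
#' @export
setGeneric("pointIds", function(x) standardGeneric("pointIds"))
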