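# Pipeline orchestration: the full per-recording ECG analysis (preprocessing
# -> frequency trend -> respiration -> modulation, per phase) and the batch
# activation-time analysis. Every exclusion is logged with the rule that
# caused it.

#' Run the full ECG analysis pipeline on one recording
#'
#' Detects and classifies beats, cancels the QRST complexes on the analysis
#' lead, extracts the 50 Hz f-wave signal, tracks the f-wave frequency with
#' quality gating, derives the joint-lead respiration per phase, and computes
#' the per-phase metrics Ff, FHR, FRR, dFf and Pr. A recording failing the
#' 10% bad-block rule is reported as excluded, never silently dropped.
#'
#' @param record an [ECGRecord-class] with a phase timeline (six-phase tilt
#'   defaults are assumed when absent: 2+3 minutes per 5-minute position).
#' @param config an [defaultAnalysisConfig()] list.
#' @param patient patient identifier for the output table.
#' @return list with `table` (one row per phase: `patient`, `phase`,
#'   `ff_hz`, `fhr_bpm`, `frr_hz`, `delta_ff_hz`, `pr_pct`,
#'   `valid_fraction`, `interp_fraction`), `excluded` (logical), `log`
#'   (character), and the intermediate objects (`beats`, `fwave`, `trend`).
#' @export
runEcgPipeline <- function(record, config = defaultAnalysisConfig(),
                           patient = "p1") {
  stopifnot(is(record, "ECGRecord"))
  logLines <- character()
  note <- function(...) {
    line <- paste0(...)
    logLines <<- c(logLines, line)
    line
  }
  phases <- record@phases
  if (!nrow(phases)) {
    dur <- nrow(record@samples) / record@fs
    starts <- cumsum(c(0, 120, 180, 120, 180, 120))
    phases <- data.frame(phase = .protocolPhases, start = starts,
                         end = c(starts[-1], 900), stringsAsFactors = FALSE)
    phases <- phases[phases$end <= dur + 1e-9, ]
    note("no phase timeline on record; applied protocol defaults (",
         nrow(phases), " phases)")
  }
  rp <- detectBeats(record, lead = config$detectionLead)
  beats <- classifyEctopic(record, rp, lead = config$detectionLead,
                           corrThreshold = config$corrThreshold,
                           rrTol = config$rrTol,
                           window = config$beatWindow)
  note(length(rp), " beats detected, ", sum(beats@ectopic),
       " classified ectopic")
  residual <- cancelQRST(record, beats, config$analysisLead)
  fwave <- resampleTo50Hz(residual, record@fs, lead = config$analysisLead)
  xa <- analyticSignal(fwave)
  f0 <- welchAnchor(fwave, band = config$anchorBand)
  trend <- frequencyTrend(xa, f0, gridStep = config$gridStep,
                          tol = config$goldenTol)
  trend <- withCallingHandlers(
    qualityIndex(xa, trend, threshold = config$sThreshold),
    warning = function(w) {
      note("quality index: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  trend <- maskTrendGaps(trend, attr(residual, "replaced"))
  usable <- recordingGate(trend, threshold = config$sThreshold,
                          maxBadFraction = config$recordingBadFraction)
  badFrac <- mean(is.na(trend@sBlocks) | trend@sBlocks <= config$sThreshold)
  if (!usable) {
    note(sprintf(paste0("recording EXCLUDED: %.1f%% of 5-s blocks fail the ",
                        "S > %.2g gate (limit %.0f%%)"),
                 100 * badFrac, config$sThreshold,
                 100 * config$recordingBadFraction))
    return(list(table = NULL, excluded = TRUE, log = logLines,
                beats = beats, fwave = fwave, trend = trend))
  }
  note(sprintf("recording usable: %.1f%% bad blocks (S gate %.2g)",
               100 * badFrac, config$sThreshold))
  nGrid <- length(trend@f)
  srAll <- tryCatch(
    lapply(colnames(record@samples), function(ld)
      slopeRangeSeries(record, beats, ld)),
    error = function(e) {
      note("slope-range series unavailable - ", conditionMessage(e))
      NULL
    })
  rows <- vector("list", nrow(phases))
  for (i in seq_len(nrow(phases))) {
    win <- c(phases$start[i], phases$end[i])
    ph <- phases$phase[i]
    fhr <- withCallingHandlers(
      meanHeartRate(beats, win),
      warning = function(w) {
        note(ph, ": FHR missing - ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    ff <- withCallingHandlers(
      phaseMedianFrequency(trend, win,
                           minValidFraction = config$minValidFraction),
      warning = function(w) {
        note(ph, ": Ff missing - ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    # per-phase joint-lead respiration
    resp <- tryCatch({
      if (is.null(srAll)) stop("no slope-range series")
      inWin <- srAll[[1]]$times >= win[1] & srAll[[1]]$times <= win[2]
      serim <- lapply(srAll, function(s)
        interpolateResp(s$values[inWin], s$times[inWin], n = nGrid,
                        band = config$respBand))
      suppressWarnings(jointRespiration(serim, band = config$respBand))
    }, error = function(e) {
      note(ph, ": respiration missing - ", conditionMessage(e))
      NULL
    })
    frr <- if (is.null(resp)) NA_real_ else resp@frr
    if (!is.null(resp)) {
      osp <- withCallingHandlers(
        phaseModulation(trend, resp, win, q = config$qDelays,
                        maxGap = config$maxGapSeconds,
                        minRun = config$minRunSeconds),
        warning = function(w) {
          note(ph, ": modulation - ", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
    } else {
      osp <- list(deltaFf = NA_real_, pr = NA_real_,
                  interpFraction = NA_real_)
    }
    idx <- .windowIndices(win, trend@fs, nGrid)
    rows[[i]] <- data.frame(
      patient = patient, phase = ph, ff_hz = ff, fhr_bpm = fhr,
      frr_hz = frr, delta_ff_hz = osp$deltaFf, pr_pct = osp$pr,
      valid_fraction = mean(trend@valid[idx]),
      interp_fraction = osp$interpFraction, stringsAsFactors = FALSE)
  }
  list(table = do.call(rbind, rows), excluded = FALSE, log = logLines,
       beats = beats, fwave = fwave, trend = trend)
}

#' Run the activation-time analysis over a batch of files
#'
#' For each activation set: per-point instantaneous frequency at 10 Hz,
#' spectral peak-conditioned selection, mean trend fs(m), Ffs (median over
#' time) and dFfs against the fixed-rate reference sinusoid. By default the
#' analysis is restricted to the final `activationWindowSeconds` (10 s, the
#' simulation analysis window); set it to NULL for the full record. Malformed
#' files yield a per-file error row and the batch continues.
#'
#' @param inputs character vector of file paths (see [readActivationText()])
#'   or a list of [ActivationSet-class] objects.
#' @param config an [defaultAnalysisConfig()] list.
#' @return list with `table` (per input: `input`, `n_points`, `n_retained`,
#'   `ffs_hz`, `delta_ffs_hz`, `error`) and `log`.
#' @export
runActivationPipeline <- function(inputs, config = defaultAnalysisConfig()) {
  if (is(inputs, "ActivationSet")) inputs <- list(inputs)
  nm <- if (is.character(inputs)) inputs else
    paste0("set", seq_along(inputs))
  logLines <- character()
  rows <- vector("list", length(inputs))
  for (i in seq_along(inputs)) {
    rows[[i]] <- tryCatch({
      set <- if (is.character(inputs)) readActivationText(inputs[[i]]) else
        inputs[[i]]
      win <- config$activationWindowSeconds
      times <- activationTimes(set)
      if (!is.null(win)) {
        t1 <- max(vapply(times, max, numeric(1)))
        times <- lapply(times, function(tt) tt[tt >= t1 - win - 0.5])
      }
      fcs <- suppressWarnings(lapply(times, instantaneousFrequency))
      retained <- peakConditionedSelection(
        fcs, minFraction = config$peakFraction,
        halfBand = config$peakHalfBand)
      tr <- meanActivationTrend(fcs, retained)
      dd <- suppressWarnings(
        deltaFfs(tr, respRate = config$simRespRate,
                 minSeconds = min(10, if (is.null(win)) 10 else win)))
      data.frame(input = nm[i], n_points = length(activationTimes(set)),
                 n_retained = sum(retained), ffs_hz = tr$ffs,
                 delta_ffs_hz = dd$deltaFfs, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      logLines <<- c(logLines, paste0(nm[i], ": ERROR - ",
                                      conditionMessage(e)))
      data.frame(input = nm[i], n_points = NA_integer_,
                 n_retained = NA_integer_, ffs_hz = NA_real_,
                 delta_ffs_hz = NA_real_, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
  }
  list(table = do.call(rbind, rows), log = logLines)
}
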