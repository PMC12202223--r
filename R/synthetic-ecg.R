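# Synthetic tilt-test ECG generator. Emulates the statistical structure of
# clinical persistent-AF tilt recordings with fully known ground truth:
# two-harmonic f-waves whose fundamental is sinusoidally modulated at the
# respiration rate, irregular (log-normal RR) ventricular activity with
# respiratory QRS-morphology modulation and occasional ectopic beats, and
# additive broadband noise.

#' F-wave generator parameters
#'
#' Parameters of the synthetic fibrillatory-wave model: a two-harmonic
#' waveform whose fundamental frequency is the sum of a phase mean, a
#' respiratory sinusoid (peak amplitude `modAmplitude`, the ground truth for
#' the respiratory f-wave modulation magnitude) and a slow Ornstein-Uhlenbeck
#' drift. Defaults follow the baseline (B1) operating point of a persistent-AF
#' tilt cohort: fundamental 6.74 Hz, modulation 0.077 Hz at a 0.13 Hz
#' respiration rate.
#'
#' @param ffMean mean fundamental frequency (Hz), in \[4, 12\].
#' @param modAmplitude peak amplitude of the respiratory frequency modulation
#'   (Hz), >= 0.
#' @param respRate respiration rate (Hz), in (0.05, 0.6).
#' @param a1,a2 amplitudes (mV) of the fundamental and second harmonic;
#'   `a1 > 0`, `a2 >= 0`.
#' @param driftSd stationary standard deviation of the slow frequency drift
#'   (Hz).
#' @param noiseSd additive white-noise standard deviation (mV).
#' @return validated parameter list of class `fWaveParams`.
#' @export
fWaveParams <- function(ffMean = 6.74, modAmplitude = 0.077, respRate = 0.13,
                        a1 = 0.1, a2 = 0.04, driftSd = 0.05, noiseSd = 0.15) {
  stopifnot(ffMean >= 4, ffMean <= 12, modAmplitude >= 0,
            respRate > 0.05, respRate < 0.6, a1 > 0, a2 >= 0,
            driftSd >= 0, noiseSd >= 0)
  structure(list(ffMean = ffMean, modAmplitude = modAmplitude,
                 respRate = respRate, a1 = a1, a2 = a2,
                 driftSd = driftSd, noiseSd = noiseSd),
            class = "fWaveParams")
}

#' Ventricular generator parameters
#'
#' Parameters of the synthetic ventricular (QRST) activity: log-normal i.i.d.
#' RR intervals (AF-like weakly correlated rhythm) with configurable mean rate
#' and coefficient of variation, respiratory amplitude modulation of the beat
#' template, and a fraction of morphologically deviant (widened,
#' polarity-inverted) ectopic beats. Defaults follow the baseline operating
#' point: 93.5 bpm, 1.07% ectopic prevalence.
#'
#' @param meanHr mean heart rate (bpm), in \[40, 180\].
#' @param rrCv coefficient of variation of RR intervals (dimensionless).
#' @param respMorphGain fractional respiratory modulation of beat amplitude.
#' @param ectopicRate probability a beat is ectopic, in \[0, 0.2\].
#' @param qrsWidth nominal QRS width (ms).
#' @param tWaveAmp T-wave amplitude (mV).
#' @return validated parameter list of class `ventricularParams`.
#' @export
ventricularParams <- function(meanHr = 93.5, rrCv = 0.15, respMorphGain = 0.2,
                              ectopicRate = 0.0107, qrsWidth = 90,
                              tWaveAmp = 0.25) {
  stopifnot(meanHr >= 40, meanHr <= 180, rrCv >= 0,
            ectopicRate >= 0, ectopicRate <= 0.2, qrsWidth > 20,
            tWaveAmp >= 0)
  structure(list(meanHr = meanHr, rrCv = rrCv, respMorphGain = respMorphGain,
                 ectopicRate = ectopicRate, qrsWidth = qrsWidth,
                 tWaveAmp = tWaveAmp),
            class = "ventricularParams")
}

.protocolPhases <- c("B1", "B2", "HDT1", "HDT2", "HUT1", "HUT2")

#' Six-phase tilt scenario
#'
#' Describes a full synthetic tilt recording: the six protocol phases (B1, B2,
#' HDT1, HDT2, HUT1, HUT2; 2 + 3 minutes per 5-minute tilt position) with
#' per-phase f-wave and ventricular parameters, plus the RNG seed. The
#' per-phase defaults are the observed cohort medians of the corresponding
#' tilt study phases, so the default scenario *is* the calibrated study
#' condition.
#'
#' @param seed integer RNG seed recorded with the scenario.
#' @param ffMean,modAmplitude,respRate length-6 numeric vectors (recycled) of
#'   per-phase f-wave fundamental (Hz), respiratory modulation amplitude (Hz)
#'   and respiration rate (Hz).
#' @param meanHr length-6 vector (recycled) of per-phase mean heart rate (bpm).
#' @param durations per-phase durations in seconds (default 120/180 pattern).
#' @param fs record sampling rate (Hz), default 1000.
#' @param noiseSd broadband noise standard deviation (mV), default 0.15.
#' @param ... further arguments passed to [fWaveParams()] / shared by phases
#'   via `fwArgs` and `ventArgs`.
#' @param fwArgs named list of extra [fWaveParams()] arguments.
#' @param ventArgs named list of extra [ventricularParams()] arguments.
#' @return scenario list of class `tiltScenario`.
#' @export
tiltScenario <- function(seed = 1L,
                         ffMean = c(6.74, 6.69, 6.49, 6.55, 6.77, 6.72),
                         modAmplitude = c(0.077, 0.070, 0.090, 0.063,
                                          0.081, 0.079),
                         respRate = c(0.13, 0.13, 0.15, 0.16, 0.12, 0.15),
                         meanHr = c(93.5, 89.75, 90.25, 93.5, 98.5, 96),
                         durations = c(120, 180, 120, 180, 120, 180),
                         fs = 1000, noiseSd = 0.15,
                         fwArgs = list(), ventArgs = list()) {
  stopifnot(length(durations) == 6L, all(durations > 0), fs >= 250)
  ffMean <- rep_len(ffMean, 6L)
  modAmplitude <- rep_len(modAmplitude, 6L)
  respRate <- rep_len(respRate, 6L)
  meanHr <- rep_len(meanHr, 6L)
  phases <- lapply(seq_len(6L), function(i) {
    list(name = .protocolPhases[i], duration = durations[i],
         fwave = do.call(fWaveParams,
                         c(list(ffMean = ffMean[i],
                                modAmplitude = modAmplitude[i],
                                respRate = respRate[i], noiseSd = 0),
                           fwArgs)),
         vent = do.call(ventricularParams,
                        c(list(meanHr = meanHr[i]), ventArgs)))
  })
  structure(list(phases = phases, seed = as.integer(seed), fs = fs,
                 noiseSd = noiseSd),
            class = "tiltScenario")
}

# Clipped Ornstein-Uhlenbeck drift with stationary sd `sd` and correlation
# time `tau` (s); clipped at +-clip Hz so the fundamental stays inside the
# +-1.5 Hz constrained search interval of the frequency tracker.
.ouDrift <- function(n, fs, sd, tau = 30, clip = 1.0) {
  if (sd <= 0 || n == 0L) return(numeric(n))
  a <- exp(-1 / (fs * tau))
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - a^2))
  x <- stats::filter(innov, a, method = "recursive")
  pmin(pmax(as.numeric(x), -clip), clip)
}

#' Generate a synthetic f-wave signal
#'
#' Produces a two-harmonic fibrillatory waveform whose instantaneous
#' fundamental frequency is `ffMean + modAmplitude * sin(2 pi respRate t)`
#' plus a slow clipped Ornstein-Uhlenbeck drift, with additive white noise:
#' `x(t) = sum_p A_p cos(p phi(t) + phi_p) + e(t)` where
#' `phi(t) = 2 pi integral of f_true`. Harmonic phase offsets are drawn
#' uniformly. Optional noise bursts exercise the downstream quality gate.
#'
#' @param params an [fWaveParams()] list.
#' @param duration signal duration (s), > 0.
#' @param fs sampling rate (Hz), >= 50.
#' @param bursts optional data.frame with columns `start`, `duration` (s) and
#'   `sd` (mV): extra white noise injected over those windows.
#' @return list with `signal` (numeric, mV) and `fTrue` (instantaneous
#'   fundamental frequency, Hz, at `fs`).
#' @export
generateFWave <- function(params, duration, fs = 1000, bursts = NULL) {
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be positive")
  if (!is.numeric(fs) || fs < 50) stop("fs must be >= 50 Hz")
  n <- round(duration * fs)
  t <- (seq_len(n) - 1L) / fs
  drift <- .ouDrift(n, fs, params$driftSd)
  fTrue <- params$ffMean +
    params$modAmplitude * sin(2 * pi * params$respRate * t) + drift
  phase <- 2 * pi * cumsum(fTrue) / fs
  phi <- stats::runif(2, -pi, pi)
  x <- params$a1 * cos(phase + phi[1]) + params$a2 * cos(2 * phase + phi[2])
  if (params$noiseSd > 0) x <- x + stats::rnorm(n, 0, params$noiseSd)
  if (!is.null(bursts) && nrow(bursts)) {
    for (i in seq_len(nrow(bursts))) {
      idx <- .windowIndices(c(bursts$start[i],
                              bursts$start[i] + bursts$duration[i]), fs, n)
      x[idx] <- x[idx] + stats::rnorm(length(idx), 0, bursts$sd[i])
    }
  }
  list(signal = x, fTrue = fTrue)
}

# Sum-of-Gaussians QRST template evaluated at offsets tt (s) from the R peak.
# Ectopic variant: widened, polarity-inverted, slightly larger.
.qrstTemplate <- function(tt, qrsWidthMs = 90, tWaveAmp = 0.25,
                          ectopic = FALSE) {
  w <- qrsWidthMs / 1000
  g <- function(a, mu, sd) a * exp(-0.5 * ((tt - mu) / sd)^2)
  if (!ectopic) {
    g(-0.12, -0.40 * w, w / 7) + g(1, 0, w / 6) +
      g(-0.25, 0.45 * w, w / 6.5) + g(tWaveAmp, 0.30, 0.06)
  } else {
    -1.2 * (g(1, 0, w / 3) + g(-0.3, 0.8 * w, w / 3)) -
      g(tWaveAmp * 1.3, 0.36, 0.08)
  }
}

#' Generate synthetic ventricular (QRST) activity
#'
#' Emits QRST complexes (sum-of-Gaussians template) at i.i.d. log-normal RR
#' intervals with mean `60 / meanHr` s and coefficient of variation `rrCv`.
#' The whole beat template is amplitude-scaled by
#' `1 + respMorphGain * sin(2 pi respRate t)` at the beat time, emulating
#' respiratory morphology modulation; beats are independently replaced by a
#' widened inverted-polarity ectopic template with probability `ectopicRate`.
#'
#' @param params a [ventricularParams()] list.
#' @param duration signal duration (s).
#' @param fs sampling rate (Hz), >= 250.
#' @param respRate respiratory modulation rate (Hz).
#' @return list with `signal` (numeric, mV), `beatTimes` (s), `ectopic`
#'   (logical per beat).
#' @export
generateVentricular <- function(params, duration, fs = 1000,
                                respRate = 0.13) {
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be positive")
  if (!is.numeric(fs) || fs < 250) stop("fs must be >= 250 Hz")
  meanRR <- 60 / params$meanHr
  nMax <- ceiling(duration / meanRR * 2) + 10L
  if (params$rrCv > 0) {
    sdlog <- sqrt(log(1 + params$rrCv^2))
    rr <- stats::rlnorm(nMax, log(meanRR) - sdlog^2 / 2, sdlog)
  } else {
    rr <- rep(meanRR, nMax)
  }
  beatTimes <- stats::runif(1, 0.1, 0.1 + meanRR) + cumsum(c(0, rr))
  beatTimes <- beatTimes[beatTimes < duration - 0.05]
  nb <- length(beatTimes)
  ectopic <- stats::runif(nb) < params$ectopicRate
  n <- round(duration * fs)
  x <- numeric(n)
  half <- c(-0.30, 0.55)
  for (i in seq_len(nb)) {
    i1 <- max(1L, floor((beatTimes[i] + half[1]) * fs) + 1L)
    i2 <- min(n, floor((beatTimes[i] + half[2]) * fs) + 1L)
    tt <- (i1:i2 - 1L) / fs - beatTimes[i]
    amp <- 1 + params$respMorphGain * sin(2 * pi * respRate * beatTimes[i])
    x[i1:i2] <- x[i1:i2] +
      amp * .qrstTemplate(tt, params$qrsWidth, params$tWaveAmp, ectopic[i])
  }
  list(signal = x, beatTimes = beatTimes, ectopic = ectopic)
}

# Lead projection gains. V1 carries the largest f-wave (the analysis lead);
# lead II carries the largest QRS (the default detection lead).
.leadGains <- function() {
  list(leads = c("V1", "II"),
       fwave = c(V1 = 1, II = 1 / 3),
       vent = c(V1 = 0.8, II = 1.1))
}

#' Generate a full synthetic tilt recording
#'
#' Concatenates the six scenario phases into a two-lead record
#' (V1 + II; the f-wave projects strongest on V1, the QRS strongest on II),
#' embeds the phase timeline, and returns the complete ground truth. Setting
#' the scenario seed makes the output bit-reproducible.
#'
#' @param scenario a [tiltScenario()] object.
#' @param bursts optional data.frame (`start`, `duration`, `sd`, record-level
#'   seconds) of injected noise bursts, applied to every lead.
#' @return list with `record` ([ECGRecord-class]) and `truth`, a list holding
#'   `phases` (per-phase data.frame of true Ff, modulation amplitude,
#'   respiration rate, nominal and realized heart rate), `fTrue` (full true
#'   fundamental trend at the record rate), `beatTimes`, `ectopic` and the
#'   scenario seed.
#' @export
generateTiltRecording <- function(scenario, bursts = NULL) {
  stopifnot(inherits(scenario, "tiltScenario"))
  set.seed(scenario$seed)
  fs <- scenario$fs
  gains <- .leadGains()
  durations <- vapply(scenario$phases, `[[`, numeric(1), "duration")
  starts <- cumsum(c(0, durations[-length(durations)]))
  sig <- list(); fTrueAll <- list(); beatTimes <- numeric(); ect <- logical()
  truthRows <- vector("list", length(scenario$phases))
  for (i in seq_along(scenario$phases)) {
    ph <- scenario$phases[[i]]
    fw <- generateFWave(ph$fwave, ph$duration, fs)
    vt <- generateVentricular(ph$vent, ph$duration, fs,
                              respRate = ph$fwave$respRate)
    n <- length(fw$signal)
    leads <- vapply(gains$leads, function(ld) {
      gains$vent[ld] * vt$signal + gains$fwave[ld] * fw$signal +
        stats::rnorm(n, 0, scenario$noiseSd)
    }, numeric(n))
    sig[[i]] <- leads
    fTrueAll[[i]] <- fw$fTrue
    beatTimes <- c(beatTimes, vt$beatTimes + starts[i])
    ect <- c(ect, vt$ectopic)
    rrOk <- diff(vt$beatTimes)[!(vt$ectopic[-1] |
                                   vt$ectopic[-length(vt$ectopic)])]
    truthRows[[i]] <- data.frame(
      phase = ph$name, start = starts[i], end = starts[i] + ph$duration,
      ffMean = ph$fwave$ffMean, modAmplitude = ph$fwave$modAmplitude,
      respRate = ph$fwave$respRate, meanHr = ph$vent$meanHr,
      realizedHr = 60 / mean(rrOk), nBeats = length(vt$beatTimes),
      stringsAsFactors = FALSE)
  }
  samples <- do.call(rbind, sig)
  colnames(samples) <- gains$leads
  phases <- data.frame(phase = vapply(scenario$phases, `[[`, character(1),
                                      "name"),
                       start = starts, end = starts + durations,
                       stringsAsFactors = FALSE)
  record <- ECGRecord(samples, fs, phases)
  if (!is.null(bursts) && nrow(bursts)) {
    for (i in seq_len(nrow(bursts))) {
      idx <- .windowIndices(c(bursts$start[i],
                              bursts$start[i] + bursts$duration[i]),
                            fs, nrow(samples))
      record@samples[idx, ] <- record@samples[idx, ] +
        stats::rnorm(length(idx) * ncol(samples), 0, bursts$sd[i])
    }
  }
  truth <- list(phases = do.call(rbind, truthRows),
                fTrue = unlist(fTrueAll), fs = fs,
                beatTimes = beatTimes, ectopic = ect,
                seed = scenario$seed)
  list(record = record, truth = truth)
}

#' Generate synthetic activation-time series
#'
#' Emulates post-processed simulation output: per-point activation times whose
#' instantaneous rate is `baseFreq + modAmplitude * sin(2 pi respRate t)`,
#' plus Gaussian timing jitter. A fraction of points instead get broadband
#' random rates (no periodic component), to exercise the downstream
#' peak-conditioned rejection.
#'
#' @param nPoints number of extracted tissue points (223 matches a 3D
#'   whole-atria extraction; 169 a 2D sheet).
#' @param duration covered duration (s).
#' @param baseFreq mean activation rate (Hz), > 0.
#' @param modAmplitude peak amplitude of the sinusoidal rate modulation (Hz).
#' @param respRate modulation frequency (Hz).
#' @param jitterSd per-activation timing jitter (s).
#' @param fracUnpeaked fraction of points given broadband random rates,
#'   in \[0, 1).
#' @return list with `set` ([ActivationSet-class]) and `unpeaked` (logical
#'   ground-truth labels per point).
#' @export
generateActivationSeries <- function(nPoints = 223, duration = 60,
                                     baseFreq = 8.25, modAmplitude = 0.13,
                                     respRate = 0.14, jitterSd = 0.001,
                                     fracUnpeaked = 0) {
  stopifnot(baseFreq > 0, fracUnpeaked >= 0, fracUnpeaked < 1,
            nPoints >= 1, duration > 0, modAmplitude >= 0, jitterSd >= 0)
  unpeaked <- seq_len(nPoints) <= round(fracUnpeaked * nPoints)
  unpeaked <- sample(unpeaked)
  tg <- seq(0, duration, by = 1e-3)
  Phi <- baseFreq * tg + if (modAmplitude > 0)
    modAmplitude / (2 * pi * respRate) *
      (1 - cos(2 * pi * respRate * tg)) else 0
  times <- lapply(seq_len(nPoints), function(c) {
    if (!unpeaked[c]) {
      u0 <- stats::runif(1)
      k <- seq(u0, max(Phi), by = 1)
      tt <- stats::approx(Phi, tg, xout = k)$y
      if (jitterSd > 0) tt <- tt + stats::rnorm(length(tt), 0, jitterSd)
    } else {
      iv <- 1 / (baseFreq + stats::runif(ceiling(duration * (baseFreq + 2)),
                                         -1.5, 1.5))
      tt <- stats::runif(1, 0, 1 / baseFreq) + cumsum(iv)
      tt <- tt[tt <= duration]
    }
    tt <- sort(tt)
    # enforce the physiological refractoriness floor
    keep <- c(TRUE, diff(tt) > 0.031)
    while (!all(keep)) {
      tt <- tt[keep]
      keep <- c(TRUE, diff(tt) > 0.031)
    }
    tt
  })
  list(set = ActivationSet(times, duration = duration), unpeaked = unpeaked)
}
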