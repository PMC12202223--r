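# Shared fixtures, built in code and memoized for the session.

.fixtures <- new.env(parent = emptyenv())

# One default-noise 120-s single-phase recording with truth, beats and the
# f-wave chain, reused across test files.
fixtureRecording <- function() {
  if (is.null(.fixtures$rec)) {
    sc <- tiltScenario(seed = 7)
    sc$phases <- sc$phases[1]
    sc$phases[[1]]$duration <- 120
    gen <- generateTiltRecording(sc)
    rec <- gen$record
    rec@phases <- data.frame(phase = "B1", start = 0, end = 120,
                             stringsAsFactors = FALSE)
    rp <- detectBeats(rec)
    beats <- classifyEctopic(rec, rp)
    fw <- resampleTo50Hz(cancelQRST(rec, beats, "V1"), samplingRate(rec))
    xa <- analyticSignal(fw)
    trend <- qualityIndex(xa, frequencyTrend(xa, welchAnchor(fw)))
    .fixtures$rec <- list(record = rec, truth = gen$truth, rPeaks = rp,
                          beats = beats, fwave = fw, xa = xa, trend = trend)
  }
  .fixtures$rec
}

# A BeatSet with no beats (for the nothing-to-subtract contract).
emptyBeatSet <- function(fs) {
  new("BeatSet", rPeaks = integer(), ectopic = logical(), corr = numeric(),
      template = matrix(0, 701, 1, dimnames = list(NULL, "V1")),
      window = c(-250L, 450L), fs = fs, detectionLead = "V1")
}

# Noiseless two-harmonic analytic-model window (the exact fit model).
harmonicWindow <- function(f, a1, a2, phi1, phi2, n = 25L, fs = 50) {
  idx <- 0:(n - 1L)
  a1 * exp(1i * (2 * pi * f * idx / fs + phi1)) +
    a2 * exp(1i * (2 * pi * 2 * f * idx / fs + phi2))
}

# Brute-force signed-rank two-sided p over all 2^n sign assignments.
bruteSignedRankP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  wObs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w <- as.matrix(signs) %*% r
  pLe <- mean(w <= wObs + 1e-9)
  pGe <- mean(w >= wObs - 1e-9)
  min(1, 2 * min(pLe, pGe))
}

# Synthetic per-patient metrics table (no ECG involved).
metricsTable <- function(nPatients, means, sd = 0.05, metric = "ff_hz") {
  phases <- names(means)
  df <- expand.grid(patient = paste0("p", seq_len(nPatients)),
                    phase = phases, stringsAsFactors = FALSE)
  df[[metric]] <- unlist(lapply(phases, function(ph)
    rnorm(nPatients, means[[ph]], sd)))
  df
}
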