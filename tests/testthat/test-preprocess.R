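# Beat detection, ectopic classification, QRST cancellation, resampling, FHR.

test_that("detector recovers metronomic beats to sample accuracy", {
  set.seed(11)
  v <- generateVentricular(ventricularParams(meanHr = 90, rrCv = 0,
                                             ectopicRate = 0),
                           duration = 60, fs = 500)
  rec <- ECGRecord(matrix(v$signal, dimnames = list(NULL, "II")), 500)
  rp <- detectBeats(rec)
  rr <- diff(rp) / 500 * 1000
  expect_true(all(abs(rr - 666.67) <= 2))
})

test_that("detector matches generator truth on default-noise records", {
  fx <- fixtureRecording()
  det <- (fx$rPeaks - 1) / samplingRate(fx$record)
  d <- vapply(fx$truth$beatTimes,
              function(t) min(abs(det - t)), numeric(1))
  expect_gte(mean(d < 0.02), 0.99)
})

test_that("degenerate inputs are rejected", {
  z <- ECGRecord(matrix(0, 5000, 1, dimnames = list(NULL, "II")), 1000)
  expect_error(detectBeats(z), "10 s")
  z2 <- ECGRecord(matrix(0, 15000, 1, dimnames = list(NULL, "II")), 1000)
  expect_error(detectBeats(z2), "no beats")
  expect_error(classifyEctopic(fixtureRecording()$record, 1:5),
               "insufficient beats")
})

test_that("ectopic classification meets sensitivity and specificity targets", {
  tp <- fp <- tn <- fn <- 0L
  for (seed in c(12, 112, 212)) {
    sc <- tiltScenario(seed = seed, meanHr = 95,
                       ventArgs = list(ectopicRate = 0.05))
    sc$phases <- sc$phases[1]
    sc$phases[[1]]$duration <- 300
    gen <- generateTiltRecording(sc)
    rp <- detectBeats(gen$record)
    beats <- classifyEctopic(gen$record, rp)
    det <- (rPeaks(beats) - 1) / 1000
    truthLab <- vapply(det, function(t) {
      i <- which.min(abs(gen$truth$beatTimes - t))
      gen$truth$ectopic[i]
    }, logical(1))
    tp <- tp + sum(isEctopic(beats) & truthLab)
    fn <- fn + sum(!isEctopic(beats) & truthLab)
    fp <- fp + sum(isEctopic(beats) & !truthLab)
    tn <- tn + sum(!isEctopic(beats) & !truthLab)
  }
  expect_gte(tp / (tp + fn), 0.9)
  expect_gte(tn / (tn + fp), 0.98)
})

test_that("clean regular recordings yield no ectopic flags", {
  set.seed(13)
  sc <- tiltScenario(seed = 13, noiseSd = 0,
                     ventArgs = list(ectopicRate = 0, rrCv = 0.05))
  sc$phases <- sc$phases[1]
  sc$phases[[1]]$duration <- 60
  gen <- generateTiltRecording(sc)
  beats <- classifyEctopic(gen$record, detectBeats(gen$record))
  expect_identical(sum(isEctopic(beats)), 0L)
  # identical beats: all correlations at 1
  v <- generateVentricular(ventricularParams(meanHr = 80, rrCv = 0,
                                             ectopicRate = 0,
                                             respMorphGain = 0),
                           duration = 60, fs = 500)
  rec <- ECGRecord(matrix(v$signal, dimnames = list(NULL, "II")), 500)
  b2 <- classifyEctopic(rec, detectBeats(rec))
  expect_true(all(templateCorrelation(b2) > 0.9999, na.rm = TRUE))
})

test_that("cancellation removes ventricular activity and keeps the f-wave", {
  set.seed(14)
  sc <- tiltScenario(seed = 14, noiseSd = 0)
  sc$phases <- sc$phases[1]
  sc$phases[[1]]$duration <- 120
  sc$phases[[1]]$fwave$a1 <- 1e-6
  sc$phases[[1]]$fwave$a2 <- 0
  gen <- generateTiltRecording(sc)
  beats <- classifyEctopic(gen$record, detectBeats(gen$record))
  resid <- cancelQRST(gen$record, beats, "V1")
  expect_lt(sqrt(mean(resid^2)) /
              sqrt(mean(ecgSamples(gen$record)[, "V1"]^2)), 0.05)
  # full record: residual spectrum still peaks at the f-wave fundamental
  fx <- fixtureRecording()
  ps <- welchPSD(fwaveSamples(fx$fwave), 50, segSeconds = 10)
  sel <- ps$freq >= 4 & ps$freq <= 12
  expect_lt(abs(ps$freq[sel][which.max(ps$power[sel])] - 6.74), 0.2)
})

test_that("cancellation is the identity without beats and scales linearly", {
  set.seed(15)
  p <- fWaveParams(noiseSd = 0)
  x <- generateFWave(p, 30, fs = 500)$signal
  rec <- ECGRecord(matrix(x, dimnames = list(NULL, "V1")), 500)
  expect_identical(cancelQRST(rec, emptyBeatSet(500), "V1"), x)
  fx <- fixtureRecording()
  r1 <- cancelQRST(fx$record, fx$beats, "V1")
  rec2 <- fx$record
  rec2@samples <- rec2@samples * 2.5
  r2 <- cancelQRST(rec2, fx$beats, "V1")
  expect_equal(r2, 2.5 * r1, tolerance = 1e-9)
})

test_that("resampling keeps in-band tones and rejects out-of-band ones", {
  t <- (0:59999) / 1000
  f7 <- resampleTo50Hz(cos(2 * pi * 7 * t), 1000)
  amp <- sqrt(2 * mean(fwaveSamples(f7)[100:2900]^2))
  expect_lt(abs(amp - 1), 0.01)
  expect_identical(length(fwaveSamples(f7)), 3000L)
  f30 <- resampleTo50Hz(cos(2 * pi * 30 * t), 1000)
  att <- 20 * log10(sqrt(mean(fwaveSamples(f30)[100:2900]^2)) /
                      sqrt(0.5))
  expect_lt(att, -40)
  expect_identical(length(fwaveSamples(resampleTo50Hz(numeric(900 * 1000),
                                                      1000))), 45000L)
  expect_error(resampleTo50Hz(numeric(1000), 80), ">= 100")
})

test_that("phase heart rate follows the ectopic-exclusion rule", {
  fs <- 1000
  rp <- as.integer(seq(1, by = 600, length.out = 50))
  mk <- function(ect) new("BeatSet", rPeaks = rp, ectopic = ect,
                          corr = rep(1, 50),
                          template = matrix(0, 701, 1,
                                            dimnames = list(NULL, "II")),
                          window = c(-250L, 450L), fs = fs,
                          detectionLead = "II")
  b0 <- mk(rep(FALSE, 50))
  expect_equal(meanHeartRate(b0, c(0, 30)), 100)
  ect <- rep(FALSE, 50); ect[25] <- TRUE
  expect_equal(meanHeartRate(mk(ect), c(0, 30)), 100)
  # relabeling any beat cannot move FHR when RR is constant
  for (i in c(2, 10, 49)) {
    e <- rep(FALSE, 50); e[i] <- TRUE
    expect_equal(meanHeartRate(mk(e), c(0, 30)), 100)
  }
  expect_warning(fhr <- meanHeartRate(b0, c(100, 101)), "missing")
  expect_true(is.na(fhr))
  # recovery against generator truth
  fx <- fixtureRecording()
  expect_lt(abs(meanHeartRate(fx$beats, c(0, 120)) -
                  fx$truth$phases$realizedHr[1]), 2)
})
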