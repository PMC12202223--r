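# Synthetic generator: waveform structure, determinism, bookkeeping.

test_that("constant-parameter f-wave is a pure tone at the set frequency", {
  set.seed(1)
  p <- fWaveParams(ffMean = 7, modAmplitude = 0, a2 = 0, driftSd = 0,
                   noiseSd = 0, respRate = 0.14)
  fw <- generateFWave(p, 20, fs = 500)
  xa <- analyticSignal(fw$signal)
  instF <- diff(Arg(xa[2000:8000])) * 500 / (2 * pi)
  instF <- instF[abs(instF) < 100]   # drop phase wraps
  expect_true(all(abs(instF - 7) < 0.05))
  expect_equal(fw$fTrue, rep(7, 10000))
})

test_that("respiratory modulation shapes the true frequency as specified", {
  set.seed(2)
  p <- fWaveParams(ffMean = 6.7, modAmplitude = 0.08, respRate = 0.14,
                   driftSd = 0, noiseSd = 0)
  fw <- generateFWave(p, 30, fs = 200)
  t <- (seq_along(fw$fTrue) - 1) / 200
  expect_equal(fw$fTrue, 6.7 + 0.08 * sin(2 * pi * 0.14 * t))
  expect_equal(range(fw$fTrue), c(6.7 - 0.08, 6.7 + 0.08), tolerance = 1e-6)
})

test_that("identical scenario and seed reproduce the record bit-exactly", {
  sc <- tiltScenario(seed = 5)
  sc$phases <- sc$phases[1:2]
  sc$phases[[1]]$duration <- 20; sc$phases[[2]]$duration <- 20
  g1 <- generateTiltRecording(sc)
  g2 <- generateTiltRecording(sc)
  expect_identical(ecgSamples(g1$record), ecgSamples(g2$record))
  expect_identical(g1$truth$beatTimes, g2$truth$beatTimes)
  sc$seed <- 6L
  g3 <- generateTiltRecording(sc)
  expect_false(identical(ecgSamples(g1$record), ecgSamples(g3$record)))
})

test_that("degenerate RR distribution gives metronomic beats", {
  set.seed(3)
  v <- generateVentricular(ventricularParams(meanHr = 90, rrCv = 0,
                                             ectopicRate = 0),
                           duration = 60, fs = 1000)
  rr <- diff(v$beatTimes) * 1000
  expect_true(all(abs(rr - 60000 / 90) <= 1))
  expect_identical(sum(v$ectopic), 0L)
})

test_that("ectopic labels are bookkept and converge to the set rate", {
  set.seed(4)
  v <- generateVentricular(ventricularParams(meanHr = 120, ectopicRate = 0.05),
                           duration = 600, fs = 500)
  expect_identical(length(v$beatTimes), length(v$ectopic))
  nb <- length(v$ectopic)
  ci <- 3 * sqrt(0.05 * 0.95 / nb)
  expect_lt(abs(mean(v$ectopic) - 0.05), ci + 1e-9)
})

test_that("QRS morphology modulation puts a spectral line at the resp rate", {
  set.seed(5)
  fx <- fixtureRecording()
  sr <- slopeRangeSeries(fx$record, fx$beats, "II")
  ri <- interpolateResp(sr$values, sr$times, n = 6000)
  ps <- welchPSD(ri[is.finite(ri)], 50, segSeconds = 60)
  sel <- ps$freq > 0.05 & ps$freq < 1
  pk <- ps$freq[sel][which.max(ps$power[sel])]
  expect_lt(abs(pk - 0.13), 0.02)
})

test_that("six default phases concatenate to a 900-s record", {
  sc <- tiltScenario(seed = 11, fs = 250)
  gen <- generateTiltRecording(sc)
  expect_identical(nrow(ecgSamples(gen$record)), 900L * 250L)
  expect_identical(phaseTimeline(gen$record)$phase,
                   c("B1", "B2", "HDT1", "HDT2", "HUT1", "HUT2"))
  expect_equal(phaseTimeline(gen$record)$end -
                 phaseTimeline(gen$record)$start,
               c(120, 180, 120, 180, 120, 180))
})

test_that("generated f-wave spectrum peaks at the set fundamental", {
  set.seed(6)
  p <- fWaveParams(ffMean = 6.3, modAmplitude = 0.08, respRate = 0.14)
  fw <- generateFWave(p, 120, fs = 100)
  ps <- welchPSD(fw$signal, 100, segSeconds = 10)
  sel <- ps$freq >= 4 & ps$freq <= 12
  pk <- ps$freq[sel][which.max(ps$power[sel])]
  expect_lt(abs(pk - 6.3), 0.11)
})

test_that("demodulated noiseless f-wave recovers the modulation amplitude", {
  set.seed(7)
  p <- fWaveParams(ffMean = 6.7, modAmplitude = 0.08, respRate = 0.14,
                   driftSd = 0, noiseSd = 0)
  fs <- 100
  fw <- generateFWave(p, 300, fs = fs)
  xa <- analyticSignal(fw$signal)
  instF <- diff(Arg(xa)) * fs / (2 * pi)
  instF[instF < 0] <- instF[instF < 0] + fs   # unwrap
  keep <- (5 * fs):(295 * fs)
  t <- keep / fs
  fit <- lm(instF[keep] ~ sin(2 * pi * 0.14 * t) + cos(2 * pi * 0.14 * t))
  amp <- sqrt(sum(coef(fit)[2:3]^2))
  expect_lt(abs(amp - 0.08) / 0.08, 0.02)
})

test_that("activation generator honours rate, count and refractoriness", {
  set.seed(8)
  g <- generateActivationSeries(nPoints = 10, duration = 30, baseFreq = 8,
                                modAmplitude = 0, jitterSd = 0)
  expect_identical(length(activationTimes(g$set)), 10L)
  iv <- unlist(lapply(activationTimes(g$set), diff))
  expect_true(all(abs(iv - 0.125) < 1e-6))
  g2 <- generateActivationSeries(nPoints = 223, duration = 10, baseFreq = 8,
                                 modAmplitude = 0.1, fracUnpeaked = 0.3)
  expect_identical(length(activationTimes(g2$set)), 223L)
  expect_equal(sum(g2$unpeaked), round(0.3 * 223))
  expect_true(all(unlist(lapply(activationTimes(g2$set), diff)) > 0.03))
})

test_that("generator parameters are validated", {
  expect_error(fWaveParams(ffMean = 3))
  expect_error(ventricularParams(ectopicRate = 0.5))
  expect_error(generateFWave(fWaveParams(), duration = -1))
  expect_error(generateFWave(fWaveParams(), duration = 10, fs = 20))
  expect_error(generateVentricular(ventricularParams(), 10, fs = 100))
  expect_error(generateActivationSeries(fracUnpeaked = 1))
})
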