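# Harmonic ML frequency tracking, Welch anchor, quality index and gates.

test_that("analytic signal has the defining properties", {
  t <- (0:4999) / 50
  x <- cos(2 * pi * 7 * t)
  xa <- analyticSignal(x)
  expect_equal(Re(xa), x, tolerance = 1e-12)
  expect_true(all(abs(Mod(xa[100:4900]) - 1) < 0.01))
  instF <- diff(Arg(xa[100:4900])) * 50 / (2 * pi)
  instF <- instF[abs(instF) < 25]
  expect_true(all(abs(instF - 7) < 0.05))
  set.seed(21)
  y <- rnorm(50000)
  y <- y - mean(y)
  expect_lt(abs(sum(Mod(analyticSignal(y))^2) / (2 * sum(y^2)) - 1), 0.01)
})

test_that("Welch anchor finds the dominant fibrillatory peak", {
  t <- (0:4499) / 50
  expect_lt(abs(welchAnchor(cos(2 * pi * 6.8 * t)) - 6.8), 0.1)
  two <- cos(2 * pi * 6.8 * t) + 0.3 * cos(2 * pi * 9 * t)
  expect_lt(abs(welchAnchor(two) - 6.8), 0.1)
  expect_warning(welchAnchor(cos(2 * pi * 4.02 * t)), "band edge")
  expect_error(welchAnchor(cos(2 * pi * 6 * (0:400) / 50)), ">= 60 s")
})

test_that("noiseless harmonic fits recover the exact parameters", {
  xa <- harmonicWindow(7.1, 1, 0.4, 0.3, -1.0)
  fit <- fitHarmonicSegment(xa, c(5.6, 8.6))
  expect_lt(abs(fit$f - 7.1), 1e-3)
  expect_lt(abs(fit$a1 - 1), 1e-3)
  expect_lt(abs(fit$a2 - 0.4), 1e-3)
  expect_lt(abs(fit$phi1 - 0.3), 1e-2)
  expect_lt(abs(fit$phi2 - (-1.0)), 1e-2)
  # absent second harmonic stays absent
  fit0 <- fitHarmonicSegment(harmonicWindow(7.1, 1, 0, 0.3, 0), c(5.6, 8.6))
  expect_lt(fit0$a2, 1e-2)
  expect_error(fitHarmonicSegment(xa, c(8, 7)), "empty")
})

test_that("frequency recovery degrades gracefully at 10 dB SNR", {
  set.seed(22)
  errs <- replicate(100, {
    xa <- harmonicWindow(7.1, 1, 0.4, runif(1, -pi, pi), runif(1, -pi, pi)) +
      sqrt(0.1 / 2) * complex(real = rnorm(25), imaginary = rnorm(25))
    abs(fitHarmonicSegment(xa, c(5.6, 8.6))$f - 7.1)
  })
  expect_lt(median(errs), 0.15)
})

test_that("golden-section refinement matches the exhaustive grid oracle", {
  set.seed(23)
  for (i in 1:10) {
    f <- runif(1, 5.8, 7.8)
    xa <- harmonicWindow(f, runif(1, 0.5, 2), runif(1, 0, 0.5),
                         runif(1, -pi, pi), runif(1, -pi, pi))
    fit <- fitHarmonicSegment(xa, c(5.3, 8.3))
    grid <- seq(5.3, 8.3, by = 1e-4)
    pe <- fwavetilt:::.harmonicGridBest(matrix(xa, ncol = 1), grid, 50)
    expect_lt(abs(fit$f - pe), 2e-4)
  }
})

test_that("the trend tracks a noiseless modulated fundamental closely", {
  set.seed(24)
  p <- fWaveParams(ffMean = 6.7, modAmplitude = 0.08, respRate = 0.14,
                   driftSd = 0, noiseSd = 0)
  fw <- generateFWave(p, 120, fs = 50)
  xa <- analyticSignal(fw$signal)
  tr <- frequencyTrend(xa, 6.7)
  ok <- which(trendValid(tr))
  inner <- ok[ok > 100 & ok < length(fw$fTrue) - 100]  # clear of Hilbert edges
  expect_lt(max(abs(trendSeries(tr)[inner] - fw$fTrue[inner])), 0.01)
  expect_identical(length(trendSeries(tr)), 6000L)
  expect_false(any(trendValid(tr)[1:12]))
  # constant tone: flat trend
  p2 <- fWaveParams(ffMean = 7, modAmplitude = 0, driftSd = 0, noiseSd = 0)
  fw2 <- generateFWave(p2, 70, fs = 50)
  tr2 <- frequencyTrend(analyticSignal(fw2$signal), 7)
  expect_lt(max(abs(trendSeries(tr2)[trendValid(tr2)] - 7)), 1e-3)
  expect_identical(length(trendSeries(tr2)), 3500L)
})

test_that("quality index hits its algebraic endpoints", {
  set.seed(25)
  p <- fWaveParams(ffMean = 6.7, modAmplitude = 0, driftSd = 0, noiseSd = 0)
  fw <- generateFWave(p, 30, fs = 50)
  xa <- analyticSignal(fw$signal)
  tr <- frequencyTrend(xa, 6.7)
  trPerfect <- qualityIndex(xa, tr)
  expect_true(all(qualityBlocks(trPerfect) > 0.999))
  trZero <- methods::initialize(tr,
                                recon = rep(0 + 0i, length(trendSeries(tr))))
  sZero <- qualityBlocks(qualityIndex(xa, trZero))
  expect_true(all(abs(sZero) < 1e-9))
})

test_that("adding white noise to the signal never raises the quality index", {
  set.seed(26)
  p <- fWaveParams(noiseSd = 0.1)
  fw <- generateFWave(p, 60, fs = 50)
  xa <- analyticSignal(fw$signal)
  tr <- qualityIndex(xa, frequencyTrend(xa, 6.74))
  for (sdn in c(0.05, 0.1, 0.2)) {
    noisy <- xa + complex(real = rnorm(length(xa), 0, sdn),
                          imaginary = rnorm(length(xa), 0, sdn))
    trN <- qualityIndex(noisy, methods::initialize(tr))
    expect_true(all(qualityBlocks(trN) <= qualityBlocks(tr) + 0.02))
  }
})

test_that("recording gate applies the 10% rule at its boundary", {
  expect_true(recordingGate(c(rep(0.8, 90), rep(0.1, 10))))
  expect_false(recordingGate(c(rep(0.8, 89), rep(0.1, 11))))
  expect_true(recordingGate(rep(0.9, 40)))
  expect_error(recordingGate(numeric()), "no quality blocks")
})

test_that("phase medians honour validity and symmetry", {
  n <- 6000L
  f <- rep(6.7, n)
  tr <- new("FrequencyTrend", f = f, valid = rep(TRUE, n),
            sBlocks = rep(0.9, 24), blockLength = 250L, f0 = 6.7, fs = 50,
            recon = rep(0 + 0i, n))
  expect_equal(phaseMedianFrequency(tr, c(0, 120)), 6.7)
  t <- (0:(n - 1)) / 50
  tr2 <- methods::initialize(tr, f = 6.7 + 0.08 * sin(2 * pi * 0.2 * t))
  expect_lt(abs(phaseMedianFrequency(tr2, c(0, 100)) - 6.7), 1e-3)
  tr3 <- methods::initialize(tr, valid = rep(c(TRUE, FALSE, FALSE), n / 3))
  expect_warning(ff <- phaseMedianFrequency(tr3, c(0, 120)), "missing")
  expect_true(is.na(ff))
})

test_that("shifting the fundamental shifts the recovered median equally", {
  set.seed(27)
  base <- NULL
  for (d in c(0, -0.5, 0.3)) {
    p <- fWaveParams(ffMean = 6.7 + d, modAmplitude = 0.05, respRate = 0.14,
                     driftSd = 0, noiseSd = 0)
    fw <- generateFWave(p, 80, fs = 50)
    xa <- analyticSignal(fw$signal)
    tr <- frequencyTrend(xa, 6.7 + d)
    m <- median(trendSeries(tr)[trendValid(tr)])
    if (d == 0) base <- m else expect_lt(abs((m - base) - d), 0.01)
  }
})

test_that("valid trend samples respect the constrained search interval", {
  fx <- fixtureRecording()
  tr <- fx$trend
  ok <- trendValid(tr)
  expect_true(all(abs(trendSeries(tr)[ok] - anchorFrequency(tr)) <= 1.5 + 1e-9))
})
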