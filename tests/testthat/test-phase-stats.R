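# Normality screening, signed-rank tests, phase comparisons, classification
# and the cohort summary.

test_that("Lilliefors test agrees with an independent implementation", {
  skip_if_not_installed("nortest")
  set.seed(61)
  for (i in 1:15) {
    x <- rnorm(20 + 5 * (i %% 3))
    p1 <- lillieforsTest(x)$p.value
    p2 <- nortest::lillie.test(x)$p.value
    expect_lt(abs(p1 - p2), 0.08)
  }
})

test_that("Lilliefors test rejects skewed data and handles degeneracy", {
  set.seed(62)
  pow <- mean(replicate(150, lillieforsTest(rexp(24))$p.value < 0.05))
  expect_gt(pow, 0.6)
  expect_warning(lf <- lillieforsTest(rep(3, 20)), "degenerate")
  expect_true(is.na(lf$p.value))
  expect_true(is.na(lillieforsTest(c(1, 2))$p.value))
  # identical seeds give identical p-values (cached seeded null)
  x <- rnorm(24)
  expect_identical(lillieforsTest(x)$p.value, lillieforsTest(x)$p.value)
})

test_that("signed-rank p-values match enumeration and the stats oracle", {
  x <- 1:8; y <- rep(0, 8)
  expect_equal(wilcoxonSignedRank(x, y)$p.value, 2 / 256)
  expect_warning(w0 <- wilcoxonSignedRank(1:5, 1:5), "zero")
  expect_equal(w0$p.value, 1)
  set.seed(63)
  for (i in 1:25) {
    n <- sample(5:10, 1)
    d <- round(rnorm(n, 0.3, 1), if (i %% 2) 3 else 0)  # some exact ties
    d <- d[d != 0]
    if (length(d) < 2) next
    ours <- wilcoxonSignedRank(d, numeric(length(d)))$p.value
    expect_equal(ours, bruteSignedRankP(d), tolerance = 1e-12)
    if (!anyDuplicated(abs(d))) {
      ref <- stats::wilcox.test(d, exact = TRUE)$p.value
      expect_equal(ours, ref, tolerance = 1e-12)
    }
  }
  # large-sample path stays close to the exact one around the boundary
  set.seed(64)
  d <- rnorm(16, 0.4)
  pExact <- wilcoxonSignedRank(d, numeric(16), exactMax = 16)$p.value
  pApprox <- wilcoxonSignedRank(d, numeric(16), exactMax = 15)$p.value
  expect_lt(abs(pExact - pApprox), 0.02)
})

test_that("phase comparisons apply the Bonferroni family threshold", {
  graph <- comparisonGraph()
  expect_identical(nrow(graph), 9L)
  set.seed(65)
  m <- metricsTable(12, list(B1 = 6.7, B2 = 6.7, HDT1 = 6.5, HDT2 = 6.5,
                             HUT1 = 6.7, HUT2 = 6.7))
  res <- suppressWarnings(comparePhases(m, graph))
  expect_equal(unique(res$threshold), 0.05 / 9)
  # identical metrics across phases: nothing significant
  m2 <- m; m2$ff_hz <- rep(1:12, 6)
  res2 <- suppressWarnings(comparePhases(m2, graph))
  expect_false(any(res2$significant, na.rm = TRUE))
})

test_that("a stepped cohort is detected with the designed power and size", {
  set.seed(66)
  hit <- null <- logical(100)
  means <- list(B1 = 6.7, B2 = 6.7, HDT1 = 6.5, HDT2 = 6.5, HUT1 = 6.5,
                HUT2 = 6.5)
  for (i in 1:100) {
    m <- metricsTable(24, means, sd = 0.05)
    res <- suppressWarnings(comparePhases(m))
    hit[i] <- res$significant[res$from == "B2" & res$to == "HDT1"]
    null[i] <- res$significant[res$from == "B1" & res$to == "B2"]
  }
  expect_gte(mean(hit), 0.9)
  expect_lte(mean(null), 0.05)
})

test_that("enlarging the comparison graph never creates significance", {
  set.seed(67)
  m <- metricsTable(15, list(B1 = 6.7, B2 = 6.65, HDT1 = 6.5, HDT2 = 6.55,
                             HUT1 = 6.75, HUT2 = 6.7), sd = 0.08)
  small <- comparisonGraph()[1:5, ]
  rSmall <- suppressWarnings(comparePhases(m, small))
  rBig <- suppressWarnings(comparePhases(m, comparisonGraph()))
  for (k in seq_len(nrow(small))) {
    sS <- rSmall$significant[rSmall$from == small$from[k] &
                               rSmall$to == small$to[k]]
    sB <- rBig$significant[rBig$from == small$from[k] &
                             rBig$to == small$to[k]]
    expect_false(!sS && sB)   # non-significant cannot turn significant
  }
})

test_that("patients missing one phase only affect that phase's pairs", {
  set.seed(68)
  means <- list(B1 = 6.7, B2 = 6.6, HDT1 = 6.5, HDT2 = 6.6, HUT1 = 6.8,
                HUT2 = 6.7)
  m <- metricsTable(14, means, sd = 0.06)
  r1 <- suppressWarnings(comparePhases(m))
  extra <- metricsTable(1, means, sd = 0.06)
  extra$patient <- "pX"
  extra$ff_hz[extra$phase == "HUT2"] <- NA
  r2 <- suppressWarnings(comparePhases(rbind(m, extra)))
  untouched <- r1$from != "HUT2" & r1$to != "HUT2"
  expect_equal(r1$n[untouched] + 1L, r2$n[untouched])
  expect_equal(r2$n[!untouched], r1$n[!untouched])
})

test_that("responses classify by the one-percent rule", {
  expect_identical(classifyResponse(6.73, 6.70), "minimal")
  expect_identical(classifyResponse(6.90, 6.70), "increase")
  expect_identical(classifyResponse(98, 100), "decrease")
  expect_warning(cl <- classifyResponse(c(0.5), c(0), cohortMedian = 1),
                 "zero previous")
  expect_identical(cl, "increase")
})

test_that("the summary picks the display form per metric", {
  m <- data.frame(patient = rep(paste0("p", 1:5), 2),
                  phase = rep(c("B1", "B2"), each = 5),
                  ff_hz = c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5))
  s <- suppressWarnings(summarizeMetrics(m, alpha = 1))  # force non-Gaussian
  row <- s[s$phase == "B1", ]
  expect_equal(row$center, 3)
  expect_equal(row$spread1, 2)
  expect_equal(row$spread2, 4)
  # constant column: degenerate Lilliefors, zero spread either way
  m$ff_hz <- 4.2
  s2 <- suppressWarnings(summarizeMetrics(m))
  expect_equal(s2$spread1[1], s2$spread2[1])
  # Gaussian-looking column reports mean +- sd
  set.seed(69)
  m$ff_hz <- rnorm(10, 6.7, 0.1)
  s3 <- suppressWarnings(summarizeMetrics(m, alpha = 0.001))
  expect_true(all(s3$gaussian))
  expect_true(all(grepl("±", s3$display)))
})
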