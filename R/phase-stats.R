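# Phase-comparison statistics: Lilliefors normality screening (Monte-Carlo
# null), exact/approximate Wilcoxon signed-rank tests, Bonferroni-corrected
# pairwise phase comparisons over the protocol comparison graph, per-patient
# response classification, and cohort summary tables.

# Cached Monte-Carlo null distributions of the Lilliefors statistic, one per
# sample size. Generated from a fixed internal seed with the caller's RNG
# state saved and restored, so p-values are reproducible and user RNG
# streams are untouched.
.lfEnv <- new.env(parent = emptyenv())

.lfStat <- function(x) {
  n <- length(x)
  p <- stats::pnorm(sort(x), mean(x), stats::sd(x))
  i <- seq_len(n)
  max(i / n - p, p - (i - 1) / n)
}

.lfNull <- function(n, reps = 10000L) {
  key <- paste0("n", n, "_", reps)
  if (!is.null(.lfEnv[[key]])) return(.lfEnv[[key]])
  hadSeed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (hadSeed) oldSeed <- get(".Random.seed", globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", oldSeed, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(190700 + n)
  null <- vapply(seq_len(reps), function(i) .lfStat(stats::rnorm(n)),
                 numeric(1))
  .lfEnv[[key]] <- sort(null)
  .lfEnv[[key]]
}

#' Lilliefors normality test
#'
#' Kolmogorov-Smirnov statistic of the sample against a normal distribution
#' with estimated mean and SD; the p-value comes from a seeded Monte-Carlo
#' null distribution (default 10,000 replicates, cached per sample size).
#'
#' @param x numeric sample, n >= 5.
#' @param mcReps Monte-Carlo replicates for the null.
#' @return list with `statistic` and `p.value`; both NA (with a warning) for
#'   degenerate samples.
#' @export
lillieforsTest <- function(x, mcReps = 10000L) {
  x <- x[is.finite(x)]
  if (length(x) < 5L) return(list(statistic = NA_real_, p.value = NA_real_))
  if (stats::sd(x) == 0) {
    warning("degenerate (constant) sample; Lilliefors test undefined")
    return(list(statistic = NA_real_, p.value = NA_real_))
  }
  D <- .lfStat(x)
  null <- .lfNull(length(x), mcReps)
  p <- (sum(null >= D) + 1L) / (length(null) + 1L)
  list(statistic = D, p.value = p)
}

# Exact null distribution of the signed-rank sum W+ by convolution over the
# (doubled, hence integer) midranks: generating function prod_i (1 + z^(2r_i)).
.signrankExact <- function(ranks2, wObs2) {
  maxW <- sum(ranks2)
  dist <- numeric(maxW + 1L)
  dist[1L] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), dist[seq_len(maxW + 1L - r)])
    dist <- dist + shifted
  }
  dist <- dist / sum(dist)
  w <- round(wObs2)
  pLe <- sum(dist[seq_len(w + 1L)])
  pGe <- sum(dist[(w + 1L):(maxW + 1L)])
  min(1, 2 * min(pLe, pGe))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided paired test on `x - y`. Zero differences are dropped
#' (signed-rank convention); ties get midranks. For n <= 15 remaining pairs
#' the exact null distribution of the rank sum is enumerated (tie-aware);
#' beyond that a normal approximation with continuity and tie correction is
#' used.
#'
#' @param x,y paired numeric vectors.
#' @param exactMax largest n for the exact enumeration (default 15).
#' @return list with `statistic` (W+, rank sum of positive differences),
#'   `n` (non-zero pairs) and `p.value`. All differences zero gives p = 1
#'   with a warning.
#' @export
wilcoxonSignedRank <- function(x, y, exactMax = 15L) {
  stopifnot(length(x) == length(y))
  d <- (x - y)[is.finite(x) & is.finite(y)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all differences zero; p = 1")
    return(list(statistic = 0, n = 0L, p.value = 1))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exactMax) {
    p <- .signrankExact(round(2 * r), 2 * W)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = W, n = n, p.value = p)
}

#' Default tilt-protocol comparison graph
#'
#' The nine pairwise phase comparisons of the protocol: each sub-phase
#' against the immediately preceding one, each transient phase against the
#' previous transient, and each steady-state phase against the previous
#' steady state.
#'
#' @return data.frame with columns `from`, `to`.
#' @export
comparisonGraph <- function() {
  data.frame(
    from = c("B1", "B2", "HDT1", "HDT2", "HUT1", "B1", "HDT1", "B2", "HDT2"),
    to = c("B2", "HDT1", "HDT2", "HUT1", "HUT2", "HDT1", "HUT1", "HDT2",
           "HUT2"),
    stringsAsFactors = FALSE)
}

#' Pairwise phase comparisons with Bonferroni correction
#'
#' For each metric and each comparison-graph pair, runs the Wilcoxon
#' signed-rank test on the paired per-patient values (patients missing either
#' phase are dropped pairwise) and flags significance at the
#' Bonferroni-corrected level `alpha / nrow(graph)`.
#'
#' @param metrics data.frame with columns `patient`, `phase` and the metric
#'   columns (one row per patient x phase).
#' @param graph comparison graph (default [comparisonGraph()]).
#' @param metricCols metric column names; default all numeric columns.
#' @param alpha family-wise significance level (default 0.05).
#' @param minPairs minimum complete pairs per comparison (default 5).
#' @return data.frame with one row per metric x pair: `n`, `medianDiff`
#'   (to - from), `p`, `threshold`, `significant`, `evaluable`.
#' @export
comparePhases <- function(metrics, graph = comparisonGraph(),
                          metricCols = NULL, alpha = 0.05, minPairs = 5L) {
  stopifnot(all(c("patient", "phase") %in% names(metrics)))
  if (is.null(metricCols))
    metricCols <- setdiff(names(metrics)[vapply(metrics, is.numeric,
                                                logical(1))],
                          c("patient"))
  thr <- alpha / nrow(graph)
  out <- list()
  for (mc in metricCols) {
    for (k in seq_len(nrow(graph))) {
      a <- graph$from[k]; b <- graph$to[k]
      va <- metrics[metrics$phase == a, c("patient", mc)]
      vb <- metrics[metrics$phase == b, c("patient", mc)]
      m <- merge(va, vb, by = "patient", suffixes = c(".a", ".b"))
      ok <- is.finite(m[[2]]) & is.finite(m[[3]])
      m <- m[ok, , drop = FALSE]
      if (nrow(m) < minPairs) {
        out[[length(out) + 1L]] <- data.frame(
          metric = mc, from = a, to = b, n = nrow(m),
          medianDiff = NA_real_, p = NA_real_, threshold = thr,
          significant = NA, evaluable = FALSE, stringsAsFactors = FALSE)
        next
      }
      wt <- suppressWarnings(wilcoxonSignedRank(m[[3]], m[[2]]))
      out[[length(out) + 1L]] <- data.frame(
        metric = mc, from = a, to = b, n = nrow(m),
        medianDiff = stats::median(m[[3]] - m[[2]]), p = wt$p.value,
        threshold = thr, significant = wt$p.value < thr, evaluable = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Classify a per-patient phase-to-phase response
#'
#' Relative to the previous phase: `"minimal"` when the relative change is
#' below `tol` (default 1%), otherwise `"increase"` or `"decrease"` by the
#' sign of the difference. A zero previous value falls back (with a warning)
#' to comparing the absolute difference against `tol` times the cohort
#' median.
#'
#' @param current,previous numeric vectors of metric values.
#' @param tol relative-change threshold (default 0.01).
#' @param cohortMedian fallback scale for zero previous values.
#' @return character vector in `{"increase", "decrease", "minimal"}`.
#' @export
classifyResponse <- function(current, previous, tol = 0.01,
                             cohortMedian = NULL) {
  stopifnot(length(current) == length(previous))
  d <- current - previous
  rel <- abs(d) / abs(previous)
  zero <- is.finite(previous) & previous == 0
  if (any(zero)) {
    warning("zero previous value(s); classifying by absolute difference")
    if (is.null(cohortMedian))
      cohortMedian <- stats::median(abs(c(current, previous)), na.rm = TRUE)
    rel[zero] <- abs(d[zero]) / (tol * cohortMedian) * tol
  }
  ifelse(rel < tol, "minimal", ifelse(d > 0, "increase", "decrease"))
}

#' Cohort summary in the tilt-table layout
#'
#' Per metric and phase: the Lilliefors test chooses the display form —
#' mean +- SD for Gaussian-compatible columns (p >= alpha), otherwise
#' median (Q1 - Q3) with linearly interpolated quartiles.
#'
#' @param metrics data.frame as in [comparePhases()].
#' @param metricCols metric columns; default all numeric.
#' @param alpha normality screening level (default 0.05).
#' @return data.frame with one row per metric x phase: `n`, `gaussian`,
#'   `center`, `spread1`, `spread2`, `display`.
#' @export
summarizeMetrics <- function(metrics, metricCols = NULL, alpha = 0.05) {
  stopifnot(all(c("patient", "phase") %in% names(metrics)))
  if (is.null(metricCols))
    metricCols <- setdiff(names(metrics)[vapply(metrics, is.numeric,
                                                logical(1))],
                          c("patient"))
  phases <- unique(metrics$phase)
  out <- list()
  for (mc in metricCols) {
    lf <- suppressWarnings(lillieforsTest(metrics[[mc]]))
    gaussian <- is.finite(lf$p.value) && lf$p.value >= alpha
    for (ph in phases) {
      v <- metrics[[mc]][metrics$phase == ph]
      v <- v[is.finite(v)]
      if (gaussian) {
        ctr <- mean(v); s1 <- stats::sd(v); s2 <- NA_real_
        disp <- sprintf("%.3g ± %.3g", ctr, s1)
      } else {
        qq <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
        ctr <- qq[2]; s1 <- qq[1]; s2 <- qq[3]
        disp <- sprintf("%.3g (%.3g−%.3g)", ctr, s1, s2)
      }
      out[[length(out) + 1L]] <- data.frame(
        metric = mc, phase = ph, n = length(v), gaussian = gaussian,
        center = ctr, spread1 = s1, spread2 = s2, display = disp,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
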