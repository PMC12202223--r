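# Maximum-likelihood harmonic tracking of the f-wave fundamental frequency.
# The analytic f-wave signal is modelled on short windows as
#   s(n) = sum_{p=1,2} c_p exp(j p 2 pi f n / fs),   c_p = A_p exp(j phi_p).
# For a candidate f the complex amplitudes have a closed-form least-squares
# solution; f itself is found by a 0.01 Hz grid search over the constrained
# interval refined by golden section to 1e-4 Hz. Under white Gaussian noise
# minimizing the residual energy is the ML estimate.

# Projection energy of windows X (nWin-sample columns) onto the two-harmonic
# basis at frequency f (scalar, or one value per column). Returns the
# projection energy and the complex amplitudes. All closed-form:
# with e_p(n) = exp(j p w n), w = 2 pi f / fs, n = 0..N-1,
#   s_p = e_p^H x,  g = e_1^H e_2 = sum_n exp(j w n),  G = [[N, g],[g*, N]].
.harmonicEval <- function(f, X, fs) {
  N <- nrow(X)
  idx <- 0:(N - 1L)
  if (length(f) == 1L) {
    B <- exp(-2i * pi * f * idx / fs)          # conj of fundamental basis
    B2 <- B * B
    s1 <- colSums(B * X)
    s2 <- colSums(B2 * X)
    g <- sum(Conj(B))
  } else {
    stopifnot(length(f) == ncol(X))
    B <- exp(outer(idx, -2i * pi * f / fs))
    B2 <- B * B
    s1 <- colSums(B * X)
    s2 <- colSums(B2 * X)
    g <- colSums(Conj(B))
  }
  det <- N^2 - Mod(g)^2
  c1 <- (N * s1 - g * s2) / det
  c2 <- (N * s2 - Conj(g) * s1) / det
  # projection energy x^H V (V^H V)^-1 V^H x = Re(s^H c)
  list(c1 = c1, c2 = c2, pe = Re(Conj(s1) * c1) + Re(Conj(s2) * c2))
}

# Clean wrapper: projection energy only.
.harmonicProjE <- function(f, X, fs) .harmonicEval(f, X, fs)$pe

# Coarse grid search over all windows at once via BLAS-level complex matrix
# products: best grid frequency per window (ties toward the lower frequency).
.harmonicGridBest <- function(X, grid, fs) {
  N <- nrow(X)
  idx <- 0:(N - 1L)
  Bc <- exp(outer(-2i * pi * idx / fs, grid))   # conj fundamental basis, N x K
  S1 <- crossprod(Bc, X)                        # K x nWin
  S2 <- crossprod(Bc * Bc, X)
  g <- colSums(Conj(Bc))
  det <- N^2 - Mod(g)^2
  C1 <- (N * S1 - g * S2) / det
  C2 <- (N * S2 - Conj(g) * S1) / det
  PE <- Re(Conj(S1) * C1) + Re(Conj(S2) * C2)
  grid[max.col(t(PE), ties.method = "first")]
}

# Vectorized golden-section refinement of the per-window frequency, bracket
# [a, b] per window, maximizing projection energy; ties resolve toward the
# lower frequency. All brackets share the same width so iterations align.
.goldenRefine <- function(X, fs, a, b, tol = 1e-4) {
  gr <- (sqrt(5) - 1) / 2
  x1 <- b - gr * (b - a)
  x2 <- a + gr * (b - a)
  e1 <- .harmonicProjE(x1, X, fs)
  e2 <- .harmonicProjE(x2, X, fs)
  while (max(b - a) > tol) {
    left <- e1 >= e2
    b[left] <- x2[left]; x2[left] <- x1[left]; e2[left] <- e1[left]
    x1[left] <- b[left] - gr * (b[left] - a[left])
    a[!left] <- x1[!left]; x1[!left] <- x2[!left]; e1[!left] <- e2[!left]
    x2[!left] <- a[!left] + gr * (b[!left] - a[!left])
    fnew <- ifelse(left, x1, x2)
    enew <- .harmonicProjE(fnew, X, fs)
    e1[left] <- enew[left]
    e2[!left] <- enew[!left]
  }
  (a + b) / 2
}

#' Welch anchor frequency
#'
#' The dominant f-wave frequency f0: location of the maximum of the Welch
#' periodogram (10-s Hamming segments, 50% overlap) within the fibrillatory
#' band, default \[4, 12\] Hz. f0 centres the constrained search interval
#' \[f0 - 1.5, f0 + 1.5\] of the frequency tracker.
#'
#' @param x [FWaveSignal-class] or numeric series at 50 Hz (>= 60 s).
#' @param fs sampling rate, default 50 Hz.
#' @param band search band in Hz.
#' @return f0 in Hz. Warns when the maximum sits on a band edge (possible
#'   out-of-band fundamental).
#' @export
welchAnchor <- function(x, fs = 50, band = c(4, 12)) {
  if (is(x, "FWaveSignal")) { fs <- x@fs; x <- x@x }
  if (length(x) < 60 * fs) stop("need >= 60 s of signal for the Welch anchor")
  ps <- welchPSD(x, fs, segSeconds = 10, overlap = 0.5)
  sel <- ps$freq >= band[1] & ps$freq <= band[2]
  fsel <- ps$freq[sel]; psel <- ps$power[sel]
  f0 <- fsel[which.max(psel)]
  res <- 1 / 10   # spectral resolution of the 10-s segments
  if (f0 <= band[1] + res || f0 >= band[2] - res)
    warning("spectral maximum at band edge; fundamental may be out of band")
  f0
}

#' Fit the two-harmonic model on one analytic-signal window
#'
#' Maximum-likelihood fit of `sum_p A_p exp(j(p 2 pi f n / fs + phi_p))`,
#' p = 1, 2, to a short analytic-signal window: complex amplitudes by linear
#' least squares at each candidate f, the frequency by 0.01 Hz grid search
#' over `fInterval` refined by golden section to `tol`; ties break toward the
#' lower frequency.
#'
#' @param xa complex analytic-signal window (canonically 25 samples = 0.5 s).
#' @param fInterval numeric length-2 frequency search interval (Hz).
#' @param fs sampling rate (default 50 Hz).
#' @param gridStep coarse grid step (Hz).
#' @param tol golden-section bracket tolerance (Hz).
#' @return list with `f`, `a1`, `a2`, `phi1`, `phi2`, `residualEnergy`.
#' @export
fitHarmonicSegment <- function(xa, fInterval, fs = 50, gridStep = 0.01,
                               tol = 1e-4) {
  stopifnot(is.complex(xa) || is.numeric(xa), length(xa) >= 5L)
  if (fInterval[2] <= fInterval[1]) stop("empty frequency interval")
  xa <- as.complex(xa)
  X <- matrix(xa, ncol = 1L)
  grid <- seq(fInterval[1], fInterval[2], by = gridStep)
  pe <- vapply(grid, function(f) .harmonicProjE(f, X, fs), numeric(1))
  i <- which.max(pe)  # first max -> lower f on ties
  a <- max(fInterval[1], grid[i] - gridStep)
  b <- min(fInterval[2], grid[i] + gridStep)
  fhat <- .goldenRefine(X, fs, a, b, tol)
  ev <- .harmonicEval(fhat, X, fs)
  list(f = fhat, a1 = Mod(ev$c1), a2 = Mod(ev$c2),
       phi1 = Arg(ev$c1), phi2 = Arg(ev$c2),
       residualEnergy = sum(Mod(xa)^2) - ev$pe)
}

#' F-wave frequency trend by sliding harmonic fits
#'
#' Fits the two-harmonic model on 0.5-s windows of the analytic signal hopped
#' by one sample (20 ms), yielding a frequency trend sampled at 50 Hz and
#' timestamped at window centres. The frequency is constrained to
#' `[f0 - 1.5, f0 + 1.5]` Hz. The first and last quarter second are marked
#' invalid. A per-sample model reconstruction (centre sample of each window's
#' fit) is stored for the quality index.
#'
#' @param xa complex analytic signal of one recording (50 Hz).
#' @param f0 Welch anchor frequency (Hz), see [welchAnchor()].
#' @param fs sampling rate (default 50).
#' @param windowSeconds fit window length (default 0.5 s).
#' @param gridStep,tol grid step and golden-section tolerance (Hz).
#' @param chunk windows processed per block (memory/throughput trade-off).
#' @return a [FrequencyTrend-class] (quality blocks not yet computed; see
#'   [qualityIndex()]).
#' @export
frequencyTrend <- function(xa, f0, fs = 50, windowSeconds = 0.5,
                           gridStep = 0.01, tol = 1e-4, chunk = 2000L) {
  stopifnot(is.complex(xa))
  N <- round(windowSeconds * fs)
  L <- length(xa)
  if (L < N + 2L) stop("signal shorter than one fit window")
  fInt <- c(f0 - 1.5, f0 + 1.5)
  nWin <- L - N + 1L
  ctr <- N %/% 2L              # centre offset (0-based local index)
  grid <- seq(fInt[1], fInt[2], by = gridStep)
  fHat <- numeric(nWin)
  reconW <- complex(nWin)
  offs <- 0:(N - 1L)
  for (s0 in seq(1L, nWin, by = chunk)) {
    s1 <- min(nWin, s0 + chunk - 1L)
    starts <- s0:s1
    X <- matrix(xa[outer(offs, starts, "+")], nrow = N)
    bestF <- .harmonicGridBest(X, grid, fs)
    a <- pmax(fInt[1], bestF - gridStep)
    b <- pmin(fInt[2], bestF + gridStep)
    fh <- .goldenRefine(X, fs, a, b, tol)
    ev <- .harmonicEval(fh, X, fs)
    w <- 2 * pi * fh * ctr / fs
    fHat[starts] <- fh
    reconW[starts] <- ev$c1 * exp(1i * w) + ev$c2 * exp(2i * w)
  }
  f <- rep(NA_real_, L)
  recon <- rep(NA_complex_, L)
  pos <- (seq_len(nWin) - 1L) + ctr + 1L   # centre sample of each window
  f[pos] <- fHat
  recon[pos] <- reconW
  valid <- !is.na(f)
  new("FrequencyTrend", f = f, valid = valid, sBlocks = numeric(),
      blockLength = as.integer(5 * fs), f0 = f0, fs = fs, recon = recon)
}

#' Signal quality index S and block gating
#'
#' For non-overlapping 5-s blocks computes `S = 1 - sd(e) / sd(xa)`, where e
#' is the complex residual between the analytic signal and the per-sample
#' model reconstruction and sd is the complex standard deviation
#' `sqrt(mean |z - mean(z)|^2)`. Trend samples in blocks with
#' `S <= threshold` (default 0.3), undefined S (zero-variance block) or a
#' trailing fragment shorter than 1 s are marked invalid.
#'
#' @param xa complex analytic signal the trend was fitted on.
#' @param trend a [FrequencyTrend-class] from [frequencyTrend()].
#' @param threshold quality gate (default 0.3).
#' @param blockSeconds block length (default 5 s).
#' @return the trend with `sBlocks` filled in and the validity mask gated.
#' @export
qualityIndex <- function(xa, trend, threshold = 0.3, blockSeconds = 5) {
  stopifnot(is(trend, "FrequencyTrend"), length(xa) == length(trend@f))
  fs <- trend@fs
  L <- length(xa)
  bl <- as.integer(round(blockSeconds * fs))
  starts <- seq(1L, L, by = bl)
  resid <- xa - trend@recon
  csd <- function(z) {
    z <- z[!is.na(z)]
    if (length(z) < 2L) return(NA_real_)
    sqrt(mean(Mod(z - mean(z))^2))
  }
  S <- rep(NA_real_, length(starts))
  valid <- trend@valid
  for (k in seq_along(starts)) {
    a <- starts[k]; b <- min(L, a + bl - 1L)
    if (b - a + 1L < fs) { valid[a:b] <- FALSE; next }  # < 1 s fragment
    sx <- csd(xa[a:b])
    se <- csd(resid[a:b])
    if (!is.finite(sx) || sx == 0) {
      warning("zero-variance block; S undefined, block invalidated")
      valid[a:b] <- FALSE
      next
    }
    S[k] <- 1 - se / sx
    if (!is.finite(S[k]) || S[k] <= threshold) valid[a:b] <- FALSE
  }
  initialize(trend, sBlocks = S, blockLength = bl, valid = valid)
}

#' Recording-level quality gate
#'
#' A recording is usable when at most `maxBadFraction` (default 10%) of its
#' 5-s quality blocks fail the S gate (S <= 0.3 or undefined).
#'
#' @param sBlocks numeric S values per block (NA = undefined), or a
#'   [FrequencyTrend-class].
#' @param threshold per-block S gate.
#' @param maxBadFraction maximum tolerated fraction of failing blocks.
#' @return logical: TRUE when the recording is usable.
#' @export
recordingGate <- function(sBlocks, threshold = 0.3, maxBadFraction = 0.1) {
  if (is(sBlocks, "FrequencyTrend")) sBlocks <- sBlocks@sBlocks
  if (!length(sBlocks)) stop("no quality blocks")
  bad <- is.na(sBlocks) | sBlocks <= threshold
  mean(bad) <= maxBadFraction
}

#' Per-phase median f-wave frequency
#'
#' Ff of a phase: the median of the valid trend samples inside the phase
#' window. Missing (with a warning) when fewer than `minValidFraction` of the
#' phase's samples are valid.
#'
#' @param trend a [FrequencyTrend-class] (quality-gated).
#' @param window numeric length-2 phase window (s from signal start).
#' @param minValidFraction minimum valid fraction (default 0.5).
#' @return Ff in Hz or NA.
#' @export
phaseMedianFrequency <- function(trend, window, minValidFraction = 0.5) {
  stopifnot(is(trend, "FrequencyTrend"))
  idx <- .windowIndices(window, trend@fs, length(trend@f))
  if (!length(idx)) {
    warning("empty phase window; Ff missing")
    return(NA_real_)
  }
  ok <- trend@valid[idx] & is.finite(trend@f[idx])
  if (mean(ok) < minValidFraction) {
    warning(sprintf("only %.0f%% of phase samples valid; Ff missing",
                    100 * mean(ok)))
    return(NA_real_)
  }
  stats::median(trend@f[idx][ok])
}
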