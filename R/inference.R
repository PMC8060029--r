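#' @include AllClasses.R kernel.R
NULL

## FFT convolution operators for the Toeplitz forward model K s = k * s
## (causal) and its adjoint; both return length-n vectors.
.makeConvOps <- function(k, n) {
  L <- length(k)
  m <- stats::nextn(n + L, 2)
  kh <- stats::fft(c(k, rep(0, m - L)))
  list(
    K = function(s) {
      f <- stats::fft(c(s, rep(0, m - n)))
      Re(stats::fft(f * kh, inverse = TRUE))[seq_len(n)] / m
    },
    Kt = function(r) {
      f <- stats::fft(c(r, rep(0, m - n)))
      Re(stats::fft(f * Conj(kh), inverse = TRUE))[seq_len(n)] / m
    })
}

## Lawson-Hanson active-set NNLS for min ||A x - y||^2, x >= 0.
.nnlsActiveSet <- function(A, y, tol = NULL) {
  n <- ncol(A)
  x <- numeric(n)
  P <- logical(n)
  w <- crossprod(A, y - A %*% x)[, 1]
  tol <- tol %||% (10 * .Machine$double.eps * max(abs(w), 1) * n)
  iter <- 0L
  while (any(!P) && max(w[!P]) > tol) {
    j <- which(!P)[which.max(w[!P])]
    P[j] <- TRUE
    repeat {
      z <- numeric(n)
      z[P] <- qr.coef(qr(A[, P, drop = FALSE]), y)
      z[P][is.na(z[P])] <- 0
      if (all(z[P] > 0)) { x <- z; break }
      neg <- P & z <= 0
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      P[P & x <= 1e-12] <- FALSE
      x[!P] <- 0
      iter <- iter + 1L
      if (iter > 50L * n) break
    }
    w <- crossprod(A, y - A %*% x)[, 1]
    iter <- iter + 1L
    if (iter > 50L * n) break
  }
  x
}

## FISTA projected-gradient NNLS using the FFT operators; runs until the
## relative objective change drops below `tol`, then polishes the active
## support with an exact equality-constrained solve when small enough.
.nnlsFista <- function(k, y, tol = 1e-9, maxIter = 5000L) {
  n <- length(y)
  ops <- .makeConvOps(k, n)
  ## Lipschitz bound: max |FFT(k)|^2 over frequencies
  m <- stats::nextn(n + length(k), 2)
  Lk <- max(Mod(stats::fft(c(k, rep(0, m - length(k)))))^2)
  x <- numeric(n); z <- x; tPrev <- 1
  objPrev <- sum(y^2)
  for (it in seq_len(maxIter)) {
    g <- ops$Kt(ops$K(z) - y)
    xNew <- pmax(z - g / Lk, 0)
    tNew <- (1 + sqrt(1 + 4 * tPrev^2)) / 2
    z <- xNew + (tPrev - 1) / tNew * (xNew - x)
    x <- xNew; tPrev <- tNew
    if (it %% 10L == 0L) {
      r <- ops$K(x) - y
      obj <- sum(r^2)
      if (abs(objPrev - obj) <= tol * max(obj, 1e-30)) break
      objPrev <- obj
    }
  }
  x
}

#' Non-negative deconvolution (NND) spike inference
#'
#' Solves \eqn{\min_s \|F - K s\|^2} subject to \eqn{s \ge 0}, where `K`
#' convolves with the calcium kernel. With the kernel peak-normalized to
#' the 1 AP dF/F amplitude, one AP contributes unit inferred mass. Low
#' frame-rate traces can be linearly upsampled before deconvolution
#' (performance at ~30 Hz improves considerably when upsampled to
#' ~150 Hz); the solution is aggregated back to native frames by summing.
#'
#' Short problems (up to `activeSetMax` frames at the working rate) are
#' solved exactly with a Lawson-Hanson active set (machine-precision KKT
#' residuals); longer ones with FISTA projected gradient (convergence
#' when the relative objective change falls below `tol`).
#'
#' @param dff a [FluoTrace-class] in dF/F units.
#' @param kernel a [Kernel-class]; resampled internally when its rate
#'   differs from the working rate.
#' @param upsampleTo optional working rate (Hz) for upsampled
#'   deconvolution.
#' @param tol relative-objective convergence tolerance (FISTA path).
#' @param maxIter FISTA iteration cap.
#' @param activeSetMax size threshold for the exact active-set path.
#' @param returnWorking also return the working-rate solution.
#' @return An [InferredActivity-class] at the native frame rate (or, with
#'   `returnWorking = TRUE`, a list with elements `native` and
#'   `working`).
#' @export
nndDeconvolve <- function(dff, kernel, upsampleTo = NULL, tol = 1e-9,
                          maxIter = 20000L, activeSetMax = 1500L,
                          returnWorking = FALSE) {
  stopifnot(is(dff, "FluoTrace"), is(kernel, "Kernel"))
  y <- dff@values
  if (any(!is.finite(y))) stop("non-finite input trace")
  nativeRate <- dff@rate
  workRate <- upsampleTo %||% nativeRate
  up <- max(1L, round(workRate / nativeRate))
  workRate <- nativeRate * up
  if (up > 1L) {
    tN <- seq_along(y) / nativeRate
    tW <- seq_len(length(y) * up) / workRate
    y <- stats::approx(tN, y, xout = tW, rule = 2)$y
  }
  k <- if (abs(kernel@rate - workRate) < 1e-9) kernel@samples
       else calciumKernel(kernel@tauRise, kernel@tauDecay, workRate,
                          amp = kernel@amp)@samples
  n <- length(y)
  s <- if (n <= activeSetMax) {
    A <- matrix(0, n, n)
    for (j in seq_len(n)) {
      len <- min(length(k), n - j + 1L)
      if (len > 0L) A[j:(j + len - 1L), j] <- k[seq_len(len)]
    }
    .nnlsActiveSet(A, y)
  } else {
    .nnlsFista(k, y, tol = tol, maxIter = maxIter)
  }
  native <- if (up > 1L)
    colSums(matrix(s, nrow = up)) else s
  out <- new("InferredActivity", values = pmax(native, 0),
             rate = nativeRate, algorithm = "nnd")
  if (returnWorking)
    list(native = out,
         working = new("InferredActivity", values = pmax(s, 0),
                       rate = workRate, algorithm = "nnd"))
  else out
}

#' KKT residuals of a non-negative least-squares solution
#'
#' For the converged solution the gradient `g = K'(K s - F)` must satisfy
#' `g >= 0` where `s = 0` and `g = 0` where `s > 0`.
#'
#' @param s solution vector.
#' @param k kernel samples at the same rate.
#' @param y observed trace.
#' @return List with `maxViolationZero` (most negative gradient on the
#'   zero set, as a positive number) and `maxGradientSupport` (largest
#'   `|g|` on the support).
#' @export
nndKktResiduals <- function(s, k, y) {
  ops <- .makeConvOps(k, length(y))
  g <- ops$Kt(ops$K(s) - y)
  zero <- s <= 0
  list(maxViolationZero = max(c(0, -g[zero])),
       maxGradientSupport = max(c(0, abs(g[!zero]))))
}

## Sum a per-frame series into bins of bin_s seconds (by frame time).
.binSeries <- function(x, rate, binS) {
  idx <- floor((seq_along(x) - 1L) / (binS * rate)) + 1L
  as.numeric(tapply(x, idx, sum))
}

#' Binned Pearson correlation of inferred and true activity
#'
#' Both series are summed into `binS`-second bins and correlated.
#'
#' @param inferred [InferredActivity-class] or numeric per-frame series.
#' @param trueCounts true AP counts per frame (same length and rate).
#' @param binS bin width in seconds (at least one frame period).
#' @param rate frame rate; taken from `inferred` when it is an
#'   [InferredActivity-class].
#' @return Pearson r, or `NA` (with a warning) when either binned series
#'   is constant.
#' @export
binnedPearson <- function(inferred, trueCounts, binS, rate = NULL) {
  if (is(inferred, "InferredActivity")) {
    rate <- rate %||% inferred@rate
    inferred <- inferred@values
  }
  if (length(inferred) != length(trueCounts))
    stop("length mismatch between inferred and true series")
  if (binS < 1 / rate) stop("binS must be at least one frame period")
  a <- .binSeries(inferred, rate, binS)
  b <- .binSeries(trueCounts, rate, binS)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant binned series; correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Binned Matthews correlation coefficient
#'
#' Bins both series, binarizes (inferred `> threshold`; truth `>= 1` AP)
#' and computes the MCC from the 2x2 table; returns 0 when any margin is
#' zero.
#'
#' @inheritParams binnedPearson
#' @param threshold binarization threshold for the inferred series
#'   (default 0: any inferred mass counts as an event).
#' @return MCC in [-1, 1].
#' @export
binnedMcc <- function(inferred, trueCounts, binS, threshold = 0,
                      rate = NULL) {
  if (is(inferred, "InferredActivity")) {
    rate <- rate %||% inferred@rate
    inferred <- inferred@values
  }
  if (threshold < 0) stop("threshold must be >= 0")
  if (length(inferred) != length(trueCounts))
    stop("length mismatch between inferred and true series")
  a <- .binSeries(inferred, rate, binS) > threshold
  b <- .binSeries(trueCounts, rate, binS) >= 1
  tp <- sum(a & b); fp <- sum(a & !b)
  fn <- sum(!a & b); tn <- sum(!a & !b)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Event-class detection ROC for blind inference output
#'
#' Each event is scored by the summed inferred activity in its window;
#' AP-free windows of the same length provide the null scores. The
#' detection threshold is the `(1 - fp)` quantile of the noise scores and
#' the detection probability is reported per AP-count class (1-5).
#'
#' @param inferred [InferredActivity-class].
#' @param events data.frame from [findIsolatedEvents()] (columns
#'   `t_first`, `n_aps`).
#' @param noiseStarts start frame indices of AP-free windows (e.g.
#'   `attr(sampleNoiseSegments(...), "starts")` mapped to the inferred
#'   rate).
#' @param windowS scoring window length (s).
#' @param fp false-positive probability (default 0.01).
#' @return Named numeric of detection probabilities for classes present
#'   (names = AP count), with the threshold as attribute `"threshold"`.
#' @export
inferenceEventRoc <- function(inferred, events, noiseStarts, windowS,
                              fp = 0.01) {
  stopifnot(is(inferred, "InferredActivity"))
  if (length(noiseStarts) < 2L) stop("at least 2 noise windows required")
  v <- inferred@values
  wlen <- max(1L, round(windowS * inferred@rate))
  score <- function(s0) {
    s0 <- max(1L, s0)
    sum(v[s0:min(length(v), s0 + wlen - 1L)])
  }
  nScores <- vapply(noiseStarts, score, numeric(1))
  thr <- stats::quantile(nScores, 1 - fp, names = FALSE)
  evStart <- floor(events$t_first * inferred@rate) + 1L
  eScores <- vapply(evStart, score, numeric(1))
  out <- tapply(eScores > thr, events$n_aps, mean)
  res <- stats::setNames(as.numeric(out), names(out))
  attr(res, "threshold") <- thr
  res
}
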