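#' @include AllClasses.R simulate.R
NULL

## Central Savitzky-Golay smoothing weights for an odd window and given
## polynomial order: w such that smooth_t = sum_i w_i x_{t+i}.
.sgWeights <- function(window, order) {
  m <- (window - 1L) / 2L
  A <- outer(seq(-m, m) / m, 0:order, `^`)   # scaled offsets: same span
  G <- crossprod(A)
  w <- A %*% solve(G, c(1, rep(0, order)))
  as.numeric(w)
}

## Savitzky-Golay smooth via FFT convolution (the 20001-tap filter the QC
## battery needs is far too long for a direct FIR pass); the first and
## last half-windows are handled by explicit polynomial fits, as in the
## usual implementation.
.sgSmooth <- function(x, window, order = 3) {
  n <- length(x)
  if (window %% 2L == 0L) stop("window must be odd")
  if (n < window) stop("trace shorter than the smoothing window")
  m <- (window - 1L) / 2L
  w <- .sgWeights(window, order)
  full <- stats::convolve(x, rev(w), type = "open")
  out <- full[(m + 1L):(m + n)]
  ## edge windows: polynomial fit over the first/last `window` samples
  basis <- outer(seq(-m, m) / m, 0:order, `^`)
  cf1 <- qr.coef(qr(basis), x[1:window])
  out[1:m] <- (outer(seq(-m, -1) / m, 0:order, `^`) %*% cf1)[, 1]
  cf2 <- qr.coef(qr(basis), x[(n - window + 1L):n])
  out[(n - m + 1L):n] <- (outer(seq(1, m) / m, 0:order, `^`) %*% cf2)[, 1]
  out
}

#' Detrend a voltage trace with a Savitzky-Golay baseline
#'
#' The baseline is a third-order Savitzky-Golay smooth over 20,001 samples
#' (half a second at 40 kHz); the detrended trace is the residual.
#'
#' @param trace a [VoltageTrace-class].
#' @param window odd filter length in samples (default 20001).
#' @param order polynomial order (default 3).
#' @return List with elements `detrended` and `baseline`, both
#'   [VoltageTrace-class] objects.
#' @export
detrendVm <- function(trace, window = 20001L, order = 3L) {
  stopifnot(is(trace, "VoltageTrace"))
  if (length(trace@samples) < window)
    stop("trace shorter than the Savitzky-Golay window")
  bl <- .sgSmooth(trace@samples, window, order)
  list(
    detrended = new("VoltageTrace", samples = trace@samples - bl,
                    rate = trace@rate, t0 = trace@t0),
    baseline = new("VoltageTrace", samples = bl, rate = trace@rate,
                   t0 = trace@t0))
}

#' Quiroga robust noise threshold
#'
#' `median(|V|) / 0.6745`; equals the Gaussian standard deviation for pure
#' zero-mean noise and is insensitive to a small fraction of spikes.
#'
#' @param samples numeric vector (typically a detrended voltage trace).
#' @return The threshold (same units as the input).
#' @export
quirogaThreshold <- function(samples) {
  if (!length(samples)) stop("empty input")
  if (all(is.na(samples))) stop("all-NaN input")
  stats::median(abs(samples), na.rm = TRUE) / 0.6745
}

## Local maxima above `thr` with a minimum separation (larger peak wins).
.findPeaks <- function(x, thr, minSep) {
  n <- length(x)
  cand <- which(x > thr)
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[x[cand] >= x[cand - 1L] & x[cand] > x[cand + 1L]]
  if (!length(cand)) return(integer(0))
  keep <- integer(0)
  ord <- cand[order(x[cand], decreasing = TRUE)]
  taken <- logical(n)
  for (i in ord) {
    lo <- max(1L, i - minSep); hi <- min(n, i + minSep)
    if (!any(taken[lo:hi])) {
      keep <- c(keep, i)
      taken[i] <- TRUE
    }
  }
  sort(keep)
}

#' Detect action potentials in a voltage trace
#'
#' Two detectors are provided. The default band-passes the trace (4th-order
#' Butterworth, 250-5000 Hz, zero-phase) and thresholds at
#' `5 * sd`; the `"qt"` detector thresholds the (already detrended) trace
#' at `k` times the Quiroga threshold, which is the path used by the
#' quality-control battery. Peaks are strict local maxima with a 1 ms
#' refractory separation; waveform snippets of 2 ms (AP time +/- 1 ms) are
#' Savitzky-Golay smoothed (quadratic kernel).
#'
#' @param trace a [VoltageTrace-class] (for `"qt"`, detrended).
#' @param method `"bandpass"` (default) or `"qt"`.
#' @param k threshold multiplier for the `"qt"` detector (default 10).
#' @param refractoryS minimum peak separation (s), default 1 ms.
#' @return An [APTrain-class]; zero detections give an empty train, not an
#'   error.
#' @export
detectAPs <- function(trace, method = c("bandpass", "qt"), k = 10,
                      refractoryS = 0.001) {
  stopifnot(is(trace, "VoltageTrace"))
  method <- match.arg(method)
  if (k <= 0) stop("k must be > 0")
  rate <- trace@rate
  if (method == "bandpass") {
    ny <- rate / 2
    hi <- min(5000, 0.9 * ny)        # keep the band inside Nyquist
    bf <- signal::butter(4, c(250, hi) / ny, type = "pass")
    ## remove the DC offset first: filtfilt rings at the edges otherwise
    x <- signal::filtfilt(bf, trace@samples - stats::median(trace@samples))
    ## threshold scale from the unfiltered trace: the band-passed noise
    ## floor sits well below it, so spurious 5-sigma crossings of the
    ## filtered noise do not register
    thr <- 5 * stats::sd(trace@samples)
  } else {
    x <- trace@samples
    thr <- k * quirogaThreshold(x)
  }
  idx <- .findPeaks(x, thr, as.integer(round(refractoryS * rate)))
  half <- as.integer(round(0.001 * rate))
  full <- idx[idx > half & idx + half <= length(x)]
  wf <- matrix(numeric(0), nrow = 0, ncol = 2L * half + 1L)
  if (length(full)) {
    wf <- t(vapply(full, function(i) x[(i - half):(i + half)],
                   numeric(2L * half + 1L)))
    wf <- t(apply(wf, 1L, function(row)
      signal::sgolayfilt(row, p = 2, n = 9)))
  }
  new("APTrain", times = trace@t0 + (full - 1L) / rate,
      amplitudes = x[full], waveforms = wf, rate = rate)
}

## slope, r2 and intercept of y ~ x by closed-form least squares
.linreg <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L || stats::var(x) == 0)
    return(c(slope = NA_real_, r2 = NA_real_, intercept = NA_real_))
  slope <- stats::cov(x, y) / stats::var(x)
  r <- if (stats::var(y) == 0) 0 else stats::cor(x, y)
  c(slope = slope, r2 = r^2, intercept = mean(y) - slope * mean(x))
}

## left/right width at half amplitude of one smoothed waveform snippet,
## with linear interpolation at the crossings; centre = peak sample
.halfWidths <- function(wf, rate) {
  c_idx <- which.max(wf)
  half <- wf[c_idx] / 2
  lw <- NA_real_; rw <- NA_real_
  below <- which(wf[1:c_idx] < half)
  if (length(below)) {
    i <- max(below)           # last sample below half before the peak
    frac <- (half - wf[i]) / (wf[i + 1L] - wf[i])
    lw <- (c_idx - i - frac) / rate
  }
  below <- which(wf[c_idx:length(wf)] < half)
  if (length(below)) {
    j <- c_idx + min(below) - 1L  # first sample below half after the peak
    frac <- (wf[j - 1L] - half) / (wf[j - 1L] - wf[j])
    rw <- (j - 1L + frac - c_idx) / rate
  }
  c(lw, rw)
}
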