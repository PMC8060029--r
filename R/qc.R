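#' @include ephys.R
NULL

#' Compute the 35-metric electrophysiology quality-control battery
#'
#' Detrends the trace (Savitzky-Golay order 3, 20,001 samples), detects APs
#' at 10x the Quiroga threshold (unless a train is supplied) and computes
#' the full battery of descriptive statistics: robust baseline ratios,
#' Quiroga-threshold stability over 1000 resampled 10 s windows, baseline
#' and threshold drift regressions, polarity balance, AP amplitude and
#' width statistics with their time trends, box-car firing-rate statistics,
#' and baseline-vs-activity correlations. AP-dependent metrics require
#' more than 3 APs and are `NA` (not applicable) otherwise.
#'
#' @param trace a raw [VoltageTrace-class].
#' @param apTrain optional [APTrain-class]; detected internally (Quiroga
#'   path, `k = 10`) when missing.
#' @param window Savitzky-Golay window (samples).
#' @param nQtWindows number of threshold-stability windows (default 1000).
#' @param qtWindowS stability window length in seconds (default 10; shrinks
#'   to a tenth of the recording when the recording is shorter than 10 s).
#' @param seed seed for the stability-window start times (recorded choice;
#'   does not touch the session RNG).
#' @return An ungated [QCReport-class] (all flags `NA`).
#' @export
computeQCMetrics <- function(trace, apTrain = NULL, window = 20001L,
                             nQtWindows = 1000L, qtWindowS = 10,
                             seed = 1L) {
  stopifnot(is(trace, "VoltageTrace"))
  rate <- trace@rate
  raw <- trace@samples
  n <- length(raw)
  dur <- n / rate
  dt <- detrendVm(trace, window = window)
  D <- dt$detrended@samples
  BL <- dt$baseline@samples
  if (is.null(apTrain)) apTrain <- detectAPs(dt$detrended, "qt", k = 10)
  m <- stats::setNames(rep(NA_real_, 35L), .QC_METRIC_NAMES)

  m["mrdm"] <- stats::mad(raw, constant = 1) / stats::median(raw)
  m["baseline_mean"] <- mean(BL)
  m["baseline_cv"] <- stats::sd(BL) / mean(BL)
  qt <- quirogaThreshold(D)
  m["qt_mean"] <- qt

  ## threshold stability: QT over uniformly resampled windows
  wlen <- if (dur >= qtWindowS) round(qtWindowS * rate)
          else round(dur / 10 * rate)
  grid <- unique(round(seq(1, n - wlen + 1, length.out = 5000L)))
  starts <- .withSeed(seed,
    sort(sample(grid, min(nQtWindows, length(grid)))))
  qts <- .windowMedianAbs(D, as.integer(starts), as.integer(wlen)) /
    0.6745
  m["qns"] <- stats::sd(qts) / mean(qts)
  reg <- .linreg((starts - 1L) / rate, qts)
  m["qt_r2"] <- reg["r2"]; m["qt_slope"] <- reg["slope"]

  tSamp <- (seq_len(n) - 1L) / rate
  reg <- .linreg(tSamp, BL)
  m["bl_r2"] <- reg["r2"]; m["bl_slope"] <- reg["slope"]
  m["polarity_ratio"] <- sum(D > qt) / sum(D < -qt)

  times <- apTrain@times
  amps <- apTrain@amplitudes
  nAps <- length(times)
  m["n_aps"] <- nAps
  if (nAps > 3L) {
    isi <- diff(times)
    m["ml_isi"] <- exp(mean(log(isi)))      # ML lognormal scale
    m["ap_amp_mean"] <- mean(amps)
    m["ap_amp_cv"] <- stats::sd(amps) / mean(amps)
    m["ap_amp_mrd"] <- stats::mad(amps, constant = 1) /
      stats::median(amps)
    m["ap_amp_rel_range"] <- (max(amps) - min(amps)) /
      stats::median(amps)
    m["ap_amp_maxmin"] <- max(amps) / min(amps)
    m["snr"] <- stats::median(amps) / qt

    hw <- t(apply(apTrain@waveforms, 1L, .halfWidths,
                  rate = apTrain@rate))
    lw <- hw[, 1]; rw <- hw[, 2]; fw <- lw + rw
    m["lwhm"] <- mean(lw, na.rm = TRUE)
    m["rwhm"] <- mean(rw, na.rm = TRUE)
    m["fwhm"] <- m["lwhm"] + m["rwhm"]
    m["lwhm_cv"] <- stats::sd(lw, na.rm = TRUE) / m["lwhm"]
    m["rwhm_cv"] <- stats::sd(rw, na.rm = TRUE) / m["rwhm"]
    m["fwhm_cv"] <- stats::sd(fw, na.rm = TRUE) / mean(fw, na.rm = TRUE)
    reg <- .linreg(times, amps)
    m["amp_vs_time_r2"] <- reg["r2"]
    m["amp_vs_time_slope"] <- reg["slope"]
    reg <- .linreg(times, fw)
    m["fwhm_vs_time_r2"] <- reg["r2"]
    m["fwhm_vs_time_slope"] <- reg["slope"]
  }

  ## firing rate: AP train binned at 10 ms, 1 s box-car; edges trimmed to
  ## full windows
  binDt <- 0.01
  nb <- max(1L, floor(dur / binDt))
  counts <- tabulate(pmin(floor(times / binDt) + 1L, nb), nbins = nb)
  wlenB <- round(1 / binDt)
  if (nb > wlenB) {
    cs <- c(0, cumsum(counts))
    fr <- (cs[(wlenB + 1L):(nb + 1L)] - cs[1:(nb - wlenB + 1L)])  # Hz
    tFr <- (seq_along(fr) - 1L + wlenB / 2) * binDt
    m["fr_mean"] <- mean(fr)
    m["fr_cv"] <- if (mean(fr) > 0) stats::sd(fr) / mean(fr) else NA_real_
    reg <- .linreg(tFr, fr)
    m["fr_vs_time_r2"] <- reg["r2"]
    m["fr_vs_time_slope"] <- reg["slope"]
    blFr <- BL[pmin(n, round(tFr * rate) + 1L)]
    m["corr_bl_fr"] <- suppressWarnings(stats::cor(blFr, fr))
  }
  if (nAps > 3L) {
    blAp <- BL[pmin(n, round((times - trace@t0) * rate) + 1L)]
    m["corr_bl_ampl"] <- suppressWarnings(stats::cor(blAp, amps))
    m["corr_bl_fwhm"] <- suppressWarnings(stats::cor(blAp, fw))
  }
  new("QCReport", metrics = m,
      flags = stats::setNames(rep(NA, 35L), .QC_METRIC_NAMES),
      verdict = "ungated")
}

## Goodness-of-fit (r^2) metrics are gated one-sided: their null
## distributions pile up at zero, so a value below the reference minimum
## only means a recording even more stationary than the reference —
## never an artifact symptom (artifacts inflate them).
.QC_ONE_SIDED <- c("qt_r2", "bl_r2", "amp_vs_time_r2",
                   "fwhm_vs_time_r2", "fr_vs_time_r2")

#' Gate a QC report against a reference population
#'
#' The acceptable range of each metric is the min-max span over the
#' reference reports; the recording passes when every applicable
#' (non-`NA`) metric lies inside its range. Regression r-squared metrics
#' are bounded above only: they are non-negative statistics whose
#' artifact-symptomatic direction is high, and whose null mass at zero
#' makes a two-sided minimum unenforceable. Enlarging the reference can
#' only widen ranges, so verdicts can only flip fail to pass.
#'
#' @param report an ungated [QCReport-class].
#' @param reference non-empty list of [QCReport-class] objects.
#' @return The report with flags and verdict filled in.
#' @export
qcGate <- function(report, reference) {
  if (!length(reference)) stop("empty reference set")
  stopifnot(is(report, "QCReport"),
            all(vapply(reference, is, TRUE, "QCReport")))
  refm <- do.call(rbind, lapply(reference, qcMetrics))
  lo <- suppressWarnings(apply(refm, 2L, min, na.rm = TRUE))
  hi <- suppressWarnings(apply(refm, 2L, max, na.rm = TRUE))
  lo[.QC_ONE_SIDED] <- -Inf
  mets <- report@metrics
  flags <- ifelse(is.na(mets), NA,
                  mets >= lo[names(mets)] & mets <= hi[names(mets)])
  appl <- flags[!is.na(flags)]
  new("QCReport", metrics = mets,
      flags = stats::setNames(as.logical(flags), names(mets)),
      verdict = if (all(appl)) "pass" else "fail")
}

#' Imaging stability statistics of a movie
#'
#' Small named battery over the spatial frame means: relative temporal
#' slope (fraction/s), last-to-first decile decay ratio, and coefficient
#' of variation. Catches photobleaching and slow intensity drift that the
#' electrophysiology battery cannot see.
#'
#' @param movie array `height x width x frames`.
#' @param frameRate frame rate (Hz).
#' @return Named numeric vector `fm_slope_rel`, `fm_decay_ratio`, `fm_cv`.
#' @export
imagingStabilityMetrics <- function(movie, frameRate) {
  nF <- dim(movie)[3]
  fm <- colMeans(matrix(movie, ncol = nF))
  t <- (seq_len(nF) - 1L) / frameRate
  dec <- max(1L, floor(nF / 10))
  ## medians over the deciles: robust to transient-driven swings
  c(fm_slope_rel = unname(.linreg(t, fm)["slope"]) / mean(fm),
    fm_decay_ratio = stats::median(fm[(nF - dec + 1L):nF]) /
      stats::median(fm[1:dec]),
    fm_cv = stats::sd(fm) / mean(fm))
}

#' Full quality control of one paired recording
#'
#' Combines the 35-metric electrophysiology battery with the imaging
#' stability battery.
#'
#' @param rec a [GroundTruthRecording-class].
#' @param ... passed to [computeQCMetrics()].
#' @return List with `report` ([QCReport-class]) and `imaging` (named
#'   numeric).
#' @export
recordingQC <- function(rec, ...) {
  list(report = computeQCMetrics(vmTrace(rec), ...),
       imaging = imagingStabilityMetrics(movieArray(rec),
                                         frameRate(rec)))
}

#' Gate a recording against a reference population (ephys + imaging)
#'
#' Both batteries are gated by the min-max rule of [qcGate()]; the
#' recording passes only when it passes both, mirroring acceptance into
#' analysis only after electrophysiology and image quality control.
#'
#' @param qc output of [recordingQC()] for the recording under test.
#' @param reference non-empty list of [recordingQC()] outputs.
#' @return List with the gated `report`, logical `imagingFlags`, overall
#'   `verdict` (`"pass"`/`"fail"`) and `failing` metric names.
#' @export
gateRecording <- function(qc, reference) {
  if (!length(reference)) stop("empty reference set")
  gated <- qcGate(qc$report, lapply(reference, `[[`, "report"))
  refi <- do.call(rbind, lapply(reference, `[[`, "imaging"))
  lo <- apply(refi, 2L, min); hi <- apply(refi, 2L, max)
  iflags <- qc$imaging >= lo & qc$imaging <= hi
  pass <- qcVerdict(gated) == "pass" && all(iflags)
  failing <- c(names(which(!qcFlags(gated))), names(which(!iflags)))
  list(report = gated, imagingFlags = iflags,
       verdict = if (pass) "pass" else "fail", failing = failing)
}

#' Write QC reports to CSV
#'
#' One row per recording: 35 metric columns, 35 flag columns, verdict.
#'
#' @param reports a [QCReport-class] or list of them.
#' @param file output path.
#' @return The written data.frame, invisibly.
#' @export
writeQCReport <- function(reports, file) {
  if (is(reports, "QCReport")) reports <- list(reports)
  df <- do.call(rbind, lapply(reports, function(r) {
    row <- c(as.list(qcMetrics(r)),
             stats::setNames(as.list(qcFlags(r)),
                             paste0(names(qcFlags(r)), "_ok")),
             list(verdict = qcVerdict(r)))
    as.data.frame(row)
  }))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}
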