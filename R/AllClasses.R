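#' @import methods
NULL

## Names of the 35 electrophysiology QC metrics, in the canonical order.
## Kept internal; exposed through qcMetricNames().
.QC_METRIC_NAMES <- c(
  "mrdm", "baseline_mean", "baseline_cv", "qt_mean", "qns",
  "qt_r2", "qt_slope", "bl_r2", "bl_slope", "polarity_ratio",
  "n_aps", "ml_isi", "ap_amp_mean", "ap_amp_cv", "ap_amp_mrd",
  "ap_amp_rel_range", "ap_amp_maxmin", "snr", "lwhm", "rwhm",
  "fwhm", "lwhm_cv", "rwhm_cv", "fwhm_cv", "amp_vs_time_r2",
  "amp_vs_time_slope", "fwhm_vs_time_r2", "fwhm_vs_time_slope",
  "fr_mean", "fr_cv", "fr_vs_time_r2", "fr_vs_time_slope",
  "corr_bl_fr", "corr_bl_ampl", "corr_bl_fwhm")

#' Names of the 35 ephys quality-control metrics
#'
#' @return Character vector of length 35 in canonical order.
#' @export
qcMetricNames <- function() .QC_METRIC_NAMES

#' Simulation configuration for a paired ground-truth recording
#'
#' Holds every parameter of the synthetic paired-recording generator:
#' spike-train statistics, the biphasic AP waveform placed on the voltage
#' trace, the difference-of-exponentials calcium kernel of the indicator,
#' neuropil contamination, and the Poisson photon-noise model of the movie.
#'
#' @slot seed integer RNG seed; identical configs give bit-identical output.
#' @slot durationS recording duration (s).
#' @slot ephysRate voltage sampling rate (Hz).
#' @slot frameRate imaging frame rate (Hz).
#' @slot fovPx integer (height, width) of the field of view in pixels.
#' @slot somaRadiusPx soma disk radius (pixels).
#' @slot indicator `"6s"` or `"6f"`.
#' @slot kernelAmp1AP peak dF/F of the 1 AP calcium transient.
#' @slot tauRise,tauDecay kernel time constants (s); `tauRise < tauDecay`.
#' @slot perApGain multipliers (length <= 5) applied to 1-5 AP events
#'   (supralinearity); default linear.
#' @slot firingRate somatic Poisson firing rate (Hz).
#' @slot refractoryS dead time between APs (s).
#' @slot neuropilAmp peak dF/F of one neuropil transient.
#' @slot neuropilRate rate of the independent neuropil event train (Hz).
#' @slot rTrue true neuropil contamination coefficient, in [0, 1.5].
#' @slot baselinePhotons mean photons/pixel/frame of the neuropil baseline.
#' @slot somaBrightness ratio of soma to neuropil baseline photon rate.
#' @slot photonGain recorded fluorescence units per photon.
#' @slot pedestal additive recorded-unit offset.
#' @slot apAmpMv,apFwhmMs AP waveform amplitude (mV) and width (ms).
#' @slot vmNoiseMv Gaussian voltage noise sd (mV).
#' @slot driftMvPerS linear baseline drift (mV/s).
#' @slot vmBaselineMv constant voltage offset (mV).
#'
#' @seealso [simConfig()] for the user constructor with per-indicator
#'   defaults, [simulateRecording()].
#' @export
setClass("SimConfig", representation(
  seed = "integer", durationS = "numeric", ephysRate = "numeric",
  frameRate = "numeric", fovPx = "integer", somaRadiusPx = "numeric",
  indicator = "character", kernelAmp1AP = "numeric", tauRise = "numeric",
  tauDecay = "numeric", perApGain = "numeric", firingRate = "numeric",
  refractoryS = "numeric", neuropilAmp = "numeric", neuropilRate = "numeric",
  rTrue = "numeric", baselinePhotons = "numeric", somaBrightness = "numeric",
  photonGain = "numeric", pedestal = "numeric", apAmpMv = "numeric",
  apFwhmMs = "numeric", vmNoiseMv = "numeric", driftMvPerS = "numeric",
  vmBaselineMv = "numeric"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@tauRise >= object@tauDecay)
    msg <- c(msg, "tauRise must be < tauDecay")
  if (length(object@perApGain) > 5L)
    msg <- c(msg, "perApGain may have at most 5 entries")
  pos <- c(ephysRate = object@ephysRate, frameRate = object@frameRate,
           baselinePhotons = object@baselinePhotons,
           photonGain = object@photonGain,
           kernelAmp1AP = object@kernelAmp1AP,
           somaBrightness = object@somaBrightness)
  if (any(pos <= 0))
    msg <- c(msg, paste("must be > 0:",
                        paste(names(pos)[pos <= 0], collapse = ", ")))
  if (object@firingRate < 0) msg <- c(msg, "firingRate must be >= 0")
  if (object@refractoryS < 0) msg <- c(msg, "refractoryS must be >= 0")
  if (object@rTrue < 0 || object@rTrue > 1.5)
    msg <- c(msg, "rTrue must lie in [0, 1.5]")
  if (!object@indicator %in% c("6s", "6f"))
    msg <- c(msg, "indicator must be '6s' or '6f'")
  if (length(object@fovPx) != 2L || any(object@fovPx < 1L))
    msg <- c(msg, "fovPx must be two positive integers")
  if (length(msg)) msg else TRUE
})

#' A sampled voltage trace
#'
#' @slot samples voltage samples (mV).
#' @slot rate sampling rate (Hz).
#' @slot t0 time of the first sample (s).
#' @export
setClass("VoltageTrace", representation(
  samples = "numeric", rate = "numeric", t0 = "numeric"))

setValidity("VoltageTrace", function(object) {
  if (object@rate <= 0) return("rate must be > 0")
  if (any(!is.finite(object@samples))) return("samples must be finite")
  TRUE
})

#' A detected (or simulated) action-potential train
#'
#' @slot times AP times (s), strictly increasing.
#' @slot amplitudes peak amplitudes (mV), one per AP.
#' @slot waveforms matrix of 2 ms waveform snippets (one row per AP).
#' @slot rate sampling rate of the waveform snippets (Hz).
#' @export
setClass("APTrain", representation(
  times = "numeric", amplitudes = "numeric", waveforms = "matrix",
  rate = "numeric"))

setValidity("APTrain", function(object) {
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (length(object@amplitudes) != length(object@times))
    return("amplitudes and times must have equal length")
  TRUE
})

#' A sampled fluorescence trace
#'
#' @slot values fluorescence (recorded units or photons).
#' @slot rate frame rate (Hz).
#' @slot t0 time of the first frame center (s).
#' @export
setClass("FluoTrace", representation(
  values = "numeric", rate = "numeric", t0 = "numeric"))

setValidity("FluoTrace", function(object) {
  if (object@rate <= 0) return("rate must be > 0")
  TRUE
})

#' A simulated paired ephys + imaging recording with hidden ground truth
#'
#' The central container of the synthetic-data module: the AP train, the
#' rendered voltage trace, the photon-noise movie, soma/neuropil masks, and
#' a `truth` list holding quantities the downstream analysis is meant to
#' recover (kernel samples, rTrue, photonGain, pedestal, per-frame AP
#' counts).
#'
#' @slot apTimes true AP times (s), sorted.
#' @slot vm a [VoltageTrace-class].
#' @slot movie array `height x width x frames` in recorded units.
#' @slot somaMask,neuropilMask disjoint logical `height x width` matrices.
#' @slot frameRate imaging frame rate (Hz).
#' @slot truth list of hidden ground-truth values.
#' @slot config the generating [SimConfig-class].
#' @slot provenance list logging artifact injections.
#' @export
setClass("GroundTruthRecording", representation(
  apTimes = "numeric", vm = "VoltageTrace", movie = "array",
  somaMask = "matrix", neuropilMask = "matrix", frameRate = "numeric",
  truth = "list", config = "SimConfig", provenance = "list"))

setValidity("GroundTruthRecording", function(object) {
  msg <- character()
  if (any(object@somaMask & object@neuropilMask))
    msg <- c(msg, "soma and neuropil masks must be disjoint")
  if (length(object@apTimes) > 1L && any(diff(object@apTimes) <= 0))
    msg <- c(msg, "apTimes must be strictly increasing")
  tc <- object@truth$frame_ap_counts
  if (!is.null(tc) && sum(tc) != length(object@apTimes))
    msg <- c(msg, "per-frame true AP counts must sum to length(apTimes)")
  if (length(msg)) msg else TRUE
})

#' The 35-metric electrophysiology quality-control report
#'
#' @slot metrics named numeric of exactly the 35 statistics (NA where a
#'   metric is not applicable, e.g. <= 3 APs).
#' @slot flags named logical in-range flags (NA until gated).
#' @slot verdict `"pass"`, `"fail"` or `"ungated"`.
#' @export
setClass("QCReport", representation(
  metrics = "numeric", flags = "logical", verdict = "character"))

setValidity("QCReport", function(object) {
  if (!identical(names(object@metrics), .QC_METRIC_NAMES))
    return("metrics must be exactly the 35 named statistics, in order")
  if (!identical(names(object@flags), .QC_METRIC_NAMES))
    return("flags must carry the 35 metric names")
  if (!object@verdict %in% c("pass", "fail", "ungated"))
    return("verdict must be 'pass', 'fail' or 'ungated'")
  if (object@verdict != "ungated") {
    applicable <- object@flags[!is.na(object@flags)]
    want <- if (all(applicable)) "pass" else "fail"
    if (object@verdict != want)
      return("verdict must be the AND of the applicable flags")
  }
  TRUE
})

#' Detection template (mean response and its zero-mean unit vector)
#'
#' @slot meanResponse mean dF/F response trace of one event class.
#' @slot unitVector same-length vector with zero mean and unit norm.
#' @export
setClass("Template", representation(
  meanResponse = "numeric", unitVector = "numeric"))

setValidity("Template", function(object) {
  if (length(object@meanResponse) != length(object@unitVector))
    return("meanResponse and unitVector must have equal length")
  if (abs(mean(object@unitVector)) >= 1e-12)
    return("unitVector must have zero mean")
  if (abs(sqrt(sum(object@unitVector^2)) - 1) >= 1e-12)
    return("unitVector must have unit norm")
  TRUE
})

#' A receiver operating characteristic curve from a threshold sweep
#'
#' @slot fpProb false-positive probabilities, ascending in [0, 1].
#' @slot tpProb true-positive probabilities in [0, 1].
#' @slot thresholds noise-percentile threshold values, one per point.
#' @slot auc trapezoidal area under the curve.
#' @export
setClass("RocCurve", representation(
  fpProb = "numeric", tpProb = "numeric", thresholds = "numeric",
  auc = "numeric"))

setValidity("RocCurve", function(object) {
  if (is.unsorted(object@fpProb)) return("fpProb must be ascending")
  if (any(object@fpProb < 0 | object@fpProb > 1) ||
      any(object@tpProb < 0 | object@tpProb > 1))
    return("probabilities must lie in [0, 1]")
  if (object@auc < 0 || object@auc > 1) return("auc must lie in [0, 1]")
  TRUE
})

#' Photon-gain calibration from the pixelwise variance-mean relation
#'
#' One (slope, offset) pair per column along the resonant scanning axis:
#' `var(F) = slope * mean(F) + offset`, so slope is the gain
#' (fluorescence units per photon) and `-offset/slope` the pedestal.
#'
#' @slot slope gain per column (fluorescence units / photon).
#' @slot offset intercept per column (fluorescence units squared).
#' @slot resonantAxis `"width"` (columns) or `"height"`.
#' @export
setClass("PhotonCalibration", representation(
  slope = "numeric", offset = "numeric", resonantAxis = "character"))

setValidity("PhotonCalibration", function(object) {
  if (any(object@slope <= 0)) return("slope must be > 0")
  if (length(object@slope) != length(object@offset))
    return("slope and offset must have equal length")
  TRUE
})

#' Difference-of-exponentials fit to a mean calcium transient
#'
#' @slot amplitude fitted A (dF/F), >= 0.
#' @slot tauRise,tauDecay fitted time constants (s), `tauRise < tauDecay`.
#' @slot rss residual sum of squares.
#' @slot converged FALSE when every start failed or the fit is degenerate.
#' @export
setClass("TransientFit", representation(
  amplitude = "numeric", tauRise = "numeric", tauDecay = "numeric",
  rss = "numeric", converged = "logical"))

setValidity("TransientFit", function(object) {
  if (isTRUE(object@converged)) {
    if (object@tauRise >= object@tauDecay)
      return("tauRise must be < tauDecay")
    if (object@amplitude < 0) return("amplitude must be >= 0")
  }
  TRUE
})

#' Per-frame non-negative spike-inference output
#'
#' @slot values non-negative per-frame AP-count estimates.
#' @slot rate frame rate (Hz).
#' @slot algorithm algorithm tag (e.g. `"nnd"`).
#' @export
setClass("InferredActivity", representation(
  values = "numeric", rate = "numeric", algorithm = "character"))

setValidity("InferredActivity", function(object) {
  if (any(object@values < -1e-12)) return("values must be non-negative")
  if (object@rate <= 0) return("rate must be > 0")
  TRUE
})

#' The 20 phase variants of a block-downsampled movie plus tiled traces
#'
#' @slot variants list of 20 movies (spatial phase 0-3 x temporal phase
#'   0-4), each block-averaged `sf x sf` in space and `tf` in time.
#' @slot phases data.frame with columns `spatial`, `temporal`.
#' @slot frameRate output frame rate (input rate / tf).
#' @slot spatialFactor,temporalFactor the block factors.
#' @slot tiledTraces matrix of 400 ROI traces (rows; sf*tf identical
#'   copies per variant), truncated to the shortest variant.
#' @export
setClass("DownsampleSet", representation(
  variants = "list", phases = "data.frame", frameRate = "numeric",
  spatialFactor = "integer", temporalFactor = "integer",
  tiledTraces = "matrix"))

setValidity("DownsampleSet", function(object) {
  nv <- object@spatialFactor * object@temporalFactor
  if (length(object@variants) != nv)
    return(sprintf("expected %d variants", nv))
  if (nrow(object@tiledTraces) > 0L &&
      nrow(object@tiledTraces) != nv * nv)
    return(sprintf("expected %d tiled traces", nv * nv))
  TRUE
})

#' DBSCAN/KS quality control of tiled downsampled traces
#'
#' @slot labels integer cluster label per trace (0 = noise point).
#' @slot medians matrix of per-cluster median traces (rows).
#' @slot ksP KS-test p value per cluster (vs matched white noise).
#' @slot kept indices of clusters with ksP < 0.05.
#' @slot selectedTrace the AP-train-selected combination trace.
#' @slot passed TRUE when the selected trace beats the Poisson null.
#' @export
setClass("ClusterQC", representation(
  labels = "integer", medians = "matrix", ksP = "numeric",
  kept = "integer", selectedTrace = "numeric", passed = "logical"))

setValidity("ClusterQC", function(object) {
  if (length(object@kept) &&
      any(object@ksP[object@kept] >= 0.05))
    return("kept clusters must have ksP < 0.05")
  TRUE
})
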