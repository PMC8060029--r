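#' @include AllClasses.R
NULL

#' Accessors for spikefluor classes
#'
#' Small accessor family; slots should not be reached with `@` by user
#' code.
#'
#' @param x an object of the documented class.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("apTimes", function(x) standardGeneric("apTimes"))
#' @rdname accessors
#' @export
setMethod("apTimes", "GroundTruthRecording", function(x) x@apTimes)
#' @rdname accessors
#' @export
setMethod("apTimes", "APTrain", function(x) x@times)

#' @rdname accessors
#' @export
setGeneric("vmTrace", function(x) standardGeneric("vmTrace"))
#' @rdname accessors
#' @export
setMethod("vmTrace", "GroundTruthRecording", function(x) x@vm)

#' @rdname accessors
#' @export
setGeneric("movieArray", function(x) standardGeneric("movieArray"))
#' @rdname accessors
#' @export
setMethod("movieArray", "GroundTruthRecording", function(x) x@movie)

#' @rdname accessors
#' @export
setGeneric("somaMask", function(x) standardGeneric("somaMask"))
#' @rdname accessors
#' @export
setMethod("somaMask", "GroundTruthRecording", function(x) x@somaMask)

#' @rdname accessors
#' @export
setGeneric("neuropilMask", function(x) standardGeneric("neuropilMask"))
#' @rdname accessors
#' @export
setMethod("neuropilMask", "GroundTruthRecording", function(x) x@neuropilMask)

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setMethod("groundTruth", "GroundTruthRecording", function(x) x@truth)

#' @rdname accessors
#' @export
setGeneric("recordingConfig", function(x) standardGeneric("recordingConfig"))
#' @rdname accessors
#' @export
setMethod("recordingConfig", "GroundTruthRecording", function(x) x@config)

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setMethod("provenance", "GroundTruthRecording", function(x) x@provenance)

#' @rdname accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setMethod("frameRate", "GroundTruthRecording", function(x) x@frameRate)
#' @rdname accessors
#' @export
setMethod("frameRate", "FluoTrace", function(x) x@rate)
#' @rdname accessors
#' @export
setMethod("frameRate", "DownsampleSet", function(x) x@frameRate)
#' @rdname accessors
#' @export
setMethod("frameRate", "InferredActivity", function(x) x@rate)

#' @rdname accessors
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))
#' @rdname accessors
#' @export
setMethod("traceValues", "FluoTrace", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("traceValues", "VoltageTrace", function(x) x@samples)
#' @rdname accessors
#' @export
setMethod("traceValues", "InferredActivity", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("qcMetrics", function(x) standardGeneric("qcMetrics"))
#' @rdname accessors
#' @export
setMethod("qcMetrics", "QCReport", function(x) x@metrics)

#' @rdname accessors
#' @export
setGeneric("qcFlags", function(x) standardGeneric("qcFlags"))
#' @rdname accessors
#' @export
setMethod("qcFlags", "QCReport", function(x) x@flags)

#' @rdname accessors
#' @export
setGeneric("qcVerdict", function(x) standardGeneric("qcVerdict"))
#' @rdname accessors
#' @export
setMethod("qcVerdict", "QCReport", function(x) x@verdict)

#' @rdname accessors
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))
#' @rdname accessors
#' @export
setMethod("auc", "RocCurve", function(x) x@auc)

#' @rdname accessors
#' @export
setGeneric("unitVector", function(x) standardGeneric("unitVector"))
#' @rdname accessors
#' @export
setMethod("unitVector", "Template", function(x) x@unitVector)

#' @rdname accessors
#' @export
setGeneric("tiledTraces", function(x) standardGeneric("tiledTraces"))
#' @rdname accessors
#' @export
setMethod("tiledTraces", "DownsampleSet", function(x) x@tiledTraces)

## ---- show methods -------------------------------------------------------

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig (GCaMP", object@indicator, ")\n", sep = "")
  cat(sprintf("  %.1f s, ephys %.0f Hz, imaging %.1f Hz, fov %dx%d px\n",
              object@durationS, object@ephysRate, object@frameRate,
              object@fovPx[1], object@fovPx[2]))
  cat(sprintf("  kernel: amp %.3f dF/F, tau %.3f/%.3f s; firing %.2f Hz\n",
              object@kernelAmp1AP, object@tauRise, object@tauDecay,
              object@firingRate))
  cat(sprintf("  neuropil: amp %.3f @ %.1f Hz, rTrue %.2f\n",
              object@neuropilAmp, object@neuropilRate, object@rTrue))
  cat(sprintf("  photons: %.0f/px/frame, gain %.2f, pedestal %.1f, seed %d\n",
              object@baselinePhotons, object@photonGain, object@pedestal,
              object@seed))
})

setMethod("show", "GroundTruthRecording", function(object) {
  d <- dim(object@movie)
  cat("GroundTruthRecording:", length(object@apTimes), "APs,",
      sprintf("movie %dx%dx%d @ %.1f Hz,", d[1], d[2], d[3],
              object@frameRate),
      sprintf("vm %d samples @ %.0f Hz\n", length(object@vm@samples),
              object@vm@rate))
  if (length(object@provenance))
    cat("  artifacts:",
        paste(vapply(object@provenance, `[[`, "", "kind"),
              collapse = ", "), "\n")
})

setMethod("show", "QCReport", function(object) {
  n_na <- sum(is.na(object@metrics))
  cat("QCReport: 35 metrics (", n_na, " not applicable), verdict: ",
      object@verdict, "\n", sep = "")
  if (object@verdict == "fail")
    cat("  out of range:",
        paste(names(which(!object@flags)), collapse = ", "), "\n")
})

setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve: %d points, AUC = %.4f\n",
              length(object@fpProb), object@auc))
})

setMethod("show", "TransientFit", function(object) {
  if (object@converged)
    cat(sprintf(
      "TransientFit: A = %.4f dF/F, tauRise = %.4f s, tauDecay = %.4f s (RSS %.3g)\n",
      object@amplitude, object@tauRise, object@tauDecay, object@rss))
  else cat("TransientFit: degenerate / non-converged\n")
})

setMethod("show", "InferredActivity", function(object) {
  cat(sprintf("InferredActivity [%s]: %d frames @ %.1f Hz, total mass %.2f\n",
              object@algorithm, length(object@values), object@rate,
              sum(object@values)))
})

setMethod("show", "DownsampleSet", function(object) {
  cat(sprintf(
    "DownsampleSet: %d phase variants (%dx space, %dx time), %.2f Hz, %d tiled traces\n",
    length(object@variants), object@spatialFactor, object@temporalFactor,
    object@frameRate, nrow(object@tiledTraces)))
})

setMethod("show", "ClusterQC", function(object) {
  cat(sprintf("ClusterQC: %d clusters (%d kept), passed = %s\n",
              nrow(object@medians), length(object@kept), object@passed))
})
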