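#' @include simulate.R
NULL

#' Inject a controlled artifact into a recording
#'
#' Returns a modified copy of a [GroundTruthRecording-class]; the original
#' is untouched and the artifact parameters are logged in the copy's
#' provenance. Supported kinds:
#' \describe{
#'   \item{`drift`}{adds a linear drift (`slope` mV/s) to the voltage
#'     trace.}
#'   \item{`bleach`}{rescales every frame so the spatial frame mean decays
#'     exponentially with time constant `tau` (default half the
#'     recording), i.e. monotone photobleaching.}
#'   \item{`waveform_change`}{re-renders the voltage trace with the AP
#'     width multiplied by `factor` (default 2) for APs in the second half
#'     of the recording.}
#'   \item{`ap_loss`}{re-renders the voltage trace with all APs after the
#'     midpoint removed (loss of spiking, e.g. seal breakdown); `apTimes`
#'     and the truth counts are updated accordingly.}
#' }
#'
#' @param rec a [GroundTruthRecording-class].
#' @param kind one of `"drift"`, `"bleach"`, `"waveform_change"`,
#'   `"ap_loss"`.
#' @param slope drift slope in mV/s (drift only).
#' @param tau bleaching time constant in s (bleach only).
#' @param factor AP width multiplier (waveform_change only).
#' @return The modified copy.
#' @export
injectArtifact <- function(rec, kind, slope = 0.5, tau = NULL, factor = 2) {
  stopifnot(is(rec, "GroundTruthRecording"))
  cfg <- rec@config
  dur <- cfg@durationS
  prov <- list(kind = kind)
  if (identical(kind, "drift")) {
    t <- (seq_along(rec@vm@samples) - 1L) / rec@vm@rate
    rec@vm@samples <- rec@vm@samples + slope * t
    prov$slope_mv_per_s <- slope
  } else if (identical(kind, "bleach")) {
    tau <- tau %||% (dur / 2)
    nF <- dim(rec@movie)[3]
    fm <- colMeans(matrix(rec@movie, ncol = nF))
    target <- fm[1] * exp(-((seq_len(nF) - 1L) / rec@frameRate) / tau)
    scale <- target / fm
    rec@movie <- sweep(rec@movie, 3, scale, `*`)
    prov$tau_s <- tau
  } else if (identical(kind, "waveform_change")) {
    fw <- ifelse(rec@apTimes > dur / 2, cfg@apFwhmMs * factor,
                 cfg@apFwhmMs)
    rec@vm <- renderVm(rec@apTimes, cfg, fwhmMs = fw)
    prov$factor <- factor
  } else if (identical(kind, "ap_loss")) {
    keep <- rec@apTimes <= dur / 2
    rec@apTimes <- rec@apTimes[keep]
    rec@vm <- renderVm(rec@apTimes, cfg)
    nF <- dim(rec@movie)[3]
    fr <- pmin(floor(rec@apTimes * rec@frameRate) + 1L, nF)
    rec@truth$frame_ap_counts <- tabulate(fr, nbins = nF)
    prov$cutoff_s <- dur / 2
  } else {
    stop("unknown artifact kind: ", kind)
  }
  rec@provenance <- c(rec@provenance, list(prov))
  validObject(rec)
  rec
}
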