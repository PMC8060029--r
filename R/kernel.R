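#' @include AllClasses.R
NULL

#' Sampled calcium-indicator impulse response
#'
#' Difference-of-exponentials transient
#' \eqn{\kappa(t) = A (e^{-t/\tau_d} - e^{-t/\tau_r})} for \eqn{t \ge 0},
#' with \eqn{A} chosen so the peak equals `amp` (the configured 1 AP
#' dF/F amplitude).
#'
#' @slot samples kernel values at `t = (1:n)/rate`.
#' @slot rate sampling rate (Hz).
#' @slot tauRise,tauDecay time constants (s).
#' @slot amp peak amplitude (dF/F per AP).
#' @export
setClass("Kernel", representation(
  samples = "numeric", rate = "numeric", tauRise = "numeric",
  tauDecay = "numeric", amp = "numeric"))

setValidity("Kernel", function(object) {
  if (object@tauRise >= object@tauDecay) return("tauRise must be < tauDecay")
  if (length(object@samples) / object@rate < 5 * object@tauDecay)
    return("kernel support must span at least 5 decay time constants")
  TRUE
})

## Peak-normalization constant: peak time and value of
## exp(-t/td) - exp(-t/tr).
.kernelPeak <- function(tauRise, tauDecay) {
  tPeak <- log(tauDecay / tauRise) * tauRise * tauDecay /
    (tauDecay - tauRise)
  list(t = tPeak, value = exp(-tPeak / tauDecay) - exp(-tPeak / tauRise))
}

## Continuous kernel, peak-normalized to `amp`; zero for t < 0.
.kernelEval <- function(t, tauRise, tauDecay, amp) {
  A <- amp / .kernelPeak(tauRise, tauDecay)$value
  ifelse(t >= 0, A * (exp(-t / tauDecay) - exp(-t / tauRise)), 0)
}

#' Build a sampled calcium kernel
#'
#' @param tauRise,tauDecay time constants in seconds (`tauRise < tauDecay`).
#' @param rate sampling rate (Hz).
#' @param amp peak amplitude in dF/F per AP (default 1).
#' @param nTaus support length in units of `tauDecay` (default 7,
#'   comfortably above the minimum of 5).
#' @return A [Kernel-class]. Samples are taken at `t = (1:n)/rate`, i.e.
#'   the response begins one sample after the AP.
#' @examples
#' k <- calciumKernel(0.02, 0.2, rate = 158)
#' max(k@samples)  # ~1 (peak-normalized)
#' @export
calciumKernel <- function(tauRise, tauDecay, rate, amp = 1, nTaus = 7) {
  stopifnot(tauRise > 0, tauDecay > tauRise, rate > 0, amp > 0)
  n <- max(2L, ceiling(nTaus * tauDecay * rate))
  t <- seq_len(n) / rate
  new("Kernel", samples = .kernelEval(t, tauRise, tauDecay, amp),
      rate = rate, tauRise = tauRise, tauDecay = tauDecay, amp = amp)
}

#' Kernel implied by a simulation configuration
#'
#' @param config a [SimConfig-class].
#' @param rate sampling rate; defaults to the config's frame rate.
#' @return A [Kernel-class] with the config's time constants and 1 AP
#'   amplitude.
#' @export
kernelFromConfig <- function(config, rate = config@frameRate) {
  calciumKernel(config@tauRise, config@tauDecay, rate,
                amp = config@kernelAmp1AP)
}
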