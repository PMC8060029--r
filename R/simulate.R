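#' @include AllClasses.R kernel.R
NULL

## Evaluate an expression with a temporary RNG seed, restoring the caller's
## RNG state afterwards. Keeps every generator reproducible from the config
## seed without clobbering the session RNG.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Construct a simulation configuration
#'
#' Returns a [SimConfig-class] with per-indicator defaults. GCaMP6s is slow
#' and large (`tauRise` 0.08 s, `tauDecay` 0.7 s, 1 AP peak 0.25 dF/F);
#' GCaMP6f fast and small (0.02 s, 0.2 s, 0.15 dF/F). All defaults can be
#' overridden by name.
#'
#' @param indicator `"6f"` (default) or `"6s"`.
#' @param seed integer RNG seed.
#' @param durationS recording duration (s).
#' @param ephysRate,frameRate sampling rates (Hz).
#' @param fovPx field of view (height, width) in pixels.
#' @param somaRadiusPx soma disk radius (pixels).
#' @param kernelAmp1AP,tauRise,tauDecay calcium kernel parameters.
#' @param perApGain supralinearity multipliers for 1-5 AP events
#'   (default linear `rep(1, 5)`).
#' @param firingRate,refractoryS spike-train parameters.
#' @param neuropilAmp,neuropilRate,rTrue neuropil contamination model.
#' @param baselinePhotons mean neuropil-baseline photons/pixel/frame.
#' @param somaBrightness soma/neuropil baseline brightness ratio.
#' @param pixelBrightnessCv lognormal cv of static per-pixel brightness
#'   heterogeneity (indicator expression and dwell-time variation); gives
#'   the per-column variance-mean photon fit its leverage.
#' @param photonGain,pedestal fluorescence-unit conversion.
#' @param apAmpMv,apFwhmMs,vmNoiseMv,driftMvPerS,vmBaselineMv voltage-trace
#'   parameters.
#' @param vmNoiseSlope fractional change of the voltage noise sd per
#'   second (models slow seal/noise nonstationarity; default 0).
#' @return A validated [SimConfig-class].
#' @examples
#' cfg <- simConfig("6f", seed = 1, durationS = 30)
#' cfg
#' @export
simConfig <- function(indicator = c("6f", "6s"), seed = 1L,
                      durationS = 60, ephysRate = 40000, frameRate = 158,
                      fovPx = c(32L, 32L), somaRadiusPx = 10,
                      kernelAmp1AP = NULL, tauRise = NULL, tauDecay = NULL,
                      perApGain = rep(1, 5),
                      firingRate = 1.5, refractoryS = 0.003,
                      neuropilAmp = 0.08, neuropilRate = 5, rTrue = 0.8,
                      baselinePhotons = 100, somaBrightness = 2,
                      pixelBrightnessCv = 0.15,
                      photonGain = 1, pedestal = 0,
                      apAmpMv = 1, apFwhmMs = 0.6, vmNoiseMv = 0.02,
                      driftMvPerS = 0, vmBaselineMv = 10,
                      vmNoiseSlope = 0) {
  indicator <- match.arg(indicator)
  defaults <- switch(indicator,
    "6s" = list(amp = 0.25, tr = 0.08, td = 0.7),
    "6f" = list(amp = 0.15, tr = 0.02, td = 0.2))
  cfg <- new("SimConfig",
    seed = as.integer(seed), durationS = durationS, ephysRate = ephysRate,
    frameRate = frameRate, fovPx = as.integer(fovPx),
    somaRadiusPx = somaRadiusPx, indicator = indicator,
    kernelAmp1AP = kernelAmp1AP %||% defaults$amp,
    tauRise = tauRise %||% defaults$tr,
    tauDecay = tauDecay %||% defaults$td,
    perApGain = perApGain, firingRate = firingRate,
    refractoryS = refractoryS, neuropilAmp = neuropilAmp,
    neuropilRate = neuropilRate, rTrue = rTrue,
    baselinePhotons = baselinePhotons, somaBrightness = somaBrightness,
    photonGain = photonGain, pedestal = pedestal, apAmpMv = apAmpMv,
    apFwhmMs = apFwhmMs, vmNoiseMv = vmNoiseMv,
    driftMvPerS = driftMvPerS, vmBaselineMv = vmBaselineMv)
  attr(cfg, "pixelBrightnessCv") <- pixelBrightnessCv
  attr(cfg, "vmNoiseSlope") <- vmNoiseSlope
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.pixelBrightnessCv <- function(config) {
  attr(config, "pixelBrightnessCv") %||% 0.15
}

#' Simulate a refractory Poisson AP train
#'
#' Renewal process with inter-spike intervals `refractoryS + Exp(rate)`
#' (a Poisson process with dead time); effective firing rate is
#' `rate / (1 + rate * refractoryS)`.
#'
#' @param config a [SimConfig-class]; uses `seed`, `durationS`,
#'   `firingRate`, `refractoryS`.
#' @return Sorted AP times in seconds (possibly empty).
#' @export
simulateAPTrain <- function(config) {
  stopifnot(config@durationS > 0)
  lambda <- config@firingRate
  tau <- config@refractoryS
  if (lambda * tau >= 1)
    stop("infeasible rate: firingRate * refractoryS must be < 1")
  if (lambda == 0) return(numeric(0))
  .withSeed(config@seed, {
    expected <- config@durationS * lambda / (1 + lambda * tau)
    times <- numeric(0)
    t_last <- 0
    repeat {
      n_draw <- max(32L, ceiling(1.5 * (expected - length(times))))
      isi <- tau + stats::rexp(n_draw, lambda)
      if (length(times)) isi[1] <- isi[1]  # continue from t_last
      newt <- t_last + cumsum(isi)
      times <- c(times, newt)
      t_last <- times[length(times)]
      if (t_last > config@durationS) break
    }
    ## first arrival has no preceding dead time
    times <- times - tau
    times[times < config@durationS & times >= 0]
  })
}

## Biphasic AP waveform added in place: positive Gaussian lobe followed by
## a smaller, broader negative lobe; normalized so the composite peak
## equals ampMv.
.apLobes <- function(u) {                    # u = t/sigma
  exp(-u^2 / 2) - 0.3 * exp(-(u - 2.5)^2 / 8)
}
.AP_PEAK <- max(.apLobes(seq(-1, 1, by = 1e-4)))

.addApWaveforms <- function(x, rate, apTimes, ampMv, fwhmMs) {
  if (!length(apTimes)) return(x)
  sigma <- (fwhmMs / 1000) / (2 * sqrt(2 * log(2)))
  if (length(fwhmMs) == 1L) sigma <- rep(sigma, length(apTimes))
  n <- length(x)
  amp <- ampMv / .AP_PEAK
  for (i in seq_along(apTimes)) {
    s <- sigma[i]
    half <- ceiling(8 * s * rate)
    c_idx <- round(apTimes[i] * rate) + 1L
    idx <- max(1L, c_idx - half):min(n, c_idx + half + ceiling(2.5 * s * rate))
    t_rel <- (idx - 1L) / rate - apTimes[i]
    x[idx] <- x[idx] + amp * .apLobes(t_rel / s)
  }
  x
}

#' Render the cell-attached voltage trace
#'
#' Constant offset plus Gaussian noise, optional linear drift, and one
#' stereotyped biphasic AP waveform per AP time.
#'
#' @param apTimes AP times in seconds.
#' @param config a [SimConfig-class].
#' @param fwhmMs optional per-AP waveform width override (recycled);
#'   defaults to `config@apFwhmMs`.
#' @return A [VoltageTrace-class] at `config@ephysRate`.
#' @export
renderVm <- function(apTimes, config, fwhmMs = NULL) {
  if (config@ephysRate < 10000)
    stop("ephysRate must be at least 10 kHz")
  if (config@apAmpMv <= 0) stop("invalid waveform: apAmpMv must be > 0")
  n <- round(config@durationS * config@ephysRate)
  t <- (seq_len(n) - 1L) / config@ephysRate
  noiseSlope <- attr(config, "vmNoiseSlope") %||% 0
  x <- .withSeed(config@seed + 1L, {
    base <- config@vmBaselineMv + config@driftMvPerS * t
    if (config@vmNoiseMv > 0) {
      sdv <- config@vmNoiseMv * pmax(1 + noiseSlope * t, 0.1)
      base + stats::rnorm(n, 0, sdv)
    } else base
  })
  fw <- fwhmMs %||% config@apFwhmMs
  if (length(fw) > 1L) fw <- rep_len(fw, length(apTimes))
  x <- .addApWaveforms(x, config@ephysRate, apTimes, config@apAmpMv, fw)
  new("VoltageTrace", samples = x, rate = config@ephysRate, t0 = 0)
}

## Soma dF/F at the frame centers: events are AP groups within 250 ms,
## each contributing perApGain[n] * n * kernel(t - t_first).
.somaDff <- function(apTimes, config, frameTimes) {
  dff <- numeric(length(frameTimes))
  ev <- groupApEvents(apTimes, window = 0.25)
  gains <- config@perApGain
  for (idx in ev) {
    n <- length(idx)
    g <- gains[min(n, length(gains))]
    tf <- apTimes[idx[1]]
    sel <- which(frameTimes > tf &
                   frameTimes <= tf + 8 * config@tauDecay)
    dff[sel] <- dff[sel] + g * n *
      .kernelEval(frameTimes[sel] - tf, config@tauRise, config@tauDecay,
                  config@kernelAmp1AP)
  }
  dff
}

## Independent neuropil transient train (plain Poisson arrivals), same
## kernel shape, peak neuropilAmp per event.
.neuropilDff <- function(config, frameTimes) {
  dff <- numeric(length(frameTimes))
  if (config@neuropilRate <= 0 || config@neuropilAmp == 0) return(dff)
  arr <- cumsum(stats::rexp(
    max(32L, ceiling(2 * config@neuropilRate * config@durationS)),
    config@neuropilRate))
  while (arr[length(arr)] < config@durationS)
    arr <- c(arr, arr[length(arr)] +
               cumsum(stats::rexp(32L, config@neuropilRate)))
  arr <- arr[arr < config@durationS]
  for (tf in arr) {
    sel <- which(frameTimes > tf & frameTimes <= tf + 8 * config@tauDecay)
    dff[sel] <- dff[sel] +
      .kernelEval(frameTimes[sel] - tf, config@tauRise, config@tauDecay,
                  config@neuropilAmp)
  }
  dff
}

## Circular soma disk and surrounding annulus, 1 px guard ring between.
.makeMasks <- function(config) {
  h <- config@fovPx[1]; w <- config@fovPx[2]
  if (config@somaRadiusPx + 3 > min(h, w) / 2)
    stop("field of view must contain the soma disk and surrounding neuropil")
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  d <- sqrt(outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, `+`))
  soma <- d <= config@somaRadiusPx
  np <- d > config@somaRadiusPx + 1 & d <= min(h, w) / 2 - 0.5
  list(soma = soma, neuropil = np)
}

#' Render the fluorescence movie and assemble the paired recording
#'
#' Builds the per-frame soma and neuropil dF/F signals, places them on
#' disjoint soma/neuropil pixel masks (soma pixels carry
#' `somaBrightness * baselinePhotons * (1 + soma dF/F)` plus the additive
#' `rTrue`-scaled neuropil fluorescence), draws per-pixel per-frame photon
#' counts from a Poisson law, and converts to recorded units via
#' `photonGain` and `pedestal`. Static per-pixel brightness heterogeneity
#' (lognormal, cv `pixelBrightnessCv`) models expression and dwell-time
#' variation.
#'
#' @param apTimes AP times (s).
#' @param config a [SimConfig-class].
#' @param vm optional pre-rendered [VoltageTrace-class]; rendered from
#'   `apTimes` when missing.
#' @return A [GroundTruthRecording-class] whose `truth` list holds the
#'   kernel, `r_true`, `photon_gain`, `pedestal`, per-frame true AP counts,
#'   and the noiseless soma/neuropil dF/F traces.
#' @export
renderMovie <- function(apTimes, config, vm = NULL) {
  masks <- .makeMasks(config)
  h <- config@fovPx[1]; w <- config@fovPx[2]
  nF <- floor(config@durationS * config@frameRate)
  frameTimes <- (seq_len(nF) - 0.5) / config@frameRate

  dffS <- .somaDff(apTimes, config, frameTimes)
  out <- .withSeed(config@seed + 2L, {
    dffN <- .neuropilDff(config, frameTimes)
    if (any(1 + dffN < 0) || any(1 + dffS < 0))
      stop("negative intensity: 1 + dF/F < 0")
    B <- config@baselinePhotons
    cv <- .pixelBrightnessCv(config)
    bright <- if (cv > 0)
      matrix(stats::rlnorm(h * w, -0.5 * log(1 + cv^2),
                           sqrt(log(1 + cv^2))), h, w)
    else matrix(1, h, w)
    ## per-frame mean photon count for the three pixel classes (unit
    ## brightness); soma carries additive rTrue-scaled neuropil signal
    muSoma <- B * (config@somaBrightness * (1 + dffS) +
                     config@rTrue * dffN)
    muNp <- B * (1 + dffN)
    muBg <- rep(B, nF)
    if (any(muSoma < 0)) stop("negative intensity: soma photon mean < 0")
    lam <- matrix(muBg, nrow = h * w, ncol = nF, byrow = TRUE)
    iS <- which(masks$soma); iN <- which(masks$neuropil)
    lam[iS, ] <- matrix(muSoma, nrow = length(iS), ncol = nF, byrow = TRUE)
    lam[iN, ] <- matrix(muNp, nrow = length(iN), ncol = nF, byrow = TRUE)
    lam <- lam * as.vector(bright)
    photons <- array(stats::rpois(length(lam), lam), dim = c(h, w, nF))
    list(photons = photons, dffN = dffN, bright = bright)
  })
  movie <- config@photonGain * out$photons + config@pedestal

  ## per-frame true AP counts; APs past the last full frame fold into it
  ## so the counts conserve the train length
  fr <- pmin(floor(apTimes * config@frameRate) + 1L, nF)
  counts <- tabulate(fr, nbins = nF)
  if (is.null(vm)) vm <- renderVm(apTimes, config)
  new("GroundTruthRecording",
      apTimes = apTimes, vm = vm, movie = movie,
      somaMask = masks$soma, neuropilMask = masks$neuropil,
      frameRate = config@frameRate,
      truth = list(kernel = kernelFromConfig(config),
                   r_true = config@rTrue,
                   photon_gain = config@photonGain,
                   pedestal = config@pedestal,
                   soma_brightness = config@somaBrightness,
                   frame_ap_counts = counts,
                   frame_times = frameTimes,
                   dff_soma = dffS, dff_neuropil = out$dffN,
                   pixel_brightness = out$bright),
      config = config, provenance = list())
}

#' Simulate a complete paired recording
#'
#' Convenience wrapper: AP train, voltage trace and movie from one config.
#' Identical configs (including seed) give bit-identical recordings.
#'
#' @param config a [SimConfig-class].
#' @return A [GroundTruthRecording-class].
#' @examples
#' rec <- simulateRecording(simConfig("6f", seed = 7, durationS = 5,
#'                                    fovPx = c(24L, 24L),
#'                                    somaRadiusPx = 7))
#' rec
#' @export
simulateRecording <- function(config) {
  ap <- simulateAPTrain(config)
  renderMovie(ap, config, vm = renderVm(ap, config))
}

#' Group AP times into events
#'
#' An event is a maximal greedy group: the earliest unassigned AP opens the
#' event and every AP within 250 ms (by default) of that first AP joins it.
#'
#' @param apTimes sorted AP times (s).
#' @param window grouping window (s), default 0.25.
#' @return List of integer index vectors into `apTimes`; every AP belongs
#'   to exactly one event.
#' @export
groupApEvents <- function(apTimes, window = 0.25) {
  stopifnot(!is.unsorted(apTimes))
  events <- list()
  i <- 1L
  n <- length(apTimes)
  while (i <= n) {
    j <- i
    while (j < n && apTimes[j + 1L] < apTimes[i] + window) j <- j + 1L
    events[[length(events) + 1L]] <- i:j
    i <- j + 1L
  }
  events
}
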