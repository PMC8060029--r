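#' @include AllClasses.R simulate.R
NULL

#' Write a recording to a plain-format directory
#'
#' Serializes a [GroundTruthRecording-class] as text plus TIFF: the movie
#' as a multi-page TIFF (rescaled to [0, 1]; scale and offset recorded),
#' the voltage trace and AP times as CSV, masks as CSV, and config plus
#' scalar truth entries as JSON.
#'
#' @param rec a [GroundTruthRecording-class].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @seealso [readRecording()]
#' @export
writeRecording <- function(rec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mv <- movieArray(rec)
  lo <- min(mv); hi <- max(mv)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(mv)[3]), function(i)
    (mv[, , i] - lo) / scale)
  tiff::writeTIFF(pages, file.path(dir, "movie.tif"),
                  bits.per.sample = 16L)
  utils::write.csv(data.frame(vm_mv = rec@vm@samples),
                   file.path(dir, "vm.csv"), row.names = FALSE)
  utils::write.csv(data.frame(ap_time_s = rec@apTimes),
                   file.path(dir, "ap_times.csv"), row.names = FALSE)
  utils::write.csv(data.frame(which(rec@somaMask, arr.ind = TRUE)),
                   file.path(dir, "soma_mask.csv"), row.names = FALSE)
  utils::write.csv(data.frame(which(rec@neuropilMask, arr.ind = TRUE)),
                   file.path(dir, "neuropil_mask.csv"), row.names = FALSE)
  cfg <- rec@config
  meta <- list(
    movie_scale = scale, movie_offset = lo,
    fov = dim(mv)[1:2], n_frames = dim(mv)[3],
    frame_rate = rec@frameRate, ephys_rate = rec@vm@rate,
    vm_t0 = rec@vm@t0,
    truth = list(r_true = rec@truth$r_true,
                 photon_gain = rec@truth$photon_gain,
                 pedestal = rec@truth$pedestal,
                 frame_ap_counts = rec@truth$frame_ap_counts),
    config = lapply(slotNames(cfg), function(s) slot(cfg, s)),
    provenance = rec@provenance)
  names(meta$config) <- slotNames(cfg)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a recording written by [writeRecording()]
#'
#' @param dir directory produced by [writeRecording()].
#' @return A [GroundTruthRecording-class] (movie quantized to the 16-bit
#'   TIFF resolution; truth restored from the JSON metadata).
#' @export
readRecording <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(file.path(dir, "movie.tif"), all = TRUE)
  mv <- array(0, dim = c(meta$fov[1], meta$fov[2], meta$n_frames))
  for (i in seq_len(meta$n_frames))
    mv[, , i] <- pages[[i]] * meta$movie_scale + meta$movie_offset
  mask <- function(f) {
    m <- matrix(FALSE, meta$fov[1], meta$fov[2])
    ix <- utils::read.csv(file.path(dir, f))
    m[as.matrix(ix)] <- TRUE
    m
  }
  cfgList <- meta$config
  cfg <- do.call(simConfig, c(
    list(indicator = cfgList$indicator, seed = cfgList$seed,
         durationS = cfgList$durationS, ephysRate = cfgList$ephysRate,
         frameRate = cfgList$frameRate, fovPx = cfgList$fovPx,
         somaRadiusPx = cfgList$somaRadiusPx,
         kernelAmp1AP = cfgList$kernelAmp1AP,
         tauRise = cfgList$tauRise, tauDecay = cfgList$tauDecay,
         perApGain = cfgList$perApGain, firingRate = cfgList$firingRate,
         refractoryS = cfgList$refractoryS,
         neuropilAmp = cfgList$neuropilAmp,
         neuropilRate = cfgList$neuropilRate, rTrue = cfgList$rTrue,
         baselinePhotons = cfgList$baselinePhotons,
         somaBrightness = cfgList$somaBrightness,
         photonGain = cfgList$photonGain, pedestal = cfgList$pedestal,
         apAmpMv = cfgList$apAmpMv, apFwhmMs = cfgList$apFwhmMs,
         vmNoiseMv = cfgList$vmNoiseMv,
         driftMvPerS = cfgList$driftMvPerS,
         vmBaselineMv = cfgList$vmBaselineMv)))
  vm <- new("VoltageTrace",
            samples = utils::read.csv(file.path(dir, "vm.csv"))$vm_mv,
            rate = meta$ephys_rate, t0 = meta$vm_t0)
  ap <- utils::read.csv(file.path(dir, "ap_times.csv"))$ap_time_s
  if (is.null(ap)) ap <- numeric(0)
  new("GroundTruthRecording",
      apTimes = as.numeric(ap), vm = vm, movie = mv,
      somaMask = mask("soma_mask.csv"),
      neuropilMask = mask("neuropil_mask.csv"),
      frameRate = meta$frame_rate,
      truth = list(r_true = meta$truth$r_true,
                   photon_gain = meta$truth$photon_gain,
                   pedestal = meta$truth$pedestal,
                   frame_ap_counts = meta$truth$frame_ap_counts),
      config = cfg, provenance = list())
}
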