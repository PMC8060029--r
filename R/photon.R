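#' @include AllClasses.R
NULL

#' Calibrate photon gain from the pixelwise variance-mean relation
#'
#' Under shot-noise-limited imaging the temporal variance of each pixel is
#' linear in its temporal mean: `var(F) = gain * (mean(F) - pedestal)`.
#' The fit is performed column-by-column along the resonant scanning axis
#' (pixel dwell time varies along it), regressing pixel variance on pixel
#' mean across the pixels of each column.
#'
#' @param movie array `height x width x frames` (recorded units), at least
#'   100 frames.
#' @param resonantAxis `"width"` (default; fit per column) or `"height"`.
#' @return A [PhotonCalibration-class] with per-column `slope` (gain) and
#'   `offset` (intercept; the pedestal is `-offset/slope`).
#' @export
fitPhotonGain <- function(movie, resonantAxis = c("width", "height")) {
  resonantAxis <- match.arg(resonantAxis)
  stopifnot(is.array(movie), length(dim(movie)) == 3L)
  d <- dim(movie)
  if (d[3] < 100L) stop("at least 100 frames are required")
  nCol <- if (resonantAxis == "width") d[2] else d[1]
  if ((if (resonantAxis == "width") d[1] else d[2]) < 2L)
    stop("fewer than 2 pixels per resonant-axis column")
  slope <- offset <- numeric(nCol)
  for (j in seq_len(nCol)) {
    X <- if (resonantAxis == "width") movie[, j, ] else movie[j, , ]
    mu <- rowMeans(X)
    va <- rowSums((X - mu)^2) / (d[3] - 1L)
    reg <- .linreg(mu, va)
    slope[j] <- reg[["slope"]]; offset[j] <- reg[["intercept"]]
  }
  new("PhotonCalibration", slope = slope, offset = offset,
      resonantAxis = resonantAxis)
}

#' Convert recorded fluorescence to photon counts
#'
#' `photons = (F - (-offset/slope)) / slope`, applied per resonant-axis
#' column for a movie, or with the mean calibration for a plain trace.
#'
#' @param x movie array, [FluoTrace-class], or numeric vector.
#' @param calib a [PhotonCalibration-class].
#' @return Object of the same shape in photon units.
#' @export
setGeneric("toPhotons", function(x, calib) standardGeneric("toPhotons"))

#' @rdname toPhotons
#' @export
setMethod("toPhotons", "array", function(x, calib) {
  d <- dim(x)
  ped <- -calib@offset / calib@slope
  if (calib@resonantAxis == "width") {
    for (j in seq_len(d[2]))
      x[, j, ] <- (x[, j, ] - ped[j]) / calib@slope[j]
  } else {
    for (i in seq_len(d[1]))
      x[i, , ] <- (x[i, , ] - ped[i]) / calib@slope[i]
  }
  x
})

#' @rdname toPhotons
#' @export
setMethod("toPhotons", "numeric", function(x, calib) {
  slope <- mean(calib@slope)
  ped <- mean(-calib@offset / calib@slope)
  (x - ped) / slope
})

#' @rdname toPhotons
#' @export
setMethod("toPhotons", "FluoTrace", function(x, calib) {
  x@values <- toPhotons(x@values, calib)
  x
})
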