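#' @include AllClasses.R imaging.R
NULL

#' Build a detection template from response segments
#'
#' The template is the mean across segments of one event class; its
#' zero-mean, unit-norm version is the projection vector.
#'
#' @param segments matrix with one response segment per row (equal
#'   lengths), or a list of equal-length numeric vectors.
#' @return A [Template-class].
#' @export
buildTemplate <- function(segments) {
  if (is.list(segments)) segments <- do.call(rbind, segments)
  if (!is.matrix(segments)) segments <- matrix(segments, nrow = 1L)
  if (!nrow(segments)) stop("at least one segment is required")
  tm <- colMeans(segments)
  u <- tm - mean(tm)
  nrm <- sqrt(sum(u^2))
  if (nrm < 1e-12) stop("zero-variance template")
  new("Template", meanResponse = tm, unitVector = u / nrm)
}

#' Sample AP-free noise segments
#'
#' Non-overlapping windows of the template length in which every sample is
#' clear of any AP by the indicator's isolation margins: a window is
#' rejected when it intersects `[t_AP - after, t_AP + before + T]` for any
#' AP (before/after margins: 1.0/0.5 s for GCaMP6s, 0.3/0.3 s for
#' GCaMP6f; `T` is the window duration). These windows are the 0 AP
#' "events" from which false-positive probabilities are computed.
#'
#' @param trace a [FluoTrace-class].
#' @param apTimes AP times (s).
#' @param templateLen window length in frames.
#' @param indicator `"6s"` or `"6f"`.
#' @return Matrix of noise segments (one per row) with the start frame
#'   indices in attribute `"starts"`.
#' @export
sampleNoiseSegments <- function(trace, apTimes, templateLen, indicator) {
  stopifnot(is(trace, "FluoTrace"))
  n <- length(trace@values)
  if (templateLen > n) stop("template longer than the trace")
  marg <- .isolationMargins(indicator)
  rate <- trace@rate
  Tsec <- templateLen / rate
  exclLo <- apTimes - marg["after"]
  exclHi <- apTimes + marg["before"] + Tsec
  starts <- integer(0)
  i <- 1L
  while (i + templateLen - 1L <= n) {
    s <- trace@t0 + (i - 1L) / rate
    bad <- any(s < exclHi & s + Tsec > exclLo)
    if (!bad) {
      starts <- c(starts, i)
      i <- i + templateLen
    } else i <- i + 1L
  }
  if (!length(starts)) stop("zero eligible noise windows")
  segs <- t(vapply(starts, function(s)
    trace@values[s:(s + templateLen - 1L)], numeric(templateLen)))
  attr(segs, "starts") <- starts
  segs
}

#' ROC curve from template projections
#'
#' Response and noise segments are projected on the template's zero-mean
#' unit vector (scalars `r_i` and `n_i`). The detection threshold sweeps
#' the percentiles of `n_i`: at percentile `x` the false-positive
#' probability is `1 - x/100` and the detection probability the fraction
#' of `r_i` above the threshold. The area under the curve is computed by
#' the trapezoidal rule.
#'
#' @param respSegs matrix of response segments (rows).
#' @param noiseSegs matrix of at least 2 noise segments (rows).
#' @param template a [Template-class] of matching length.
#' @param xStep percentile sweep granularity (default 0.1).
#' @return A [RocCurve-class] (fp ascending).
#' @export
rocFromProjection <- function(respSegs, noiseSegs, template,
                              xStep = 0.1) {
  if (is.list(respSegs)) respSegs <- do.call(rbind, respSegs)
  if (!nrow(respSegs)) stop("empty response set")
  if (nrow(noiseSegs) < 2L) stop("at least 2 noise segments are required")
  u <- template@unitVector
  stopifnot(ncol(respSegs) == length(u), ncol(noiseSegs) == length(u))
  ri <- as.numeric(respSegs %*% u)
  ni <- as.numeric(noiseSegs %*% u)
  x <- seq(0, 100, by = xStep)
  thr <- stats::quantile(ni, x / 100, names = FALSE, type = 7)
  thr[1] <- -Inf                       # x = 0: accept everything
  rs <- sort(ri)
  tp <- (length(rs) - findInterval(thr, rs)) / length(rs)  # P(r_i > thr)
  fp <- 1 - x / 100
  ord <- order(fp)
  fp <- fp[ord]; tp <- tp[ord]; thr <- thr[ord]
  aucv <- sum(diff(fp) * (tp[-1] + tp[-length(tp)]) / 2)
  new("RocCurve", fpProb = fp, tpProb = tp, thresholds = thr,
      auc = min(max(aucv, 0), 1))
}

#' Detection probability at a fixed false-positive rate
#'
#' Returns the true-positive probability at the largest tabulated
#' false-positive probability not exceeding the requested one
#' (conservative).
#'
#' @param roc a [RocCurve-class].
#' @param fp requested false-positive probability in (0, 1].
#' @return Detection probability in [0, 1].
#' @export
detectionProbability <- function(roc, fp = 0.01) {
  if (fp <= 0 || fp > 1) stop("fp must lie in (0, 1]")
  idx <- which(roc@fpProb <= fp + 1e-9)
  if (!length(idx)) return(roc@tpProb[1])
  roc@tpProb[max(idx)]
}

## dF/F segments of one event class plus matched noise segments for a
## given neuropil-subtracted trace; shared by optimizeR and the
## higher-level detection wrappers
.classSegments <- function(trace, apTimes, indicator, nApsClass = 1L,
                           preS = 0.1) {
  events <- findIsolatedEvents(apTimes, indicator)
  ed <- computeEventDff(trace, events, indicator, preS = preS)
  cls <- ed[ed$n_aps == nApsClass, , drop = FALSE]
  if (!nrow(cls)) return(NULL)
  segs <- do.call(rbind, cls$dff)
  f0g <- attr(ed, "f0_global")[as.character(nApsClass)]
  dffFull <- new("FluoTrace",
                 values = (trace@values - f0g) / f0g,
                 rate = trace@rate, t0 = trace@t0)
  noise <- sampleNoiseSegments(dffFull, apTimes, ncol(segs), indicator)
  list(events = ed, resp = segs, noise = noise, f0_local = ed$f0_local)
}

#' Ground-truth-optimized detection probability for one trace
#'
#' Convenience wrapper: isolated events of the requested AP class, their
#' dF/F segments, the mean-response template, matched noise windows, the
#' projection ROC, and the detection probability at the requested
#' false-positive rate.
#'
#' @param trace neuropil-subtracted [FluoTrace-class].
#' @param apTimes ground-truth AP times (s).
#' @param indicator `"6s"` or `"6f"`.
#' @param nApsClass event class (number of APs), default 1.
#' @param fp false-positive probability, default 0.01.
#' @return List with `roc`, `detection`, `template`, `nEvents`, `nNoise`;
#'   `NULL` when the trace has no events of the class.
#' @export
detectEvents <- function(trace, apTimes, indicator, nApsClass = 1L,
                         fp = 0.01) {
  cs <- .classSegments(trace, apTimes, indicator, nApsClass)
  if (is.null(cs)) return(NULL)
  tmpl <- buildTemplate(cs$resp)
  roc <- rocFromProjection(cs$resp, cs$noise, tmpl)
  list(roc = roc, detection = detectionProbability(roc, fp),
       template = tmpl, nEvents = nrow(cs$resp), nNoise = nrow(cs$noise))
}

#' Optimize the neuropil coefficient by ROC area
#'
#' For each `r` on the grid the neuropil-scaled trace is subtracted, the
#' 1 AP template rebuilt, and the projection ROC computed; `r` values for
#' which any event's `F0_local` (or the class `F0_global`) is
#' non-positive are flagged as over-subtracted and excluded. The optimum
#' maximizes the area under the ROC curve (smallest `r` on ties).
#'
#' @param cell,neuropil measured soma and neuropil [FluoTrace-class]
#'   objects.
#' @param apTimes ground-truth AP times (s).
#' @param rGrid ascending grid of candidate `r` (default 0 to 1.2 by
#'   0.05).
#' @param indicator `"6s"` or `"6f"`.
#' @param nApsClass event class used for the templates (default 1).
#' @return List with `rOpt`, `curve` (data.frame `r`, `auc`, `flagged`)
#'   and `best` (the winning [detectEvents()] result).
#' @export
optimizeR <- function(cell, neuropil, apTimes, rGrid = seq(0, 1.2, 0.05),
                      indicator = "6f", nApsClass = 1L) {
  if (!length(rGrid) || is.unsorted(rGrid))
    stop("rGrid must be nonempty and ascending")
  aucs <- rep(NA_real_, length(rGrid))
  flagged <- logical(length(rGrid))
  results <- vector("list", length(rGrid))
  for (i in seq_along(rGrid)) {
    ft <- new("FluoTrace",
              values = cell@values - rGrid[i] * neuropil@values,
              rate = cell@rate, t0 = cell@t0)
    cs <- tryCatch(
      .classSegments(ft, apTimes, indicator, nApsClass),
      spikefluor_negative_f0 = function(e) "neg_f0")
    if (identical(cs, "neg_f0") ||
        (!is.null(cs) && any(cs$f0_local <= 0))) {
      flagged[i] <- TRUE
      next
    }
    if (is.null(cs)) next
    tmpl <- buildTemplate(cs$resp)
    roc <- rocFromProjection(cs$resp, cs$noise, tmpl)
    aucs[i] <- auc(roc)
    results[[i]] <- list(roc = roc, template = tmpl)
  }
  ok <- which(!flagged & !is.na(aucs))
  if (!length(ok)) stop("all r values flagged or without events")
  best <- ok[which.max(aucs[ok])]      # first max = smallest r on ties
  list(rOpt = rGrid[best],
       curve = data.frame(r = rGrid, auc = aucs, flagged = flagged),
       best = results[[best]])
}
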