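#' @include AllClasses.R detection.R
NULL

## Block mean of a movie with given factors and phase offsets; trailing
## partial blocks are dropped.
.blockMean <- function(movie, sf, tf, sp, tp) {
  d <- dim(movie)
  Hb <- (d[1] - sp) %/% sf; Wb <- (d[2] - sp) %/% sf
  Tb <- (d[3] - tp) %/% tf
  if (Hb < 1L || Wb < 1L || Tb < 1L)
    stop("movie smaller than one block")
  sub <- movie[(sp + 1L):(sp + Hb * sf), (sp + 1L):(sp + Wb * sf),
               (tp + 1L):(tp + Tb * tf), drop = FALSE]
  a <- array(sub, dim = c(sf, Hb, sf, Wb, tf, Tb))
  a <- aperm(a, c(1L, 3L, 5L, 2L, 4L, 6L))
  array(colMeans(matrix(a, nrow = sf * sf * tf)), dim = c(Hb, Wb, Tb))
}

#' Block-downsample a movie over all phase variants
#'
#' Sub-samples by `sf` in space and `tf` in time (defaults 4 and 5,
#' turning ~158 Hz single-soma movies into the ~30 Hz, coarse-pixel
#' regime of population imaging). All `sf * tf` phase combinations
#' (starting with the 1st..`sf`th pixel and 1st..`tf`th frame) are
#' computed in parallel; each variant is the block mean over
#' `sf x sf` pixels and `tf` frames from its offset, with trailing
#' partial blocks dropped.
#'
#' @param movie array `height x width x frames`, or a
#'   [GroundTruthRecording-class].
#' @param sf,tf spatial and temporal factors.
#' @param rate input frame rate (Hz; taken from the recording when one is
#'   given).
#' @return A [DownsampleSet-class] (tiled traces are filled in by
#'   [extractTiledTraces()]).
#' @export
downsampleMovie <- function(movie, sf = 4L, tf = 5L, rate = NULL) {
  if (is(movie, "GroundTruthRecording")) {
    rate <- rate %||% frameRate(movie)
    movie <- movieArray(movie)
  }
  stopifnot(is.array(movie), length(dim(movie)) == 3L)
  if (any(dim(movie) < c(sf, sf, tf)))
    stop("movie smaller than one block")
  phases <- expand.grid(spatial = 0:(sf - 1L), temporal = 0:(tf - 1L))
  variants <- lapply(seq_len(nrow(phases)), function(i)
    .blockMean(movie, sf, tf, phases$spatial[i], phases$temporal[i]))
  new("DownsampleSet", variants = variants, phases = phases,
      frameRate = (rate %||% NA_real_) / tf,
      spatialFactor = as.integer(sf), temporalFactor = as.integer(tf),
      tiledTraces = matrix(numeric(0), 0L, 0L))
}

#' Extract the tiled family of downsampled ROI traces
#'
#' For each phase variant the soma ROI is the set of downsampled pixels
#' covered at least half by the original soma mask, and the variant trace
#' is the per-frame mean over that ROI. Each variant is replicated into
#' its `sf * tf` internally identical tiled blocks, giving
#' `(sf*tf)^2` (400 for 4x5) almost identical traces, truncated to the
#' shortest variant. The per-timepoint median across traces is the
#' consensus trace (attribute `"consensus"`).
#'
#' @param ds a [DownsampleSet-class] with all variants present.
#' @param somaMask original-resolution logical soma mask.
#' @return The [DownsampleSet-class] with `tiledTraces` filled (rows =
#'   traces); consensus in `attr(tiledTraces(ds), "consensus")`.
#' @export
extractTiledTraces <- function(ds, somaMask) {
  stopifnot(is(ds, "DownsampleSet"))
  sf <- ds@spatialFactor; tf <- ds@temporalFactor
  if (length(ds@variants) != sf * tf)
    stop("all phase variants are required")
  variantTraces <- lapply(seq_along(ds@variants), function(i) {
    sp <- ds@phases$spatial[i]
    v <- ds@variants[[i]]
    mm <- .blockMean(array(somaMask + 0, dim = c(dim(somaMask), 1L)),
                     sf, 1L, sp, 0L)[, , 1L]
    roi <- mm >= 0.5
    if (!any(roi)) stop("soma vanished after downsampling")
    flat <- matrix(v, ncol = dim(v)[3])
    idx <- which(roi)
    if (length(idx) == 1L) flat[idx, ] else colMeans(flat[idx, ])
  })
  L <- min(lengths(variantTraces))
  tiled <- do.call(rbind, lapply(variantTraces, function(tr)
    matrix(rep(tr[seq_len(L)], each = sf * tf), nrow = sf * tf,
           byrow = FALSE)))
  attr(tiled, "consensus") <- apply(tiled, 2L, stats::median)
  ds@tiledTraces <- tiled
  validObject(ds)
  ds
}

## Plain DBSCAN on a precomputed distance matrix (1 - Pearson
## correlation); labels 0 = noise point.
.dbscan <- function(D, eps, minPts) {
  n <- nrow(D)
  labels <- integer(n)
  visited <- logical(n)
  cluster <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    nb <- which(D[i, ] <= eps)
    if (length(nb) < minPts) next    # noise (may be claimed later)
    cluster <- cluster + 1L
    labels[i] <- cluster
    seeds <- nb
    queued <- logical(n)
    queued[seeds] <- TRUE
    k <- 1L
    while (k <= length(seeds)) {     # each point enters the set once
      j <- seeds[k]; k <- k + 1L
      if (labels[j] == 0L) labels[j] <- cluster
      if (!visited[j]) {
        visited[j] <- TRUE
        nbj <- which(D[j, ] <= eps)
        if (length(nbj) >= minPts) {
          add <- nbj[!queued[nbj]]
          queued[add] <- TRUE
          seeds <- c(seeds, add)
        }
      }
    }
  }
  labels
}

#' Cluster tiled traces and reject noise-like clusters
#'
#' Traces are clustered with DBSCAN on the `1 - Pearson` correlation
#' distance (`eps = 0.2`, `minPts = 5`: phase-variant traces of one
#' neuron correlate far above 0.8). Each cluster's per-timepoint median
#' is compared against white noise of the same mean and standard
#' deviation (two-sample Kolmogorov-Smirnov test) and rejected as an
#' artifact when not significantly different (p >= 0.05).
#'
#' @param traces matrix, one trace per row (at least 2), e.g.
#'   [tiledTraces()].
#' @param eps,minPts DBSCAN parameters.
#' @param seed seed for the generated white-noise comparison samples.
#' @return A [ClusterQC-class]; an empty `kept` set signals a failed
#'   recording downstream.
#' @export
clusterAndTest <- function(traces, eps = 0.2, minPts = 5L, seed = 1L) {
  stopifnot(is.matrix(traces), nrow(traces) >= 2L)
  cm <- suppressWarnings(stats::cor(t(traces)))
  cm[!is.finite(cm)] <- 0
  labels <- .dbscan(1 - cm, eps, minPts)
  ncl <- max(labels)
  if (ncl == 0L)
    return(new("ClusterQC", labels = labels,
               medians = matrix(numeric(0), 0L, ncol(traces)),
               ksP = numeric(0), kept = integer(0),
               selectedTrace = numeric(0), passed = NA))
  medians <- t(vapply(seq_len(ncl), function(k)
    apply(traces[labels == k, , drop = FALSE], 2L, stats::median),
    numeric(ncol(traces))))
  ksP <- .withSeed(seed, vapply(seq_len(ncl), function(k) {
    x <- medians[k, ]
    wn <- stats::rnorm(length(x), mean(x), stats::sd(x))
    suppressWarnings(stats::ks.test(x, wn)$p.value)
  }, numeric(1)))
  new("ClusterQC", labels = labels, medians = medians, ksP = ksP,
      kept = which(ksP < 0.05), selectedTrace = numeric(0), passed = NA)
}

#' Select the cluster combination best matched to the AP train
#'
#' Candidate traces are the sums over every non-empty subset of the (up
#' to) three largest kept clusters' medians. Each candidate is correlated
#' (Pearson) with the AP-count-per-frame vector box-car smoothed over 3
#' frames; the best candidate is selected. Significance is calibrated
#' against 1000 rate-matched random Poisson trains: for each null train
#' the maximum correlation over all candidates is taken (the correct null
#' for a selected maximum), and the recording passes when the best
#' observed correlation exceeds the null's 99.5th percentile.
#'
#' @param cqc a [ClusterQC-class] with at least one kept cluster.
#' @param apCounts true AP counts per downsampled frame.
#' @param nNull number of null Poisson trains (default 1000).
#' @param smoothFrames box-car width for the AP-count target (default 3).
#' @param seed seed for the null trains.
#' @return The [ClusterQC-class] with `selectedTrace` and `passed`
#'   filled, plus attributes `"cor"` and `"nullQuantile"`.
#' @export
selectTrace <- function(cqc, apCounts, nNull = 1000L, smoothFrames = 3L,
                        seed = 1L) {
  stopifnot(is(cqc, "ClusterQC"))
  if (!length(cqc@kept)) stop("no kept clusters: recording failed")
  sizes <- tabulate(cqc@labels)[cqc@kept]
  top <- cqc@kept[order(sizes, decreasing = TRUE)]
  top <- top[seq_len(min(3L, length(top)))]
  subsets <- unlist(lapply(seq_along(top), function(k)
    utils::combn(top, k, simplify = FALSE)), recursive = FALSE)
  L <- ncol(cqc@medians)
  cand <- t(vapply(subsets, function(s)
    colSums(cqc@medians[s, , drop = FALSE]), numeric(L)))
  target <- as.numeric(stats::filter(apCounts[seq_len(L)],
                                     rep(1, smoothFrames), sides = 2L))
  ok <- !is.na(target)
  cors <- suppressWarnings(apply(cand[, ok, drop = FALSE], 1L,
                                 stats::cor, y = target[ok]))
  cors[!is.finite(cors)] <- -Inf
  best <- which.max(cors)
  lambda <- sum(apCounts) / length(apCounts)
  nullMax <- .withSeed(seed, {
    trains <- matrix(stats::rpois(L * nNull, lambda), nrow = L)
    sm <- stats::filter(trains, rep(1, smoothFrames), sides = 2L)
    okb <- !is.na(sm[, 1])
    cs <- suppressWarnings(stats::cor(t(cand[, okb, drop = FALSE]),
                                      sm[okb, , drop = FALSE]))
    cs[!is.finite(cs)] <- -Inf
    apply(cs, 2L, max)
  })
  q995 <- stats::quantile(nullMax, 0.995, names = FALSE)
  cqc@selectedTrace <- cand[best, ]
  cqc@passed <- is.finite(cors[best]) && cors[best] > q995
  attr(cqc@selectedTrace, "cor") <- cors[best]
  attr(cqc@selectedTrace, "nullQuantile") <- q995
  cqc
}

#' Robust standard deviation of a fluorescence trace
#'
#' Median-based noise estimate with outlier removal: scaled first
#' differences (`diff(x)/sqrt(2)`, removing slow signal), an initial
#' `1.4826 * MAD` scale, exclusion of differences more than 4 initial
#' scales from their median (transients, glitches), and the final
#' `1.4826 * MAD` of the kept differences. Consistent for the Gaussian
#' standard deviation and scale-equivariant.
#'
#' @param x numeric trace, at least 10 samples.
#' @return Noise scale in the units of `x` (0 for a constant trace).
#' @export
robustStd <- function(x) {
  if (length(x) < 10L) stop("at least 10 samples are required")
  d <- diff(x) / sqrt(2)
  med <- stats::median(d)
  r0 <- 1.4826 * stats::median(abs(d - med))
  if (r0 == 0) return(0)
  keep <- d[abs(d - med) <= 4 * r0]
  1.4826 * stats::median(abs(keep - stats::median(keep)))
}
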