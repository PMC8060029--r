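#' @include AllClasses.R simulate.R
NULL

.isolationMargins <- function(indicator) {
  switch(indicator,
         "6s" = c(before = 1.0, after = 0.5),
         "6f" = c(before = 0.3, after = 0.3),
         stop("unknown indicator: ", indicator))
}

## time -> 1-based frame index, half-open window convention
.timeToFrame <- function(t, rate, t0 = 0) floor((t - t0) * rate) + 1L

#' Extract soma and neuropil fluorescence traces
#'
#' Per-frame mean over the mask pixels.
#'
#' @param movie array `height x width x frames`, or a
#'   [GroundTruthRecording-class] (masks and frame rate then come from the
#'   recording).
#' @param somaMask,neuropilMask disjoint nonempty logical matrices.
#' @param rate frame rate (Hz).
#' @param t0 time of the first frame center (s).
#' @return List with `cell` and `neuropil`, both [FluoTrace-class].
#' @export
extractTraces <- function(movie, somaMask = NULL, neuropilMask = NULL,
                          rate = NULL, t0 = NULL) {
  if (is(movie, "GroundTruthRecording")) {
    rec <- movie
    somaMask <- somaMask %||% somaMask(rec)
    neuropilMask <- neuropilMask %||% neuropilMask(rec)
    rate <- rate %||% frameRate(rec)
    t0 <- t0 %||% (0.5 / frameRate(rec))
    movie <- movieArray(rec)
  }
  t0 <- t0 %||% 0
  stopifnot(is.array(movie), length(dim(movie)) == 3L)
  if (!any(somaMask) || !any(neuropilMask)) stop("empty mask")
  if (any(somaMask & neuropilMask)) stop("masks must be disjoint")
  flat <- matrix(movie, ncol = dim(movie)[3])
  mk <- function(mask) {
    idx <- which(mask)
    v <- if (length(idx) == 1L) flat[idx, ] else colMeans(flat[idx, ])
    new("FluoTrace", values = v, rate = rate, t0 = t0)
  }
  list(cell = mk(somaMask), neuropil = mk(neuropilMask))
}

#' Subtract scaled neuropil fluorescence
#'
#' `F_true(t) = F_cell(t) - r * F_neuropil(t)`. When the requested `r`
#' leaves a non-positive baseline estimate (lowest decile of the
#' subtracted trace), `r` steps down through the fallback ladder
#' `{0.8, 0.7, 0.6, 0.5}`; if the baseline is still non-positive at the
#' last value the recording is flagged.
#'
#' @param cell,neuropil [FluoTrace-class] objects of equal length (or
#'   plain numeric vectors).
#' @param r requested contamination coefficient, `>= 0`.
#' @param fallback descending ladder tried when `r` over-subtracts.
#' @return List with `trace` ([FluoTrace-class] or numeric, matching the
#'   input), `rUsed`, and logical `flagged`.
#' @export
subtractNeuropil <- function(cell, neuropil, r = 0.8,
                             fallback = c(0.8, 0.7, 0.6, 0.5)) {
  if (r < 0) stop("r must be >= 0")
  fc <- if (is(cell, "FluoTrace")) cell@values else cell
  fn <- if (is(neuropil, "FluoTrace")) neuropil@values else neuropil
  if (length(fc) != length(fn)) stop("traces must have equal length")
  ladder <- c(r, fallback[fallback < r])
  flagged <- FALSE
  for (ri in ladder) {
    ft <- fc - ri * fn
    if (stats::quantile(ft, 0.1) > 0) break
  }
  if (stats::quantile(ft, 0.1) <= 0) flagged <- TRUE
  out <- if (is(cell, "FluoTrace"))
    new("FluoTrace", values = ft, rate = cell@rate, t0 = cell@t0)
  else ft
  list(trace = out, rUsed = ri, flagged = flagged)
}

#' Find isolated AP events
#'
#' APs are grouped into events (all APs within 250 ms of the event's first
#' AP). An event is isolated when the gap from the previous AP to the
#' event's first AP is at least the pre-margin (1.0 s for GCaMP6s, 0.3 s
#' for GCaMP6f) and the gap from the event's last AP to the next AP is at
#' least the post-margin (0.5 s for 6s, 0.3 s for 6f). Events of more than
#' 5 APs are excluded.
#'
#' @param apTimes sorted AP times (s).
#' @param indicator `"6s"` or `"6f"`.
#' @return data.frame with `t_first`, `t_last`, `n_aps` and a list column
#'   `ap_times`, one row per isolated event (possibly zero rows).
#' @export
findIsolatedEvents <- function(apTimes, indicator) {
  marg <- .isolationMargins(indicator)
  ev <- groupApEvents(apTimes, window = 0.25)
  keep <- list()
  for (idx in ev) {
    tf <- apTimes[idx[1]]; tl <- apTimes[idx[length(idx)]]
    prevOk <- idx[1] == 1L ||
      tf - apTimes[idx[1] - 1L] >= marg["before"]
    nextOk <- idx[length(idx)] == length(apTimes) ||
      apTimes[idx[length(idx)] + 1L] - tl >= marg["after"]
    if (prevOk && nextOk && length(idx) <= 5L)
      keep[[length(keep) + 1L]] <-
        list(t_first = tf, t_last = tl, n_aps = length(idx),
             ap_times = apTimes[idx])
  }
  data.frame(
    t_first = vapply(keep, `[[`, numeric(1), "t_first"),
    t_last = vapply(keep, `[[`, numeric(1), "t_last"),
    n_aps = vapply(keep, function(k) as.integer(k$n_aps), integer(1)),
    ap_times = I(lapply(keep, `[[`, "ap_times")))
}

#' Compute event-aligned dF/F segments and peak amplitudes
#'
#' For each isolated event, `F0_local` is the mean fluorescence over the
#' 100 ms before the first AP, and `F0_global` the minimum `F0_local`
#' across the neuron's events of the same AP-count class;
#' `dF/F = (F - F0_local) / F0_global`. Segments run from 100 ms before
#' the event (`t = 0` at the frame at or just before the first AP) to the
#' indicator's post-window (0.5 s for 6s, 0.3 s for 6f). Peak dF/F is the
#' mean over a 100 ms window centered on the maximum within the
#' post-window.
#'
#' @param trace the neuropil-subtracted [FluoTrace-class].
#' @param events data.frame from [findIsolatedEvents()].
#' @param indicator `"6s"` or `"6f"`.
#' @param preS pre-event baseline window (s), default 0.1.
#' @return The events data.frame with added columns `f0_local`,
#'   `peak_dff`, list column `dff` (aligned segment) and `seg_start`
#'   (first frame index); `f0_global` per class is attached as an
#'   attribute. Events without full pre/post history are dropped.
#' @export
computeEventDff <- function(trace, events, indicator, preS = 0.1) {
  stopifnot(is(trace, "FluoTrace"))
  rate <- trace@rate
  v <- trace@values
  n <- length(v)
  marg <- .isolationMargins(indicator)
  postS <- marg["after"]
  nPre <- round(preS * rate)
  nPost <- round(postS * rate)

  s0 <- .timeToFrame(events$t_first, rate, trace@t0)
  inb <- s0 - nPre >= 1L & s0 + nPost - 1L <= n
  events <- events[inb, , drop = FALSE]
  s0 <- s0[inb]
  if (!nrow(events)) {
    events$f0_local <- numeric(0); events$peak_dff <- numeric(0)
    attr(events, "f0_global") <- numeric(0)
    return(events)
  }
  f0l <- vapply(seq_len(nrow(events)), function(i)
    mean(v[(s0[i] - nPre):(s0[i] - 1L)]), numeric(1))
  f0gA <- tapply(f0l, events$n_aps, min)
  f0g <- stats::setNames(as.numeric(f0gA), dimnames(f0gA)[[1]])
  if (any(f0g <= 0))
    stop(errorCondition("non-positive F0_global; lower the neuropil r",
                        class = "spikefluor_negative_f0"))
  segs <- vector("list", nrow(events))
  peaks <- numeric(nrow(events))
  for (i in seq_len(nrow(events))) {
    g <- f0g[as.character(events$n_aps[i])]
    seg <- (v[(s0[i] - nPre):(s0[i] + nPost - 1L)] - f0l[i]) / g
    segs[[i]] <- seg
    post <- seg[(nPre + 1L):length(seg)]
    iMax <- which.max(post) + nPre
    w <- max(1L, round(0.05 * rate))
    lo <- max(1L, iMax - w); hi <- min(length(seg), iMax + w)
    peaks[i] <- mean(seg[lo:hi])
  }
  events$f0_local <- f0l
  events$peak_dff <- peaks
  events$dff <- I(segs)
  events$seg_start <- s0 - nPre
  attr(events, "f0_global") <- f0g
  events
}

#' Fit a difference-of-exponentials transient
#'
#' Nonlinear least squares of
#' \eqn{f(t) = A (e^{-t/\tau_d} - e^{-t/\tau_r})} for \eqn{t \ge 0}
#' to a mean dF/F segment, with three starting points; the best fit by
#' residual sum of squares is kept. If the optimizer lands with
#' `tauRise > tauDecay` the parameters are relabeled (the model is
#' symmetric up to the sign of A).
#'
#' @param meanDff mean dF/F segment (first `preS` seconds are the
#'   pre-event baseline; the transient starts near `t = 0`).
#' @param rate frame rate (Hz).
#' @param preS pre-event window contained in the segment (s).
#' @param t optional explicit time axis (s, relative to the event onset);
#'   overrides `rate`/`preS` and may be unsorted (e.g. pooled samples
#'   from several events aligned to their exact AP times).
#' @param fitOnset fit a small onset latency `d` (bounded to one frame
#'   period) absorbing the sub-frame alignment of segments; fixed to 0
#'   when `FALSE`.
#' @return A [TransientFit-class]; degenerate or non-converged fits carry
#'   `converged = FALSE`. The fitted latency is in attribute `"onset"`.
#' @export
fitTransient <- function(meanDff, rate, preS = 0.1, t = NULL,
                         fitOnset = is.null(t)) {
  if (is.null(t)) t <- (seq_along(meanDff) - 1L) / rate - preS
  df <- data.frame(t = t, y = meanDff)
  peak <- max(abs(meanDff))
  if (peak < 1e-12)
    return(new("TransientFit", amplitude = 0, tauRise = NA_real_,
               tauDecay = NA_real_, rss = sum(meanDff^2),
               converged = FALSE))
  dMax <- if (fitOnset) 1.5 / rate else 1e-9
  starts <- list(c(tr = 0.02, td = 0.2), c(tr = 0.08, td = 0.7),
                 c(tr = 0.2, td = 1.5))
  best <- NULL
  for (s in starts) {
    A0 <- max(meanDff) / .kernelPeak(s[["tr"]], s[["td"]])$value
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A * (exp(-pmax(t - d, 0) / td) - exp(-pmax(t - d, 0) / tr)) *
          (t >= d),
        data = df,
        start = list(A = A0, tr = s[["tr"]], td = s[["td"]], d = 0),
        lower = c(-Inf, 1e-4, 1e-4, -dMax), upper = c(Inf, Inf, Inf, dMax),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(rss = rss, par = stats::coef(fit))
    }
  }
  if (is.null(best))
    return(new("TransientFit", amplitude = NA_real_, tauRise = NA_real_,
               tauDecay = NA_real_, rss = NA_real_, converged = FALSE))
  p <- best$par
  A <- p[["A"]]; tr <- p[["tr"]]; td <- p[["td"]]
  if (tr > td) { tmp <- tr; tr <- td; td <- tmp; A <- -A }
  out <- new("TransientFit", amplitude = max(A, 0), tauRise = tr,
             tauDecay = td, rss = best$rss,
             converged = A >= 0 && tr < td)
  attr(out, "onset") <- p[["d"]]
  out
}

#' Trial-to-trial variability of 1 AP responses
#'
#' Each trial's mean photon count over the 100 ms before the AP is
#' subtracted; `t_max` is taken from the mean trace; the per-trial value
#' at `t_max` is compared against a 95% confidence band around the
#' across-trial mean. The band half-width is `1.96 * SEM` (default) or,
#' with `ci = "mean_peak"`, the literal `1.96 * mean peak` reading.
#'
#' @param trials matrix of baseline-aligned 1 AP photon traces (one row
#'   per trial; the first `preS` seconds are pre-AP baseline).
#' @param rate frame rate (Hz).
#' @param preS pre-AP baseline window (s).
#' @param ci `"sem"` or `"mean_peak"`.
#' @return Fraction of trials with peak outside the band, in [0, 1].
#' @export
trialVariability <- function(trials, rate, preS = 0.1,
                             ci = c("sem", "mean_peak")) {
  ci <- match.arg(ci)
  if (nrow(trials) < 5L) stop("at least 5 one-AP trials are required")
  nPre <- round(preS * rate)
  bl <- rowMeans(trials[, seq_len(nPre), drop = FALSE])
  x <- trials - bl
  mt <- colMeans(x)
  iMax <- which.max(mt[(nPre + 1L):ncol(x)]) + nPre
  peaks <- x[, iMax]
  mu <- mean(peaks)
  half <- switch(ci,
                 sem = 1.96 * stats::sd(peaks) / sqrt(length(peaks)),
                 mean_peak = 1.96 * abs(mu))
  mean(peaks < mu - half | peaks > mu + half)
}

#' Write an events table to CSV
#'
#' @param events data.frame from [computeEventDff()].
#' @param file output path.
#' @param neuronId identifier written with each row.
#' @param rUsed neuropil coefficient used for the trace.
#' @return The written data.frame, invisibly.
#' @export
writeEventsTable <- function(events, file, neuronId = "neuron1",
                             rUsed = NA_real_) {
  df <- data.frame(neuron_id = neuronId, t_first = events$t_first,
                   n_aps = events$n_aps, f0_local = events$f0_local,
                   peak_dff = events$peak_dff, r_used = rUsed)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}
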