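test_that("trace extraction averages mask pixels", {
  mv <- array(7, dim = c(6, 6, 10))
  soma <- matrix(FALSE, 6, 6); soma[3:4, 3:4] <- TRUE
  np <- matrix(FALSE, 6, 6); np[1, ] <- TRUE
  tr <- extractTraces(mv, soma, np, rate = 30)
  expect_equal(traceValues(tr$cell), rep(7, 10))
  expect_equal(traceValues(tr$neuropil), rep(7, 10))

  # soma-only signal leaves the neuropil trace flat
  sig <- sin(seq_len(10))
  for (i in 1:10) mv[3:4, 3:4, i] <- 7 + sig[i]
  tr <- extractTraces(mv, soma, np, rate = 30)
  expect_equal(traceValues(tr$cell), 7 + sig)
  expect_equal(diff(range(traceValues(tr$neuropil))), 0)

  # single-pixel mask returns that pixel's series
  one <- matrix(FALSE, 6, 6); one[2, 5] <- TRUE
  tr <- extractTraces(mv, one, np, rate = 30)
  expect_equal(traceValues(tr$cell), mv[2, 5, ])

  expect_error(extractTraces(mv, matrix(FALSE, 6, 6), np, rate = 30),
               "empty mask")
})

test_that("neuropil subtraction is linear with a fallback ladder", {
  fc <- c(10, 12); fn <- c(5, 5)
  expect_equal(subtractNeuropil(fc, fn, r = 0.8)$trace, c(6, 8))
  expect_equal(subtractNeuropil(fc, fn, r = 0)$trace, fc)
  expect_error(subtractNeuropil(fc, fn, r = -0.1), "r must be")

  # exact linearity in r
  set.seed(1)
  fc <- 100 + rnorm(50); fn <- 40 + rnorm(50)
  o1 <- subtractNeuropil(fc, fn, 0.3)$trace
  o2 <- subtractNeuropil(fc, fn, 0.7)$trace
  expect_equal(o1 - o2, (0.7 - 0.3) * fn)

  # over-subtraction steps down the ladder, flags when still negative
  fc <- rep(10, 100); fn <- rep(16, 100)
  res <- subtractNeuropil(fc, fn, r = 0.8)   # 0.8*16=12.8 > 10 -> step
  expect_equal(res$rUsed, 0.6)               # 0.6*16 = 9.6 < 10
  expect_false(res$flagged)
  fn <- rep(25, 100)
  res <- subtractNeuropil(fc, fn, r = 0.8)   # negative even at 0.5
  expect_equal(res$rUsed, 0.5)
  expect_true(res$flagged)
})

test_that("isolated-event bookkeeping matches hand-computed answers", {
  # 6f: 300 ms margins both sides
  ev <- findIsolatedEvents(c(1.00, 1.10, 1.20, 2.00), "6f")
  expect_equal(nrow(ev), 2)
  expect_equal(ev$t_first, c(1.00, 2.00))
  expect_equal(ev$n_aps, c(3L, 1L))

  # 6s: >= 1.0 s before and >= 0.5 s after
  ev <- findIsolatedEvents(c(1.0, 1.6), "6s")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$t_first, 1.0)

  # bursts of more than 5 APs are excluded
  burst <- seq(1.0, 1.24, length.out = 7)
  expect_equal(nrow(findIsolatedEvents(burst, "6f")), 0)
  five <- seq(1.0, 1.2, length.out = 5)
  expect_equal(findIsolatedEvents(five, "6f")$n_aps, 5L)

  expect_error(findIsolatedEvents(1, "6x"), "unknown indicator")
})

test_that("every AP belongs to exactly one event", {
  cfg <- quickCfg(seed = 71, durationS = 60, firingRate = 3)
  ap <- simulateAPTrain(cfg)
  groups <- groupApEvents(ap)
  expect_equal(sort(unlist(groups)), seq_along(ap))
  ev <- findIsolatedEvents(ap, "6f")
  expect_lte(sum(ev$n_aps), length(ap))
  # isolated events use the same grouping: each matches one group
  for (i in seq_len(nrow(ev)))
    expect_true(any(vapply(groups, function(g)
      isTRUE(all.equal(ap[g], ev$ap_times[[i]])), logical(1))))
})

test_that("event dF/F uses local baselines over the class-global minimum", {
  rate <- 100
  v <- rep(100, 400)
  # event 2 sits on a raised local baseline of 120
  v[201:400] <- 120
  k <- calciumKernel(0.02, 0.2, rate, amp = 30)   # absolute units
  v[101:180] <- v[101:180] + k@samples[1:80]
  v[301:380] <- v[301:380] + k@samples[1:80]
  tr <- new("FluoTrace", values = v, rate = rate, t0 = 0)
  ev <- data.frame(t_first = c(1.0, 3.0), t_last = c(1.0, 3.0),
                   n_aps = c(1L, 1L))
  ed <- computeEventDff(tr, ev, "6f")
  expect_equal(ed$f0_local, c(100, 120))
  expect_equal(unname(attr(ed, "f0_global")), 100)  # min rule
  # both events share the global denominator
  expect_equal(max(ed$dff[[1]]), max(ed$dff[[2]]), tolerance = 1e-10)
  expect_equal(ed$peak_dff[1], ed$peak_dff[2], tolerance = 1e-10)

  # constant trace: all-zero dF/F
  ed0 <- computeEventDff(new("FluoTrace", values = rep(50, 400),
                             rate = rate, t0 = 0),
                         ev[1, , drop = FALSE], "6f")
  expect_equal(ed0$peak_dff, 0)
  expect_true(all(abs(ed0$dff[[1]]) < 1e-12))
})

test_that("dF/F segments are exactly invariant under trace rescaling", {
  cfg <- quickCfg(seed = 72, durationS = 30, firingRate = 1.5)
  rec <- simulateRecording(cfg)
  tr <- extractTraces(rec)
  sub <- subtractNeuropil(tr$cell, tr$neuropil, 0.8)$trace
  ev <- findIsolatedEvents(apTimes(rec), "6f")
  ed1 <- computeEventDff(sub, ev, "6f")
  sub2 <- new("FluoTrace", values = 3.7 * traceValues(sub),
              rate = sub@rate, t0 = sub@t0)
  ed2 <- computeEventDff(sub2, ev, "6f")
  expect_equal(ed1$peak_dff, ed2$peak_dff)
  for (i in seq_len(nrow(ed1)))
    expect_equal(ed1$dff[[i]], ed2$dff[[i]])
})

test_that("peak dF/F matches the analytic transient maximum", {
  rate <- 158
  amp <- 0.3; tr_ <- 0.02; td <- 0.2
  n <- 200
  f0 <- 100
  v <- rep(f0, n)
  tAp <- 0.5
  t <- (seq_len(n) - 1) / rate
  v <- v + f0 * spikefluor:::.kernelEval(t - tAp, tr_, td, amp)
  ftr <- new("FluoTrace", values = v, rate = rate, t0 = 0)
  ev <- data.frame(t_first = tAp, t_last = tAp, n_aps = 1L)
  ed <- computeEventDff(ftr, ev, "6f")
  # analytic: mean of kernel over 100 ms around its peak
  pk <- spikefluor:::.kernelPeak(tr_, td)
  tt <- seq(pk$t - 0.05, pk$t + 0.05, length.out = 400)
  expected <- mean(spikefluor:::.kernelEval(tt, tr_, td, amp))
  expect_equal(ed$peak_dff, expected, tolerance = 0.05)
})

test_that("transient fits recover parameters and relabel swapped taus", {
  rate <- 158
  seg <- c(rep(0, 16),
           spikefluor:::.kernelEval(seq(0, 2, by = 1 / rate), 0.05, 0.6,
                                    0.3))
  fit <- fitTransient(seg, rate, preS = 16 / rate)
  expect_true(fit@converged)
  expect_lt(abs(fit@tauRise - 0.05) / 0.05, 0.01)
  expect_lt(abs(fit@tauDecay - 0.6) / 0.6, 0.01)
  expect_lt(abs(fit@amplitude * spikefluor:::.kernelPeak(
    fit@tauRise, fit@tauDecay)$value - 0.3) / 0.3, 0.01)
  expect_true(fit@tauRise < fit@tauDecay)   # relabeling guarantee

  fit0 <- fitTransient(rep(0, 100), rate)
  expect_false(fit0@converged)
  expect_equal(fit0@amplitude, 0)
})

test_that("trial variability counts trials outside the confidence band", {
  rate <- 100
  base <- c(rep(0, 10), calciumKernel(0.02, 0.2, rate, amp = 50)@samples)
  trials <- matrix(rep(base, 8), nrow = 8, byrow = TRUE)
  expect_equal(trialVariability(trials, rate), 0)   # identical trials

  set.seed(5)
  n <- 200
  peaks <- rnorm(n, 50, 10)
  trials <- t(vapply(peaks, function(p)
    c(rep(0, 10), calciumKernel(0.02, 0.2, rate, amp = p)@samples),
    numeric(length(base) - 10 + 10)))
  frac <- trialVariability(trials, rate, ci = "sem")
  expect_gt(frac, 0.7)    # +/-1.96*SEM band excludes most draws
  expect_error(trialVariability(trials[1:3, ], rate), "5 one-AP")
})

test_that("photon gain calibration inverts the recorded-unit transform", {
  # formula arithmetic: slope 2, offset -4 -> pedestal 2, photons (10-2)/2
  cal <- new("PhotonCalibration", slope = 2, offset = -4,
             resonantAxis = "width")
  expect_equal(toPhotons(10, cal), 4)

  cfg <- simConfig("6f", seed = 73, durationS = 13, firingRate = 0,
                   ephysRate = 10000, fovPx = c(32L, 32L),
                   somaRadiusPx = 4, neuropilAmp = 0,
                   baselinePhotons = 50, photonGain = 2, pedestal = 100)
  rec <- simulateRecording(cfg)   # ~2000 frames
  cal <- fitPhotonGain(movieArray(rec))
  expect_lt(abs(mean(cal@slope) - 2) / 2, 0.05)
  ped <- mean(-cal@offset / cal@slope)
  expect_lt(abs(ped - 100) / 100, 0.05)
  ph <- toPhotons(movieArray(rec), cal)
  expect_lt(abs(mean(ph) / 50 - 1), 0.1)

  expect_error(fitPhotonGain(array(1, dim = c(4, 4, 50))), "100 frames")
})
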