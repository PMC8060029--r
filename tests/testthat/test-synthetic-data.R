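test_that("AP train generator respects rate, refractory period and seed", {
  cfg <- quickCfg(firingRate = 0)
  expect_length(simulateAPTrain(cfg), 0)

  cfg <- quickCfg(firingRate = 400, refractoryS = 0.01)
  expect_error(simulateAPTrain(cfg), "infeasible")

  cfg <- quickCfg(seed = 5, durationS = 30, firingRate = 5,
                  refractoryS = 0.005)
  ap <- simulateAPTrain(cfg)
  expect_gt(length(ap), 0)
  expect_false(is.unsorted(ap, strictly = TRUE))
  expect_gte(min(diff(ap)), 0.005)
  expect_identical(ap, simulateAPTrain(cfg))  # reproducible from seed
})

test_that("mean AP count matches the dead-time-corrected Poisson rate", {
  # renewal train with ISI = tau + Exp(lambda): rate lambda/(1+lambda*tau)
  lambda <- 2; tau <- 0.005; dur <- 100
  counts <- vapply(1:200, function(s) {
    cfg <- quickCfg(seed = s, durationS = dur, firingRate = lambda,
                    refractoryS = tau)
    length(simulateAPTrain(cfg))
  }, numeric(1))
  expected <- dur * lambda / (1 + lambda * tau)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("rendered voltage trace carries baseline, drift and AP peaks", {
  cfg <- quickCfg(firingRate = 0, vmNoiseMv = 0, driftMvPerS = 0,
                  durationS = 2)
  vm <- renderVm(numeric(0), cfg)
  expect_equal(diff(range(traceValues(vm))), 0)
  expect_equal(traceValues(vm)[1], 10)  # vmBaselineMv default

  apT <- c(0.5, 1.0, 1.5)
  cfg <- quickCfg(durationS = 2, vmNoiseMv = 0.02, apAmpMv = 1)
  vm <- renderVm(apT, cfg)
  x <- traceValues(vm)
  # three largest peaks, greedily deduplicated with 10 ms separation
  ord <- order(x, decreasing = TRUE)
  pkI <- integer(0)
  for (i in ord) {
    if (all(abs(i - pkI) > 0.01 * vm@rate)) pkI <- c(pkI, i)
    if (length(pkI) == 3) break
  }
  pkT <- sort((pkI - 1) / vm@rate)
  expect_lt(max(abs(pkT - apT)), 5e-4)

  cfg <- quickCfg(seed = 2, firingRate = 0, driftMvPerS = 0.1,
                  durationS = 60)
  vm <- renderVm(numeric(0), cfg)
  t <- (seq_along(traceValues(vm)) - 1) / vm@rate
  slope <- cov(t, traceValues(vm)) / var(t)
  expect_lt(abs(slope - 0.1) / 0.1, 0.05)

  expect_error(renderVm(1, quickCfg(apAmpMv = -1)), "waveform")
})

test_that("movies are reproducible and conserve per-frame AP counts", {
  cfg <- quickCfg(seed = 11, durationS = 5)
  rec1 <- simulateRecording(cfg)
  rec2 <- simulateRecording(cfg)
  expect_identical(movieArray(rec1), movieArray(rec2))
  expect_identical(apTimes(rec1), apTimes(rec2))
  expect_equal(sum(groundTruth(rec1)$frame_ap_counts),
               length(apTimes(rec1)))
  expect_false(any(somaMask(rec1) & neuropilMask(rec1)))
})

test_that("photon counts are Poisson: per-pixel Fano factor near 1", {
  cfg <- quickCfg(seed = 3, durationS = 26, firingRate = 0,
                  neuropilAmp = 0, baselinePhotons = 20,
                  pixelBrightnessCv = 0.1)
  rec <- simulateRecording(cfg)   # ~4100 frames at 158 Hz
  mv <- movieArray(rec)           # gain 1, pedestal 0: counts directly
  flat <- matrix(mv, ncol = dim(mv)[3])
  mu <- rowMeans(flat)
  va <- rowSums((flat - mu)^2) / (ncol(flat) - 1)
  fano <- va / mu
  expect_gt(mean(fano >= 0.9 & fano <= 1.1), 0.99)
  expect_lt(abs(mean(fano) - 1), 0.02)
})

test_that("noiseless mean 1 AP trace reproduces the configured kernel", {
  cfg <- quickCfg(seed = 4, durationS = 3, firingRate = 0,
                  neuropilAmp = 0, baselinePhotons = 6e6,
                  somaBrightness = 1, pixelBrightnessCv = 0)
  rec <- renderMovie(1.0, cfg, vm = renderVm(1.0, quickCfg(durationS = 3)))
  tr <- extractTraces(rec)
  f <- traceValues(tr$cell)
  dff <- f / mean(f[1:100]) - 1
  ft <- groundTruth(rec)$frame_times
  expected <- spikefluor:::.kernelEval(ft - 1.0, cfg@tauRise,
                                       cfg@tauDecay, cfg@kernelAmp1AP)
  rms <- sqrt(mean((dff - expected)^2))
  expect_lt(rms / max(expected), 0.001)
})

test_that("movie values are photonGain * photons + pedestal", {
  cfg <- quickCfg(seed = 8, durationS = 2, firingRate = 0,
                  neuropilAmp = 0, photonGain = 2, pedestal = 100)
  rec <- simulateRecording(cfg)
  v <- movieArray(rec)
  expect_true(all((v - 100) %% 2 == 0))   # integer photons, scaled
  expect_gte(min(v), 100)
})

test_that("artifact injection modifies a copy with logged provenance", {
  cfg <- quickCfg(seed = 21, durationS = 10, firingRate = 2)
  rec <- simulateRecording(cfg)
  vm0 <- traceValues(vmTrace(rec))

  bl <- injectArtifact(rec, "bleach")
  fm <- colMeans(matrix(movieArray(bl), ncol = dim(movieArray(bl))[3]))
  expect_true(all(diff(fm) < 0))          # monotone decay
  expect_identical(traceValues(vmTrace(rec)), vm0)  # original untouched
  expect_equal(provenance(bl)[[1]]$kind, "bleach")

  dr <- injectArtifact(rec, "drift", slope = 0.5)
  t <- (seq_along(vm0) - 1) / vmTrace(rec)@rate
  d <- traceValues(vmTrace(dr)) - vm0
  expect_equal(cov(t, d) / var(t), 0.5, tolerance = 1e-6)

  wc <- injectArtifact(rec, "waveform_change", factor = 2)
  tr1 <- detectAPs(detrendVm(vmTrace(wc))$detrended, "qt")
  hw <- t(apply(tr1@waveforms, 1, spikefluor:::.halfWidths,
                rate = tr1@rate))
  fw <- rowSums(hw)
  firstHalf <- apTimes(tr1) <= cfg@durationS / 2
  expect_gte(mean(fw[!firstHalf]) / mean(fw[firstHalf]), 1.8)

  expect_error(injectArtifact(rec, "wobble"), "unknown")
})
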