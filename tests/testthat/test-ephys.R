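test_that("Savitzky-Golay detrending reproduces polynomial baselines", {
  rate <- 10000
  n <- 40000
  tr <- new("VoltageTrace", samples = rep(3.2, n), rate = rate, t0 = 0)
  dt <- detrendVm(tr)
  expect_lt(max(abs(traceValues(dt$detrended))), 1e-9)
  expect_lt(max(abs(traceValues(dt$baseline) - 3.2)), 1e-9)

  ramp <- seq(0, 1, length.out = n)
  dt <- detrendVm(new("VoltageTrace", samples = ramp, rate = rate,
                      t0 = 0))
  interior <- 10001:(n - 10000)
  expect_lt(sqrt(mean(traceValues(dt$detrended)[interior]^2)), 1e-9)

  expect_error(detrendVm(new("VoltageTrace", samples = rnorm(100),
                             rate = rate, t0 = 0)), "shorter")
})

test_that("baseline tracks a ramp under a superimposed AP", {
  cfg <- quickCfg(seed = 31, durationS = 4, vmNoiseMv = 0,
                  driftMvPerS = 0.5, apAmpMv = 1)
  vm <- renderVm(2.0, cfg)
  dt <- detrendVm(vm)
  t <- (seq_along(traceValues(vm)) - 1) / vm@rate
  ramp <- 10 + 0.5 * t
  interior <- 10001:(length(t) - 10000)
  err <- abs(traceValues(dt$baseline)[interior] - ramp[interior])
  expect_lt(max(err), 0.01 * cfg@apAmpMv)
})

test_that("Quiroga threshold estimates the Gaussian scale", {
  set.seed(42)
  x <- rnorm(1e6, 0, 0.37)
  expect_lt(abs(quirogaThreshold(x) - 0.37) / 0.37, 0.01)
  expect_equal(quirogaThreshold(rep(0, 10)), 0)
  expect_equal(quirogaThreshold(c(-1, 1, -1, 1)), 1 / 0.6745)
  # scale equivariance
  expect_equal(quirogaThreshold(-2.5 * x), 2.5 * quirogaThreshold(x))
  expect_error(quirogaThreshold(numeric(0)), "empty")
  expect_error(quirogaThreshold(rep(NaN, 5)), "NaN")
})

test_that("AP detection finds injected spikes and rejects pure noise", {
  cfg <- quickCfg(seed = 32, durationS = 3, vmNoiseMv = 0.02,
                  apAmpMv = 1)
  apT <- c(0.8, 1.5, 2.2)
  vm <- renderVm(apT, cfg)
  det <- detectAPs(detrendVm(vm)$detrended, "qt", k = 10)
  expect_length(apTimes(det), 3)
  expect_lt(max(abs(apTimes(det) - apT)), 5e-4)

  det2 <- detectAPs(vm, "bandpass")
  expect_length(apTimes(det2), 3)

  set.seed(7)
  noise <- new("VoltageTrace", samples = rnorm(4e5, 0, 0.05),
               rate = 40000, t0 = 0)
  expect_length(apTimes(detectAPs(noise, "qt", k = 10)), 0)
  expect_error(detectAPs(vm, "qt", k = 0), "k must be")
})

test_that("detection count is non-increasing in the threshold multiplier", {
  cfg <- quickCfg(seed = 33, durationS = 5, firingRate = 3,
                  vmNoiseMv = 0.05)
  vm <- renderVm(simulateAPTrain(cfg), cfg)
  d <- detrendVm(vm)$detrended
  counts <- vapply(c(2, 4, 6, 8, 10, 15),
                   function(k) length(apTimes(detectAPs(d, "qt", k = k))),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("QC battery has exactly 35 metrics with sane trivial values", {
  cfg <- quickCfg(seed = 34, durationS = 15, firingRate = 2,
                  vmNoiseMv = 0.02)
  vm <- renderVm(simulateAPTrain(cfg), cfg)
  rep1 <- computeQCMetrics(vm)
  m <- qcMetrics(rep1)
  expect_identical(names(m), qcMetricNames())
  expect_length(m, 35)
  expect_equal(qcVerdict(rep1), "ungated")

  det <- detectAPs(detrendVm(vm)$detrended, "qt", k = 10)
  expect_equal(m[["n_aps"]], length(apTimes(det)))
  # identity: SNR is median amplitude over the Quiroga threshold
  expect_equal(m[["snr"]], median(det@amplitudes) / m[["qt_mean"]])
  # near-constant positive baseline: MAD/median of raw Vm is ~0 and
  # stereotyped APs give ~0 amplitude cv
  expect_lt(abs(m[["mrdm"]]), 0.01)
  expect_lt(m[["ap_amp_cv"]], 0.1)
  expect_lt(abs(m[["bl_slope"]]), 0.002)       # stationary recording
  expect_lt(abs(m[["fr_vs_time_slope"]]), 0.2)
})

test_that("few-AP recordings mark AP metrics not applicable", {
  cfg <- quickCfg(seed = 35, durationS = 15, firingRate = 0,
                  vmNoiseMv = 0.02)
  vm <- renderVm(c(5.0, 7.0), cfg)   # 2 APs only
  m <- qcMetrics(computeQCMetrics(vm))
  expect_equal(m[["n_aps"]], 2)
  expect_true(is.na(m[["ap_amp_mean"]]))
  expect_true(is.na(m[["fwhm"]]))
  expect_false(is.na(m[["qt_mean"]]))
})

test_that("time-independent metrics are invariant under time reversal", {
  cfg <- quickCfg(seed = 36, durationS = 15, firingRate = 2,
                  vmNoiseMv = 0.02)
  vm <- renderVm(simulateAPTrain(cfg), cfg)
  rv <- new("VoltageTrace", samples = rev(traceValues(vm)),
            rate = vm@rate, t0 = 0)
  m1 <- qcMetrics(computeQCMetrics(vm))
  m2 <- qcMetrics(computeQCMetrics(rv))
  inv <- c("mrdm", "baseline_mean", "baseline_cv", "qt_mean",
           "polarity_ratio", "n_aps", "ml_isi", "ap_amp_mean",
           "ap_amp_cv", "ap_amp_mrd", "ap_amp_rel_range",
           "ap_amp_maxmin", "snr", "fwhm", "fwhm_cv")
  expect_equal(m1[inv], m2[inv], tolerance = 1e-8)
  # left and right half-widths swap under reversal
  expect_equal(m1[["lwhm"]], m2[["rwhm"]], tolerance = 1e-8)
  expect_equal(m1[["rwhm"]], m2[["lwhm"]], tolerance = 1e-8)
})

test_that("the min-max gate passes members and is monotone in the reference", {
  reports <- lapply(1:6, function(i) {
    cfg <- quickCfg(seed = 40 + i, durationS = 12, firingRate = 2,
                    vmNoiseMv = 0.02)
    computeQCMetrics(renderVm(simulateAPTrain(cfg), cfg))
  })
  gated <- qcGate(reports[[1]], reports)
  expect_equal(qcVerdict(gated), "pass")   # member of its own reference

  # monotonicity: enlarging the reference can only flip fail -> pass
  v_small <- qcVerdict(qcGate(reports[[1]], reports[2:3]))
  v_large <- qcVerdict(qcGate(reports[[1]], reports[2:6]))
  expect_false(v_small == "pass" && v_large == "fail")
  expect_error(qcGate(reports[[1]], list()), "empty")
})

test_that("injected drift fails the gate on the baseline-slope family", {
  ref <- lapply(1:8, function(i) {
    cfg <- quickCfg(seed = 50 + i, durationS = 12, firingRate = 2,
                    driftMvPerS = c(-0.002, 0, 0.002)[i %% 3 + 1])
    computeQCMetrics(renderVm(simulateAPTrain(cfg), cfg))
  })
  cfg <- quickCfg(seed = 60, durationS = 12, firingRate = 2,
                  driftMvPerS = 0.5)
  bad <- computeQCMetrics(renderVm(simulateAPTrain(cfg), cfg))
  gated <- qcGate(bad, ref)
  expect_equal(qcVerdict(gated), "fail")
  expect_true(any(c("bl_slope", "bl_r2") %in%
                    names(which(!qcFlags(gated)))))
})
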