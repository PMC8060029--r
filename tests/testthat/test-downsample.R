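test_that("block downsampling averages correctly over all phases", {
  mv <- array(4.2, dim = c(8, 8, 20))
  ds <- downsampleMovie(mv, sf = 4, tf = 5, rate = 158)
  expect_length(ds@variants, 20)
  expect_equal(frameRate(ds), 158 / 5)
  for (v in ds@variants) expect_true(all(v == 4.2))

  # phase-0 variant of evenly divisible dims preserves the grand mean
  set.seed(20)
  mv <- array(rnorm(8 * 8 * 20, 100, 5), dim = c(8, 8, 20))
  ds <- downsampleMovie(mv, rate = 158)
  v0 <- ds@variants[[which(ds@phases$spatial == 0 &
                             ds@phases$temporal == 0)]]
  expect_equal(mean(v0), mean(mv))

  # frame counts follow floor((T - phase)/tf)
  for (i in seq_len(20))
    expect_equal(dim(ds@variants[[i]])[3],
                 (20 - ds@phases$temporal[i]) %/% 5)

  expect_error(downsampleMovie(array(1, dim = c(2, 2, 3)), rate = 30),
               "smaller than one block")
})

test_that("iid noise variance shrinks by the block size", {
  set.seed(21)
  sigma <- 3
  mv <- array(rnorm(16 * 16 * 1000, 50, sigma), dim = c(16, 16, 1000))
  ds <- downsampleMovie(mv, rate = 158)
  v0 <- ds@variants[[1]]
  expect_equal(var(as.numeric(v0)), sigma^2 / 80, tolerance = 0.1)
})

test_that("tiled traces replicate each variant into identical blocks", {
  cfg <- quickCfg(seed = 76, durationS = 4, firingRate = 2,
                  baselinePhotons = 1e5, pixelBrightnessCv = 0,
                  vmNoiseMv = 0.01)
  rec <- simulateRecording(cfg)
  ds <- downsampleMovie(rec)
  ds <- extractTiledTraces(ds, somaMask(rec))
  tt <- tiledTraces(ds)
  expect_equal(nrow(tt), 400)
  # the 20 copies of each variant are identical
  for (g in seq_len(20)) {
    block <- tt[((g - 1) * 20 + 1):(g * 20), ]
    expect_true(all(abs(sweep(block, 2, block[1, ])) < 1e-12))
  }
  # near-noiseless: the consensus equals any one trace up to shot noise
  cons <- attr(tt, "consensus")
  expect_gt(cor(cons, tt[1, ]), 0.95)

  dsPartial <- ds
  dsPartial@variants <- ds@variants[1:3]
  expect_error(extractTiledTraces(dsPartial, somaMask(rec)),
               "variants")
})

test_that("phase-variant traces of one neuron correlate strongly", {
  cfg <- quickCfg(seed = 77, durationS = 10, firingRate = 3,
                  baselinePhotons = 200)
  rec <- simulateRecording(cfg)
  ds <- extractTiledTraces(downsampleMovie(rec), somaMask(rec))
  tt <- tiledTraces(ds)
  picks <- seq(1, 400, by = 20)    # one trace per variant
  cc <- cor(t(tt[picks, ]))
  expect_gt(min(cc), 0.9)
})

test_that("DBSCAN/KS QC keeps signal clusters and rejects noise", {
  cfg <- quickCfg(seed = 78, durationS = 10, firingRate = 3,
                  baselinePhotons = 200)
  rec <- simulateRecording(cfg)
  ds <- extractTiledTraces(downsampleMovie(rec), somaMask(rec))
  cq <- clusterAndTest(tiledTraces(ds))
  expect_equal(nrow(cq@medians), 1)     # one dense cluster
  expect_equal(cq@kept, 1L)

  # mixture: soma traces plus a self-similar flat-noise artifact family
  set.seed(30)
  L <- ncol(tiledTraces(ds))
  flatBase <- rnorm(L, 100, 0.5)
  flat <- t(replicate(40, flatBase + rnorm(L, 0, 0.05)))
  mix <- rbind(tiledTraces(ds), flat)
  cqm <- clusterAndTest(mix)
  expect_gte(nrow(cqm@medians), 2)
  keptLabels <- cqm@kept
  # the kept cluster(s) must contain soma traces, not the flat block
  somaCluster <- cqm@labels[1]
  expect_true(somaCluster %in% keptLabels)
  flatClusters <- setdiff(unique(cqm@labels[401:440]), 0L)
  expect_false(any(flatClusters %in% keptLabels))

  # pure white-noise trace families are rejected most of the time
  rejected <- vapply(1:20, function(s) {
    set.seed(100 + s)
    wn <- rnorm(300)
    traces <- t(replicate(25, wn))   # one self-similar noise family
    cq <- clusterAndTest(traces, seed = s)
    length(cq@kept) == 0
  }, logical(1))
  expect_gte(mean(rejected), 0.9)
})

test_that("trace selection calibrates against rate-matched Poisson nulls", {
  cfg <- quickCfg(seed = 79, durationS = 30, firingRate = 3,
                  baselinePhotons = 200)
  rec <- simulateRecording(cfg)
  ds <- extractTiledTraces(downsampleMovie(rec), somaMask(rec))
  cq <- clusterAndTest(tiledTraces(ds))
  counts <- colSums(matrix(
    groundTruth(rec)$frame_ap_counts[
      seq_len(5 * (length(groundTruth(rec)$frame_ap_counts) %/% 5))],
    nrow = 5))
  sel <- selectTrace(cq, counts, nNull = 500, seed = 3)
  expect_true(sel@passed)      # real soma trace beats the null

  # noise medians fail the calibration
  cqNoise <- cq
  set.seed(31)
  cqNoise@medians <- t(replicate(nrow(cq@medians),
                                 rnorm(ncol(cq@medians))))
  selN <- selectTrace(cqNoise, counts, nNull = 500, seed = 4)
  expect_false(selN@passed)

  cqEmpty <- cq; cqEmpty@kept <- integer(0)
  expect_error(selectTrace(cqEmpty, counts), "failed")
})

test_that("robust standard deviation resists outliers and trends", {
  set.seed(32)
  x <- rnorm(1e5, 0, 2.5)
  expect_lt(abs(robustStd(x) - 2.5) / 2.5, 0.02)
  expect_equal(robustStd(rep(7, 100)), 0)
  # 1% large outliers barely move the estimate (naive sd explodes)
  y <- x; y[sample(1e5, 1000)] <- 100
  expect_lt(abs(robustStd(y) - 2.5) / 2.5, 0.05)
  expect_gt(sd(y) / 2.5, 2)
  # scale equivariance and trend removal
  expect_equal(robustStd(3 * x), 3 * robustStd(x), tolerance = 1e-10)
  trend <- x + seq(0, 50, length.out = 1e5)
  expect_lt(abs(robustStd(trend) - 2.5) / 2.5, 0.05)
  expect_error(robustStd(1:5), "10 samples")
})
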