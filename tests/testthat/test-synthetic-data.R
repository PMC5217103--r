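# Generators: determinism, distributional correctness, planted structure.

test_that("generators are deterministic under a fixed seed", {
  cfg <- simConfig(seed = 1, nGenes = 50, chromSizes = c(chrI = 8e5),
                   nPeaks = 5)
  a1 <- simulateAnnotation(cfg); a2 <- simulateAnnotation(cfg)
  expect_identical(as.data.frame(geneModels(a1)),
                   as.data.frame(geneModels(a2)))
  s1 <- simulateChipCoverage(a1, cfg); s2 <- simulateChipCoverage(a1, cfg)
  expect_identical(fwdCoverage(s1$tracks[[1]]), fwdCoverage(s2$tracks[[1]]))
  expect_identical(s1$truth, s2$truth)
  d1 <- simulateDETable(a1, cfg); d2 <- simulateDETable(a1, cfg)
  expect_identical(d1$records, d2$records)
  l1 <- simulateLuciferase(cfg); l2 <- simulateLuciferase(cfg)
  expect_identical(l1$series, l2$series)
})

test_that("annotation packing: divergent pairs, zero-divergent, infeasible", {
  cfg <- simConfig(seed = 2, nGenes = 40, chromSizes = c(chrI = 6e5),
                   divergentFraction = 0.3)
  ann <- simulateAnnotation(cfg)
  pairs <- attr(ann, "divergentPairs")
  expect_equal(nrow(pairs), floor(0.3 * 40 / 2))
  g <- geneModels(ann)
  for (i in seq_len(nrow(pairs))) {
    a <- g[pairs[i, 1]]; b <- g[pairs[i, 2]]
    expect_equal(as.character(GenomicRanges::strand(a)), "-")
    expect_equal(as.character(GenomicRanges::strand(b)), "+")
    gap <- GenomicRanges::start(b) - GenomicRanges::end(a) - 1L
    expect_true(gap > 0 && gap < 5000)   # facing TSSs across < 5 kb
  }
  none <- simulateAnnotation(simConfig(seed = 2, nGenes = 40,
    chromSizes = c(chrI = 6e5), divergentFraction = 0))
  expect_equal(nrow(attr(none, "divergentPairs")), 0L)
  expect_error(simulateAnnotation(simConfig(seed = 2, nGenes = 500,
    chromSizes = c(chrI = 6e5))), "packing")
  # genes never overlap and respect bounds
  expect_true(IRanges::isDisjoint(GenomicRanges::ranges(geneModels(ann))))
})

test_that("background-only coverage follows the rounded lognormal law", {
  cfg <- simConfig(seed = 3, nGenes = 8, chromSizes = c(chrI = 1e5),
                   nPeaks = 0)
  sim <- simulateChipCoverage(simulateAnnotation(cfg), cfg)
  cc <- combinedCoverage(sim$tracks[[1]])
  # empirical CDF at integer support vs the discretized lognormal CDF
  # (rounding maps X to k iff X in [k - .5, k + .5)); DKW sup bound at
  # alpha = 0.01 for n = 1e5
  ks <- 0:max(cc)
  ecdf_v <- vapply(ks, function(k) mean(cc <= k), numeric(1))
  model_v <- pnorm(log(ks + 0.5), cfg$backgroundMu, cfg$backgroundSigma)
  dkw <- sqrt(log(2 / 0.01) / (2 * length(cc)))
  expect_lt(max(abs(ecdf_v - model_v)), dkw)
})

test_that("planted peaks separate forward and reverse modes by d", {
  cfg <- simConfig(seed = 4, nGenes = 10, chromSizes = c(chrI = 2e5),
                   nPeaks = 1, peakHeight = 60, fragmentOffset = 70)
  sim <- simulateChipCoverage(simulateAnnotation(cfg), cfg)
  tr <- sim$tracks[[1]]
  ctr <- sim$truth$center[1]
  win <- (ctr - 400):(ctr + 400)
  sep <- win[which.max(revCoverage(tr)[win])] -
    win[which.max(fwdCoverage(tr)[win])]
  expect_true(abs(sep - 70) <= 15)
})

test_that("zero peak height reproduces the background-only stream", {
  cfg_h0 <- simConfig(seed = 5, nGenes = 8, chromSizes = c(chrI = 2e5),
                      nPeaks = 3, peakHeight = 0)
  ann <- simulateAnnotation(cfg_h0)
  with_peaks <- simulateChipCoverage(ann, cfg_h0)
  expect_equal(with_peaks$truth$nFragments, rep(0L, 3))
  cfg_none <- simConfig(seed = 5, nGenes = 8, chromSizes = c(chrI = 2e5),
                        nPeaks = 0)
  bg_only <- simulateChipCoverage(ann, cfg_none)
  expect_identical(fwdCoverage(with_peaks$tracks[[1]]),
                   fwdCoverage(bg_only$tracks[[1]]))
  expect_identical(revCoverage(with_peaks$tracks[[1]]),
                   revCoverage(bg_only$tracks[[1]]))
})

test_that("DE generator plants coherent labels and calibrated nulls", {
  cfg <- simConfig(seed = 6, nGenes = 300, chromSizes = c(chrI = 4e6))
  ann <- simulateAnnotation(cfg)
  de <- simulateDETable(ann, cfg)
  truth <- de$truthLabels
  act <- truth$gene_id[truth$label == "activated"]
  rec_act <- de$records[de$records$gene_id %in% act, ]
  # activated = lower in the mutant: mean log2fc strongly negative
  expect_true(all(tapply(rec_act$log2fc, rec_act$gene_id, mean) < 0))
  # null calibration: with no planted effects the q <= 0.2 fraction is tiny
  fracs <- vapply(1:20, function(s) {
    cfg0 <- simConfig(seed = 600 + s, nGenes = 2000,
                      chromSizes = c(chrI = 2.5e7), deFraction = 0)
    a0 <- simulateAnnotation(cfg0)
    length(filterDE(simulateDETable(a0, cfg0)$records)) / 2000
  }, numeric(1))
  expect_lte(mean(fracs), 0.02)
})

test_that("luciferase sampling grid and degenerate shapes", {
  cfg <- simConfig(seed = 7)
  sim <- simulateLuciferase(cfg)
  one <- sim$series[sim$series$replicate_id == "rep01", ]
  expect_equal(nrow(one), 77L)                 # t = 0, 1.5, ..., 114
  expect_equal(one$time_h, seq(0, 114, by = 1.5))

  # noiseless undamped sinusoid: the fitter recovers the period to 1e-3 h
  pure <- simulateLuciferase(cfg, truth = list(noiseSd = 0, damping = 0,
                                               trend = 0, nReplicates = 1))
  sf <- fitSine(list(t = pure$series$time_h, y = pure$series$value))
  expect_lt(abs(sf$period - 20.3), 1e-3)

  # zero amplitude: a pure trend must not be called rhythmic
  flat <- simulateLuciferase(cfg, truth = list(amplitude = 0, nReplicates = 1))
  pre <- preprocessSeries(data.frame(time_h = flat$series$time_h,
                                     value = flat$series$value))
  expect_false(rhythmTest(pre)$rhythmic)
})
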