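# Lognormal background fitting, position scoring, region rules, strand-shift
# filter, and the assembled caller against planted truth and a brute-force
# reference.

test_that("background fit: constant coverage, moment recovery, data floor", {
  const <- CoverageTrack("chrI", rep(4, 2000), rep(4, 2000))  # combined 8
  bg <- fitBackground(const)
  expect_equal(bg@mu, log(8))
  expect_equal(bg@sigma, 0)
  expect_true(bg@degenerate)
  expect_error(scorePositions(const, bg), "degenerate")

  set.seed(11)
  x <- rlnorm(1e5, meanlog = 1.0, sdlog = 0.5)
  tr <- CoverageTrack("chrI", x / 2, x / 2)
  bg2 <- fitBackground(tr)
  expect_lt(abs(bg2@mu - 1.0), 0.02)
  expect_lt(abs(bg2@sigma - 0.5), 0.02)

  sparse <- CoverageTrack("chrI", c(rep(1, 500), rep(0, 1500)), rep(0, 2000))
  expect_error(fitBackground(sparse), "insufficient coverage")
})

test_that("position scoring matches the standard-normal quantile threshold", {
  # mu = 0, sigma = 1, alpha = 0.01: threshold exp(2.3263...) ~ 10.23
  bg <- new("LognormalBackground", mu = 0, sigma = 1, nFit = 10000L,
            degenerate = FALSE)
  tr <- CoverageTrack("chrI", c(11, 10, 0, 200), c(0, 0, 0, 0))
  expect_equal(scorePositions(tr, bg, 0.01), c(TRUE, FALSE, FALSE, TRUE))
  # alpha = 1: every positive-coverage position is enriched
  expect_equal(scorePositions(tr, bg, 1 - 1e-12), c(TRUE, TRUE, FALSE, TRUE))
})

test_that("region merging applies the strict >100 bp rule and gap joining", {
  cfg <- peakCallerConfig()
  m150 <- rep(FALSE, 1000); m150[101:250] <- TRUE
  r <- mergeRegions(m150, cfg)
  expect_equal(IRanges::width(r), 150L)

  m100 <- rep(FALSE, 1000); m100[101:200] <- TRUE   # exactly 100: dropped
  expect_equal(length(mergeRegions(m100, cfg)), 0L)

  mgap <- rep(FALSE, 1000)
  mgap[101:180] <- TRUE; mgap[211:290] <- TRUE      # 80 + 30 gap + 80
  r2 <- mergeRegions(mgap, cfg)
  expect_equal(length(r2), 1L)
  expect_equal(IRanges::width(r2), 190L)

  mfar <- rep(FALSE, 1000)
  mfar[101:180] <- TRUE; mfar[232:311] <- TRUE      # gap 51 > 50: no join
  expect_equal(length(mergeRegions(mfar, cfg)), 0L) # each run only 80 bp
})

test_that("strand-shift estimation finds the planted lag, boundaries inclusive", {
  set.seed(21)
  base <- abs(stats::filter(rnorm(3000), rep(1, 20), circular = TRUE))
  f <- as.numeric(base)
  mk_shift <- function(lag) {
    r <- c(rep(0, lag), f[seq_len(3000 - lag)])
    CoverageTrack("chrI", f, r)
  }
  reg <- IRanges::IRanges(1200, 1500)
  cfg <- peakCallerConfig()
  expect_equal(estimateShift(reg, mk_shift(70), cfg)$shift, 70L)
  expect_true(estimateShift(reg, mk_shift(70), cfg)$passed)
  same <- estimateShift(reg, CoverageTrack("chrI", f, f), cfg)
  expect_equal(same$shift, 0L)
  expect_false(same$passed)
  at60 <- estimateShift(reg, mk_shift(60), cfg)
  expect_equal(at60$shift, 60L)
  expect_true(at60$passed)                        # >= 60 is inclusive
  at59 <- estimateShift(reg, mk_shift(59), cfg)
  expect_false(at59$passed)
  flat <- CoverageTrack("chrI", rep(3, 3000), rep(3, 3000))
  zv <- estimateShift(reg, flat, cfg)
  expect_equal(zv$shift, -1L)
  expect_false(zv$passed)
})

test_that("planted peaks are recovered with accurate summits, no extras", {
  cfg <- simConfig(seed = 3, chromSizes = c(chrI = 1e6), nGenes = 60,
                   nPeaks = 20)
  sim <- simulateChipDataset(cfg)
  ps <- callPeaks(sim$tracks)
  pk <- peakRanges(ps)
  truth <- sim$truth
  hits <- vapply(truth$center, function(ctr) min(abs(pk$summit - ctr)),
                 numeric(1))
  expect_gte(sum(hits <= 50), 19L)
  ghost <- vapply(pk$summit, function(s) min(abs(truth$center - s)),
                  numeric(1))
  expect_equal(sum(ghost > 50), 0L)
  # every retained peak satisfies the PeakRegion invariants
  expect_true(all(GenomicRanges::width(pk) > 100))
  expect_true(all(pk$q < 0.01))
  expect_true(all(pk$shift >= 60))
  expect_true(all(pk$summit >= GenomicRanges::start(pk) &
                    pk$summit <= GenomicRanges::end(pk)))
  expect_false(is.unsorted(GenomicRanges::start(pk)))  # sorted by position
})

test_that("relaxing the shift filter never loses peaks (monotonicity)", {
  cfg <- simConfig(seed = 8, chromSizes = c(chrI = 5e5), nGenes = 30,
                   nPeaks = 8)
  sim <- simulateChipDataset(cfg)
  n_default <- length(callPeaks(sim$tracks))
  n_noshift <- length(callPeaks(sim$tracks, peakCallerConfig(minShift = 0)))
  expect_gte(n_noshift, n_default)
  n_strict <- length(callPeaks(sim$tracks,
                               peakCallerConfig(alphaPosition = 0.001)))
  expect_lte(n_strict, n_noshift)
})

test_that("caller equals a brute-force reference on short chromosomes", {
  for (seed in c(31, 32, 33)) {
    cfg <- simConfig(seed = seed, chromSizes = c(chrI = 1e4), nGenes = 1,
                     nPeaks = 1, peakHeight = 40)
    truth <- data.frame(chrom = "chrI", center = 3000L + 1000L * (seed - 31),
                        class = "upstream", gene_id = "g1",
                        stringsAsFactors = FALSE)
    sim <- simulateChipCoverage(empty_annotation(c(chrI = 1e4)), cfg,
                                truth = truth)
    tr <- sim$tracks[[1]]
    fast <- peakRanges(callPeaks(tr))
    slow <- brute_call(tr)
    expect_equal(length(fast), nrow(slow))
    if (nrow(slow)) {
      expect_equal(GenomicRanges::start(fast), slow$start)
      expect_equal(GenomicRanges::end(fast), slow$end)
      expect_equal(fast$shift, slow$shift)
    }
  }
})

test_that("multi-chromosome samples pool the background and keep seqlevels", {
  cfg <- simConfig(seed = 9, chromSizes = c(chrI = 3e5, chrII = 2e5),
                   nGenes = 25, nPeaks = 6)
  sim <- simulateChipDataset(cfg)
  ps <- callPeaks(sim$tracks)
  expect_true(all(as.character(GenomeInfoDb::seqnames(peakRanges(ps))) %in%
                    c("chrI", "chrII")))
  counts <- attr(ps, "stageCounts")
  expect_gte(counts$candidateRegions, counts$fdrPassed)
  expect_gte(counts$fdrPassed, counts$shiftPassed)
})
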