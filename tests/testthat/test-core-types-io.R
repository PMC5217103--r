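# Shared data model and format round-trips.

test_that("GFF3 reading preserves 1-based coordinates, strand, and sizes", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "##sequence-region chrI 1 10000",
               "chrI\t.\tgene\t101\t200\t.\t+\t.\tID=g1",
               "chrI\t.\tgene\t301\t450\t.\t-\t.\tID=g2"), gff)
  ann <- readGeneAnnotation(gff)
  g <- geneModels(ann)
  expect_equal(names(g), c("g1", "g2"))
  expect_equal(GenomicRanges::start(g), c(101L, 301L))
  expect_equal(GenomicRanges::end(g), c(200L, 450L))
  expect_equal(as.character(GenomicRanges::strand(g)), c("+", "-"))
  expect_equal(unname(chromSizes(ann)["chrI"]), 10000)
})

test_that("GFF3 edge cases: empty file, malformed record, unknown chrom", {
  empty <- withr::local_tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty)
  expect_equal(length(readGeneAnnotation(empty)), 0L)

  bad <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chrI\t.\tgene\t500\t400\t.\t+\t.\tID=g1"), bad)
  expect_error(readGeneAnnotation(bad), "line 2.*end < start")

  ok <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chrX\t.\tgene\t10\t99\t.\t+\t.\tID=g1"), ok)
  expect_error(readGeneAnnotation(ok, chromSizes = c(chrI = 1000)),
               "unknown chromosome")
})

test_that("annotation write/read round-trips coordinates exactly", {
  ann <- simulateAnnotation(simConfig(seed = 4, nGenes = 25,
                                      chromSizes = c(chrI = 5e5)))
  path <- withr::local_tempfile(fileext = ".gff3")
  writeGeneAnnotation(ann, path)
  back <- readGeneAnnotation(path)
  expect_equal(names(geneModels(back)), names(geneModels(ann)))
  expect_equal(GenomicRanges::start(geneModels(back)),
               GenomicRanges::start(geneModels(ann)))
  expect_equal(GenomicRanges::end(geneModels(back)),
               GenomicRanges::end(geneModels(ann)))
  expect_equal(as.character(GenomicRanges::strand(geneModels(back))),
               as.character(GenomicRanges::strand(geneModels(ann))))
  expect_equal(chromSizes(back), chromSizes(ann))
})

test_that("bedGraph pairs densify to per-base vectors with zero default", {
  fwd <- withr::local_tempfile(fileext = ".bedgraph")
  rev <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines("chrI\t10\t13\t4", fwd)     # 0-based half-open [10,13)
  writeLines("chrI\t0\t2\t1", rev)
  ct <- readCoverageTrack(fwd, rev, c(chrI = 20))
  expected_f <- numeric(20); expected_f[11:13] <- 4
  expected_r <- numeric(20); expected_r[1:2] <- 1
  expect_equal(fwdCoverage(ct), expected_f)
  expect_equal(revCoverage(ct), expected_r)
})

test_that("bedGraph validation: chrom mismatch, overlap, out of bounds", {
  a <- withr::local_tempfile(); b <- withr::local_tempfile()
  writeLines("chrI\t0\t5\t1", a)
  writeLines("chrII\t0\t5\t1", b)
  expect_error(readCoverageTrack(a, b, c(chrI = 20, chrII = 20)),
               "strand tracks disagree")
  ov <- withr::local_tempfile()
  writeLines(c("chrI\t0\t5\t1", "chrI\t3\t8\t2"), ov)
  expect_error(readCoverageTrack(ov, a, c(chrI = 20)), "overlapping")
  far <- withr::local_tempfile()
  writeLines("chrI\t10\t30\t1", far)
  expect_error(readCoverageTrack(far, a, c(chrI = 20)), "beyond end")
})

test_that("coverage track write/read round-trips including zero runs", {
  set.seed(42)
  ct <- CoverageTrack("chrI", rbinom(500, 5, 0.3), rbinom(500, 5, 0.3))
  f <- withr::local_tempfile(); r <- withr::local_tempfile()
  writeCoverageTrack(ct, f, r)
  back <- readCoverageTrack(f, r, c(chrI = 500))
  expect_equal(fwdCoverage(back), fwdCoverage(ct))
  expect_equal(revCoverage(back), revCoverage(ct))
})

test_that("BED6 reads convert to stranded coverage", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrI\t0\t10\tr1\t0\t+", "chrI\t5\t15\tr2\t0\t-"), bed)
  ct <- readBedReads(bed, c(chrI = 30))
  expect_equal(sum(fwdCoverage(ct)), 10)
  expect_equal(sum(revCoverage(ct)), 10)
  expect_equal(which(revCoverage(ct) > 0), 6:15)
})

test_that("narrowPeak output uses 0-based half-open starts and summit offsets", {
  gr <- GenomicRanges::GRanges("chrI", IRanges::IRanges(101, 260),
          summit = 181L, minP = 1e-5, regionP = 1e-3, q = 1e-3,
          shift = 70L, passedShift = TRUE, signal = 33)
  ps <- PeakSet(gr)
  path <- withr::local_tempfile(fileext = ".narrowPeak")
  writePeaks(ps, path)
  f <- strsplit(readLines(path), "\t")[[1]]
  expect_equal(as.integer(f[2]), 100L)   # chromStart, 0-based
  expect_equal(as.integer(f[3]), 260L)   # chromEnd, half-open
  expect_equal(as.integer(f[10]), 80L)   # summit offset from start
})

test_that("narrowPeak caps -log10(0) and round-trips coordinates", {
  gr <- GenomicRanges::GRanges("chrI", IRanges::IRanges(c(101, 501), c(260, 700)),
          summit = c(181L, 600L), minP = c(0, 1e-6), regionP = c(0, 1e-2),
          q = c(0, 1e-2), shift = c(70L, 65L), passedShift = c(TRUE, TRUE),
          signal = c(33, 21))
  ps <- PeakSet(gr)
  path <- withr::local_tempfile()
  writePeaks(ps, path)
  df <- read.table(path, sep = "\t")
  expect_equal(df$V8[1], 400)   # -log10(0) written at the cap
  back <- readPeaks(path)
  expect_equal(GenomicRanges::start(peakRanges(back)),
               GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(peakRanges(back)), GenomicRanges::end(gr))
  expect_equal(peakRanges(back)$summit, gr$summit)

  empty <- withr::local_tempfile()
  writePeaks(PeakSet(), empty)
  expect_equal(length(readLines(empty)), 0L)
  expect_equal(length(readPeaks(empty)), 0L)
})

test_that("DE table reader handles Cuffdiff schema and orientation flag", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("gene_id", "sample_1", "sample_2", "value_1", "value_2",
                     "log2(fold_change)", "p_value", "q_value", sep = "\t"),
               paste("g1", "WT", "mut", "100", "10", "-3.3219", "0.001",
                     "0.01", sep = "\t")), path)
  de <- readDETable(path)
  expect_equal(de$log2fc, -3.3219)
  expect_equal(de$fpkm_wt, 100)
  flipped <- readDETable(path, orientation = "wt_vs_mut")
  expect_equal(flipped$log2fc, 3.3219)

  bad <- withr::local_tempfile()
  writeLines(c("gene_id\tvalue_1\tvalue_2\tp_value", "g1\t1\t2\t0.5"), bad)
  expect_error(readDETable(bad), "q")
})

test_that("class validity catches malformed objects", {
  expect_error(CoverageTrack("chrI", c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(CoverageTrack("chrI", c(-1, 2), c(1, 2)), "non-negative")
  gr <- suppressWarnings(
    GenomicRanges::GRanges("chrI", IRanges::IRanges(1, 200),
                           strand = "+", seqlengths = c(chrI = 100)))
  names(gr) <- "g1"
  expect_error(GenomeAnnotation(gr), "chromosome bounds")
  gr2 <- GenomicRanges::GRanges("chrI", IRanges::IRanges(c(1, 10), c(5, 20)),
                                strand = "+", seqlengths = c(chrI = 100))
  names(gr2) <- c("g1", "g1")
  expect_error(GenomeAnnotation(gr2), "unique")
  pk <- GenomicRanges::GRanges("chrI", IRanges::IRanges(100, 300),
          summit = 500L, minP = 0.5, regionP = 0.5, q = 0.5, shift = 0L,
          passedShift = FALSE, signal = 1)
  expect_error(PeakSet(pk), "summit")
})

test_that("time-series CSV reader enforces increasing time", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_h,value,replicate_id", "0,5,a", "1.5,6,a", "0,4,b",
               "1.5,5,b"), path)
  ts <- readTimeSeries(path)
  expect_equal(nrow(ts), 4L)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_h,value,replicate_id", "3,5,a", "1.5,6,a"), bad)
  expect_error(readTimeSeries(bad), "strictly increasing")
})
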