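# Small in-code fixtures shared across test files.

# two-chromosome toy annotation built by hand: a + gene, a - gene, and a
# divergent head-to-head pair on chrI
tiny_annotation <- function() {
  gr <- GenomicRanges::GRanges(
    c("chrI", "chrI", "chrI", "chrII"),
    IRanges::IRanges(start = c(10001, 20001, 23001, 5001),
                     end = c(12000, 21500, 25000, 8000)),
    strand = c("+", "-", "+", "-"),
    seqlengths = c(chrI = 50000, chrII = 20000))
  names(gr) <- c("gA", "gDivL", "gDivR", "gB")
  GenomeAnnotation(gr, genomeGeneCount = 10L)
}

# an annotation with no gene models, just chromosome sizes
empty_annotation <- function(chromSizes) {
  gr <- GenomicRanges::GRanges()
  GenomeInfoDb::seqlevels(gr) <- names(chromSizes)
  GenomeInfoDb::seqlengths(gr) <- unname(chromSizes)
  GenomeAnnotation(gr, genomeGeneCount = 0L)
}

# a PeakSet with given summits (width 201 regions centered on each summit)
peakset_at <- function(summits, chrom = "chrI", chromSizes = c(chrI = 50000)) {
  n <- length(summits)
  gr <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(summits - 100L, summits + 100L),
    summit = as.integer(summits), minP = rep(1e-8, n),
    regionP = rep(1e-4, n), q = rep(1e-4, n),
    shift = rep(70L, n), passedShift = rep(TRUE, n),
    signal = rep(50, n),
    seqlengths = chromSizes[chrom])
  PeakSet(gr)
}

# brute-force peak-to-gene assignment: straight double loop over the window
# predicates, independent of the GRanges-based implementation
brute_assign <- function(peaks, annotation, upBp = 5000, downBp = 3000) {
  pk <- peakRanges(peaks)
  genes <- geneModels(annotation)
  rows <- list()
  for (p in seq_along(pk)) {
    s <- pk$summit[p]
    pchr <- as.character(GenomeInfoDb::seqnames(pk))[p]
    for (g in seq_along(genes)) {
      if (as.character(GenomeInfoDb::seqnames(genes))[g] != pchr) next
      gs <- GenomicRanges::start(genes)[g]
      ge <- GenomicRanges::end(genes)[g]
      plus <- as.character(GenomicRanges::strand(genes))[g] == "+"
      tss <- if (plus) gs else ge
      tes <- if (plus) ge else gs
      cls <- NA; dist <- NA
      if (s >= gs && s <= ge) {
        cls <- "genic"; dist <- 0
      } else if (plus && s < gs && tss - s <= upBp) {
        cls <- "upstream"; dist <- tss - s
      } else if (!plus && s > ge && s - tss <= upBp) {
        cls <- "upstream"; dist <- s - tss
      } else if (plus && s > ge && s - tes <= downBp) {
        cls <- "downstream"; dist <- s - tes
      } else if (!plus && s < gs && tes - s <= downBp) {
        cls <- "downstream"; dist <- tes - s
      }
      if (!is.na(cls))
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = names(genes)[g], peak_id = p,
          location_class = cls, distance = as.integer(dist),
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene_id = character(), peak_id = integer(),
                      location_class = character(), distance = integer()))
  df <- do.call(rbind, rows)
  df[order(df$peak_id, df$gene_id), ]
}

# brute-force peak caller on one short chromosome: enumerates positions and
# applies the published rules naively, mirroring callPeaks() semantics
brute_call <- function(track, cfg = peakCallerConfig()) {
  bg <- fitBackground(track)
  cc <- combinedCoverage(track)
  p <- ifelse(cc > 0, pnorm(log(pmax(cc, 1e-300)), bg@mu, bg@sigma,
                            lower.tail = FALSE), 1)
  enriched <- cc > 0 & p <= cfg$alphaPosition
  # naive run merging with gap joining
  regions <- list(); i <- 1L; L <- length(cc)
  while (i <= L) {
    if (!enriched[i]) { i <- i + 1L; next }
    start <- i; end <- i; j <- i + 1L; gap <- 0L
    while (j <= L && gap <= cfg$maxMergeGap) {
      if (enriched[j]) { end <- j; gap <- 0L } else gap <- gap + 1L
      j <- j + 1L
    }
    regions[[length(regions) + 1L]] <- c(start, end)
    i <- end + 1L
  }
  keep <- Filter(function(r) (r[2] - r[1] + 1) > cfg$minRegionLen, regions)
  if (!length(keep)) return(data.frame(start = integer(), end = integer()))
  minP <- vapply(keep, function(r) min(p[r[1]:r[2]]), numeric(1))
  regionP <- 1 - (1 - minP)^L
  q <- p.adjust(regionP, "BH")
  out <- list()
  for (k in seq_along(keep)) {
    if (q[k] >= cfg$fdr) next
    r <- keep[[k]]
    sh <- estimateShift(IRanges::IRanges(r[1], r[2]), track, cfg)
    if (!sh$passed) next
    out[[length(out) + 1L]] <- data.frame(start = r[1], end = r[2],
                                          shift = sh$shift)
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer()))
  do.call(rbind, out)
}
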