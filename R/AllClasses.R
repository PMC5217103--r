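#' @import methods
#' @importFrom stats cor lm lm.fit coef pnorm qnorm p.adjust phyper rlnorm
#'   rnorm rbinom runif sd var setNames residuals
#' @importFrom utils read.table write.table head
NULL

#' Stranded per-base coverage for one chromosome
#'
#' Holds dense forward- and reverse-strand read coverage vectors for a single
#' chromosome of one ChIP sample. Coverage is per base: element \code{i} is
#' the number of reads (or read-anchored fragments) covering base \code{i}
#' (1-based). Values are non-negative but not required to be integer, so
#' model-exact continuous coverage can also be represented.
#'
#' @slot chrom single chromosome name.
#' @slot fwd numeric vector of forward-strand coverage.
#' @slot rev numeric vector of reverse-strand coverage, same length as
#'   \code{fwd}.
#'
#' @seealso [CoverageTrack()] constructor, [readCoverageTrack()],
#'   [fitBackground()], [callPeaks()]
#' @export
setClass("CoverageTrack",
  representation(chrom = "character", fwd = "numeric", rev = "numeric"))

setValidity("CoverageTrack", function(object) {
  msg <- character()
  if (length(object@chrom) != 1L || is.na(object@chrom) || !nzchar(object@chrom))
    msg <- c(msg, "'chrom' must be a single non-empty string")
  if (length(object@fwd) != length(object@rev))
    msg <- c(msg, "forward and reverse coverage must have equal length")
  if (length(object@fwd) && (anyNA(object@fwd) || anyNA(object@rev)))
    msg <- c(msg, "coverage must not contain NA")
  if (length(object@fwd) && (min(object@fwd) < 0 || min(object@rev) < 0))
    msg <- c(msg, "coverage must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @rdname CoverageTrack-class
#' @param chrom chromosome name.
#' @param fwd,rev per-base coverage vectors (equal length).
#' @return A \code{CoverageTrack} object.
#' @examples
#' ct <- CoverageTrack("chrI", fwd = c(0, 2, 3, 1), rev = c(1, 0, 2, 2))
#' combinedCoverage(ct)
#' @export
CoverageTrack <- function(chrom, fwd, rev) {
  new("CoverageTrack", chrom = as.character(chrom),
      fwd = as.numeric(fwd), rev = as.numeric(rev))
}

#' Gene annotation with chromosome sizes
#'
#' Wraps a [GenomicRanges::GRanges] of single-interval gene models (1-based
#' closed coordinates, named by gene id, strand \code{+}/\code{-}) together
#' with the total number of genes predicted in the genome, which may exceed
#' the number of models listed (used as the enrichment population size).
#' Chromosome lengths live in the \code{seqinfo} of the ranges.
#'
#' @slot genes \code{GRanges} of gene spans; \code{names()} are gene ids.
#' @slot genomeGeneCount total predicted gene count for the genome.
#'
#' @seealso [GenomeAnnotation()], [readGeneAnnotation()], [assignPeaks()]
#' @export
setClass("GenomeAnnotation",
  representation(genes = "GRanges", genomeGeneCount = "integer"))

setValidity("GenomeAnnotation", function(object) {
  g <- object@genes
  msg <- character()
  if (length(g)) {
    if (is.null(names(g)) || anyNA(names(g)) || any(!nzchar(names(g))))
      msg <- c(msg, "all genes must be named by gene id")
    else if (anyDuplicated(names(g)))
      msg <- c(msg, "gene ids must be unique within an annotation")
    if (any(!as.character(GenomicRanges::strand(g)) %in% c("+", "-")))
      msg <- c(msg, "gene strand must be '+' or '-'")
    sl <- GenomeInfoDb::seqlengths(g)
    if (anyNA(sl))
      msg <- c(msg, "all chromosomes must carry a length")
    else {
      ends <- GenomicRanges::end(g)
      lim <- sl[as.character(GenomeInfoDb::seqnames(g))]
      if (any(ends > lim) || any(GenomicRanges::start(g) < 1L))
        msg <- c(msg, "genes must lie within chromosome bounds")
    }
  }
  if (length(object@genomeGeneCount) != 1L || is.na(object@genomeGeneCount))
    msg <- c(msg, "'genomeGeneCount' must be a single integer")
  else if (object@genomeGeneCount < length(g))
    msg <- c(msg, "'genomeGeneCount' must be >= number of genes listed")
  if (length(msg)) msg else TRUE
})

#' @rdname GenomeAnnotation-class
#' @param genes \code{GRanges} with names, strand, and seqlengths set.
#' @param genomeGeneCount total predicted genes in the genome; defaults to
#'   \code{length(genes)}.
#' @return A \code{GenomeAnnotation} object.
#' @export
GenomeAnnotation <- function(genes, genomeGeneCount = length(genes)) {
  new("GenomeAnnotation", genes = genes,
      genomeGeneCount = as.integer(genomeGeneCount))
}

#' Set of called ChIP-seq peaks
#'
#' A container for retained enriched regions. Backing store is a
#' [GenomicRanges::GRanges] whose metadata columns carry, per peak, the
#' summit (absolute base of maximal combined coverage), the smallest
#' per-position tail probability inside the region (\code{minP}), the
#' length-adjusted region p-value (\code{regionP}), the BH-adjusted q,
#' the estimated forward-to-reverse strand shift in bp (\code{-1} when
#' undefined), whether the shift filter passed, and a signal value (maximal
#' combined coverage).
#'
#' @slot peaks \code{GRanges} with metadata columns \code{summit, minP,
#'   regionP, q, shift, passedShift, signal}.
#' @seealso [callPeaks()], [writePeaks()], [readPeaks()]
#' @export
setClass("PeakSet", representation(peaks = "GRanges"))

.peakset_cols <- c("summit", "minP", "regionP", "q", "shift",
                   "passedShift", "signal")

setValidity("PeakSet", function(object) {
  g <- object@peaks
  msg <- character()
  mc <- S4Vectors::mcols(g)
  miss <- setdiff(.peakset_cols, colnames(mc))
  if (length(miss))
    return(paste("missing peak columns:", paste(miss, collapse = ", ")))
  if (length(g)) {
    if (any(mc$summit < GenomicRanges::start(g)) ||
        any(mc$summit > GenomicRanges::end(g)))
      msg <- c(msg, "summit must lie within the peak region")
    if (any(mc$minP < 0) || any(mc$minP > 1))
      msg <- c(msg, "minP must be in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname PeakSet-class
#' @param peaks \code{GRanges} carrying the peak metadata columns.
#' @return A \code{PeakSet}.
#' @export
PeakSet <- function(peaks = GenomicRanges::GRanges(
    summit = integer(), minP = numeric(), regionP = numeric(), q = numeric(),
    shift = integer(), passedShift = logical(), signal = numeric())) {
  new("PeakSet", peaks = peaks)
}

#' Lognormal background model for ChIP coverage
#'
#' Parameters of the background law fitted to positive combined coverage:
#' \code{ln(fwd + rev) ~ Normal(mu, sigma)} over bases with coverage > 0.
#'
#' @slot mu mean of log coverage on positive bases.
#' @slot sigma standard deviation of log coverage.
#' @slot nFit number of positive-coverage bases used in the fit.
#' @slot degenerate \code{TRUE} when \code{sigma < 1e-6}; such a background
#'   cannot be used for tail-probability scoring.
#' @seealso [fitBackground()], [scorePositions()]
#' @export
setClass("LognormalBackground",
  representation(mu = "numeric", sigma = "numeric", nFit = "integer",
                 degenerate = "logical"))

setValidity("LognormalBackground", function(object) {
  if (length(object@sigma) == 1L && !is.na(object@sigma) && object@sigma < 0)
    return("sigma must be >= 0")
  if (!identical(object@degenerate, object@sigma < 1e-6))
    return("degenerate flag must equal (sigma < 1e-6)")
  TRUE
})
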