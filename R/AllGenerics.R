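#' @rdname CoverageTrack-class
#' @param object,x a \code{CoverageTrack}, \code{GenomeAnnotation},
#'   \code{PeakSet} or \code{LognormalBackground} as appropriate.
#' @export
setGeneric("chromName", function(x) standardGeneric("chromName"))

#' @rdname CoverageTrack-class
#' @export
setGeneric("fwdCoverage", function(x) standardGeneric("fwdCoverage"))

#' @rdname CoverageTrack-class
#' @export
setGeneric("revCoverage", function(x) standardGeneric("revCoverage"))

#' @rdname CoverageTrack-class
#' @export
setGeneric("combinedCoverage", function(x) standardGeneric("combinedCoverage"))

#' @rdname GenomeAnnotation-class
#' @export
setGeneric("geneModels", function(x) standardGeneric("geneModels"))

#' @rdname GenomeAnnotation-class
#' @export
setGeneric("chromSizes", function(x) standardGeneric("chromSizes"))

#' @rdname GenomeAnnotation-class
#' @export
setGeneric("genomeGeneCount", function(x) standardGeneric("genomeGeneCount"))

#' @rdname PeakSet-class
#' @export
setGeneric("peakRanges", function(x) standardGeneric("peakRanges"))

#' @describeIn CoverageTrack-class chromosome name.
setMethod("chromName", "CoverageTrack", function(x) x@chrom)

#' @describeIn CoverageTrack-class forward-strand coverage vector.
setMethod("fwdCoverage", "CoverageTrack", function(x) x@fwd)

#' @describeIn CoverageTrack-class reverse-strand coverage vector.
setMethod("revCoverage", "CoverageTrack", function(x) x@rev)

#' @describeIn CoverageTrack-class per-base \code{fwd + rev} coverage.
setMethod("combinedCoverage", "CoverageTrack", function(x) x@fwd + x@rev)

#' @describeIn CoverageTrack-class chromosome length in bp.
#' @export
setMethod("length", "CoverageTrack", function(x) length(x@fwd))

setMethod("show", "CoverageTrack", function(object) {
  cat("CoverageTrack on", object@chrom, "(", length(object@fwd), "bp )\n")
  cat("  total fwd/rev coverage:", sum(object@fwd), "/", sum(object@rev), "\n")
})

#' @describeIn GenomeAnnotation-class the gene \code{GRanges}.
setMethod("geneModels", "GenomeAnnotation", function(x) x@genes)

#' @describeIn GenomeAnnotation-class named vector of chromosome lengths.
setMethod("chromSizes", "GenomeAnnotation",
          function(x) GenomeInfoDb::seqlengths(x@genes))

#' @describeIn GenomeAnnotation-class total predicted genes in the genome.
setMethod("genomeGeneCount", "GenomeAnnotation",
          function(x) x@genomeGeneCount)

#' @describeIn GenomeAnnotation-class number of gene models listed.
#' @export
setMethod("length", "GenomeAnnotation", function(x) length(x@genes))

setMethod("show", "GenomeAnnotation", function(object) {
  cat("GenomeAnnotation:", length(object@genes), "gene models on",
      length(chromSizes(object)), "chromosome(s);",
      object@genomeGeneCount, "genes in genome\n")
})

#' @describeIn PeakSet-class the underlying \code{GRanges}.
setMethod("peakRanges", "PeakSet", function(x) x@peaks)

#' @describeIn PeakSet-class number of peaks.
#' @export
setMethod("length", "PeakSet", function(x) length(x@peaks))

#' @describeIn PeakSet-class peaks as a plain data.frame.
#' @param row.names,optional,... passed on conventionally; unused.
#' @export
setMethod("as.data.frame", "PeakSet",
  function(x, row.names = NULL, optional = FALSE, ...) {
    as.data.frame(x@peaks, row.names = row.names, optional = optional, ...)
  })

setMethod("show", "PeakSet", function(object) {
  cat("PeakSet with", length(object@peaks), "retained peak(s)\n")
  if (length(object@peaks)) show(object@peaks)
})

setMethod("show", "LognormalBackground", function(object) {
  cat(sprintf("LognormalBackground: mu = %.4f, sigma = %.4f (n = %d%s)\n",
              object@mu, object@sigma, object@nFit,
              if (object@degenerate) ", degenerate" else ""))
})
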