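# Peak-to-gene assignment with strand-aware distance windows: a peak is a
# candidate regulator of a gene when its summit lies within 5 kb upstream of
# the transcription start site, within the gene span, or within 3 kb
# downstream of the transcription end site (both window sizes configurable,
# inclusive). One peak between two divergently transcribed genes is assigned
# to both.

.loc_priority <- c(genic = 3L, upstream = 2L, downstream = 1L)

#' Assign peaks to genes by distance windows
#'
#' Distances are measured from the peak summit. For a \code{+}-strand gene
#' the TSS is the gene start and the TES the gene end; for a \code{-}-strand
#' gene the TSS is the end and the TES the start. A summit is
#' \describe{
#'   \item{genic}{within the gene span (distance 0),}
#'   \item{upstream}{within \code{upBp} of the TSS on the gene's 5' side
#'     (distance = bp from summit to TSS, in \code{[1, upBp]}),}
#'   \item{downstream}{within \code{downBp} of the TES on the gene's 3' side
#'     (distance in \code{[1, downBp]}).}
#' }
#' A peak may be assigned to several genes (divergent promoters); for a
#' single (peak, gene) pair, class priority is genic > upstream > downstream.
#' With \code{anchor = "edges"} the window predicates are evaluated against
#' the nearest region edge instead of the summit.
#'
#' @param peaks a [PeakSet].
#' @param annotation a [GenomeAnnotation].
#' @param upBp upstream window in bp (default 5000, inclusive).
#' @param downBp downstream window in bp (default 3000, inclusive).
#' @param anchor \code{"summit"} (default) or \code{"edges"}.
#' @return data.frame with one row per (peak, gene) assignment: columns
#'   \code{gene_id, peak_id, chrom, peak_start, peak_end, summit,
#'   location_class, distance}.
#' @examples
#' ann <- simulateAnnotation(simConfig(seed = 2, nGenes = 20,
#'                                     chromSizes = c(chrI = 4e5)))
#' sim <- simulateChipDataset(simConfig(seed = 2, nGenes = 20,
#'                                      chromSizes = c(chrI = 4e5), nPeaks = 5))
#' asn <- assignPeaks(callPeaks(sim$tracks), sim$annotation)
#' head(asn)
#' @export
assignPeaks <- function(peaks, annotation, upBp = 5000L, downBp = 3000L,
                        anchor = c("summit", "edges")) {
  anchor <- match.arg(anchor)
  stopifnot(is(peaks, "PeakSet"), is(annotation, "GenomeAnnotation"))
  pk <- peakRanges(peaks)
  genes <- geneModels(annotation)
  empty <- data.frame(gene_id = character(), peak_id = integer(),
                      chrom = character(), peak_start = integer(),
                      peak_end = integer(), summit = integer(),
                      location_class = character(), distance = integer(),
                      stringsAsFactors = FALSE)
  if (!length(pk) || !length(genes)) return(empty)
  unknown <- setdiff(unique(as.character(GenomeInfoDb::seqnames(pk))),
                     names(chromSizes(annotation)))
  if (length(unknown))
    stop("unknown chromosome in peaks: ", paste(unknown, collapse = ", "),
         call. = FALSE)

  # anchor points of each peak: summit, or both region edges
  if (anchor == "summit") {
    anch <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(pk),
              IRanges::IRanges(pk$summit, width = 1L))
    anch_peak <- seq_along(pk)
  } else {
    anch <- c(GenomicRanges::GRanges(GenomeInfoDb::seqnames(pk),
                IRanges::IRanges(GenomicRanges::start(pk), width = 1L)),
              GenomicRanges::GRanges(GenomeInfoDb::seqnames(pk),
                IRanges::IRanges(GenomicRanges::end(pk), width = 1L)))
    anch_peak <- rep(seq_along(pk), 2L)
  }

  plus <- as.character(GenomicRanges::strand(genes)) == "+"
  gs <- GenomicRanges::start(genes); ge <- GenomicRanges::end(genes)
  tss <- ifelse(plus, gs, ge)
  tes <- ifelse(plus, ge, gs)

  window_gr <- function(lo, hi) {
    ok <- lo <= hi & hi >= 1L
    GenomicRanges::GRanges(GenomeInfoDb::seqnames(genes)[ok],
      IRanges::IRanges(pmax(1L, lo[ok]), hi[ok]), gene = which(ok))
  }
  # upstream: 5' of TSS; downstream: 3' of TES (strand-aware), clipped at 1
  up <- window_gr(ifelse(plus, gs - upBp, ge + 1L),
                  ifelse(plus, gs - 1L, ge + upBp))
  dn <- window_gr(ifelse(plus, ge + 1L, gs - downBp),
                  ifelse(plus, ge + downBp, gs - 1L))
  genic <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(genes),
             IRanges::IRanges(gs, ge), gene = seq_along(genes))

  hit_rows <- function(windows, class) {
    h <- GenomicRanges::findOverlaps(anch, windows, ignore.strand = TRUE)
    if (!length(h)) return(NULL)
    gi <- windows$gene[S4Vectors::subjectHits(h)]
    pi <- anch_peak[S4Vectors::queryHits(h)]
    pos <- GenomicRanges::start(anch)[S4Vectors::queryHits(h)]
    dist <- switch(class,
      genic = rep(0L, length(h)),
      upstream = abs(tss[gi] - pos),
      downstream = abs(pos - tes[gi]))
    data.frame(gene = gi, peak = pi, pos = pos, class = class,
               distance = as.integer(dist), stringsAsFactors = FALSE)
  }
  hits <- rbind(hit_rows(genic, "genic"), hit_rows(up, "upstream"),
                hit_rows(dn, "downstream"))
  if (is.null(hits) || !nrow(hits)) return(empty)

  # per (peak, gene): keep the highest-priority class (smallest distance on
  # the rare tie within a class, from edge anchors)
  hits <- hits[order(hits$peak, hits$gene,
                     -.loc_priority[hits$class], hits$distance), ]
  hits <- hits[!duplicated(hits[c("peak", "gene")]), ]

  data.frame(
    gene_id = names(genes)[hits$gene],
    peak_id = hits$peak,
    chrom = as.character(GenomeInfoDb::seqnames(pk))[hits$peak],
    peak_start = GenomicRanges::start(pk)[hits$peak],
    peak_end = GenomicRanges::end(pk)[hits$peak],
    summit = pk$summit[hits$peak],
    location_class = hits$class,
    distance = hits$distance,
    stringsAsFactors = FALSE)
}

#' Union of target genes across conditions
#'
#' @param perCondition a list of assignment data.frames (from
#'   [assignPeaks()]) or of gene-id character vectors, one per condition.
#' @return sorted character vector of unique target gene ids.
#' @export
unionTargets <- function(perCondition) {
  stopifnot(length(perCondition) >= 1L)
  ids <- lapply(perCondition, function(x) {
    if (is.data.frame(x)) x$gene_id else as.character(x)
  })
  sort(unique(unlist(ids, use.names = FALSE)))
}

#' Distribution of binding locations
#'
#' Each peak is counted once with its highest-priority class across all of
#' its gene assignments (genic > upstream > downstream), and the fractions
#' of peaks in each class are returned.
#'
#' @param assignments data.frame from [assignPeaks()].
#' @return named numeric vector \code{c(upstream, downstream, genic)}
#'   summing to 1.
#' @export
locationDistribution <- function(assignments) {
  if (!is.data.frame(assignments) || !nrow(assignments))
    stop("no assignments: location distribution undefined", call. = FALSE)
  pr <- .loc_priority[assignments$location_class]
  best <- vapply(split(pr, assignments$peak_id), max, integer(1))
  cls <- names(.loc_priority)[match(best, .loc_priority)]
  n <- length(best)
  c(upstream = sum(cls == "upstream") / n,
    downstream = sum(cls == "downstream") / n,
    genic = sum(cls == "genic") / n)
}
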