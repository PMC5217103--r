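# Gene-set integration: light/clock membership partition of a focal gene
# set, hypergeometric over-representation of term annotations, and
# reproducibility of peak sets between growth conditions as the squared
# Pearson correlation of per-interval coverage sums.

#' Partition a gene set by light and clock membership
#'
#' Exact four-way partition of the focal set into light-and-clock,
#' light-only, clock-only, and neither, with counts, gene lists, and
#' percentages of the focal set.
#'
#' @param focal character vector of gene ids (non-empty).
#' @param lightSet,clockSet character vectors of light-regulated and
#'   clock-controlled gene ids.
#' @return list with \code{counts} (named integer vector), \code{percent}
#'   (named numeric, sums to 100), and \code{genes} (named list of ids);
#'   cell names \code{both, light_only, clock_only, neither}.
#' @examples
#' partitionMembership(c("a", "b", "c", "d"), lightSet = c("a", "b"),
#'                     clockSet = c("b", "c"))$percent
#' @export
partitionMembership <- function(focal, lightSet, clockSet) {
  focal <- unique(focal)
  if (!length(focal)) stop("empty focal set", call. = FALSE)
  inL <- focal %in% lightSet
  inC <- focal %in% clockSet
  genes <- list(both = focal[inL & inC],
                light_only = focal[inL & !inC],
                clock_only = focal[!inL & inC],
                neither = focal[!inL & !inC])
  counts <- vapply(genes, length, integer(1))
  list(counts = counts, percent = 100 * counts / length(focal), genes = genes)
}

#' Hypergeometric term enrichment
#'
#' For each term, over-representation of its genes in the study set relative
#' to the population is scored with the upper-tail hypergeometric
#' probability \code{P(X >= x)} where \code{x} is the number of study genes
#' annotated to the term, \code{K} the number of population genes annotated,
#' \code{n} the study size, and \code{N} the population size. p-values are
#' BH-adjusted across the terms tested. Terms annotating fewer than
#' \code{minTermSize} population genes are skipped as uninformative.
#'
#' @param study character vector of study gene ids (must be contained in
#'   \code{population}).
#' @param population character vector of background gene ids.
#' @param termMap named list mapping term id to a character vector of gene
#'   ids (genes outside the population are ignored).
#' @param minTermSize smallest population hit count tested (default 2).
#' @return data.frame with one row per tested term: \code{term_id, x, n, K,
#'   N, p, q}, sorted by p.
#' @examples
#' pop <- sprintf("g%02d", 1:20)
#' hypergeomEnrichment(pop[1:5], pop, list(T1 = pop[1:5]))
#' @export
hypergeomEnrichment <- function(study, population, termMap, minTermSize = 2L) {
  study <- unique(study); population <- unique(population)
  off <- setdiff(study, population)
  if (length(off))
    stop("study gene(s) absent from population: ",
         paste(head(off, 10), collapse = ", "), call. = FALSE)
  N <- length(population); n <- length(study)
  rows <- lapply(names(termMap), function(tid) {
    term_genes <- intersect(unique(termMap[[tid]]), population)
    K <- length(term_genes)
    if (K < minTermSize) return(NULL)
    x <- length(intersect(study, term_genes))
    p <- phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tid, x = x, n = n, K = K, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(term_id = character(), x = integer(), n = integer(),
                      K = integer(), N = integer(), p = numeric(),
                      q = numeric(), stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df$q <- p.adjust(df$p, method = "BH")
  df[order(df$p, df$term_id), ]
}

#' Peak-set reproducibility between two samples
#'
#' Takes the union of peak intervals from both sets, sums combined coverage
#' from each sample's track over every union interval, and returns the
#' squared Pearson correlation of the two \code{log2(x + 1)}-transformed
#' vectors. Symmetric in its arguments.
#'
#' @param peaksA,peaksB [PeakSet]s called in the two samples.
#' @param trackA,trackB the samples' [CoverageTrack]s (or named lists of
#'   tracks keyed by chromosome).
#' @return squared Pearson correlation (R^2).
#' @export
peakSetCorrelation <- function(peaksA, peaksB, trackA, trackB) {
  ta <- .as_track_list(trackA); tb <- .as_track_list(trackB)
  ga <- peakRanges(peaksA); gb <- peakRanges(peaksB)
  u <- GenomicRanges::reduce(c(GenomicRanges::granges(ga),
                               GenomicRanges::granges(gb)))
  if (!length(u)) stop("empty peak union", call. = FALSE)
  sums <- function(tracks) {
    vapply(seq_along(u), function(i) {
      chrom <- as.character(GenomeInfoDb::seqnames(u))[i]
      tr <- tracks[[chrom]]
      if (is.null(tr)) stop("no track for chromosome ", chrom, call. = FALSE)
      idx <- GenomicRanges::start(u)[i]:min(GenomicRanges::end(u)[i],
                                            length(tr))
      sum(combinedCoverage(tr)[idx])
    }, numeric(1))
  }
  cor(log2(sums(ta) + 1), log2(sums(tb) + 1))^2
}
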