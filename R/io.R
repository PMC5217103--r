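# Readers and writers for the standard formats consumed by the pipeline:
# GFF3 gene annotations, per-strand bedGraph coverage, BED6 read intervals,
# ENCODE narrowPeak output, differential-expression TSVs, time-series CSVs,
# and one-id-per-line gene-set files. Internal coordinates are GRanges
# (1-based closed); 0-based half-open conversion happens here only.

.stop_io <- function(...) stop(..., call. = FALSE)

# -- GFF3 ---------------------------------------------------------------

#' Read a gene annotation from GFF3
#'
#' Parses a GFF3 file and keeps \code{gene} features as single-interval gene
#' models. Chromosome lengths are taken from \code{##sequence-region}
#' pragmas, or from \code{chromSizes} when given (which also validates that
#' every gene's chromosome is known); when neither is available each
#' chromosome's length is set to the maximal gene end observed.
#'
#' @param path GFF3 file.
#' @param chromSizes optional named vector of chromosome lengths (bp).
#' @param genomeGeneCount total predicted genes in the genome; defaults to
#'   the number of gene features read.
#' @param featureType feature type(s) to keep (default \code{"gene"}).
#' @return A [GenomeAnnotation].
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3", "##sequence-region chrI 1 10000",
#'   "chrI\t.\tgene\t101\t200\t.\t+\t.\tID=g1"), gff)
#' ann <- readGeneAnnotation(gff)
#' geneModels(ann)
#' @export
readGeneAnnotation <- function(path, chromSizes = NULL,
                               genomeGeneCount = NULL,
                               featureType = "gene") {
  lines <- readLines(path)
  body <- which(!grepl("^\\s*(#|$)", lines))
  # line-numbered validation before handing to the parser
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L)
      .stop_io(sprintf("GFF3 parse error at line %d: expected >= 8 tab-separated fields", i))
    s <- suppressWarnings(as.numeric(f[4])); e <- suppressWarnings(as.numeric(f[5]))
    if (is.na(s) || is.na(e))
      .stop_io(sprintf("GFF3 parse error at line %d: non-numeric coordinates", i))
    if (e < s)
      .stop_io(sprintf("GFF3 parse error at line %d: end < start", i))
  }
  pragma <- grep("^##sequence-region", lines, value = TRUE)
  pragma_sizes <- NULL
  if (length(pragma)) {
    f <- do.call(rbind, strsplit(trimws(pragma), "\\s+"))
    pragma_sizes <- setNames(as.numeric(f[, 4]), f[, 2])
  }
  sizes <- if (!is.null(chromSizes)) chromSizes else pragma_sizes

  if (!length(body)) {
    gr <- GenomicRanges::GRanges()
    if (!is.null(sizes))
      GenomeInfoDb::seqlevels(gr) <- names(sizes)
    if (!is.null(sizes))
      GenomeInfoDb::seqlengths(gr) <- unname(sizes)
    return(GenomeAnnotation(gr, genomeGeneCount = genomeGeneCount %||% 0L))
  }

  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% featureType]
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) {
    nm <- gr$Name
    ids <- if (!is.null(nm)) ifelse(is.na(ids), nm, ids) else ids
  }
  if (is.null(ids) || anyNA(ids))
    .stop_io("GFF3 parse error: gene feature without ID attribute")
  names(gr) <- ids
  S4Vectors::mcols(gr) <- NULL
  if (is.null(sizes)) {
    sizes <- vapply(split(GenomicRanges::end(gr),
                          as.character(GenomeInfoDb::seqnames(gr))), max,
                    numeric(1))
  }
  unknown <- setdiff(GenomeInfoDb::seqlevelsInUse(gr), names(sizes))
  if (length(unknown))
    .stop_io("unknown chromosome in annotation: ", paste(unknown, collapse = ", "))
  GenomeInfoDb::seqlevels(gr) <- names(sizes)
  GenomeInfoDb::seqlengths(gr) <- unname(sizes)
  GenomeAnnotation(gr,
    genomeGeneCount = genomeGeneCount %||% length(gr))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a gene annotation as GFF3
#'
#' Emits one \code{gene} feature per model with its id in the \code{ID}
#' attribute and \code{##sequence-region} pragmas for chromosome lengths,
#' so that [readGeneAnnotation()] round-trips coordinates exactly.
#'
#' @param annotation a [GenomeAnnotation].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeGeneAnnotation <- function(annotation, path) {
  g <- geneModels(annotation)
  sizes <- chromSizes(annotation)
  hdr <- c("##gff-version 3",
           sprintf("##sequence-region %s 1 %d", names(sizes), as.integer(sizes)))
  rows <- if (length(g)) {
    sprintf("%s\tregulonscope\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            as.character(GenomeInfoDb::seqnames(g)),
            GenomicRanges::start(g), GenomicRanges::end(g),
            as.character(GenomicRanges::strand(g)), names(g))
  } else character()
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# -- bedGraph coverage --------------------------------------------------

.read_bedgraph <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "bedGraph"),
                 error = function(e) .stop_io("bedGraph parse error in ", path,
                                              ": ", conditionMessage(e)))
  gr
}

#' Read stranded coverage from a pair of bedGraph files
#'
#' Builds dense per-base forward/reverse coverage for one chromosome from
#' 0-based half-open bedGraph intervals. Bases not covered by any interval
#' are zero. Both files must describe the same single chromosome;
#' overlapping intervals within a strand, or intervals beyond the
#' chromosome end, are errors.
#'
#' @param fwdPath,revPath bedGraph files for the forward/reverse strand.
#' @param chromSizes named vector of chromosome lengths.
#' @return A [CoverageTrack].
#' @export
readCoverageTrack <- function(fwdPath, revPath, chromSizes) {
  dense <- function(gr, strand_lab) {
    chroms <- unique(as.character(GenomeInfoDb::seqnames(gr)))
    if (length(chroms) != 1L)
      .stop_io("coverage file must describe exactly one chromosome (",
               strand_lab, " strand has ", length(chroms), ")")
    if (!chroms %in% names(chromSizes))
      .stop_io("unknown chromosome in coverage: ", chroms)
    L <- as.integer(chromSizes[[chroms]])
    if (any(GenomicRanges::end(gr) > L))
      .stop_io("coverage interval beyond end of ", chroms)
    if (!IRanges::isDisjoint(gr))
      .stop_io("overlapping intervals on ", strand_lab, " strand")
    v <- numeric(L)
    s <- GenomicRanges::start(gr); e <- GenomicRanges::end(gr)
    for (i in seq_along(gr)) v[s[i]:e[i]] <- gr$score[i]
    list(chrom = chroms, cov = v)
  }
  f <- dense(.read_bedgraph(fwdPath), "forward")
  r <- dense(.read_bedgraph(revPath), "reverse")
  if (!identical(f$chrom, r$chrom))
    .stop_io("strand tracks disagree: forward is ", f$chrom,
             ", reverse is ", r$chrom)
  CoverageTrack(f$chrom, f$cov, r$cov)
}

#' Write a coverage track to a pair of bedGraph files
#'
#' Zero-coverage runs are omitted, matching the sparse bedGraph convention
#' read back by [readCoverageTrack()].
#'
#' @param track a [CoverageTrack].
#' @param fwdPath,revPath output bedGraph paths.
#' @return invisibly, \code{c(fwdPath, revPath)}.
#' @export
writeCoverageTrack <- function(track, fwdPath, revPath) {
  emit <- function(v, path) {
    r <- rle(v)
    e <- cumsum(r$lengths)
    s <- e - r$lengths          # 0-based starts
    keep <- r$values != 0
    df <- data.frame(chrom = chromName(track), start = s[keep], end = e[keep],
                     score = r$values[keep])
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  emit(fwdCoverage(track), fwdPath)
  emit(revCoverage(track), revPath)
  invisible(c(fwdPath, revPath))
}

#' Convert BED6 read intervals to a coverage track
#'
#' Optional input path: per-strand read coverage is computed from aligned
#' read intervals (BED6, 0-based half-open, strand in column 6).
#'
#' @param path BED6 file of aligned reads for one chromosome.
#' @param chromSizes named vector of chromosome lengths.
#' @return A [CoverageTrack].
#' @export
readBedReads <- function(path, chromSizes) {
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) .stop_io("BED parse error in ", path, ": ",
                                              conditionMessage(e)))
  chroms <- unique(as.character(GenomeInfoDb::seqnames(gr)))
  if (length(chroms) != 1L)
    .stop_io("BED reads must describe exactly one chromosome")
  if (!chroms %in% names(chromSizes))
    .stop_io("unknown chromosome in BED: ", chroms)
  L <- as.integer(chromSizes[[chroms]])
  if (any(GenomicRanges::end(gr) > L))
    .stop_io("read interval beyond end of ", chroms)
  one <- function(strand_sym) {
    sub <- gr[as.character(GenomicRanges::strand(gr)) == strand_sym]
    v <- numeric(L)
    if (length(sub)) {
      cov <- GenomicRanges::coverage(sub)[[chroms]]
      v[seq_len(length(cov))] <- as.numeric(cov)
    }
    v
  }
  CoverageTrack(chroms, one("+"), one("-"))
}

# -- narrowPeak ---------------------------------------------------------

#' Write peaks in ENCODE narrowPeak format
#'
#' Ten tab-separated columns, 0-based half-open: chrom, start, end, name,
#' score (0-1000), strand ("."), signalValue, -log10(p), -log10(q), and
#' summit offset from start. \code{-log10(0)} is written as \code{cap}.
#'
#' @param peaks a [PeakSet].
#' @param path output file.
#' @param cap finite stand-in for \code{-log10(0)} (default 400).
#' @return \code{path}, invisibly.
#' @export
writePeaks <- function(peaks, path, cap = 400) {
  g <- peakRanges(peaks)
  neglog10 <- function(p) ifelse(p <= 0, cap, pmin(-log10(p), cap))
  if (!length(g)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  mc <- S4Vectors::mcols(g)
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(g)),
    start = GenomicRanges::start(g) - 1L,
    end = GenomicRanges::end(g),
    name = sprintf("peak_%d", seq_along(g)),
    score = pmin(1000L, as.integer(round(10 * neglog10(mc$q)))),
    strand = ".",
    signalValue = mc$signal,
    pValue = neglog10(mc$minP),
    qValue = neglog10(mc$q),
    peak = mc$summit - GenomicRanges::start(g))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read peaks from a narrowPeak file written by [writePeaks()]
#'
#' @param path narrowPeak file.
#' @param chromSizes optional named chromosome lengths for the seqinfo.
#' @param cap the \code{-log10} cap used when writing (values at the cap
#'   are read back as p = 0).
#' @return A [PeakSet]. The shift/passedShift columns are not representable
#'   in narrowPeak and come back as \code{-1}/\code{TRUE} (all written peaks
#'   passed the filter); \code{regionP} is read back equal to \code{minP}.
#' @export
readPeaks <- function(path, chromSizes = NULL, cap = 400) {
  df <- tryCatch(
    read.table(path, sep = "\t", header = FALSE,
               col.names = c("chrom", "start", "end", "name", "score",
                             "strand", "signalValue", "pValue", "qValue",
                             "peak"),
               colClasses = c("character", "integer", "integer", "character",
                              "integer", "character", "numeric", "numeric",
                              "numeric", "integer")),
    error = function(e) NULL)
  back <- function(nl) ifelse(nl >= cap, 0, 10^(-nl))
  if (is.null(df) || !nrow(df)) return(PeakSet())
  gr <- GenomicRanges::GRanges(df$chrom,
          IRanges::IRanges(df$start + 1L, df$end),
          summit = df$start + 1L + df$peak,
          minP = back(df$pValue), regionP = back(df$pValue),
          q = back(df$qValue),
          shift = rep(-1L, nrow(df)), passedShift = rep(TRUE, nrow(df)),
          signal = df$signalValue)
  if (!is.null(chromSizes)) {
    GenomeInfoDb::seqlevels(gr) <- union(GenomeInfoDb::seqlevels(gr),
                                         names(chromSizes))
    GenomeInfoDb::seqlengths(gr)[names(chromSizes)] <- unname(chromSizes)
  }
  PeakSet(sort(gr))
}

# -- expression tables, time series, gene sets --------------------------

#' Read a differential-expression table
#'
#' Accepts either the package's internal schema (columns \code{gene_id,
#' condition, fpkm_wt, fpkm_mut, log2fc, p, q}) or a Cuffdiff-style table
#' (columns \code{gene_id, sample_1, sample_2, value_1, value_2,
#' log2.fold_change., p_value, q_value}; an optional \code{condition}
#' column is carried through). For Cuffdiff input, \code{orientation}
#' states which sample ratio the reported fold change is:
#' \code{"mut_vs_wt"} (default; \code{value_1} = WT) keeps
#' \code{log2fc = log2(mut/wt)}, \code{"wt_vs_mut"} flips the sign so that
#' internally \code{log2fc} is always \code{log2(mut/wt)}.
#'
#' @param path tab-delimited file with a header row.
#' @param orientation fold-change orientation of a Cuffdiff-style input.
#' @return data.frame with the internal schema.
#' @export
readDETable <- function(path, orientation = c("mut_vs_wt", "wt_vs_mut")) {
  orientation <- match.arg(orientation)
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  internal <- c("gene_id", "condition", "fpkm_wt", "fpkm_mut", "log2fc",
                "p", "q")
  if (all(internal %in% names(df))) return(df[internal])
  cuff_lfc <- intersect(c("log2(fold_change)", "log2.fold_change."), names(df))
  need <- c("gene_id", "value_1", "value_2", "p_value", "q_value")
  if (!all(need %in% names(df)) || !length(cuff_lfc))
    .stop_io("unrecognized DE table schema; need internal or Cuffdiff columns ",
             "(missing q/column set)")
  lfc <- df[[cuff_lfc[1]]]
  if (orientation == "wt_vs_mut") lfc <- -lfc
  data.frame(gene_id = df$gene_id,
             condition = if ("condition" %in% names(df)) df$condition else NA_character_,
             fpkm_wt = df$value_1, fpkm_mut = df$value_2,
             log2fc = lfc, p = df$p_value, q = df$q_value,
             stringsAsFactors = FALSE)
}

#' Write a differential-expression table (internal schema)
#' @param records internal-schema data.frame.
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
writeDETable <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read luminescence time series from CSV
#'
#' Expects columns \code{time_h, value, replicate_id} (a missing replicate
#' column yields a single replicate \code{"rep1"}).
#'
#' @param path CSV file.
#' @return data.frame with columns \code{time_h, value, replicate_id},
#'   ordered by replicate then time.
#' @export
readTimeSeries <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("time_h", "value") %in% names(df)))
    .stop_io("time-series CSV must have columns time_h and value")
  if (!"replicate_id" %in% names(df)) df$replicate_id <- "rep1"
  for (ts in split(df$time_h, df$replicate_id))
    if (any(diff(ts) <= 0))
      .stop_io("time points must be strictly increasing within a replicate")
  df[order(df$replicate_id, df$time_h), c("time_h", "value", "replicate_id")]
}

#' Write luminescence time series to CSV
#' @param series data.frame with \code{time_h, value, replicate_id}.
#' @param path output CSV.
#' @return \code{path}, invisibly.
#' @export
writeTimeSeries <- function(series, path) {
  write.table(series, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene sets (one gene id per line)
#' @param path text file.
#' @return character vector of unique gene ids.
#' @export
readGeneSet <- function(path) {
  x <- readLines(path)
  unique(x[nzchar(trimws(x))])
}

#' @rdname readGeneSet
#' @param genes character vector of gene ids.
#' @export
writeGeneSet <- function(genes, path) {
  writeLines(unique(genes), path)
  invisible(path)
}

#' Read a term-to-gene map (two-column TSV: term_id, gene_id)
#' @param path TSV file, no header.
#' @return named list mapping term id to a character vector of gene ids.
#' @export
readTermMap <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("term_id", "gene_id"),
                   stringsAsFactors = FALSE)
  lapply(split(df$gene_id, df$term_id), unique)
}
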