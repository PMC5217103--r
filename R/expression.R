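# Differential-expression integration: fold-change/q filtering across light
# conditions, activated/repressed classification by the sign of log2(mut/wt),
# direct/indirect partition against the ChIP target union, and a log2 matrix
# export for heat maps. The internal convention throughout is
# log2fc = log2(mutant / wild type), so a gene *activated* by the factor is
# lower in the deletion strain (log2fc < 0).

.check_records <- function(records) {
  need <- c("gene_id", "condition", "log2fc", "q")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("DE records missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(records)
}

.condition_rank <- function(cond) {
  # sort key for the deterministic condition order LL0 < LL15 < LL30 < LL60
  # (numeric suffix); conditions without a numeric suffix sort last
  cond <- as.character(cond)
  has <- grepl("[0-9]+$", cond)
  num <- rep(Inf, length(cond))
  num[has] <- as.numeric(sub("^.*?([0-9]+)$", "\\1", cond[has]))
  num
}

#' Filter differentially expressed genes
#'
#' A gene is retained when, in \emph{any} condition, its absolute fold
#' change is at least \code{minFold} and its q-value at most \code{maxQ}
#' (both thresholds inclusive). The returned set is the union across
#' conditions.
#'
#' @param records DE data.frame (internal schema, one row per gene x
#'   condition; see [readDETable()]).
#' @param minFold minimal fold change (default 2; compared as
#'   \code{|log2fc| >= log2(minFold)}).
#' @param maxQ maximal q-value (default 0.2).
#' @return sorted character vector of retained gene ids.
#' @examples
#' de <- data.frame(gene_id = c("g1", "g1", "g2"),
#'                  condition = c("LL0", "LL15", "LL0"),
#'                  log2fc = c(0.4, -1.1, 0.9), q = c(0.5, 0.15, 0.01))
#' filterDE(de)   # g1 qualifies at LL15; g2 misses the fold cutoff
#' @export
filterDE <- function(records, minFold = 2, maxQ = 0.2) {
  .check_records(records)
  stopifnot(minFold >= 1, maxQ >= 0, maxQ <= 1)
  pass <- abs(records$log2fc) >= log2(minFold) & records$q <= maxQ
  pass[is.na(pass)] <- FALSE
  sort(unique(records$gene_id[pass]))
}

#' Classify genes as activated or repressed by the factor
#'
#' For each gene of \code{deSet}, direction is taken from the sign of
#' \code{log2fc} in the condition of maximal \code{|log2fc|} among the
#' conditions that pass the filter thresholds (ties broken by the earliest
#' condition in LL0 < LL15 < LL60 order): \code{activated} when expression
#' is lower in the deletion strain (\code{log2fc < 0}), \code{repressed}
#' when higher. A gene whose qualifying fold changes are all zero cannot be
#' classified and raises an error.
#'
#' @param records DE data.frame (internal schema).
#' @param deSet gene ids to classify (subset of \code{records$gene_id}).
#' @param minFold,maxQ the filter thresholds defining qualifying conditions
#'   (defaults as in [filterDE()]). Genes with no qualifying condition fall
#'   back to all their conditions.
#' @return data.frame \code{gene_id, direction, condition, log2fc}.
#' @export
classifyRegulation <- function(records, deSet, minFold = 2, maxQ = 0.2) {
  .check_records(records)
  missing_ids <- setdiff(deSet, records$gene_id)
  if (length(missing_ids))
    stop("genes not present in records: ",
         paste(head(missing_ids, 5), collapse = ", "), call. = FALSE)
  out <- lapply(deSet, function(g) {
    rec <- records[records$gene_id == g, , drop = FALSE]
    qual <- abs(rec$log2fc) >= log2(minFold) & rec$q <= maxQ
    qual[is.na(qual)] <- FALSE
    if (any(qual)) rec <- rec[qual, , drop = FALSE]
    rec <- rec[order(-abs(rec$log2fc), .condition_rank(rec$condition),
                     rec$condition), , drop = FALSE]
    top <- rec[1, ]
    if (top$log2fc == 0)
      stop("unclassifiable: gene ", g,
           " has log2fc = 0 in all qualifying conditions", call. = FALSE)
    data.frame(gene_id = g,
               direction = if (top$log2fc < 0) "activated" else "repressed",
               condition = top$condition, log2fc = top$log2fc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Partition differentially expressed genes into direct and indirect targets
#'
#' Direct targets are DE genes also bound by the factor (present in the ChIP
#' target union); the rest are indirect.
#'
#' @param deSet character vector of DE gene ids.
#' @param chipUnion character vector of ChIP target gene ids.
#' @return list with sorted character vectors \code{direct} and
#'   \code{indirect}; their sizes sum to \code{length(unique(deSet))}.
#' @export
partitionDirectIndirect <- function(deSet, chipUnion) {
  deSet <- unique(deSet)
  list(direct = sort(intersect(deSet, chipUnion)),
       indirect = sort(setdiff(deSet, chipUnion)))
}

#' Export a log2 expression matrix for heat maps
#'
#' Rows follow \code{geneOrder}; columns are genotype x condition
#' (\code{WT_<cond>}, \code{mut_<cond>}, conditions in LL order). Cells are
#' \code{log2(FPKM + pseudocount)}.
#'
#' @param records DE data.frame (internal schema with \code{fpkm_wt} and
#'   \code{fpkm_mut}).
#' @param geneOrder character vector of gene ids (all must be present).
#' @param pseudocount added before the log (default 1, so FPKM 0 maps to 0).
#' @return numeric matrix with rownames \code{geneOrder}.
#' @export
log2Matrix <- function(records, geneOrder, pseudocount = 1) {
  .check_records(records)
  stopifnot(all(c("fpkm_wt", "fpkm_mut") %in% names(records)))
  missing_ids <- setdiff(geneOrder, records$gene_id)
  if (length(missing_ids))
    stop("genes not present in records: ",
         paste(head(missing_ids, 5), collapse = ", "), call. = FALSE)
  conds <- unique(records$condition)
  conds <- conds[order(.condition_rank(conds), conds)]
  m <- matrix(NA_real_, nrow = length(geneOrder), ncol = 2L * length(conds),
              dimnames = list(geneOrder,
                c(paste0("WT_", conds), paste0("mut_", conds))))
  for (j in seq_along(conds)) {
    rec <- records[records$condition == conds[j], , drop = FALSE]
    idx <- match(geneOrder, rec$gene_id)
    m[, j] <- log2(rec$fpkm_wt[idx] + pseudocount)
    m[, length(conds) + j] <- log2(rec$fpkm_mut[idx] + pseudocount)
  }
  m
}
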