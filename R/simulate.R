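# Synthetic-data generators. They emulate the statistical structure the
# analysis assumes: i.i.d. lognormal background coverage with planted
# bimodal (strand-shifted) binding peaks, Cuffdiff-like expression tables
# with planted fold changes, damped trending sinusoidal reporter traces
# sampled every 1.5 h, and light/clock gene-set memberships. Every
# generator is deterministic given the config seed, and each draws from its
# own derived stream so partial reruns reproduce.

#' Simulation configuration
#'
#' Bundles all generator parameters with defaults chosen to emulate the
#' study system: a lognormal coverage background (log-scale mu = 1,
#' sigma = 0.5), planted peaks 30x the background median with a 70 bp
#' forward/reverse mode separation, expression effects around twofold, and
#' reporter traces with a ~20.3 h free-running period sampled every 1.5 h
#' over 114 h.
#'
#' @param seed integer seed; every generator derives its own stream from it.
#' @param chromSizes named vector of chromosome lengths (bp).
#' @param nGenes number of gene models to place (needs ~12 kb per gene).
#' @param divergentFraction fraction of genes arranged as divergently
#'   transcribed pairs with facing TSSs < 5 kb apart (default 0.2).
#' @param geneLengthRange min/max gene length in bp.
#' @param genomeGeneCount total predicted genes (default: \code{nGenes}).
#' @param backgroundMu,backgroundSigma log-scale lognormal background
#'   parameters.
#' @param roundCoverage round background coverage to integer counts
#'   (default TRUE; set FALSE for model-exact continuous coverage).
#' @param backgroundSmooth half-width of an optional running-mean kernel
#'   applied to the background to stress-test the caller's independence
#'   assumption (default 0 = off).
#' @param nPeaks number of planted binding sites.
#' @param peakHeight planted per-strand mode height as a multiple of the
#'   background median (default 30).
#' @param heightDispersion per-site occupancy spread: each planted site's
#'   height is scaled by \code{2^Uniform(-h, h)} with \code{h} this value
#'   (default 0.4, i.e., sites span roughly 23x-40x at the default height;
#'   real binding sites differ in occupancy). The factor is part of the
#'   planted truth, so replicate samples share it.
#' @param fragmentOffset expected forward/reverse mode separation d in bp
#'   (default 70).
#' @param jitterSd Gaussian jitter of fragment anchors in bp (default 35).
#' @param kernelHalfwidth half-width of the per-fragment coverage kernel
#'   (default 25, i.e., a ~50 bp read footprint centered on the anchor).
#' @param locationProbs probabilities that a planted site is upstream,
#'   downstream, or genic relative to its gene (default 0.67/0.31/0.02,
#'   the binding-location mix reported for this factor).
#' @param conditionPeakFraction fraction of planted sites active in any one
#'   ChIP condition (default 0.85), so per-condition target sets differ and
#'   their union exceeds each of them.
#' @param deFraction fraction of genes with a planted expression effect.
#' @param deLog2fcMean,deLog2fcSd planted |log2 fold change| distribution
#'   (Normal, default mean 2, sd 0.25).
#' @param activatedFraction fraction of planted effects that are
#'   activations, i.e., lower in the deletion strain (default 0.8).
#' @param fpkmMu,fpkmSigma log-scale lognormal baseline FPKM parameters.
#' @param deNoiseSd replicate noise sd on the log2 scale (default 0.25).
#' @param conditions DE/ChIP condition labels.
#' @param luminescence list of reporter-trace parameters: \code{period} h,
#'   \code{phase} h (time of first peak), \code{amplitude}, \code{damping}
#'   per h, \code{trend} per h, \code{noiseSd}, \code{samplingH},
#'   \code{durationH}, \code{baseline}, \code{nReplicates}.
#' @param membershipProbs probabilities that a ChIP target gene is both
#'   light- and clock-regulated, light-only, clock-only, or neither
#'   (default 0.10/0.20/0.16/0.53).
#' @param backgroundLightRate,backgroundClockRate membership rates for
#'   non-target genes (defaults 0.31 and 0.23).
#' @return a list of class \code{SimConfig}.
#' @export
simConfig <- function(seed = 1L,
                      chromSizes = c(chrI = 1e6),
                      nGenes = 60L,
                      divergentFraction = 0.2,
                      geneLengthRange = c(1000L, 3000L),
                      genomeGeneCount = NULL,
                      backgroundMu = 1.0, backgroundSigma = 0.5,
                      roundCoverage = TRUE, backgroundSmooth = 0L,
                      nPeaks = 20L, peakHeight = 30, heightDispersion = 0.4,
                      fragmentOffset = 70L, jitterSd = 35,
                      kernelHalfwidth = 25L,
                      locationProbs = c(upstream = 0.67, downstream = 0.31,
                                        genic = 0.02),
                      conditionPeakFraction = 0.85,
                      deFraction = 0.15, deLog2fcMean = 2, deLog2fcSd = 0.25,
                      activatedFraction = 0.8,
                      fpkmMu = 3, fpkmSigma = 1, deNoiseSd = 0.25,
                      conditions = c("LL0", "LL15", "LL60"),
                      luminescence = list(),
                      membershipProbs = c(both = 0.10, light_only = 0.20,
                                          clock_only = 0.16, neither = 0.53),
                      backgroundLightRate = 0.31,
                      backgroundClockRate = 0.23) {
  lum <- utils::modifyList(
    list(period = 20.3, phase = 20, amplitude = 100, damping = 0.005,
         trend = -0.1, noiseSd = 10, samplingH = 1.5, durationH = 114,
         baseline = 500, nReplicates = 12L),
    luminescence)
  stopifnot(backgroundSigma > 0, deFraction >= 0, deFraction <= 1,
            lum$samplingH > 0, fragmentOffset >= 0, nGenes >= 1,
            all(locationProbs >= 0), all(membershipProbs >= 0))
  # published category percentages can sum to 99 or 101 from rounding
  locationProbs <- locationProbs / sum(locationProbs)
  membershipProbs <- membershipProbs / sum(membershipProbs)
  structure(list(seed = as.integer(seed), chromSizes = chromSizes,
                 nGenes = as.integer(nGenes),
                 divergentFraction = divergentFraction,
                 geneLengthRange = as.integer(geneLengthRange),
                 genomeGeneCount = genomeGeneCount,
                 backgroundMu = backgroundMu,
                 backgroundSigma = backgroundSigma,
                 roundCoverage = roundCoverage,
                 backgroundSmooth = as.integer(backgroundSmooth),
                 nPeaks = as.integer(nPeaks), peakHeight = peakHeight,
                 heightDispersion = heightDispersion,
                 fragmentOffset = as.integer(fragmentOffset),
                 jitterSd = jitterSd,
                 kernelHalfwidth = as.integer(kernelHalfwidth),
                 locationProbs = locationProbs,
                 conditionPeakFraction = conditionPeakFraction,
                 deFraction = deFraction, deLog2fcMean = deLog2fcMean,
                 deLog2fcSd = deLog2fcSd,
                 activatedFraction = activatedFraction,
                 fpkmMu = fpkmMu, fpkmSigma = fpkmSigma,
                 deNoiseSd = deNoiseSd, conditions = conditions,
                 luminescence = lum, membershipProbs = membershipProbs,
                 backgroundLightRate = backgroundLightRate,
                 backgroundClockRate = backgroundClockRate),
            class = "SimConfig")
}

# run expr under a seed derived from (seed, stream), restoring RNG state
.with_stream <- function(seed, stream, expr) {
  derived <- (as.numeric(seed) * 7919 + stream * 104729) %%
    (.Machine$integer.max - 1) + 1
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(derived))
  expr
}

#' Simulate a toy gene annotation
#'
#' Places non-overlapping single-interval gene models with at least ~12 kb
#' of spacing per gene slot, a configurable fraction of them as divergently
#' transcribed head-to-head pairs whose TSSs face each other across less
#' than 5 kb. Deterministic given the config seed.
#'
#' @param cfg a [simConfig()].
#' @return a [GenomeAnnotation]; divergent partners are recorded in the
#'   \code{"divergentPairs"} attribute (two-column matrix of gene ids).
#' @examples
#' ann <- simulateAnnotation(simConfig(seed = 1, nGenes = 20,
#'                                     chromSizes = c(chrI = 4e5)))
#' ann
#' @export
simulateAnnotation <- function(cfg = simConfig()) {
  .with_stream(cfg$seed, 1L, {
    slot_bp <- 12000L
    sizes <- cfg$chromSizes
    n_slots <- pmax(0L, as.integer(sizes %/% slot_bp) - 1L)
    # a divergent pair occupies one slot and spends two genes of the budget
    n_pairs <- floor(cfg$divergentFraction * cfg$nGenes / 2)
    n_units <- cfg$nGenes - n_pairs
    if (sum(n_slots) < n_units)
      stop("infeasible packing: ", cfg$nGenes, " genes need ", n_units,
           " slots of ", slot_bp, " bp, chromosomes provide ",
           sum(n_slots), call. = FALSE)
    chrom_of <- rep(names(sizes), n_slots)
    slot_idx <- unlist(lapply(n_slots, seq_len), use.names = FALSE)
    take <- sort(sample(length(chrom_of), n_units))
    chrom <- chrom_of[take]; slot <- slot_idx[take]
    is_pair <- rep(FALSE, n_units)
    if (n_pairs > 0) is_pair[sample(n_units, n_pairs)] <- TRUE

    rows <- vector("list", n_units)
    pairs <- list()
    g_i <- 0L
    gid <- function() sprintf("g%04d", g_i)
    for (i in seq_len(n_units)) {
      base <- (slot[i] - 1L) * slot_bp + 1L
      len <- sample(cfg$geneLengthRange[1]:cfg$geneLengthRange[2], 1L)
      if (is_pair[i]) {
        # head-to-head pair inside one slot: <-geneA  gap  geneB->
        lenB <- sample(cfg$geneLengthRange[1]:cfg$geneLengthRange[2], 1L)
        gap <- sample(500:4000, 1L)
        startA <- base + sample(0:500, 1L)
        g_i <- g_i + 1L; idA <- gid()
        g_i <- g_i + 1L; idB <- gid()
        startB <- startA + len + gap
        rows[[i]] <- data.frame(
          chrom = chrom[i], start = c(startA, startB),
          end = c(startA + len - 1L, startB + lenB - 1L),
          strand = c("-", "+"), id = c(idA, idB))
        pairs[[length(pairs) + 1L]] <- c(idA, idB)
      } else {
        start <- base + sample(0:2000, 1L)
        g_i <- g_i + 1L
        rows[[i]] <- data.frame(chrom = chrom[i], start = start,
                                end = start + len - 1L,
                                strand = sample(c("+", "-"), 1L),
                                id = gid())
      }
    }
    df <- do.call(rbind, rows)
    gr <- GenomicRanges::GRanges(df$chrom,
            IRanges::IRanges(df$start, df$end), strand = df$strand,
            seqlengths = sizes)
    names(gr) <- df$id
    ann <- GenomeAnnotation(sort(gr),
      genomeGeneCount = cfg$genomeGeneCount %||% length(gr))
    attr(ann, "divergentPairs") <-
      if (length(pairs)) do.call(rbind, pairs) else
        matrix(character(), ncol = 2)
    ann
  })
}

# choose planted binding-site centers relative to genes; returns the truth
# table (chrom, center, class, gene_ids comma-separated)
.place_peaks <- function(annotation, cfg) {
  genes <- geneModels(annotation)
  sizes_all <- chromSizes(annotation)
  lim_of <- sizes_all[as.character(GenomeInfoDb::seqnames(genes))]
  # keep planted windows clear of chromosome edges so a site's class is
  # unambiguous
  eligible <- which(GenomicRanges::start(genes) > 6000 &
                      GenomicRanges::end(genes) < lim_of - 6000)
  if (cfg$nPeaks > length(eligible))
    stop("more planted peaks than eligible genes", call. = FALSE)
  pick <- eligible[sample(length(eligible), cfg$nPeaks)]
  cls <- sample(names(cfg$locationProbs), cfg$nPeaks, replace = TRUE,
                prob = cfg$locationProbs)
  plus <- as.character(GenomicRanges::strand(genes)) == "+"
  gs <- GenomicRanges::start(genes); ge <- GenomicRanges::end(genes)
  chrom_of_gene <- as.character(GenomeInfoDb::seqnames(genes))
  # geometric class of a point relative to ALL genes of the chromosome,
  # with the same priority rule the assignment stage uses
  point_class <- function(chrom, pos) {
    on_chr <- which(chrom_of_gene == chrom)
    best <- 0L
    for (i in on_chr) {
      c_i <- if (pos >= gs[i] && pos <= ge[i]) 3L
        else if ((plus[i] && pos < gs[i] && gs[i] - pos <= 5000) ||
                 (!plus[i] && pos > ge[i] && pos - ge[i] <= 5000)) 2L
        else if ((plus[i] && pos > ge[i] && pos - ge[i] <= 3000) ||
                 (!plus[i] && pos < gs[i] && gs[i] - pos <= 3000)) 1L
        else 0L
      best <- max(best, c_i)
    }
    c("none", "downstream", "upstream", "genic")[best + 1L]
  }
  centers <- integer(cfg$nPeaks)
  for (k in seq_len(cfg$nPeaks)) {
    i <- pick[k]
    # rejection-sample until the point's geometric class (against all genes)
    # matches the intended class, so planted truth labels are exact
    for (try in 1:80) {
      ctr <- switch(cls[k],
        upstream = if (plus[i]) gs[i] - sample(500:4000, 1L)
                   else ge[i] + sample(500:4000, 1L),
        downstream = if (plus[i]) ge[i] + sample(500:2500, 1L)
                     else gs[i] - sample(500:2500, 1L),
        genic = gs[i] + sample(seq_len(max(1L, ge[i] - gs[i])), 1L) - 1L)
      if (point_class(chrom_of_gene[i], ctr) == cls[k]) break
      if (try == 80L) ctr <- NA_integer_
    }
    if (is.na(ctr)) {  # fall back to another eligible gene
      alt <- setdiff(eligible, pick)
      i <- if (length(alt)) alt[sample(length(alt), 1L)] else i
      ctr <- switch(cls[k],
        upstream = if (plus[i]) gs[i] - 2000L else ge[i] + 2000L,
        downstream = if (plus[i]) ge[i] + 1500L else gs[i] - 1500L,
        genic = (gs[i] + ge[i]) %/% 2L)
      pick[k] <- i
    }
    centers[k] <- ctr
  }
  truth <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(genes))[pick],
                      center = centers, class = cls,
                      gene_id = names(genes)[pick],
                      heightFactor = 2^runif(cfg$nPeaks,
                                             -cfg$heightDispersion,
                                             cfg$heightDispersion),
                      stringsAsFactors = FALSE)
  truth[order(truth$chrom, truth$center), ]
}

#' Simulate stranded ChIP coverage with planted peaks
#'
#' Background combined coverage is drawn i.i.d. per base from
#' \code{round(Lognormal(mu, sigma))} (rounding optional) and split
#' binomially between strands. Each planted site adds \code{nFragments}
#' fragments: forward anchors at \code{center - d/2} and reverse anchors at
#' \code{center + d/2}, jittered with Gaussian sd \code{jitterSd}, each
#' depositing a \code{2 * kernelHalfwidth + 1} bp footprint on its strand.
#' \code{nFragments} is derived so the per-strand mode height is
#' \code{peakHeight} times the background median.
#'
#' @param annotation a [GenomeAnnotation].
#' @param cfg a [simConfig()].
#' @param truth optional pre-placed truth table (from a previous call), so
#'   several samples can share planted sites; placed fresh when NULL.
#' @param activePeaks optional logical/index vector selecting which truth
#'   rows receive fragments (default all).
#' @param stream RNG sub-stream index (vary to get independent replicates).
#' @return list with \code{tracks} (named list of [CoverageTrack]) and
#'   \code{truth} (data.frame: chrom, center, class, gene_id, nFragments,
#'   fragmentOffset, active).
#' @export
simulateChipCoverage <- function(annotation, cfg = simConfig(), truth = NULL,
                                 activePeaks = NULL, stream = 2L) {
  if (is.null(truth)) {
    # placement draws from its own sub-stream so coverage noise is
    # reproducible whether placement ran or a truth table was supplied
    truth <- .with_stream(cfg$seed, stream + 7000L, {
      if (cfg$nPeaks > 0) .place_peaks(annotation, cfg) else
        data.frame(chrom = character(), center = integer(),
                   class = character(), gene_id = character(),
                   stringsAsFactors = FALSE)
    })
  }
  .with_stream(cfg$seed, stream, {
    cov_frac <- 2 * pnorm(cfg$kernelHalfwidth / cfg$jitterSd) - 1
    if (!("nFragments" %in% names(truth))) {
      hf <- if ("heightFactor" %in% names(truth)) truth$heightFactor else 1
      truth$nFragments <- if (nrow(truth)) as.integer(ceiling(
        hf * cfg$peakHeight * exp(cfg$backgroundMu) / cov_frac)) else integer()
    }
    if (!("fragmentOffset" %in% names(truth)))
      truth$fragmentOffset <- if (nrow(truth)) cfg$fragmentOffset else
        integer()
    active <- rep(TRUE, nrow(truth))
    if (!is.null(activePeaks)) {
      active <- rep(FALSE, nrow(truth))
      active[activePeaks] <- TRUE
    }
    truth$active <- active

    sizes <- cfg$chromSizes
    tracks <- list()
    for (chrom in names(sizes)) {
      L <- as.integer(sizes[[chrom]])
      combined <- rlnorm(L, cfg$backgroundMu, cfg$backgroundSigma)
      if (cfg$backgroundSmooth > 0) {
        k <- 2L * cfg$backgroundSmooth + 1L
        combined <- as.numeric(stats::filter(combined, rep(1 / k, k),
                                             sides = 2))
        combined[is.na(combined)] <- exp(cfg$backgroundMu)
      }
      if (cfg$roundCoverage) {
        combined <- round(combined)
        fwd <- rbinom(L, combined, 0.5)
        rev <- combined - fwd
      } else {
        u <- runif(L)            # random strand split, preserves fwd + rev
        fwd <- combined * u
        rev <- combined * (1 - u)
      }
      rows <- which(truth$chrom == chrom & truth$active &
                      truth$nFragments > 0)
      if (length(rows)) {
        hw <- cfg$kernelHalfwidth
        add_kernels <- function(anchors) {
          anchors <- anchors[anchors > hw & anchors <= L - hw]
          pos <- rep(anchors, each = 2L * hw + 1L) +
            rep.int(-hw:hw, length(anchors))
          tabulate(pos, nbins = L)
        }
        for (r in rows) {
          ctr <- truth$center[r]; d <- truth$fragmentOffset[r]
          nf <- truth$nFragments[r]
          fa <- round(rnorm(nf, ctr - d / 2, cfg$jitterSd))
          ra <- round(rnorm(nf, ctr + d / 2, cfg$jitterSd))
          fwd <- fwd + add_kernels(fa)
          rev <- rev + add_kernels(ra)
        }
      }
      tracks[[chrom]] <- CoverageTrack(chrom, fwd, rev)
    }
    list(tracks = tracks, truth = truth)
  })
}

#' Simulate an annotated genome plus ChIP coverage in one call
#'
#' Convenience wrapper: [simulateAnnotation()] followed by
#' [simulateChipCoverage()].
#'
#' @param cfg a [simConfig()].
#' @return list with \code{annotation}, \code{tracks}, \code{truth}.
#' @export
simulateChipDataset <- function(cfg = simConfig()) {
  ann <- simulateAnnotation(cfg)
  sim <- simulateChipCoverage(ann, cfg)
  list(annotation = ann, tracks = sim$tracks, truth = sim$truth)
}

#' Simulate a differential-expression table with planted effects
#'
#' Per-gene baseline FPKMs are lognormal; a planted fraction of genes gets
#' \code{|log2fc| ~ Normal(deLog2fcMean, deLog2fcSd)}, with sign negative
#' (activated: lower in the deletion strain) with probability
#' \code{activatedFraction}. Two replicates per genotype carry
#' multiplicative noise on the log2 scale; p comes from a two-sample t-test
#' on \code{log2(FPKM + 1)} and q from Benjamini-Hochberg within each
#' condition. The t-test exists only to give synthetic tables coherent p/q
#' columns; real tables come from an external DE engine.
#'
#' @param annotation a [GenomeAnnotation].
#' @param cfg a [simConfig()].
#' @param stream RNG sub-stream index.
#' @return list with \code{records} (internal-schema data.frame over all
#'   conditions) and \code{truthLabels} (data.frame gene_id, label in
#'   activated/repressed/null).
#' @export
simulateDETable <- function(annotation, cfg = simConfig(), stream = 3L) {
  .with_stream(cfg$seed, stream, {
    ids <- names(geneModels(annotation))
    n <- length(ids)
    n_de <- floor(cfg$deFraction * n)
    if (cfg$deFraction > 0 && n_de < 1)
      stop("deFraction * nGenes must be >= 1 when deFraction > 0",
           call. = FALSE)
    de_idx <- if (n_de > 0) sample(n, n_de) else integer()
    lfc <- numeric(n)
    label <- rep("null", n)
    if (n_de > 0) {
      mag <- abs(rnorm(n_de, cfg$deLog2fcMean, cfg$deLog2fcSd))
      act <- runif(n_de) < cfg$activatedFraction
      lfc[de_idx] <- ifelse(act, -mag, mag)
      label[de_idx] <- ifelse(act, "activated", "repressed")
    }
    base <- rlnorm(n, cfg$fpkmMu, cfg$fpkmSigma)
    recs <- lapply(cfg$conditions, function(cond) {
      reps <- function(mean_fpkm) {
        sapply(mean_fpkm, function(m)
          m * 2^rnorm(2, 0, cfg$deNoiseSd))     # 2 x n matrix
      }
      wt <- reps(base)
      mut <- reps(base * 2^lfc)
      lw <- log2(wt + 1); lmut <- log2(mut + 1)
      # pooled-variance Student t: with 2 replicates per genotype the Welch
      # approximation collapses to ~1 df and has no power
      p <- vapply(seq_len(n), function(i) {
        tryCatch(stats::t.test(lmut[, i], lw[, i], var.equal = TRUE)$p.value,
                 error = function(e) 1)
      }, numeric(1))
      p[is.na(p)] <- 1
      mw <- colMeans(wt); mm <- colMeans(mut)
      data.frame(gene_id = ids, condition = cond,
                 fpkm_wt = mw, fpkm_mut = mm,
                 log2fc = log2((mm + 1) / (mw + 1)),
                 p = p, q = p.adjust(p, method = "BH"),
                 stringsAsFactors = FALSE)
    })
    list(records = do.call(rbind, recs),
         truthLabels = data.frame(gene_id = ids, label = label,
                                  stringsAsFactors = FALSE))
  })
}

#' Simulate bioluminescence reporter traces
#'
#' \code{y(t) = baseline + trend * t + A exp(-damping t)
#' sin(2 pi (t - phase0) / period) + Normal(0, noiseSd)}, sampled every
#' \code{samplingH} hours from 0 to \code{durationH}, where \code{phase0}
#' places the first undamped peak at \code{phase} hours. One series per
#' replicate, independent noise.
#'
#' @param cfg a [simConfig()] (parameters under \code{cfg$luminescence}).
#' @param truth optional overrides for the luminescence parameter list.
#' @param stream RNG sub-stream index.
#' @return list with \code{series} (data.frame time_h, value, replicate_id)
#'   and \code{truth} (the parameter list used).
#' @examples
#' sim <- simulateLuciferase(simConfig(seed = 1))
#' nrow(sim$series) / 12   # 77 samples per replicate
#' @export
simulateLuciferase <- function(cfg = simConfig(), truth = list(),
                               stream = 4L) {
  .with_stream(cfg$seed, stream, {
    p <- utils::modifyList(cfg$luminescence, truth)
    t <- seq(0, p$durationH, by = p$samplingH)
    phase0 <- p$phase - p$period / 4    # sine peaks a quarter period later
    series <- lapply(seq_len(p$nReplicates), function(r) {
      y <- p$baseline + p$trend * t +
        p$amplitude * exp(-p$damping * t) *
          sin(2 * pi * (t - phase0) / p$period) +
        rnorm(length(t), 0, p$noiseSd)
      data.frame(time_h = t, value = y,
                 replicate_id = sprintf("rep%02d", r),
                 stringsAsFactors = FALSE)
    })
    list(series = do.call(rbind, series), truth = p)
  })
}

#' Simulate light-regulated and clock-controlled gene sets
#'
#' Target genes are assigned to the four light x clock membership cells
#' with the configured probabilities; non-target genes receive independent
#' light/clock memberships at the genome background rates.
#'
#' @param annotation a [GenomeAnnotation].
#' @param targets character vector of target gene ids.
#' @param cfg a [simConfig()].
#' @param stream RNG sub-stream index.
#' @return list with \code{light} and \code{clock} gene-id vectors.
#' @export
simulateGeneSets <- function(annotation, targets, cfg = simConfig(),
                             stream = 5L) {
  .with_stream(cfg$seed, stream, {
    ids <- names(geneModels(annotation))
    targets <- intersect(targets, ids)
    rest <- setdiff(ids, targets)
    cell <- sample(names(cfg$membershipProbs), length(targets),
                   replace = TRUE, prob = cfg$membershipProbs)
    light <- targets[cell %in% c("both", "light_only")]
    clock <- targets[cell %in% c("both", "clock_only")]
    light <- c(light, rest[runif(length(rest)) < cfg$backgroundLightRate])
    clock <- c(clock, rest[runif(length(rest)) < cfg$backgroundClockRate])
    list(light = sort(light), clock = sort(clock))
  })
}

#' Write a complete synthetic dataset to disk
#'
#' Emits the formats the pipeline reads -- GFF3 annotation, per-strand
#' bedGraph coverage per ChIP condition, a DE TSV, a time-series CSV,
#' light/clock gene-set files -- plus a \code{truth.json} with every planted
#' quantity, so downstream recovery is checkable from files alone.
#'
#' @param cfg a [simConfig()].
#' @param outDir output directory (created if needed).
#' @return invisibly, the list of generated objects.
#' @export
simulateDataset <- function(cfg = simConfig(), outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  ann <- simulateAnnotation(cfg)
  writeGeneAnnotation(ann, file.path(outDir, "genes.gff3"))
  base <- simulateChipCoverage(ann, cfg)    # shared truth placement
  chip <- list()
  for (i in seq_along(cfg$conditions)) {
    cond <- cfg$conditions[i]
    keep <- .with_stream(cfg$seed, 100L + i, {
      runif(nrow(base$truth)) < cfg$conditionPeakFraction
    })
    sim <- simulateChipCoverage(ann, cfg, truth = base$truth,
                                activePeaks = which(keep),
                                stream = 10L + i)
    for (chrom in names(sim$tracks))
      writeCoverageTrack(sim$tracks[[chrom]],
        file.path(outDir, sprintf("chip_%s_%s_fwd.bedgraph", cond, chrom)),
        file.path(outDir, sprintf("chip_%s_%s_rev.bedgraph", cond, chrom)))
    chip[[cond]] <- sim
  }
  de <- simulateDETable(ann, cfg)
  writeDETable(de$records, file.path(outDir, "de_table.tsv"))
  lum <- simulateLuciferase(cfg)
  writeTimeSeries(lum$series, file.path(outDir, "luciferase.csv"))
  sets <- simulateGeneSets(ann, unique(base$truth$gene_id), cfg)
  writeGeneSet(sets$light, file.path(outDir, "light_genes.txt"))
  writeGeneSet(sets$clock, file.path(outDir, "clock_genes.txt"))
  truth <- list(peaks = base$truth, deLabels = de$truthLabels,
                luminescence = lum$truth,
                chromSizes = as.list(cfg$chromSizes), seed = cfg$seed)
  jsonlite::write_json(truth, file.path(outDir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(annotation = ann, chip = chip, de = de, luminescence = lum,
                 geneSets = sets))
}
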