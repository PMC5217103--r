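---
title: "Methods: peak calling, target assignment, and rhythm detection in regulonscope"
author: "regulonscope authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak calling, target assignment, and rhythm detection in regulonscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulonscope)
```

# Overview

`regulonscope` maps the regulon of a light-responsive, clock-controlled
transcription factor from three data types: stranded ChIP-seq coverage,
differential-expression tables comparing wild type to a deletion strain, and
bioluminescence reporter traces recorded in constant darkness. This vignette
documents the statistical models, the tunable parameters and their defaults,
the numerical choices, and what the synthetic-data generators do and do not
emulate.

# The peak caller

## Background model

Background coverage is modeled as lognormal: over all bases of the sample
with positive combined coverage `c = fwd + rev`, `ln c ~ Normal(mu, sigma)`.
`fitBackground()` estimates `mu` and `sigma` by the sample mean and standard
deviation of `ln c`, pooled across chromosomes (a per-chromosome fit is
available via `callPeaks(perChromosome = TRUE)`; which pooling the original
pipelines used is not documented, and pooled fits are more stable on small
chromosomes). Zero-coverage bases carry no information about a distribution
supported on `(0, Inf)` and are excluded from the fit; they are never called
enriched. Fewer than 1000 positive bases is an error rather than a silent
bad fit. A fitted `sigma` below `1e-6` flags the background as degenerate
(e.g., perfectly uniform coverage); tail probabilities are then undefined
and scoring refuses to proceed rather than divide by zero.

## Position scoring and region assembly

A position with coverage `c > 0` is enriched when the model upper-tail
probability `P(X >= c)` is at most `alphaPosition` (default 0.01). Internally
the comparison is done once against the equivalent coverage threshold
`exp(mu + sigma * z(1 - alpha))` rather than through a million `pnorm()`
calls.

Enriched runs separated by at most `maxMergeGap` bases (default 50) are
joined, and only regions strictly longer than `minRegionLen` (default 100 bp)
survive. The merge gap default reflects fragment-scale smoothing: with
chromatin sheared to roughly 500 bp, sub-fragment gaps in an enriched block
are sampling noise, not separate binding events.

## Region-level FDR

Each candidate region is scored by its smallest per-position tail
probability. That minimum is the extreme of a genome-wide scan, so using it
raw as a p-value is invalid — merged noise clusters would flood the
Benjamini-Hochberg step and produce spurious "significant" regions on pure
background. We therefore apply the scan (Sidak) correction
`p_region = 1 - (1 - minP)^L`, with `L` the number of positions scored in
the sample, before BH adjustment across candidate regions; regions with
`q < fdr` (default 0.01) are retained. The correction is deliberately
conservative: strongly enriched sites (the planted 30x-background peaks the
tests use, and anything comparable in real data) carry `minP` so small that
the correction is immaterial, while weakly enriched regions (below roughly
10x background under the default parameters) are sacrificed for a null in
which essentially no pure-noise region is ever retained. Simulation on
10^6 bp i.i.d. lognormal genomes shows zero retained peaks in virtually all
seeds, and calibration of the per-position rule within three binomial
standard errors of `alphaPosition`. Note the per-position rule is exactly
calibrated on continuous lognormal coverage; on integer counts the
achievable rejection fractions are quantized to the discrete tail masses,
which is the usual and benign discretization effect.

## Strand-shift filter

True binding sites produce forward- and reverse-strand pileups displaced by
roughly the fragment size; symmetric artifacts do not. For each
FDR-surviving region, extended by `shiftFlank` (default 500 bp) on each
side, `estimateShift()` finds the lag in `[0, shiftSearchMax]` (default
300 bp) that maximizes the Pearson correlation between `fwd(x)` and
`rev(x + lag)`, taking the leftmost lag on ties for determinism. Regions
pass when the lag is at least `minShift` (default 60 bp, inclusive).
Zero-variance windows cannot be tested and fail the filter with the shift
reported as -1. The summit is the leftmost argmax of combined coverage
within the region.

# Peak-to-gene assignment

A peak is assigned to a gene when its summit lies within 5 kb upstream of
the transcription start site, inside the gene span, or within 3 kb
downstream of the transcription end site, all strand-aware and inclusive at
the boundary. Distances are measured from the summit — the best point
estimate of the binding site — rather than from region edges; an edge-based
mode (`anchor = "edges"`) is provided since the original analyses do not
state which convention they used. Genes are modeled as single intervals:
the assignment geometry only needs the transcription start and end sites,
so exon structure is deliberately out of scope, and "within the coding
region" is interpreted as the annotated gene span.

One peak may be assigned to several genes; the canonical case is a summit
between two divergently transcribed genes, upstream of both. For
summarizing binding locations each peak is counted once with its
highest-priority class, genic > upstream > downstream (published
distributions report mutually exclusive percentages without stating the
rule; some fixed priority is needed and genic is the most specific call).

# Expression integration

The differential-expression table carries, per gene and condition, FPKM in
both genotypes, `log2fc = log2(mutant / wild type)`, p, and q. A gene is
differentially expressed when in *any* condition `|log2fc| >= log2(2)` and
`q <= 0.2`, both inclusive; the retained set is the union across
conditions. Direction is read from the condition of maximal `|log2fc|`
among qualifying conditions (ties broken by earliest condition in
LL0 < LL15 < LL60 order): a gene is *activated* by the factor when its mRNA
is lower in the deletion strain (`log2fc < 0`), *repressed* when higher.
Genes changing in opposite directions across conditions are classified by
the largest effect; this is configurable in the sense that the thresholds
defining "qualifying" are arguments, since published heat maps do not state
how such genes were colored. Direct targets are DE genes that are also in
the ChIP target union; everything else DE is indirect. Log2 matrices for
heat maps use a pseudocount of 1 so FPKM 0 maps to 0.

# Rhythm detection

## Preprocessing

The first day of recording is excluded (`dropBeforeH = 24`): plate transfer
into the luminometer produces transient artifacts. Exclusion precedes
detrending (the original order is not documented; excluding first means the
trend estimate is not contaminated by the discarded transient). Traces are
then detrended by subtracting a centered *local-linear* fit over a
`detrendWindowH = 24` h window, truncated at the series ends. A local line,
unlike a plain moving average, removes linear drift exactly even in the
truncated edge windows; it also absorbs the slow amplitude decay of the
reporter. Global linear detrending is available
(`detrendWindowH = "linear"`).

## Model fits and the rhythmicity call

Two models are fitted by least squares to the preprocessed trace: a line
(slope, intercept) and a plain sine `y = c + A sin(2*pi*(t - phi0)/T)`.
Damping is intentionally *not* part of the fitted model — the detrending
step is responsible for amplitude decay, and the sine fit estimates period,
phase, and amplitude only; the simulator generates damped traces precisely
to stress this division of labor.

The sine fit is nonlinear only in `T`, so it is parameterized as
`c + b1 cos(wt) + b2 sin(wt)` and solved by multi-start: for each trial
period on a 1 h grid over `periodBounds` (default 16-32 h, bracketing the
organism's free-running period of roughly 20-22 h), the linear harmonic
coefficients initialize a bounded Levenberg-Marquardt refinement of all
four parameters; the smallest residual sum of squares wins. The reported
amplitude is non-negative and the phase is the time of the first model peak,
normalized to `[0, T)`.

Model comparison uses the small-sample corrected Akaike criterion,
`AICc = n ln(rss/n) + 2k + 2k(k+1)/(n - k - 1)`, counting the residual
variance as a parameter (line k = 3, sine k = 5): traces have ~60 points
after first-day exclusion, where the correction still matters. The
probability that a sine fits better than a line is operationalized as the
two-model Akaike weight of the sine; a trace is rhythmic when that weight
reaches 0.95 and the sine fit converged. The weight is invariant under
affine rescaling of the data, and for exact fits the residual sum of
squares is floored at the smallest positive double to keep the log finite.
Both the weight and its complement are available in the returned call, as
published "P values" of this kind are ambiguous about which side is
reported; the weight drives the verdict.

Replicate summaries average periods arithmetically and phases circularly
(unit vectors on a circle whose circumference is the mean period), so
phases of 21.9 h and 0.1 h at a 22 h period average to ~0, not 11.

# Set integration

Membership partitions split a focal gene set into light-and-clock,
light-only, clock-only, and neither. Term enrichment uses the upper-tail
hypergeometric probability with BH adjustment across terms; the population
defaults to all annotated genes (enrichment "relative to the whole
genome"), and terms annotating fewer than 2 population genes are skipped as
uninformative. Reproducibility between two samples' peak sets is the
squared Pearson correlation of `log2(x + 1)`-transformed coverage sums over
the union of both sets' intervals; the transform tames the heavy right tail
of coverage sums, and the statistic is symmetric in its arguments.

# The synthetic-data generators

The generators produce data with exactly the structure the analysis
assumes, plus planted truth for scoring:

* **Annotation**: non-overlapping single-interval genes in ~12 kb slots,
  with a configurable fraction (default 20%) of divergently transcribed
  head-to-head pairs whose transcription start sites face each other across
  less than 5 kb — the geometry that makes double assignment real.
* **ChIP coverage**: background combined coverage i.i.d. per base from
  `round(Lognormal(mu = 1, sigma = 0.5))`, split binomially between
  strands. The i.i.d. choice matches the caller's model so calibration
  tests are exact; an optional running-mean kernel (`backgroundSmooth`)
  introduces autocorrelation to stress-test robustness. Each planted site
  adds fragments whose forward anchors sit at `center - d/2` and reverse
  anchors at `center + d/2` (`d = 70` bp by default, Gaussian jitter 35 bp),
  each depositing a ~50 bp footprint on its strand; mode separation `d` is
  simulated directly because it is the quantity the shift filter tests,
  not sonication length distributions. Site height defaults to 30x the
  background median with a per-site occupancy factor `2^U(-0.4, 0.4)`
  carried in the truth table so replicate samples share it.
* **Expression tables**: lognormal baseline FPKM, planted
  `|log2fc| ~ Normal(2, 0.25)` effects (negative — activated — with
  probability 0.8), two replicates per genotype with multiplicative noise,
  p from a pooled-variance two-sample t-test on `log2(FPKM + 1)` and q by
  BH within condition. With two replicates per group the Welch
  approximation collapses to ~1 degree of freedom and has essentially no
  power, so the pooled test is used. This internal test exists only so
  synthetic tables carry coherent p/q columns; real tables come from an
  external differential-expression engine and are consumed as-is.
* **Reporter traces**: `y = baseline + trend*t +
  A exp(-damping*t) sin(2*pi*(t - phi0)/T) + noise`, sampled every 1.5 h
  over 114 h (77 samples), default period 20.3 h, damping 0.005/h, noise
  10% of amplitude, 12 replicates.
* **Gene sets**: target genes fall into the light/clock membership cells
  with probabilities 0.10/0.20/0.16/0.53 (normalized), non-targets at
  background rates 0.31 (light) and 0.23 (clock).

Every generator draws from its own stream derived from the single config
seed, so partial reruns reproduce, and the caller's RNG state is restored
afterwards.

What the generators do *not* emulate: mappability and GC structure, read
duplication, input-control biases, autocorrelated background (except via
the optional kernel), count-based expression noise (FPKMs are treated as
continuous), non-sinusoidal waveforms, and inter-replicate phase drift.
Passing the test suite therefore demonstrates correctness of the
algorithms under their stated assumptions, not robustness to every
pathology of real sequencing data.

# Problem sizes used by the tests and acceptance script

Calibration and null behaviour use twenty 10^6 bp genomes; planted
recovery uses 20 sites at 30x background; assignment is cross-checked
against a brute-force double loop on 200-gene annotations over 100 random
peak sets; expression analyses use 2000-gene tables; rhythm recovery uses
200 damped noisy traces and a 500-trace white-noise null; enrichment is
enumerated exhaustively for populations up to 12 genes. These sizes give
stable statistics (binomial standard errors a few percent or less) while
keeping a full run to a few minutes.

# A worked end-to-end example

```{r pipeline, eval = FALSE}
cfg <- pipelineConfig(outDir = "regulonscope_demo",
                      sim = simConfig(seed = 1))
report <- runPipeline(cfg)
str(report)
```

The report lists, per ChIP condition, the positions enriched, candidate
regions, FDR survivors, and shift survivors; then the per-condition and
union target counts, the binding-location split, the DE-filtered gene
count with its activated/repressed split, the direct/indirect partition,
the rhythmic replicate count with the period estimate, and the light/clock
membership percentages.

# Known limitations

* The caller's scan-corrected FDR is conservative by construction; weak
  but real binding sites (below roughly 10x background at default
  parameters) will be missed. Lower `alphaPosition` stringency does not
  rescue them because the scan correction dominates.
* Genes are single intervals; assignment cannot distinguish promoters of
  alternative transcripts.
* The rhythm module assumes a single stationary period within the search
  bounds; period lability and waveform asymmetry are not modeled.
* Windowed detrending mildly distorts the waveform when the window length
  is close to the oscillation period (24 h vs ~20 h here), biasing the
  recovered period downward by roughly 1-2%. This is well inside the
  replicate-to-replicate spread the pipeline reports; when amplitude decay
  is mild, `detrendWindowH = "linear"` avoids it entirely.
* The internal DE test is for synthetic-table coherence only and is not a
  substitute for a count-based differential-expression analysis.
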