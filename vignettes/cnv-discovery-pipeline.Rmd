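---
title: "Consensus CNV discovery, population screening and qPCR validation"
author: "CNVpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus CNV discovery, population screening and qPCR validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CNVpop)
library(GenomicRanges)
```

## The problem this package addresses

SNP-array copy number variant (CNV) calls are noisy: individual calling
algorithms disagree on both the existence and the breakpoints of events, and
small cohorts — typical for population-genetic surveys of isolated or
under-studied populations — leave no room for statistical error correction
across thousands of samples. The established remedy is procedural rather
than statistical: run several independent callers, keep only calls that are
well supported and well placed, collapse the survivors across samples into
copy number variable regions (CNVRs), and screen them against public CNV
catalogues to isolate what is genuinely new to the cohort. Candidate novel
variants are then confirmed on an orthogonal platform, usually quantitative
PCR.

`CNVpop` implements that whole chain as composable, testable stages, plus a
set of seeded simulators so the chain can be validated end-to-end against a
known answer without any external data.

## Coordinate conventions

Every coordinate inside the package is **1-based inclusive**, so that
`length = end − start + 1` reproduces the sizes printed in CNV tables
directly. BED-dialect and UCSC gap-table inputs (0-based half-open) are
converted at the reader boundary (`readReferenceSet()`, `readGapTable()`,
`readGenes()`), and nowhere else. Chromosome labels are normalized
(`"1"` and `"chr1"` are the same chromosome) because public catalogues mix
both dialects.

Two primitives carry most of the pipeline:

* **Reciprocal overlap**, `min(o/|a|, o/|b|)` for overlap `o` — the field's
  standard criterion for "the same event seen twice". It is symmetric, 1
  for identical intervals, and for nested intervals equals the length
  ratio.
* **Overlap components** — connected components of the ≥1 bp overlap graph
  of a set of intervals. Because interval overlap is transitive along a
  chromosome after merging, components are computed with
  `GenomicRanges::reduce(..., with.revmap = TRUE)` rather than an explicit
  graph; book-ended intervals (no shared base) are *not* connected.

## Stage 1 — QC and consensus

`filterRawCalls()` retains calls that are at least `minSizeBp` (default
1 kb) long and span at least `minProbes` (default 5) probes, and discards
complex-type calls (they carry no gain/loss direction and cannot be merged
with either). `applyExclusionZones()` removes calls on excluded chromosomes
(X and Y by default — hemizygous males make autosomal-style CN calling
unreliable there) and calls overlapping any assembly gap expanded by
`exclusionMarginBp` (default 300 kb) on both flanks; centromeric and
telomeric flanks are notorious for array artefacts. A chromosome with no
telomere gap records gets synthetic 1 bp anchors at its ends so the margin
rule always applies.

`consensusPerSample()` implements the *2-of-3 rule*: within each (sample,
chromosome, type) group, calls are linked by ≥1 bp overlap (a reciprocal
variant is configurable via `supportRule = "reciprocal"`), and each
connected component supported by at least `minAlgorithms` (default 2)
distinct algorithms emits one consensus call. Two genuinely open choices
are fixed here as defaults and kept configurable:

* **Support rule.** "Detected by at least two algorithms" has no canonical
  positional definition; we use any-overlap linkage, consistent with
  merge-then-count practice. A reciprocal-overlap variant exists for
  sensitivity analysis.
* **Consensus breakpoints.** The merged call spans the outermost
  breakpoints of its members (union), which retains all probe evidence;
  `consensusSpan = "intersection"` gives the conservative alternative.

## Stage 2 — CNVRs and frequencies

`buildCnvrs()` collapses consensus calls across samples, **type-agnostic**:
gains and losses may join one region, and a region carrying both is
classified `multi_allelic` — classification must follow component
formation, otherwise multi-allelic regions cannot exist. Carrier frequency
is carrier genomes over cohort size, not allele counts; a genome
contributing several member calls counts once, and the denominator is the
full genotyped cohort at every locus. Frequencies are stored at full
precision; `formatFrequency()` / `formatPercent()` apply the reporting
convention (2 decimals, half away from zero) only at output time.

## Stage 3 — novelty screen

`screenPopulationSpecific()` matches each consensus CNV against reference
tiers in order (an array-CNP catalogue, then DGV-, HapMap3- and SGVP-style
sets, by convention). A CNV is *known* to a tier when some entry exceeds
`roThreshold` (default 0.5) reciprocal overlap — **strictly**: a tie at
exactly 0.5 counts as novel, the reading consistent with defining novelty
as "below 50% reciprocal overlap". The boundary is explicitly tested.
Matching is type-agnostic by default (a catalogued gain can mask a study
loss; `typeAware = TRUE` is available) and per-CNV, not per-CNVR, since
filtering precedes region summarization. Survivors shorter than
`minNovelSizeBp` (default 10 kb) are removed — small array CNVs validate
poorly, driven by probe sparsity near breakpoints. Tier order affects only
provenance labels, never the surviving set (tested by permuting tiers).
`recurrenceTable()` groups survivors into loci with the CNVR component rule
and flags singletons versus recurrent loci.

## Stage 4 — qPCR validation

`estimateCopyNumber()` implements comparative CT: with target and
reference-gene Ct means in the test sample and a calibrator,
ΔΔCt = (Ct_target − Ct_ref)_test − (Ct_target − Ct_ref)_calibrator and the
copy number estimate is 2·2^(−ΔΔCt). The calibrator must be supplied
explicitly and is assumed diploid — 2^(−ΔΔCt) is only interpretable
against a declared reference state. Replicate-level estimates (replicate
*i* of the target paired with replicate *i* of the reference, against the
calibrator means) yield the sd and CV% = 100·sd/mean; a replicate-count
mismatch is a hard error. The CV is invariant under any uniform Ct shift,
which is what makes it a within-assay reproducibility measure.

`callIntegerCn()` uses fixed thresholds — below 1.5 → 1, at or above
2.5 → 3, else 2 — rather than nearest-integer rounding: deep losses
(estimate 0.45) must still call one copy, and a boundary estimate of
exactly 2.50 calls as a gain. `amplificationEfficiency()` fits mean Ct
against log10 concentration over a dilution series (five-fold, 50 ng/µl
down to 0.08 ng/µl, by convention) and reports 10^(−1/slope) − 1;
efficiencies outside 0.9–1.1 warn but do not gate, since no hard
acceptance band is standard. A flat curve is a named degenerate error.

`concordance()` scores a gain as validated only by copy number 3 and a
loss only by 1; `validationSummary()` reports the true-positive rate
overall and stratified at the 10 kb boundary.

## Stage 5 — gene annotation

`annotateGenes()` reports *involved* genes (≥1 bp overlap) and *disrupted*
genes (involved but not fully contained — a CNV boundary falls inside the
gene body), the only containment-based definition under which disrupted
genes form a strict subset of involved ones. `gainLossSignTest()` is an
exact binomial sign test: twice the one-sided tail of the larger count
under Binomial(n, ½), capped at 1. For a 15-versus-6 split this gives
p ≈ 0.078 — worth noting because gain/loss asymmetries of this size in
small region sets are *not* significant under an exact test, whatever a
normal approximation may suggest. GO/pathway enrichment is deliberately
out of scope (it depends on external versioned services);
`exportGeneList()` writes the submission-ready gene list.

## The simulators, and what they do and do not emulate

`SimulationConfig()` fixes the synthetic study conditions: 34 diploid
genomes; a miniature genome of four 30 Mb autosomes plus an excluded sex
chromosome (small enough for per-base brute-force oracles in the tests,
large enough to leave room outside the 300 kb margins); 500 truth loci
with sizes log-uniform on [1 kb, 1 Mb]; a founder-style carrier spectrum
(65% singletons, geometric tail, p = 0.5); equal gains and losses; three
callers with sensitivity 0.9, breakpoint jitter sd 500 bp, 2 false
positives per genome each, and probe spacings 400/600/800 bp; per-tier
known fractions 0.05/0.25/0.15/0.10 (array-CNP/DGV/HapMap3/SGVP); and
0.15-cycle Ct noise. These values were chosen once as a realistic
rendering of a small founder-population array study and are not tuned.

Placement is rejection-free: sizes are drawn first, loci are assigned to
free segments (the complement of the exclusion zones, shrunk by a further
5 kb buffer so jittered calls cannot leak into a zone) proportionally to
segment length with a capacity retry, and the slack within each segment is
distributed as uniform random gaps with a 1 kb minimum between loci. A
cohort that cannot fit raises a named error rather than looping forever.

Jitter is clamped to a quarter of the true span per endpoint, which
guarantees every emitted call retains at least half of the true span;
reference-tier boundary perturbation is clamped to an eighth of the span,
which guarantees reciprocal overlap above 0.5 with the source locus. Both
bounds are deterministic, so the closed-loop properties they protect hold
for every seed, not just on average.

The simulators deliberately do **not** model array intensity or
B-allele-frequency data, linkage disequilibrium, pedigree structure,
locus-specific probe density, or caller-correlated errors (false positives
are independent across callers, which is exactly why the 2-of-3 rule
removes them). Passing closed-loop tests therefore demonstrates the
correctness of the post-processing logic under the stated error model, not
the performance of any real caller on real arrays.

## Problem sizes and numerical choices

The bundled tests run the closed loop at 34 genomes × 500 loci (noise-free
and default-noise), the interval oracles on 200 random small instances
against per-base brute force, and the qPCR Monte-Carlo at 1,000 assays —
sizes chosen so the whole suite completes in a few minutes on one core
while keeping binomial confidence intervals tight enough to be
informative. Ties and degenerate inputs are handled explicitly: a
reciprocal overlap of exactly the threshold is novel; a size exactly on a
histogram bin edge falls in the upper bin; book-ended intervals merge in
`mergeOverlapping()` (their covered bases are contiguous) but do not link
consensus or CNVR components (no shared base); empty call sets flow
through the whole pipeline and produce all-zero reports.

## Known limitations

* Consensus and CNVR boundaries are union spans; heterogeneous breakpoints
  across many samples can stretch a CNVR well beyond any individual event.
* Carrier frequencies ignore genotype (a homozygous and a heterozygous
  carrier count the same), and the denominator never drops samples that
  failed locus-level QC — per-locus denominators were judged unknowable
  from typical published tables.
* The qPCR calculator assumes equal amplification efficiency of target and
  reference assays (classic ΔΔCt); efficiency-corrected quantification is
  a possible extension, not implemented.
* The screen treats reference catalogues as ground truth; a catalogue
  error propagates directly into the novelty labels.
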