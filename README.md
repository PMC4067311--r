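# CNVpop

Post-processing and validation pipeline for SNP-array copy number variant
(CNV) calls in small population cohorts — the kind of survey that genotypes
a few dozen genomes from an isolated population, calls CNVs with several
independent algorithms, and asks: *which of these variants are real, how
common are they in the cohort, and which are new to this population?*

The package is aimed at population and medical geneticists post-processing
multi-algorithm array CNV calls, and at methodologists who need a fully
simulated, ground-truthed test bed for CNV consensus/screening logic.

## What it computes

The pipeline chains five stages, each exposed as plain functions over
S4/`GRanges` containers:

1. **QC + consensus** (`filterRawCalls`, `applyExclusionZones`,
   `consensusPerSample`): keep calls ≥ 1 kb spanning ≥ 5 probes; drop sex
   chromosomes and anything within 300 kb of a centromere/telomere gap;
   merge per-sample calls supported by ≥ 2 of 3 algorithms into
   "stringent" consensus calls (union span of the supporting calls).
2. **CNVRs** (`buildCnvrs`, `carrierFrequency`, `classifyCounts`):
   collapse consensus calls across samples into copy number variable
   regions by overlap-component formation (type-agnostic, so regions
   carrying both gains and losses classify as *multi-allelic*), with
   carrier frequencies = carrier genomes / cohort size.
3. **Novelty screen** (`screenPopulationSpecific`, `recurrenceTable`):
   a CNV is *known* to a reference tier (array-CNP / DGV-like /
   HapMap3-like / SGVP-like) when reciprocal overlap
   `min(o/|a|, o/|b|)` exceeds 0.5 — a tie at exactly 0.5 is novel;
   survivors < 10 kb are discarded as unreliable. What remains is
   *population-specific*, tallied into singleton vs recurrent loci.
4. **qPCR validation** (`estimateCopyNumber`, `callIntegerCn`,
   `concordance`, `validationSummary`, `amplificationEfficiency`):
   comparative-CT copy number, CN = 2·2^(−ΔΔCt) against a diploid
   calibrator, with integer calls by fixed thresholds (< 1.5 → 1,
   ≥ 2.5 → 3) and CV% = 100·sd/mean across replicates.
5. **Gene annotation** (`annotateGenes`, `gainLossSignTest`): involved vs
   disrupted (boundary-crossing) genes, and an exact binomial sign test
   for gain/loss asymmetry among gene-bearing regions.

A seeded simulator suite (`SimulationConfig`, `simulateTruth`,
`simulateAlgorithmCalls`, `simulateReferenceSets`, `simulateQpcr`)
generates every input with known ground truth, so the whole chain is
testable closed-loop. See the vignette
(`vignettes/cnv-discovery-pipeline.Rmd`) for the model, parameter
rationale and limitations.

## Worked example

Simulate a 34-genome cohort with 120 planted CNV loci, three imperfect
callers and partially overlapping reference catalogues, then run the full
pipeline:

```r
library(CNVpop)
cfg   <- SimulationConfig(seed = 11, nTruthLoci = 120)
truth <- simulateTruth(cfg)
calls <- simulateAlgorithmCalls(truth, cfg)
refs  <- simulateReferenceSets(truth, cfg)
res   <- runPipeline(calls, cfg@genome, refs = refs,
                     nGenomes = cfg@nGenomes)
res$consensus
#> ConsensusCnvSet: 142 consensus calls ( 86 gain / 56 loss ) in 33 sample(s)
res$cnvrs
#> CnvrSet: 99 CNVRs ( 38 loss / 61 gain / 0 multi-allelic ) over 34 genomes
res$perGenome$meanPerGenome
#> [1] 4.2
head(res$recurrence, 3)
#>   chrom   start     end n_cnvs n_carriers recurrent
#> 1  chr1  721348 1108443      2          2      TRUE
#> 2  chr1 3743580 3761331      1          1     FALSE
#> 3  chr1 5914077 5932492      1          1     FALSE
```

142 raw-consensus events (mean 4.2 per genome) collapse into 99 CNVRs;
the recurrence table lists the population-specific loci that survived the
reference screen, with carrier counts distinguishing singletons from loci
seen in ≥ 2 unrelated genomes.

Validate one candidate locus by comparative-CT qPCR (triplicate Ct values
for target and FOXP2-style reference gene in test and calibrator samples):

```r
est <- estimateCopyNumber(QpcrAssay("candidate",
  targetCts      = c(24.71, 24.76, 24.68),
  refCts         = c(25.70, 25.70, 25.72),
  calibTargetCts = c(25.21, 25.15, 25.22),
  calibRefCts    = c(25.70, 25.68, 25.71),
  arrayCall = "gain"))
est
#> CnEstimate: CN 3 (2.80, sd 0.097, CV 3.5%)
concordance("gain", est@integerCall)
#> [1] "true_positive"
```

The unrounded estimate 2.80 calls as three copies (threshold ≥ 2.5),
validating the array gain. An exact sign test of a 15-gain / 6-loss split
among gene-bearing regions:

```r
gainLossSignTest(15, 6)
#> [1] 0.07835388
```

— not significant at 0.05, a useful caution for small region sets.

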