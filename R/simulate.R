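## Seeded simulators: cohort truth, three imperfect callers, reference
## catalogue tiers, and qPCR Ct replicates. These generate every input the
## pipeline consumes, with ground truth attached, so all stages can be
## exercised closed-loop.

#' Miniature genome build for simulation
#'
#' Four 30 Mb autosomes plus one excluded 20 Mb sex chromosome; 10 kb
#' telomere gaps at both ends of every chromosome and a 60 kb centromere
#' gap at each midpoint. Small enough for brute-force per-base oracles,
#' large enough to leave room outside the 300 kb exclusion margins.
#'
#' @return a [GenomeBuild-class].
#' @export
miniatureGenome <- function() {
  lens <- c(chr1 = 30e6, chr2 = 30e6, chr3 = 30e6, chr4 = 30e6,
            chrX = 20e6)
  teloW <- 10e3; centroW <- 60e3
  L <- unname(lens)
  gaps <- GenomicRanges::GRanges(
    rep(names(lens), each = 3),
    IRanges::IRanges(
      start = as.vector(rbind(1, L - teloW + 1, L / 2 - centroW / 2 + 1)),
      end = as.vector(rbind(teloW, L, L / 2 + centroW / 2))))
  gaps$gap_type <- rep(c("telomere", "telomere", "centromere"),
                       length(lens))
  GenomeBuild(lens, gaps = gaps, excludedChroms = "chrX")
}

#' SimulationConfig: study conditions for the synthetic cohort
#'
#' Defaults encode the study design the pipeline targets: 34 unrelated
#' diploid genomes, a CNV size spectrum log-uniform between 1 kb and 1 Mb,
#' a founder-style carrier spectrum dominated by singletons (65% of loci
#' have one carrier, geometric tail beyond), equal gains and losses, three
#' imperfect callers with distinct probe spacings, and triplicate Ct
#' measurements with 0.15-cycle noise.
#'
#' @slot nGenomes cohort size.
#' @slot genome a [GenomeBuild-class].
#' @slot nTruthLoci number of true CNV loci to plant.
#' @slot singletonWeight probability a locus has exactly one carrier.
#' @slot carrierGeomP geometric tail parameter for carrier counts >= 2.
#' @slot sizeRange log-uniform size range in bp.
#' @slot gainFraction probability a locus is a gain.
#' @slot fractionKnownPerTier named per-tier probability that a locus is
#'   present in that reference tier.
#' @slot algorithms,sensitivity,fpRate,jitterSd,probeSpacing parallel
#'   per-caller profiles: detection probability per carried event, Poisson
#'   false-positive count per genome, Gaussian breakpoint jitter sd (bp),
#'   and probe spacing (bp).
#' @slot complexRate Poisson rate of complex-type calls per genome for the
#'   last-listed caller (the only one emitting them).
#' @slot ctNoiseSd Gaussian Ct noise sd in cycles.
#' @slot seed mandatory integer seed; every generator derives its stream
#'   from it.
#' @export
setClass("SimulationConfig",
  slots = c(nGenomes = "numeric", genome = "GenomeBuild",
            nTruthLoci = "numeric", singletonWeight = "numeric",
            carrierGeomP = "numeric", sizeRange = "numeric",
            gainFraction = "numeric", fractionKnownPerTier = "numeric",
            algorithms = "character", sensitivity = "numeric",
            fpRate = "numeric", jitterSd = "numeric",
            probeSpacing = "numeric", complexRate = "numeric",
            ctNoiseSd = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  probs <- c(object@singletonWeight, object@carrierGeomP,
             object@gainFraction, object@fractionKnownPerTier,
             object@sensitivity)
  if (any(probs < 0 | probs > 1))
    msgs <- c(msgs, "probabilities must lie in [0, 1]")
  if (length(object@seed) != 1 || is.na(object@seed))
    msgs <- c(msgs, "a seed is mandatory")
  k <- length(object@algorithms)
  if (length(object@sensitivity) != k || length(object@fpRate) != k ||
      length(object@jitterSd) != k || length(object@probeSpacing) != k)
    msgs <- c(msgs, "per-algorithm profiles must be parallel vectors")
  if (length(object@sizeRange) != 2 ||
      object@sizeRange[1] >= object@sizeRange[2])
    msgs <- c(msgs, "sizeRange must be (min, max) with min < max")
  if (length(msgs)) msgs else TRUE
})

#' @rdname SimulationConfig-class
#' @param seed integer seed (mandatory).
#' @param nGenomes,genome,nTruthLoci,singletonWeight,carrierGeomP,sizeRange,gainFraction,fractionKnownPerTier,algorithms,sensitivity,fpRate,jitterSd,probeSpacing,complexRate,ctNoiseSd see slots.
#' @return a `SimulationConfig`.
#' @export
SimulationConfig <- function(seed,
    nGenomes = 34, genome = miniatureGenome(), nTruthLoci = 500,
    singletonWeight = 0.65, carrierGeomP = 0.5,
    sizeRange = c(1e3, 1e6), gainFraction = 0.5,
    fractionKnownPerTier = c(arrayCNP = 0.05, DGV = 0.25,
                             HapMap3 = 0.15, SGVP = 0.10),
    algorithms = c("gtc", "birdsuite", "ipattern"),
    sensitivity = c(0.9, 0.9, 0.9), fpRate = c(2, 2, 2),
    jitterSd = c(500, 500, 500), probeSpacing = c(400, 600, 800),
    complexRate = 1, ctNoiseSd = 0.15) {
  new("SimulationConfig", nGenomes = nGenomes, genome = genome,
      nTruthLoci = nTruthLoci, singletonWeight = singletonWeight,
      carrierGeomP = carrierGeomP, sizeRange = sizeRange,
      gainFraction = gainFraction,
      fractionKnownPerTier = fractionKnownPerTier,
      algorithms = algorithms, sensitivity = sensitivity, fpRate = fpRate,
      jitterSd = jitterSd, probeSpacing = probeSpacing,
      complexRate = complexRate, ctNoiseSd = ctNoiseSd,
      seed = as.integer(seed))
}

#' Noise-free variant of a simulation configuration
#'
#' Perfect sensitivity, zero jitter, zero false positives, no complex
#' calls and empty reference tiers — the configuration under which the
#' pipeline must reproduce the planted truth exactly.
#'
#' @param cfg a [SimulationConfig-class].
#' @return the modified `SimulationConfig`.
#' @export
noiseFreeConfig <- function(cfg) {
  k <- length(cfg@algorithms)
  cfg@sensitivity <- rep(1, k)
  cfg@jitterSd <- rep(0, k)
  cfg@fpRate <- rep(0, k)
  cfg@complexRate <- 0
  cfg@fractionKnownPerTier[] <- 0
  cfg
}

# Free placement territory: analysed chromosomes minus exclusion zones
# (with a safety buffer so jittered calls cannot leak into a zone).
freeSegments <- function(build, marginBp = 300000, bufferBp = 5000) {
  lens <- chromLengths(build)[analysedChroms(build)]
  whole <- GenomicRanges::GRanges(names(lens),
                                  IRanges::IRanges(1, as.integer(lens)))
  zones <- exclusionZones(build, marginBp + bufferBp)
  zones <- zones[as.character(GenomicRanges::seqnames(zones)) %in%
                   names(lens)]
  GenomicRanges::setdiff(whole, GenomicRanges::GRanges(
    GenomicRanges::seqnames(zones),
    IRanges::IRanges(GenomicRanges::start(zones),
                     GenomicRanges::end(zones))))
}

#' Simulate the cohort's true CNV landscape
#'
#' Places `nTruthLoci` non-overlapping loci uniformly in the territory
#' outside exclusion zones (sizes drawn first, loci allocated to free
#' segments proportionally to segment length with a capacity check, slack
#' distributed as uniform random gaps with a 1 kb minimum between loci),
#' then draws type, carriers and per-tier known flags. Fully reproducible
#' from the config seed.
#'
#' @param cfg a [SimulationConfig-class].
#' @return a `GRanges` with columns `locus_id`, `cn_type`, `carriers`
#'   (`CharacterList` of genome ids) and `known_in` (`CharacterList` of
#'   tier names; empty = private to the cohort).
#' @export
simulateTruth <- function(cfg) {
  set.seed(deriveSeed(cfg@seed, 1L))
  n <- cfg@nTruthLoci
  segs <- freeSegments(cfg@genome)
  if (n == 0) {
    out <- GenomicRanges::GRanges()
    out$locus_id <- character(0)
    out$cn_type <- character(0)
    out$carriers <- IRanges::CharacterList()
    out$known_in <- IRanges::CharacterList()
    return(out)
  }
  sizes <- round(exp(stats::runif(n, log(cfg@sizeRange[1]),
                                  log(cfg@sizeRange[2]))))
  gapMin <- 1000
  segW <- GenomicRanges::width(segs)
  assign <- NULL
  for (try in seq_len(200)) {
    a <- sample(length(segs), n, replace = TRUE, prob = segW)
    load <- tapply(sizes, factor(a, levels = seq_along(segs)), sum,
                   default = 0)
    kcnt <- tabulate(a, nbins = length(segs))
    if (all(load + pmax(kcnt - 1, 0) * gapMin <= segW)) {
      assign <- a
      break
    }
  }
  if (is.null(assign))
    stopNamed("genomeTooSmallError",
              "cannot place truth loci without overlap")
  starts <- integer(n)
  for (s in seq_along(segs)) {
    idx <- which(assign == s)
    if (!length(idx)) next
    idx <- idx[sample.int(length(idx))]
    k <- length(idx)
    slack <- segW[s] - sum(sizes[idx]) - (k - 1) * gapMin
    cuts <- stats::rexp(k + 1)
    gaps <- floor(slack * cuts / sum(cuts))
    pos <- GenomicRanges::start(segs)[s]
    for (j in seq_len(k)) {
      pos <- pos + gaps[j]
      starts[idx[j]] <- pos
      pos <- pos + sizes[idx[j]] + gapMin
    }
  }
  chrom <- as.character(GenomicRanges::seqnames(segs))[assign]
  out <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(starts, width = sizes))
  GenomeInfoDb::seqlevels(out) <- analysedChroms(cfg@genome)
  out <- sort(out)
  out$locus_id <- sprintf("L%04d", seq_len(n))
  out$cn_type <- ifelse(stats::runif(n) < cfg@gainFraction, "gain", "loss")
  genomes <- sprintf("NG%02d", seq_len(cfg@nGenomes))
  nCarriers <- ifelse(stats::runif(n) < cfg@singletonWeight, 1L,
                      2L + stats::rgeom(n, cfg@carrierGeomP))
  nCarriers <- pmin(nCarriers, cfg@nGenomes)
  out$carriers <- IRanges::CharacterList(lapply(nCarriers, function(k)
    sort(sample(genomes, k))))
  tiers <- names(cfg@fractionKnownPerTier)
  out$known_in <- IRanges::CharacterList(lapply(seq_len(n), function(i)
    tiers[stats::runif(length(tiers)) < cfg@fractionKnownPerTier]))
  out
}

#' Simulate raw calls from imperfect callers
#'
#' Each carried truth locus is emitted per caller with the caller's
#' sensitivity; breakpoints get independent Gaussian jitter clamped to a
#' quarter of the true span per endpoint (guaranteeing at least half of
#' the true span is retained); probe count is the jittered span divided by
#' the caller's probe spacing, rounded down. False positives are random
#' intervals at the caller's Poisson rate per genome; the last-listed
#' caller additionally emits complex-type calls at `complexRate` per
#' genome.
#'
#' @param truth output of [simulateTruth()].
#' @param cfg the same [SimulationConfig-class].
#' @return a [CnvCallSet-class] whose calls carry an extra `truth_locus`
#'   column (`NA` for false positives and complex calls).
#' @export
simulateAlgorithmCalls <- function(truth, cfg) {
  set.seed(deriveSeed(cfg@seed, 2L))
  lens <- chromLengths(cfg@genome)[analysedChroms(cfg@genome)]
  carriers <- truth$carriers
  events <- data.frame(
    locus = rep(seq_along(truth), lengths(carriers)),
    genome = unlist(carriers, use.names = FALSE),
    stringsAsFactors = FALSE)
  pieces <- list()
  for (j in seq_along(cfg@algorithms)) {
    alg <- cfg@algorithms[j]
    det <- stats::runif(nrow(events)) < cfg@sensitivity[j]
    ev <- events[det, , drop = FALSE]
    if (nrow(ev)) {
      tr <- truth[ev$locus]
      w <- GenomicRanges::width(tr)
      clamp <- floor(w / 4)
      ds <- pmax(pmin(round(stats::rnorm(nrow(ev), 0, cfg@jitterSd[j])),
                      clamp), -clamp)
      de <- pmax(pmin(round(stats::rnorm(nrow(ev), 0, cfg@jitterSd[j])),
                      clamp), -clamp)
      st <- GenomicRanges::start(tr) + ds
      en <- GenomicRanges::end(tr) + de
      st <- pmax(st, 1L)
      pieces[[length(pieces) + 1L]] <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(tr)),
        start = st, end = en, sample_id = ev$genome, algorithm = alg,
        cn_type = tr$cn_type,
        n_probes = floor((en - st + 1) / cfg@probeSpacing[j]),
        truth_locus = tr$locus_id, stringsAsFactors = FALSE)
    }
    # false positives, uniform over analysed territory
    nfp <- stats::rpois(cfg@nGenomes, cfg@fpRate[j])
    if (sum(nfp)) {
      genomes <- rep(sprintf("NG%02d", seq_len(cfg@nGenomes)), nfp)
      m <- length(genomes)
      fw <- round(exp(stats::runif(m, log(cfg@sizeRange[1]),
                                   log(cfg@sizeRange[2]))))
      ch <- sample(names(lens), m, replace = TRUE, prob = lens)
      fs <- floor(stats::runif(m, 1, pmax(2, lens[ch] - fw)))
      pieces[[length(pieces) + 1L]] <- data.frame(
        chrom = ch, start = fs, end = fs + fw - 1,
        sample_id = genomes, algorithm = alg,
        cn_type = sample(c("gain", "loss"), m, replace = TRUE),
        n_probes = floor(fw / cfg@probeSpacing[j]),
        truth_locus = NA_character_, stringsAsFactors = FALSE)
    }
    # complex-type calls, designated caller only (the last listed)
    if (j == length(cfg@algorithms) && cfg@complexRate > 0) {
      ncx <- stats::rpois(cfg@nGenomes, cfg@complexRate)
      if (sum(ncx)) {
        genomes <- rep(sprintf("NG%02d", seq_len(cfg@nGenomes)), ncx)
        m <- length(genomes)
        cw <- round(exp(stats::runif(m, log(cfg@sizeRange[1]),
                                     log(cfg@sizeRange[2]))))
        ch <- sample(names(lens), m, replace = TRUE, prob = lens)
        cs <- floor(stats::runif(m, 1, pmax(2, lens[ch] - cw)))
        pieces[[length(pieces) + 1L]] <- data.frame(
          chrom = ch, start = cs, end = cs + cw - 1,
          sample_id = genomes, algorithm = alg, cn_type = "complex",
          n_probes = floor(cw / cfg@probeSpacing[j]),
          truth_locus = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(pieces)) {
    x <- CnvCallSet(character(0), integer(0), integer(0), character(0),
                    character(0), character(0), integer(0))
    x@calls$truth_locus <- character(0)
    return(x)
  }
  df <- do.call(rbind, pieces)
  x <- CnvCallSet(df$chrom, df$start, df$end, df$sample_id, df$algorithm,
                  df$cn_type, df$n_probes)
  x@calls$truth_locus <- df$truth_locus
  x
}

#' Simulate tiered reference CNV catalogues
#'
#' Every truth locus flagged known in a tier is emitted into that tier
#' with mild boundary perturbation (Gaussian, clamped to an eighth of the
#' span per endpoint, which guarantees reciprocal overlap above 0.5 with
#' the source locus). Decoy entries overlapping no truth locus are added
#' to each tier.
#'
#' @param truth output of [simulateTruth()].
#' @param cfg the same [SimulationConfig-class].
#' @param nDecoys decoy entries per tier.
#' @return a named list of [ReferenceSet-class], one per configured tier,
#'   in screening order.
#' @export
simulateReferenceSets <- function(truth, cfg, nDecoys = 50) {
  set.seed(deriveSeed(cfg@seed, 3L))
  lens <- chromLengths(cfg@genome)[analysedChroms(cfg@genome)]
  tiers <- names(cfg@fractionKnownPerTier)
  out <- list()
  for (tier in tiers) {
    inTier <- vapply(truth$known_in, function(t) tier %in% t, logical(1))
    tr <- truth[inTier]
    if (length(tr)) {
      w <- GenomicRanges::width(tr)
      clamp <- floor(w / 8)
      ds <- pmax(pmin(round(stats::rnorm(length(tr), 0,
                                         pmin(100, w / 16))), clamp),
                 -clamp)
      de <- pmax(pmin(round(stats::rnorm(length(tr), 0,
                                         pmin(100, w / 16))), clamp),
                 -clamp)
      entries <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(tr),
        IRanges::IRanges(pmax(1L, GenomicRanges::start(tr) + ds),
                         GenomicRanges::end(tr) + de))
      entries$cn_type <- tr$cn_type
    } else {
      entries <- GenomicRanges::GRanges(
        factor(character(0), levels = names(lens)), IRanges::IRanges())
      entries$cn_type <- character(0)
    }
    # decoys: random intervals rejected against the truth set
    made <- 0L; decoys <- list()
    while (made < nDecoys) {
      m <- nDecoys - made
      dw <- round(exp(stats::runif(m, log(cfg@sizeRange[1]),
                                   log(cfg@sizeRange[2]))))
      ch <- sample(names(lens), m, replace = TRUE, prob = lens)
      dstart <- floor(stats::runif(m, 1, pmax(2, lens[ch] - dw)))
      cand <- GenomicRanges::GRanges(factor(ch, levels = names(lens)),
        IRanges::IRanges(dstart, width = dw))
      if (length(truth)) {
        hit <- GenomicRanges::findOverlaps(cand, GenomicRanges::granges(
          truth))
        bad <- unique(S4Vectors::queryHits(hit))
        cand <- cand[setdiff(seq_along(cand), bad)]
      }
      if (length(cand)) {
        cand$cn_type <- NA_character_
        decoys[[length(decoys) + 1L]] <- cand
        made <- made + length(cand)
      }
    }
    all <- c(entries, do.call(c, decoys))
    out[[tier]] <- ReferenceSet(tier, sort(all))
  }
  out
}

#' Simulate qPCR Ct replicate tables
#'
#' For each (locus, true copy number) pair, emits triplicate Ct values for
#' the target and the reference gene in both the test sample and a diploid
#' calibrator. The target Ct of the test sample is shifted by
#' -log2(CN / 2) so the comparative-CT estimate is centred on the true
#' copy number; all values carry Gaussian noise of `cfg@ctNoiseSd` cycles.
#'
#' @param trueCn a `data.frame` with columns `locus` and `cn`
#'   (integer copy number in 1..3).
#' @param cfg a [SimulationConfig-class].
#' @param nReplicates replicates per series (default 3).
#' @return a `data.frame` in the dialect of [readCtTable()].
#' @export
simulateQpcr <- function(trueCn, cfg, nReplicates = 3) {
  set.seed(deriveSeed(cfg@seed, 4L))
  baseTarget <- 27; baseRef <- 25
  rows <- lapply(seq_len(nrow(trueCn)), function(i) {
    cn <- trueCn$cn[i]
    mk <- function(role, gene, centre) data.frame(
      locus = trueCn$locus[i], sample_role = role, gene_role = gene,
      replicate = seq_len(nReplicates),
      ct = centre + stats::rnorm(nReplicates, 0, cfg@ctNoiseSd),
      stringsAsFactors = FALSE)
    rbind(mk("test", "target", baseTarget - log2(cn / 2)),
          mk("test", "reference", baseRef),
          mk("calibrator", "target", baseTarget),
          mk("calibrator", "reference", baseRef))
  })
  do.call(rbind, rows)
}
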