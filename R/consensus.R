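## Stage 1: call-level QC, exclusion zones, and 2-of-3 consensus merging.

#' Apply call-level QC filters
#'
#' Retains exactly the calls that are at least `minSizeBp` long, span at
#' least `minProbes` probes and are not of complex type; input order is
#' preserved. Calls with a missing probe count are a validation error, not
#' silently dropped.
#'
#' @param x a [CnvCallSet-class].
#' @param cfg a [FilterConfig-class].
#' @return a filtered `CnvCallSet`.
#' @export
filterRawCalls <- function(x, cfg = FilterConfig()) {
  gr <- granges2(x)
  if (anyNA(gr$n_probes))
    stopNamed("missingProbeCountError",
              "n_probes missing on one or more calls")
  keep <- GenomicRanges::width(gr) >= cfg@minSizeBp &
    gr$n_probes >= cfg@minProbes &
    gr$cn_type != "complex"
  asCnvCallSet(gr[keep])
}

#' Exclusion zones of a genome build
#'
#' Expands every centromere/telomere gap by `marginBp` on both flanks,
#' clipped to chromosome bounds. Chromosomes with no telomere gap records
#' get 1 bp telomere anchors at position 1 and at the chromosome end, so
#' the margin rule is always applicable.
#'
#' @param build a [GenomeBuild-class].
#' @param marginBp flank size in bp (default 300 kb).
#' @return a reduced `GRanges` of excluded territory.
#' @export
exclusionZones <- function(build, marginBp = 300000) {
  gaps <- gapRanges(build)
  lens <- chromLengths(build)
  teloChroms <- unique(as.character(GenomicRanges::seqnames(
    gaps[gaps$gap_type == "telomere"])))
  anchorChroms <- setdiff(names(lens), teloChroms)
  if (length(anchorChroms)) {
    anchors <- GenomicRanges::GRanges(
      rep(anchorChroms, each = 2),
      IRanges::IRanges(
        start = as.vector(rbind(1L, lens[anchorChroms])),
        width = 1L),
      seqinfo = build@seqinfo)
    anchors$gap_type <- "telomere"
    gaps <- c(gaps, anchors)
  }
  zone <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(gaps),
    IRanges::IRanges(
      pmax(1L, GenomicRanges::start(gaps) - marginBp),
      pmin(lens[as.character(GenomicRanges::seqnames(gaps))],
           GenomicRanges::end(gaps) + marginBp)),
    seqinfo = build@seqinfo)
  GenomicRanges::reduce(sort(zone))
}

#' Remove calls on excluded chromosomes or near assembly gaps
#'
#' Drops calls on the build's excluded chromosomes (sex chromosomes by
#' default) and calls overlapping any gap interval expanded by
#' `cfg@exclusionMarginBp` on both flanks.
#'
#' @param x a [CnvCallSet-class].
#' @param build a [GenomeBuild-class]; calls on chromosomes unknown to the
#'   build raise a validation error listing the offending labels.
#' @param cfg a [FilterConfig-class].
#' @return a filtered `CnvCallSet`.
#' @export
applyExclusionZones <- function(x, build, cfg = FilterConfig()) {
  gr <- granges2(x)
  chrom <- normalizeChrom(GenomicRanges::seqnames(gr))
  known <- GenomeInfoDb::seqlevels(build@seqinfo)
  unknown <- setdiff(unique(chrom), union(known, cfg@excludedChroms))
  if (length(unknown))
    stopNamed("unknownChromosomeError",
              paste("chromosomes absent from build:",
                    paste(unknown, collapse = ", ")))
  excluded <- union(excludedChroms(build), cfg@excludedChroms)
  gr <- gr[!chrom %in% excluded]
  if (!length(gr)) return(asCnvCallSet(gr))
  zones <- exclusionZones(build, cfg@exclusionMarginBp)
  bare <- GenomicRanges::GRanges(
    normalizeChrom(GenomicRanges::seqnames(gr)),
    IRanges::IRanges(GenomicRanges::start(gr), GenomicRanges::end(gr)))
  hit <- GenomicRanges::findOverlaps(bare, zones)
  drop <- unique(S4Vectors::queryHits(hit))
  keep <- setdiff(seq_along(gr), drop)
  asCnvCallSet(gr[keep])
}

# Component labels within one (sample, chromosome, type) group under the
# configured support rule.
supportComponents <- function(gr, cfg) {
  if (cfg@supportRule == "any") return(overlapComponents(gr))
  hits <- GenomicRanges::findOverlaps(gr, gr)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  keep <- qi < si
  qi <- qi[keep]; si <- si[keep]
  if (length(qi)) {
    ro <- reciprocalOverlap(gr[qi], gr[si])
    ok <- ro >= cfg@supportRoThreshold
    edges <- cbind(qi[ok], si[ok])
  } else edges <- cbind(integer(0), integer(0))
  comp <- unionFind(length(gr), edges)
  match(comp, unique(comp))
}

#' Build per-sample consensus (stringent) CNV calls
#'
#' Within each (sample, chromosome, type) group, calls are linked under the
#' support rule (>= 1 bp overlap by default) and each connected component
#' supported by at least `cfg@minAlgorithms` distinct algorithms emits one
#' consensus call spanning its members (outermost breakpoints under the
#' default union rule). Components with insufficient algorithm support emit
#' nothing. Complex-type calls never participate.
#'
#' @param x a QC-filtered [CnvCallSet-class].
#' @param cfg a [FilterConfig-class].
#' @return a [ConsensusCnvSet-class], sorted by position within sample.
#' @export
consensusPerSample <- function(x, cfg = FilterConfig()) {
  gr <- granges2(x)
  gr <- gr[gr$cn_type %in% c("gain", "loss")]
  emptyOut <- function() {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      sample_id = character(0), cn_type = character(0),
      support = IRanges::CharacterList(), n_members = integer(0))
    members <- GenomicRanges::GRanges()
    members$consensus_id <- integer(0)
    new("ConsensusCnvSet", ranges = out, memberCalls = members)
  }
  if (!length(gr)) return(emptyOut())
  key <- paste(gr$sample_id,
               normalizeChrom(GenomicRanges::seqnames(gr)),
               gr$cn_type, sep = "\r")
  idxByGroup <- split(seq_along(gr), key)
  rows <- list(); memberRows <- list(); cid <- 0L
  for (idx in idxByGroup) {
    g <- gr[idx]
    comp <- supportComponents(g, cfg)
    for (cmp in unique(comp)) {
      sel <- comp == cmp
      algs <- unique(g$algorithm[sel])
      if (length(algs) < cfg@minAlgorithms) next
      cid <- cid + 1L
      st <- GenomicRanges::start(g)[sel]
      en <- GenomicRanges::end(g)[sel]
      span <- if (cfg@consensusSpan == "union")
        c(min(st), max(en)) else c(max(st), min(en))
      rows[[cid]] <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(g))[1],
        start = span[1], end = span[2],
        sample_id = g$sample_id[1], cn_type = g$cn_type[1],
        support = paste(sort(algs), collapse = ","),
        n_members = sum(sel), stringsAsFactors = FALSE)
      mg <- g[sel]
      mg$consensus_id <- cid
      memberRows[[cid]] <- mg
    }
  }
  if (!cid) return(emptyOut())
  df <- do.call(rbind, rows)
  out <- GenomicRanges::GRanges(df$chrom,
                                IRanges::IRanges(df$start, df$end))
  out$sample_id <- df$sample_id
  out$cn_type <- df$cn_type
  out$support <- IRanges::CharacterList(strsplit(df$support, ","))
  out$n_members <- df$n_members
  ord <- order(df$sample_id, df$chrom, df$start, df$end)
  members <- do.call(c, unname(memberRows))
  # renumber member consensus_id to follow the sorted consensus order
  members$consensus_id <- match(members$consensus_id, ord)
  new("ConsensusCnvSet", ranges = out[ord], memberCalls = members)
}

#' Per-genome summary of a consensus call set
#'
#' Totals, gain/loss split, mean calls per genome (one decimal, half away
#' from zero), the per-genome call-count range (over genomes with at least
#' one call) and the size range.
#'
#' @param x a [ConsensusCnvSet-class] (or any `GRanges`-backed set with a
#'   `sample_id` and `cn_type` column).
#' @param nGenomes number of genotyped genomes (>= 1).
#' @return a list with elements `nTotal`, `nGain`, `nLoss`,
#'   `meanPerGenome`, `perGenomeMin`, `perGenomeMax`, `minSize`, `maxSize`.
#' @examples
#' ## 1,111 stringent calls over 34 genomes give a mean of 32.7 per genome
#' @export
perGenomeSummary <- function(x, nGenomes) {
  if (length(nGenomes) != 1 || is.na(nGenomes) || nGenomes < 1)
    stopNamed("emptyCohortError", "nGenomes must be >= 1")
  gr <- granges2(x)
  n <- length(gr)
  counts <- if (n) table(gr$sample_id) else integer(0)
  list(
    nTotal = n,
    nGain = if (n) sum(gr$cn_type == "gain") else 0L,
    nLoss = if (n) sum(gr$cn_type == "loss") else 0L,
    meanPerGenome = roundHalfUp(n / nGenomes, 1),
    perGenomeMin = if (length(counts)) min(counts) else 0L,
    perGenomeMax = if (length(counts)) max(counts) else 0L,
    minSize = if (n) min(GenomicRanges::width(gr)) else NA_integer_,
    maxSize = if (n) max(GenomicRanges::width(gr)) else NA_integer_)
}

#' Per-algorithm and merged summary table
#'
#' A compact cohort summary: one column block per calling algorithm from
#' the raw calls and one for the merged consensus — total gain/loss/complex
#' counts, mean calls per genome (one decimal) and min/max call size.
#'
#' @param raw a [CnvCallSet-class] of raw calls.
#' @param consensus a [ConsensusCnvSet-class].
#' @param nGenomes cohort size.
#' @return a `data.frame` with one row per algorithm plus `"merged"`.
#' @export
algorithmSummaryTable <- function(raw, consensus, nGenomes) {
  gr <- granges2(raw)
  algs <- sort(unique(gr$algorithm))
  oneBlock <- function(sub, label) {
    n <- length(sub)
    data.frame(
      set = label,
      gain = sum(sub$cn_type == "gain"),
      loss = sum(sub$cn_type == "loss"),
      complex = sum(sub$cn_type == "complex"),
      total = n,
      mean_per_genome = roundHalfUp(n / nGenomes, 1),
      min_size = if (n) min(GenomicRanges::width(sub)) else NA_integer_,
      max_size = if (n) max(GenomicRanges::width(sub)) else NA_integer_,
      stringsAsFactors = FALSE)
  }
  blocks <- lapply(algs, function(a) oneBlock(gr[gr$algorithm == a], a))
  blocks <- c(blocks, list(oneBlock(granges2(consensus), "merged")))
  do.call(rbind, blocks)
}
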