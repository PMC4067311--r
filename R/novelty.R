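## Stage 3: reciprocal-overlap screening against tiered reference CNV
## catalogues (array CNP loci, DGV-, HapMap3-, SGVP-style sets).

# Best reciprocal overlap of each query range against a reference GRanges.
# Returns a data.frame (best_ro, best_idx); best_idx NA when no overlap.
bestReferenceHit <- function(query, ref, queryType = NULL,
                             typeAware = FALSE) {
  n <- length(query)
  res <- data.frame(best_ro = numeric(n), best_idx = rep(NA_integer_, n))
  if (!n || !length(ref)) return(res)
  bareQ <- GenomicRanges::GRanges(
    normalizeChrom(GenomicRanges::seqnames(query)),
    IRanges::IRanges(GenomicRanges::start(query),
                     GenomicRanges::end(query)))
  bareR <- GenomicRanges::GRanges(
    normalizeChrom(GenomicRanges::seqnames(ref)),
    IRanges::IRanges(GenomicRanges::start(ref), GenomicRanges::end(ref)))
  # a tier may cover chromosomes the study set lacks (and vice versa);
  # the seqlevel mismatch is routine here, not a data problem
  hits <- suppressWarnings(GenomicRanges::findOverlaps(bareQ, bareR))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  if (typeAware && !is.null(queryType)) {
    rt <- ref$cn_type[si]
    keep <- is.na(rt) | rt == queryType[qi]
    qi <- qi[keep]; si <- si[keep]
  }
  if (length(qi)) {
    ro <- reciprocalOverlap(bareQ[qi], bareR[si])
    for (k in order(ro)) {  # last write wins: the maximizing entry
      res$best_ro[qi[k]] <- ro[k]
      res$best_idx[qi[k]] <- si[k]
    }
  }
  res
}

#' Match CNVs against one reference tier
#'
#' A CNV is *known* to the tier iff some reference entry has reciprocal
#' overlap strictly greater than `cfg@roThreshold` with it (and the same
#' type, when `cfg@typeAware`); a tie at exactly the threshold is novel.
#' The maximizing entry is reported for every CNV.
#'
#' @param x a [ConsensusCnvSet-class] or `GRanges` of study CNVs.
#' @param ref a [ReferenceSet-class].
#' @param cfg a [NoveltyConfig-class].
#' @return a `data.frame` with one row per CNV: `status`
#'   (`"known"`/`"novel"`), `best_ro`, and the best match's coordinates
#'   (`NA` when nothing overlaps).
#' @export
matchReference <- function(x, ref, cfg = NoveltyConfig()) {
  gr <- if (is(x, "GRanges")) x else granges2(x)
  hit <- bestReferenceHit(gr, granges2(ref), queryType = gr$cn_type,
                          typeAware = cfg@typeAware)
  rr <- granges2(ref)
  has <- !is.na(hit$best_idx)
  data.frame(
    status = ifelse(hit$best_ro > cfg@roThreshold, "known", "novel"),
    best_ro = hit$best_ro,
    match_chrom = ifelse(has,
      as.character(GenomicRanges::seqnames(rr))[hit$best_idx],
      NA_character_),
    match_start = ifelse(has, GenomicRanges::start(rr)[hit$best_idx],
                         NA_integer_),
    match_end = ifelse(has, GenomicRanges::end(rr)[hit$best_idx],
                       NA_integer_),
    stringsAsFactors = FALSE)
}

#' Screen CNVs for population specificity across reference tiers
#'
#' Tiers are evaluated in the order given (array-CNP catalogue first, then
#' DGV-, HapMap3- and SGVP-style sets by convention); a CNV known to any
#' tier is eliminated with that tier recorded as provenance. Survivors of
#' every tier are then subjected to the minimum-size rule
#' (`cfg@minNovelSizeBp`, default 10 kb); undersized CNVs are eliminated
#' with provenance `"size"`. Tier order affects only provenance labels,
#' never the surviving set.
#'
#' @param x a [ConsensusCnvSet-class].
#' @param refs a list of [ReferenceSet-class] tiers, in screening order.
#' @param cfg a [NoveltyConfig-class].
#' @return a list with `specific` (the surviving `ConsensusCnvSet`) and
#'   `provenance` (a `data.frame`: one row per input CNV with its id,
#'   `eliminated_by` tier label / `"size"` / `"specific"`, and the best
#'   reciprocal overlap seen across all tiers).
#' @export
screenPopulationSpecific <- function(x, refs, cfg = NoveltyConfig()) {
  gr <- granges2(x)
  n <- length(gr)
  ids <- if (n) sprintf("%s:%d-%d:%s:%s",
                        as.character(GenomicRanges::seqnames(gr)),
                        GenomicRanges::start(gr), GenomicRanges::end(gr),
                        gr$cn_type, gr$sample_id) else character(0)
  eliminated <- rep(NA_character_, n)
  bestRo <- numeric(n)
  for (ref in refs) {
    m <- matchReference(gr, ref, cfg)
    bestRo <- pmax(bestRo, m$best_ro)
    newKnown <- is.na(eliminated) & m$status == "known"
    eliminated[newKnown] <- ref@name
  }
  small <- is.na(eliminated) & GenomicRanges::width(gr) < cfg@minNovelSizeBp
  eliminated[small] <- "size"
  eliminated[is.na(eliminated)] <- "specific"
  keep <- eliminated == "specific"
  members <- x@memberCalls
  if (!is.null(members$consensus_id) && length(members)) {
    sel <- members$consensus_id %in% which(keep)
    members <- members[sel]
    members$consensus_id <- match(members$consensus_id, which(keep))
  }
  list(
    specific = new("ConsensusCnvSet", ranges = gr[keep],
                   memberCalls = members),
    provenance = data.frame(cnv_id = ids, eliminated_by = eliminated,
                            best_ro = bestRo, stringsAsFactors = FALSE))
}

#' Recurrence of population-specific CNVs
#'
#' Groups population-specific CNVs into loci with the same cross-sample
#' component rule used for CNVRs and tallies carriers per locus,
#' distinguishing singletons (one carrier genome) from recurrent loci.
#'
#' @param x a [ConsensusCnvSet-class] of population-specific CNVs.
#' @return a `data.frame` with one row per locus: coordinates, `n_cnvs`
#'   (member calls), `n_carriers` (distinct genomes) and `recurrent`.
#' @export
recurrenceTable <- function(x) {
  gr <- granges2(x)
  if (!length(gr))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_cnvs = integer(0),
                      n_carriers = integer(0), recurrent = logical(0)))
  bare <- GenomicRanges::GRanges(
    normalizeChrom(GenomicRanges::seqnames(gr)),
    IRanges::IRanges(GenomicRanges::start(gr), GenomicRanges::end(gr)))
  comp <- overlapComponents(bare)
  rows <- lapply(unique(comp), function(cmp) {
    sel <- comp == cmp
    g <- gr[sel]
    data.frame(
      chrom = as.character(GenomicRanges::seqnames(g))[1],
      start = min(GenomicRanges::start(g)),
      end = max(GenomicRanges::end(g)),
      n_cnvs = sum(sel),
      n_carriers = length(unique(g$sample_id)),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df$recurrent <- df$n_carriers >= 2
  df
}
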