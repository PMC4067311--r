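## Stage 2: cross-sample CNVR construction, classification, frequencies.

#' Collapse consensus calls into copy number variable regions
#'
#' CNVRs are the connected components of the cross-sample overlap graph
#' (>= 1 bp, type-agnostic — gains and losses can join one region, which is
#' what makes multi-allelic CNVRs possible). Each CNVR spans the outermost
#' breakpoints of its members and is classified `gain` or `loss` when all
#' members agree, `multi_allelic` when both types occur. Carriers are the
#' distinct sample ids among members; frequency is carriers / `nGenomes`,
#' stored at full precision.
#'
#' @param consensus a [ConsensusCnvSet-class].
#' @param nGenomes cohort size used as the frequency denominator (>= 1).
#' @return a [CnvrSet-class], sorted by position.
#' @export
buildCnvrs <- function(consensus, nGenomes) {
  if (length(nGenomes) != 1 || is.na(nGenomes) || nGenomes < 1)
    stopNamed("emptyCohortError", "nGenomes must be >= 1")
  gr <- granges2(consensus)
  if (!length(gr)) {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      type_class = character(0), carriers = IRanges::CharacterList(),
      n_carriers = integer(0), frequency = numeric(0))
    members <- GenomicRanges::GRanges(); members$cnvr_id <- integer(0)
    return(new("CnvrSet", ranges = out, members = members,
               nGenomes = nGenomes))
  }
  bare <- GenomicRanges::GRanges(
    normalizeChrom(GenomicRanges::seqnames(gr)),
    IRanges::IRanges(GenomicRanges::start(gr), GenomicRanges::end(gr)))
  comp <- overlapComponents(bare)
  ids <- unique(comp)
  rows <- lapply(ids, function(cmp) {
    sel <- comp == cmp
    g <- gr[sel]
    types <- unique(g$cn_type)
    carriers <- sort(unique(g$sample_id))
    data.frame(
      chrom = as.character(GenomicRanges::seqnames(g))[1],
      start = min(GenomicRanges::start(g)),
      end = max(GenomicRanges::end(g)),
      type_class = if (length(types) > 1) "multi_allelic" else types,
      n_carriers = length(carriers),
      carriers = paste(carriers, collapse = ","),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  out <- GenomicRanges::GRanges(df$chrom,
                                IRanges::IRanges(df$start, df$end))
  out$type_class <- df$type_class
  out$carriers <- IRanges::CharacterList(strsplit(df$carriers, ","))
  out$n_carriers <- df$n_carriers
  out$frequency <- df$n_carriers / nGenomes
  ord <- order(df$chrom, df$start, df$end)
  members <- gr
  members$cnvr_id <- match(match(comp, ids), ord)
  new("CnvrSet", ranges = out[ord], members = members,
      nGenomes = nGenomes)
}

#' Carrier frequency
#'
#' Fraction of genotyped genomes carrying at least one CNV at a locus.
#' A genome contributing several member calls to one CNVR counts once.
#'
#' @param x a [CnvrSet-class] (frequencies of every CNVR) or a numeric
#'   vector of carrier counts.
#' @param nGenomes cohort denominator (>= 1; defaults to the `CnvrSet`'s
#'   own denominator).
#' @return numeric vector of frequencies at full precision.
#' @seealso [formatFrequency()], [formatPercent()] for report rounding.
#' @export
carrierFrequency <- function(x, nGenomes = NULL) {
  if (is(x, "CnvrSet")) {
    if (is.null(nGenomes)) nGenomes <- x@nGenomes
    x <- granges2(x)$n_carriers
  }
  if (is.null(nGenomes) || length(nGenomes) != 1 || is.na(nGenomes) ||
      nGenomes < 1)
    stopNamed("emptyCohortError", "nGenomes must be >= 1")
  if (any(x > nGenomes))
    stopNamed("carrierCountError", "more carriers than genomes")
  x / nGenomes
}

#' Report-time frequency rounding
#'
#' Frequencies are stored at full precision; published tables print them to
#' two decimals (half away from zero) or as whole percentages.
#'
#' @param f numeric vector of frequencies.
#' @param digits decimal places (default 2).
#' @return rounded numeric vector.
#' @export
formatFrequency <- function(f, digits = 2) roundHalfUp(f, digits)

#' @rdname formatFrequency
#' @export
formatPercent <- function(f, digits = 0) roundHalfUp(100 * f, digits)

#' Count CNVRs by type class
#'
#' @param x a [CnvrSet-class].
#' @return named integer vector `(n_loss, n_gain, n_multi, n_total)` with
#'   `n_total` the sum of the three classes.
#' @export
classifyCounts <- function(x) {
  tc <- granges2(x)$type_class
  c(n_loss = sum(tc == "loss"), n_gain = sum(tc == "gain"),
    n_multi = sum(tc == "multi_allelic"), n_total = length(tc))
}

#' Size histogram of CNVs or CNVRs
#'
#' Counts per half-open size bin `[edge_i, edge_{i+1})`; an item whose size
#' equals a bin edge falls in the upper bin. Sizes outside the outermost
#' edges are a validation error so that counts always sum to the number of
#' items.
#'
#' @param x a [CnvrSet-class], [ConsensusCnvSet-class], `GRanges`, or a
#'   numeric vector of sizes in bp.
#' @param binEdges strictly increasing numeric vector of bin boundaries.
#' @return integer vector of counts, one per bin.
#' @export
sizeDistribution <- function(x, binEdges) {
  if (any(diff(binEdges) <= 0))
    stopNamed("binEdgeError", "bin edges must be strictly increasing")
  sizes <- if (is.numeric(x)) x else
    GenomicRanges::width(if (is(x, "GRanges")) x else granges2(x))
  if (length(sizes) &&
      (any(sizes < binEdges[1]) || any(sizes >= binEdges[length(binEdges)])))
    stopNamed("binRangeError",
              "sizes outside the outermost bin edges")
  bin <- findInterval(sizes, binEdges)
  tabulate(bin, nbins = length(binEdges) - 1L)
}
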