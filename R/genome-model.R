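## Interval arithmetic under 1-based inclusive coordinates.
##
## Every coordinate in this package is 1-based inclusive, so that
## length = end - start + 1 reproduces printed CNV sizes directly; BED and
## UCSC gap-table inputs (0-based half-open) are converted at the reader
## boundary.

#' Inclusive interval length
#'
#' @param x a `GRanges` (1-based inclusive, as everywhere in this package).
#' @return integer vector of lengths in bp (`end - start + 1`).
#' @examples
#' intervalLength(GenomicRanges::GRanges("chr2",
#'   IRanges::IRanges(41716288, 41781081)))  # 64794
#' @export
intervalLength <- function(x) GenomicRanges::width(x)

#' Pairwise overlap in base pairs
#'
#' Elementwise overlap of two `GRanges` (recycled to a common length):
#' 0 when on different chromosomes or disjoint, otherwise the inclusive
#' intersection length. Chromosome labels are normalized before comparison
#' so `"1"` and `"chr1"` match.
#'
#' @param a,b `GRanges` objects, recycled to the longer length.
#' @return integer vector of overlap sizes in bp.
#' @export
overlapBp <- function(a, b) {
  n <- max(length(a), length(b))
  if (n == 0L) return(integer(0))
  a <- rep(a, length.out = n)
  b <- rep(b, length.out = n)
  same <- normalizeChrom(GenomicRanges::seqnames(a)) ==
    normalizeChrom(GenomicRanges::seqnames(b))
  ov <- pmin(GenomicRanges::end(a), GenomicRanges::end(b)) -
    pmax(GenomicRanges::start(a), GenomicRanges::start(b)) + 1L
  as.integer(ifelse(same & ov > 0L, ov, 0L))
}

#' Pairwise reciprocal overlap
#'
#' The standard criterion for declaring two CNV calls the same event:
#' the minimum of the two mutual overlap fractions,
#' `min(overlap/len(a), overlap/len(b))`. Symmetric in its arguments; 1 for
#' identical intervals, 0 for disjoint ones.
#'
#' @param a,b `GRanges` objects, recycled to the longer length.
#' @return numeric vector of fractions in `[0, 1]`.
#' @export
reciprocalOverlap <- function(a, b) {
  n <- max(length(a), length(b))
  if (n == 0L) return(numeric(0))
  a <- rep(a, length.out = n)
  b <- rep(b, length.out = n)
  ov <- overlapBp(a, b)
  pmin(ov / GenomicRanges::width(a), ov / GenomicRanges::width(b))
}

#' Merge overlapping (or book-ended) intervals
#'
#' Returns the minimal set of disjoint intervals covering exactly the same
#' bases as the input, sorted by chromosome then start. Intervals sharing
#' even a single base are merged, as are book-ended intervals (the union of
#' their covered bases is contiguous).
#'
#' @param x a `GRanges`.
#' @return a sorted, disjoint `GRanges` covering the same bases.
#' @export
mergeOverlapping <- function(x) {
  gr <- GenomicRanges::GRanges(normalizeChrom(GenomicRanges::seqnames(x)),
                               IRanges::IRanges(GenomicRanges::start(x),
                                                GenomicRanges::end(x)))
  GenomicRanges::reduce(sort(gr))
}

# Connected components of the strict-overlap (>= 1 bp) graph of a GRanges.
# Book-ended ranges are NOT connected. Returns an integer component id per
# input range. Transitive closure comes free from interval reduction.
overlapComponents <- function(gr) {
  if (!length(gr)) return(integer(0))
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L, with.revmap = TRUE)
  comp <- integer(length(gr))
  rm <- red$revmap
  for (i in seq_along(red)) comp[rm[[i]]] <- i
  comp
}
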