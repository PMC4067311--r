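## Stage 5: gene-overlap annotation and the gain/loss sign test.

#' Annotate target regions with overlapping genes
#'
#' For each target region, *involved* genes overlap it by at least 1 bp;
#' *disrupted* genes are the involved genes not fully contained in the
#' target (the CNV boundary falls inside the gene body), a strict subset of
#' the involved genes. Gene list order does not matter.
#'
#' @param targets a `GRanges`, [CnvrSet-class] or [ConsensusCnvSet-class].
#' @param genes a `GRanges` of gene models with a `name` metadata column.
#' @return a `data.frame` with one row per target: coordinates,
#'   `genes_involved` and `genes_disrupted` (comma-joined, sorted, empty
#'   string when none) and the two counts.
#' @export
annotateGenes <- function(targets, genes) {
  if (is.null(genes$name))
    stopNamed("geneNameError", "gene GRanges needs a 'name' column")
  gr <- if (is(targets, "GRanges")) targets else granges2(targets)
  bareT <- GenomicRanges::GRanges(
    normalizeChrom(GenomicRanges::seqnames(gr)),
    IRanges::IRanges(GenomicRanges::start(gr), GenomicRanges::end(gr)))
  bareG <- GenomicRanges::GRanges(
    normalizeChrom(GenomicRanges::seqnames(genes)),
    IRanges::IRanges(GenomicRanges::start(genes),
                     GenomicRanges::end(genes)))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(bareT, bareG))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  contained <- GenomicRanges::start(bareG)[si] >=
    GenomicRanges::start(bareT)[qi] &
    GenomicRanges::end(bareG)[si] <= GenomicRanges::end(bareT)[qi]
  inv <- split(genes$name[si], factor(qi, levels = seq_along(bareT)))
  dis <- split(genes$name[si][!contained],
               factor(qi[!contained], levels = seq_along(bareT)))
  involved <- vapply(inv, function(g)
    paste(sort(unique(g)), collapse = ","), character(1))
  disrupted <- vapply(dis, function(g)
    paste(sort(unique(g)), collapse = ","), character(1))
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    genes_involved = unname(involved),
    genes_disrupted = unname(disrupted),
    n_involved = unname(vapply(inv, function(g)
      length(unique(g)), integer(1))),
    n_disrupted = unname(vapply(dis, function(g)
      length(unique(g)), integer(1))),
    stringsAsFactors = FALSE)
}

#' Count gene-bearing regions by type class
#'
#' @param typeClass character vector of region type classes (`gain`,
#'   `loss`, `multi_allelic`).
#' @param nInvolved integer vector of involved-gene counts per region
#'   (e.g. the `n_involved` column of [annotateGenes()]).
#' @return a list: `gainsWithGenes`, `lossesWithGenes`, `multiWithGenes`,
#'   `geneEmpty`, `nTotal`.
#' @export
geneRegionCounts <- function(typeClass, nInvolved) {
  stopifnot(length(typeClass) == length(nInvolved))
  withGenes <- nInvolved > 0
  list(gainsWithGenes = sum(withGenes & typeClass == "gain"),
       lossesWithGenes = sum(withGenes & typeClass == "loss"),
       multiWithGenes = sum(withGenes & typeClass == "multi_allelic"),
       geneEmpty = sum(!withGenes),
       nTotal = length(typeClass))
}

#' Exact sign test for gain/loss asymmetry
#'
#' Two-sided exact binomial test of the observed gain/loss split against
#' equal probability: twice the one-sided tail of the larger count under
#' Binomial(n, 1/2), capped at 1. Symmetric in its arguments.
#'
#' @param nGain,nLoss non-negative counts; their sum must be >= 1.
#' @return two-sided exact p-value.
#' @examples
#' gainLossSignTest(15, 6)   # ~0.078
#' gainLossSignTest(21, 0)   # ~9.5e-7
#' @export
gainLossSignTest <- function(nGain, nLoss) {
  if (nGain < 0 || nLoss < 0)
    stopNamed("signTestError", "counts must be non-negative")
  n <- nGain + nLoss
  if (n < 1)
    stopNamed("signTestError", "at least one observation required")
  k <- max(nGain, nLoss)
  min(1, 2 * stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE))
}

#' Export a gene list for external enrichment services
#'
#' Writes the union of involved genes, one symbol per line — the format
#' expected by GO/pathway web services. Enrichment itself is out of scope
#' for this package (it depends on external versioned databases).
#'
#' @param annotation output of [annotateGenes()].
#' @param file destination path.
#' @return the sorted unique gene symbols, invisibly.
#' @export
exportGeneList <- function(annotation, file) {
  symbols <- unlist(strsplit(annotation$genes_involved[
    nzchar(annotation$genes_involved)], ","))
  symbols <- sort(unique(symbols))
  writeLines(symbols, file)
  invisible(symbols)
}
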