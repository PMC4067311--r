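#' @import methods
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#'   reduce findOverlaps pintersect sort.GenomicRanges mcols
#' @importFrom IRanges IRanges CharacterList IntegerList
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits DataFrame Rle
#' @importFrom GenomeInfoDb Seqinfo seqlevels seqlengths seqinfo keepSeqlevels
#'   seqnames<- seqlevels<-
NULL

CN_TYPES <- c("gain", "loss", "complex")
GAP_TYPES <- c("centromere", "telomere")
CNVR_CLASSES <- c("gain", "loss", "multi_allelic")

## ---------------------------------------------------------------------------
## GenomeBuild
## ---------------------------------------------------------------------------

#' GenomeBuild: chromosomes, assembly gaps and excluded chromosomes
#'
#' Holds the coordinate frame every stage works in: ordered chromosome
#' lengths, centromere/telomere gap intervals (used to derive exclusion
#' zones), and chromosomes excluded outright from autosomal CNV analysis
#' (sex chromosomes by default). All coordinates are 1-based inclusive.
#'
#' @slot seqinfo a [GenomeInfoDb::Seqinfo] with chromosome lengths.
#' @slot gaps a `GRanges` of assembly gaps with metadata column `gap_type`
#'   (`"centromere"` or `"telomere"`).
#' @slot excludedChroms normalized labels of chromosomes dropped from
#'   analysis.
#' @export
setClass("GenomeBuild",
  slots = c(seqinfo = "Seqinfo", gaps = "GRanges",
            excludedChroms = "character"))

setValidity("GenomeBuild", function(object) {
  msgs <- character()
  gp <- object@gaps
  if (length(gp)) {
    if (is.null(gp$gap_type) || !all(gp$gap_type %in% GAP_TYPES))
      msgs <- c(msgs, "gaps must carry gap_type in {centromere, telomere}")
    bad <- !(as.character(GenomicRanges::seqnames(gp)) %in%
               GenomeInfoDb::seqlevels(object@seqinfo))
    if (any(bad))
      msgs <- c(msgs, "gap chromosomes absent from the build")
    lens <- GenomeInfoDb::seqlengths(object@seqinfo)[
      as.character(GenomicRanges::seqnames(gp))]
    if (!any(bad) && (any(GenomicRanges::start(gp) < 1) ||
                      any(GenomicRanges::end(gp) > lens)))
      msgs <- c(msgs, "gap intervals fall outside chromosome bounds")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenomeBuild
#'
#' @param chromLengths named numeric vector of chromosome lengths (bp);
#'   names are chromosome labels (any dialect, normalized internally).
#' @param gaps `GRanges` with metadata column `gap_type`, or `NULL`.
#' @param excludedChroms chromosomes removed from autosomal analysis.
#' @return a [GenomeBuild-class] object.
#' @examples
#' gb <- GenomeBuild(c(chr1 = 1e6), excludedChroms = "chrX")
#' @export
GenomeBuild <- function(chromLengths, gaps = NULL,
                        excludedChroms = c("chrX", "chrY")) {
  nm <- normalizeChrom(names(chromLengths))
  si <- GenomeInfoDb::Seqinfo(seqnames = nm,
                              seqlengths = as.integer(chromLengths))
  if (is.null(gaps)) {
    gaps <- GenomicRanges::GRanges(seqinfo = si)
    gaps$gap_type <- character(0)
  } else {
    gaps <- GenomicRanges::GRanges(
      normalizeChrom(GenomicRanges::seqnames(gaps)),
      IRanges::IRanges(GenomicRanges::start(gaps), GenomicRanges::end(gaps)),
      gap_type = gaps$gap_type, seqinfo = si)
  }
  new("GenomeBuild", seqinfo = si, gaps = gaps,
      excludedChroms = normalizeChrom(excludedChroms))
}

#' @describeIn GenomeBuild chromosome lengths (named integer vector).
#' @param build,object a `GenomeBuild`.
#' @export
chromLengths <- function(build) GenomeInfoDb::seqlengths(build@seqinfo)

#' @describeIn GenomeBuild gap intervals as a `GRanges`.
#' @export
gapRanges <- function(build) build@gaps

#' @describeIn GenomeBuild labels of excluded chromosomes.
#' @export
excludedChroms <- function(build) build@excludedChroms

#' @describeIn GenomeBuild labels of analysed (non-excluded) chromosomes.
#' @export
analysedChroms <- function(build)
  setdiff(GenomeInfoDb::seqlevels(build@seqinfo), build@excludedChroms)

setMethod("show", "GenomeBuild", function(object) {
  cat("GenomeBuild:", length(chromLengths(object)), "chromosomes,",
      length(object@gaps), "gap records,",
      length(object@excludedChroms), "excluded chromosome(s)\n")
})

## ---------------------------------------------------------------------------
## Configuration classes
## ---------------------------------------------------------------------------

#' FilterConfig: call-level QC and consensus parameters
#'
#' Defaults encode the stringent filtering used throughout: calls at least
#' 1 kb long spanning at least 5 probes, supported by at least 2 of 3
#' algorithms, with a 300 kb exclusion margin around centromere/telomere
#' gaps and sex chromosomes removed.
#'
#' @slot minSizeBp minimum call length (bp).
#' @slot minProbes minimum probe count per call.
#' @slot minAlgorithms minimum distinct supporting algorithms.
#' @slot exclusionMarginBp margin added to both flanks of every gap (bp).
#' @slot excludedChroms chromosomes excluded outright.
#' @slot supportRule `"any"` (>= 1 bp overlap links same-type calls) or
#'   `"reciprocal"` (reciprocal overlap >= `supportRoThreshold`).
#' @slot supportRoThreshold reciprocal-overlap threshold for the
#'   `"reciprocal"` rule.
#' @slot consensusSpan `"union"` (outermost breakpoints of the supporting
#'   calls) or `"intersection"` (innermost).
#' @export
setClass("FilterConfig",
  slots = c(minSizeBp = "numeric", minProbes = "numeric",
            minAlgorithms = "numeric", exclusionMarginBp = "numeric",
            excludedChroms = "character", supportRule = "character",
            supportRoThreshold = "numeric", consensusSpan = "character"))

setValidity("FilterConfig", function(object) {
  msgs <- character()
  if (any(c(object@minSizeBp, object@minProbes, object@minAlgorithms,
            object@exclusionMarginBp) < 0))
    msgs <- c(msgs, "all thresholds must be >= 0")
  if (!object@supportRule %in% c("any", "reciprocal"))
    msgs <- c(msgs, "supportRule must be 'any' or 'reciprocal'")
  if (!object@consensusSpan %in% c("union", "intersection"))
    msgs <- c(msgs, "consensusSpan must be 'union' or 'intersection'")
  if (length(msgs)) msgs else TRUE
})

#' @rdname FilterConfig-class
#' @param minSizeBp,minProbes,minAlgorithms,exclusionMarginBp,excludedChroms,supportRule,supportRoThreshold,consensusSpan see slots.
#' @return a `FilterConfig`.
#' @export
FilterConfig <- function(minSizeBp = 1000, minProbes = 5, minAlgorithms = 2,
                         exclusionMarginBp = 300000,
                         excludedChroms = c("chrX", "chrY"),
                         supportRule = c("any", "reciprocal"),
                         supportRoThreshold = 0.5,
                         consensusSpan = c("union", "intersection")) {
  new("FilterConfig", minSizeBp = minSizeBp, minProbes = minProbes,
      minAlgorithms = minAlgorithms, exclusionMarginBp = exclusionMarginBp,
      excludedChroms = normalizeChrom(excludedChroms),
      supportRule = match.arg(supportRule),
      supportRoThreshold = supportRoThreshold,
      consensusSpan = match.arg(consensusSpan))
}

#' NoveltyConfig: reference-screen parameters
#'
#' A study CNV is *known* to a reference tier when some reference entry has
#' reciprocal overlap strictly greater than `roThreshold` with it; a CNV
#' novel against every tier and at least `minNovelSizeBp` long is
#' population-specific. A tie at exactly the threshold counts as novel.
#'
#' @slot roThreshold reciprocal-overlap threshold (default 0.5).
#' @slot minNovelSizeBp minimum size retained after screening (default
#'   10 kb, reflecting the poor validation rate of smaller calls).
#' @slot typeAware match only same-type reference entries when `TRUE`.
#' @export
setClass("NoveltyConfig",
  slots = c(roThreshold = "numeric", minNovelSizeBp = "numeric",
            typeAware = "logical"))

setValidity("NoveltyConfig", function(object) {
  if (object@roThreshold <= 0 || object@roThreshold > 1)
    "roThreshold must lie in (0, 1]" else TRUE
})

#' @rdname NoveltyConfig-class
#' @param roThreshold,minNovelSizeBp,typeAware see slots.
#' @return a `NoveltyConfig`.
#' @export
NoveltyConfig <- function(roThreshold = 0.5, minNovelSizeBp = 10000,
                          typeAware = FALSE) {
  new("NoveltyConfig", roThreshold = roThreshold,
      minNovelSizeBp = minNovelSizeBp, typeAware = typeAware)
}

## ---------------------------------------------------------------------------
## Call containers
## ---------------------------------------------------------------------------

REQUIRED_CALL_COLS <- c("sample_id", "algorithm", "cn_type", "n_probes")

#' CnvCallSet: raw per-sample, per-algorithm CNV calls
#'
#' Wraps a `GRanges` (1-based inclusive coordinates, normalized chromosome
#' labels) whose metadata columns identify, for each call, the sample, the
#' calling algorithm, the copy-number type (`gain`/`loss`/`complex`), the
#' probe count (may be `NA`, rejected later by QC) and an optional
#' confidence score.
#'
#' @slot calls the underlying `GRanges`.
#' @export
setClass("CnvCallSet", slots = c(calls = "GRanges"))

setValidity("CnvCallSet", function(object) {
  mc <- S4Vectors::mcols(object@calls)
  missing <- setdiff(REQUIRED_CALL_COLS, colnames(mc))
  if (length(missing))
    return(paste("missing call columns:", paste(missing, collapse = ", ")))
  if (length(object@calls) && !all(mc$cn_type %in% CN_TYPES))
    return("cn_type must be gain, loss or complex")
  ok <- is.na(mc$n_probes) | mc$n_probes >= 0
  if (!all(ok)) return("n_probes must be >= 0 where present")
  TRUE
})

#' @rdname CnvCallSet-class
#' @param chrom,start,end call coordinates (1-based inclusive).
#' @param sample_id,algorithm,cn_type,n_probes,confidence per-call metadata.
#' @return a `CnvCallSet`.
#' @examples
#' CnvCallSet("1", 1000, 5000, "S1", "gtc", "loss", 8)
#' @export
CnvCallSet <- function(chrom, start, end, sample_id, algorithm, cn_type,
                       n_probes = NA_integer_, confidence = NA_real_) {
  n <- length(start)
  gr <- GenomicRanges::GRanges(normalizeChrom(chrom),
                               IRanges::IRanges(start, end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    sample_id = as.character(rep_len(sample_id, n)),
    algorithm = as.character(rep_len(algorithm, n)),
    cn_type = as.character(rep_len(cn_type, n)),
    n_probes = rep_len(as.integer(n_probes), n),
    confidence = rep_len(as.numeric(confidence), n))
  new("CnvCallSet", calls = gr)
}

# Internal: wrap an already-conforming GRanges without copying columns.
asCnvCallSet <- function(gr) new("CnvCallSet", calls = gr)

#' ConsensusCnvSet: per-sample merged (stringent) CNV calls
#'
#' One range per consensus event per sample. Metadata columns: `sample_id`,
#' `cn_type` (`gain`/`loss`), `support` (`CharacterList` of supporting
#' algorithm labels) and `n_members` (number of contributing raw calls).
#' The contributing raw calls are retained in `memberCalls`, tagged with
#' `consensus_id` indexing into the consensus ranges.
#'
#' @slot ranges the consensus `GRanges`.
#' @slot memberCalls the contributing raw-call `GRanges`.
#' @export
setClass("ConsensusCnvSet",
  slots = c(ranges = "GRanges", memberCalls = "GRanges"))

setValidity("ConsensusCnvSet", function(object) {
  mc <- S4Vectors::mcols(object@ranges)
  need <- c("sample_id", "cn_type", "support", "n_members")
  missing <- setdiff(need, colnames(mc))
  if (length(missing))
    return(paste("missing consensus columns:",
                 paste(missing, collapse = ", ")))
  if (length(object@ranges) && !all(mc$cn_type %in% c("gain", "loss")))
    return("consensus cn_type must be gain or loss")
  TRUE
})

#' CnvrSet: cross-sample copy number variable regions
#'
#' One range per CNVR with metadata columns `type_class`
#' (`gain`/`loss`/`multi_allelic`), `carriers` (`CharacterList` of distinct
#' carrier sample ids), `n_carriers` and `frequency` (carriers divided by
#' the cohort size, stored at full precision). Member consensus calls are
#' retained with a `cnvr_id` tag.
#'
#' @slot ranges the CNVR `GRanges`.
#' @slot members member consensus `GRanges` tagged with `cnvr_id`.
#' @slot nGenomes cohort size used as the frequency denominator.
#' @export
setClass("CnvrSet",
  slots = c(ranges = "GRanges", members = "GRanges", nGenomes = "numeric"))

setValidity("CnvrSet", function(object) {
  mc <- S4Vectors::mcols(object@ranges)
  need <- c("type_class", "carriers", "n_carriers", "frequency")
  missing <- setdiff(need, colnames(mc))
  if (length(missing))
    return(paste("missing CNVR columns:", paste(missing, collapse = ", ")))
  if (length(object@ranges)) {
    if (!all(mc$type_class %in% CNVR_CLASSES))
      return("type_class must be gain, loss or multi_allelic")
    if (any(mc$frequency < 0 | mc$frequency > 1))
      return("frequency must lie in [0, 1]")
  }
  TRUE
})

#' ReferenceSet: one tier of a reference CNV catalogue
#'
#' @slot name tier label (e.g. `"DGV"`, `"HapMap3"`).
#' @slot regions reference entries as `GRanges`; optional metadata column
#'   `cn_type` for type-aware matching.
#' @export
setClass("ReferenceSet", slots = c(name = "character", regions = "GRanges"))

#' @rdname ReferenceSet-class
#' @param name tier label.
#' @param regions `GRanges` of reference entries (chromosome labels are
#'   normalized; an absent `cn_type` column is added as `NA`).
#' @return a `ReferenceSet`.
#' @export
ReferenceSet <- function(name, regions) {
  gr <- GenomicRanges::GRanges(
    normalizeChrom(GenomicRanges::seqnames(regions)),
    IRanges::IRanges(GenomicRanges::start(regions),
                     GenomicRanges::end(regions)))
  gr$cn_type <- if (is.null(regions$cn_type))
    rep(NA_character_, length(gr)) else as.character(regions$cn_type)
  new("ReferenceSet", name = name, regions = gr)
}

## ---------------------------------------------------------------------------
## qPCR classes
## ---------------------------------------------------------------------------

#' QpcrAssay: Ct replicates for one validation locus
#'
#' Holds the cycle-threshold replicates of the target amplicon and the
#' reference gene (FOXP2-style single-copy control) in the test sample and
#' in a calibrator sample of known diploid state, plus the array call being
#' validated.
#'
#' @slot locus locus identifier.
#' @slot targetCts,refCts Ct replicates of target/reference gene in the
#'   test sample.
#' @slot calibTargetCts,calibRefCts the same series in the calibrator.
#' @slot arrayCall the array call under validation (`"gain"`, `"loss"`,
#'   or `NA`).
#' @export
setClass("QpcrAssay",
  slots = c(locus = "character", targetCts = "numeric", refCts = "numeric",
            calibTargetCts = "numeric", calibRefCts = "numeric",
            arrayCall = "character"))

setValidity("QpcrAssay", function(object) {
  series <- list(object@targetCts, object@refCts, object@calibTargetCts,
                 object@calibRefCts)
  if (any(vapply(series, length, 1L) < 2))
    return("each Ct series needs >= 2 replicates")
  if (any(unlist(series) <= 0) || any(!is.finite(unlist(series))))
    return("Ct values must be positive and finite")
  TRUE
})

#' @rdname QpcrAssay-class
#' @param locus,targetCts,refCts,calibTargetCts,calibRefCts,arrayCall see slots.
#' @return a `QpcrAssay`.
#' @export
QpcrAssay <- function(locus, targetCts, refCts, calibTargetCts, calibRefCts,
                      arrayCall = NA_character_) {
  new("QpcrAssay", locus = as.character(locus), targetCts = targetCts,
      refCts = refCts, calibTargetCts = calibTargetCts,
      calibRefCts = calibRefCts, arrayCall = as.character(arrayCall))
}

#' CnEstimate: comparative-CT copy-number estimate for one assay
#'
#' @slot estimate unrounded copy number (2 * 2^-ddCt against a diploid
#'   calibrator).
#' @slot sd standard deviation of replicate-level estimates.
#' @slot cvPercent 100 * sd / mean of replicate-level estimates.
#' @slot integerCall integer copy number (1, 2 or 3).
#' @slot ddct the delta-delta-Ct underlying the estimate.
#' @export
setClass("CnEstimate",
  slots = c(estimate = "numeric", sd = "numeric", cvPercent = "numeric",
            integerCall = "integer", ddct = "numeric"))

setValidity("CnEstimate", function(object) {
  if (object@estimate <= 0) return("estimate must be > 0")
  if (!object@integerCall %in% 1:3) return("integerCall must be 1, 2 or 3")
  TRUE
})

setMethod("show", "CnEstimate", function(object) {
  cat(sprintf("CnEstimate: CN %d (%.2f, sd %.3f, CV %.1f%%)\n",
              object@integerCall, object@estimate, object@sd,
              object@cvPercent))
})

#' StandardCurve: qPCR dilution series
#'
#' A serial dilution (five-fold by convention, e.g. 50 ng/ul down to
#' 0.08 ng/ul) with the mean Ct observed at each level, from which the
#' assay's amplification efficiency is estimated.
#'
#' @slot concentrations template concentrations, strictly decreasing.
#' @slot meanCts mean Ct per dilution level.
#' @export
setClass("StandardCurve",
  slots = c(concentrations = "numeric", meanCts = "numeric"))

setValidity("StandardCurve", function(object) {
  if (length(object@concentrations) < 3)
    return("need >= 3 dilution levels")
  if (length(object@concentrations) != length(object@meanCts))
    return("concentrations and meanCts must have equal length")
  if (any(diff(object@concentrations) >= 0))
    return("concentrations must be strictly decreasing")
  if (any(object@concentrations <= 0))
    return("concentrations must be positive")
  TRUE
})

#' @rdname StandardCurve-class
#' @param concentrations,meanCts see slots.
#' @return a `StandardCurve`.
#' @export
StandardCurve <- function(concentrations, meanCts) {
  new("StandardCurve", concentrations = concentrations, meanCts = meanCts)
}

## ---------------------------------------------------------------------------
## Shared generics / methods
## ---------------------------------------------------------------------------

#' Extract the underlying GRanges of a container
#'
#' @param x a `CnvCallSet`, `ConsensusCnvSet`, `CnvrSet` or `ReferenceSet`.
#' @return the `GRanges` of primary records.
#' @export
setGeneric("granges2", function(x) standardGeneric("granges2"))

#' @rdname granges2
#' @export
setMethod("granges2", "CnvCallSet", function(x) x@calls)
#' @rdname granges2
#' @export
setMethod("granges2", "ConsensusCnvSet", function(x) x@ranges)
#' @rdname granges2
#' @export
setMethod("granges2", "CnvrSet", function(x) x@ranges)
#' @rdname granges2
#' @export
setMethod("granges2", "ReferenceSet", function(x) x@regions)

setMethod("length", "CnvCallSet", function(x) length(x@calls))
setMethod("length", "ConsensusCnvSet", function(x) length(x@ranges))
setMethod("length", "CnvrSet", function(x) length(x@ranges))
setMethod("length", "ReferenceSet", function(x) length(x@regions))

setMethod("show", "CnvCallSet", function(object) {
  gr <- object@calls
  cat("CnvCallSet:", length(gr), "calls,",
      length(unique(gr$sample_id)), "sample(s),",
      length(unique(gr$algorithm)), "algorithm(s)\n")
})

setMethod("show", "ConsensusCnvSet", function(object) {
  gr <- object@ranges
  cat("ConsensusCnvSet:", length(gr), "consensus calls (",
      sum(gr$cn_type == "gain"), "gain /", sum(gr$cn_type == "loss"),
      "loss ) in", length(unique(gr$sample_id)), "sample(s)\n")
})

setMethod("show", "CnvrSet", function(object) {
  gr <- object@ranges
  cat("CnvrSet:", length(gr), "CNVRs (",
      sum(gr$type_class == "loss"), "loss /",
      sum(gr$type_class == "gain"), "gain /",
      sum(gr$type_class == "multi_allelic"), "multi-allelic ) over",
      object@nGenomes, "genomes\n")
})

setMethod("show", "ReferenceSet", function(object) {
  cat("ReferenceSet", sQuote(object@name), "with", length(object@regions),
      "entries\n")
})
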