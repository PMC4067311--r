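## Orchestration: QC -> consensus -> CNVR -> novelty screen -> annotation,
## with per-stage TSV outputs and a compact summary report.

#' Run the CNV discovery pipeline
#'
#' Executes the full post-processing chain on a raw call set: call-level
#' QC ([filterRawCalls()]), exclusion zones ([applyExclusionZones()]),
#' per-sample consensus ([consensusPerSample()]), CNVR construction
#' ([buildCnvrs()]), the reference-tier novelty screen
#' ([screenPopulationSpecific()]) with recurrence tallies, and optional
#' gene annotation and reference-frequency comparison. Stage-level errors
#' propagate with the stage name attached. When `outDir` is given every
#' stage output is persisted as TSV together with a human-readable
#' summary; reruns with identical inputs reproduce identical files.
#'
#' @param rawCalls a [CnvCallSet-class] (or path to a call TSV).
#' @param build a [GenomeBuild-class].
#' @param filterCfg a [FilterConfig-class].
#' @param noveltyCfg a [NoveltyConfig-class].
#' @param refs list of [ReferenceSet-class] tiers in screening order (may
#'   be empty).
#' @param nGenomes cohort size (frequency denominator).
#' @param genes optional gene `GRanges` (with `name`) for annotation.
#' @param referenceFrequencies optional `data.frame` for
#'   [frequencyComparison()].
#' @param outDir optional output directory for the report bundle.
#' @param sizeBinEdges bin edges for the size histograms.
#' @return a list with the per-stage objects: `filtered`, `consensus`,
#'   `summaryTable`, `perGenome`, `cnvrs`, `cnvrCounts`, `screen`,
#'   `recurrence`, `annotation` (or `NULL`), `frequencyFlags` (or `NULL`),
#'   and `log` (stage counts and config fingerprint).
#' @export
runPipeline <- function(rawCalls, build, filterCfg = FilterConfig(),
                        noveltyCfg = NoveltyConfig(), refs = list(),
                        nGenomes, genes = NULL,
                        referenceFrequencies = NULL, outDir = NULL,
                        sizeBinEdges = c(1e3, 1e4, 1e5, 1e6, 1e7)) {
  if (is.character(rawCalls)) rawCalls <- readCnvCalls(rawCalls)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  filtered <- stage("qc_filter", filterRawCalls(rawCalls, filterCfg))
  filtered <- stage("exclusion_zones",
                    applyExclusionZones(filtered, build, filterCfg))
  consensus <- stage("consensus", consensusPerSample(filtered, filterCfg))
  summaryTable <- stage("summary",
                        algorithmSummaryTable(rawCalls, consensus,
                                              nGenomes))
  perGenome <- stage("summary", perGenomeSummary(consensus, nGenomes))
  cnvrs <- stage("cnvr", buildCnvrs(consensus, nGenomes))
  cnvrCounts <- classifyCounts(cnvrs)
  screen <- stage("novelty_screen",
                  screenPopulationSpecific(consensus, refs, noveltyCfg))
  recurrence <- stage("novelty_screen", recurrenceTable(screen$specific))
  annotation <- if (!is.null(genes))
    stage("gene_annotation",
          annotateGenes(buildCnvrs(screen$specific, nGenomes), genes))
  frequencyFlags <- if (!is.null(referenceFrequencies))
    stage("frequency_comparison",
          frequencyComparison(cnvrs, referenceFrequencies,
                              noveltyCfg@roThreshold))
  log <- list(
    config_fingerprint = configFingerprint(list(
      filterCfg = filterCfg, noveltyCfg = noveltyCfg,
      nGenomes = nGenomes, tiers = vapply(refs, function(r) r@name,
                                          character(1)))),
    n_raw = length(rawCalls), n_filtered = length(filtered),
    n_consensus = length(consensus), n_cnvr = length(cnvrs),
    n_specific = length(screen$specific),
    n_specific_loci = nrow(recurrence))
  result <- list(filtered = filtered, consensus = consensus,
                 summaryTable = summaryTable, perGenome = perGenome,
                 cnvrs = cnvrs, cnvrCounts = cnvrCounts, screen = screen,
                 recurrence = recurrence, annotation = annotation,
                 frequencyFlags = frequencyFlags, log = log)
  if (!is.null(outDir)) writeReportBundle(result, outDir, sizeBinEdges)
  result
}

#' Compare study CNVR frequencies with reference cohort frequencies
#'
#' Matches study CNVRs to rows of a reference frequency table by
#' reciprocal overlap above `roThreshold` and reports the study frequency
#' beside each reference population's, flagging loci whose study frequency
#' falls outside the reference min–max range (a descriptive screen; no
#' test statistic is attached).
#'
#' @param cnvrs a [CnvrSet-class].
#' @param referenceFrequencies a `data.frame` with columns `chrom`,
#'   `start`, `end` and one numeric frequency column per reference
#'   population.
#' @param roThreshold reciprocal-overlap threshold for locus matching.
#' @return a `data.frame` with one row per matched locus: CNVR
#'   coordinates, `study_frequency` (2 decimals), the reference columns,
#'   `ref_min`, `ref_max` and `flagged`. Zero rows (with a warning) when
#'   the reference table is empty.
#' @export
frequencyComparison <- function(cnvrs, referenceFrequencies,
                                roThreshold = 0.5) {
  popCols <- setdiff(names(referenceFrequencies),
                     c("chrom", "start", "end"))
  gr <- granges2(cnvrs)
  if (!nrow(referenceFrequencies)) {
    warning("empty reference frequency table; no loci compared")
    return(data.frame())
  }
  refGr <- GenomicRanges::GRanges(
    normalizeChrom(referenceFrequencies$chrom),
    IRanges::IRanges(referenceFrequencies$start,
                     referenceFrequencies$end))
  hit <- bestReferenceHit(gr, refGr)
  keep <- which(hit$best_ro > roThreshold)
  if (!length(keep)) return(data.frame())
  rows <- lapply(keep, function(i) {
    ref <- referenceFrequencies[hit$best_idx[i], popCols, drop = FALSE]
    freqs <- as.numeric(ref[1, ])
    sf <- formatFrequency(gr$frequency[i])
    cbind(data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr))[i],
      start = GenomicRanges::start(gr)[i],
      end = GenomicRanges::end(gr)[i],
      study_frequency = sf, stringsAsFactors = FALSE),
      ref,
      data.frame(ref_min = min(freqs), ref_max = max(freqs),
                 flagged = sf < min(freqs) | sf > max(freqs)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Persist the pipeline result as a TSV bundle plus a plain-text summary.
writeReportBundle <- function(result, outDir, sizeBinEdges) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outDir, f)
  writeCnvCalls(result$consensus, p("consensus_calls.tsv"))
  writeCnvrTable(result$cnvrs, p("cnvrs.tsv"))
  exportCnvrBed(result$cnvrs, p("cnvrs.bed"))
  utils::write.table(result$summaryTable, p("algorithm_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$screen$provenance, p("screen_provenance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeCnvCalls(result$screen$specific, p("population_specific.tsv"))
  utils::write.table(result$recurrence, p("recurrence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(result$annotation))
    utils::write.table(result$annotation, p("gene_annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$frequencyFlags) && nrow(result$frequencyFlags))
    utils::write.table(result$frequencyFlags,
                       p("frequency_comparison.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  cc <- result$cnvrCounts
  pg <- result$perGenome
  sizes <- GenomicRanges::width(granges2(result$cnvrs))
  histo <- if (length(sizes) == 0 ||
               (all(sizes >= sizeBinEdges[1]) &&
                all(sizes < sizeBinEdges[length(sizeBinEdges)])))
    sizeDistribution(sizes, sizeBinEdges) else NULL
  lines <- c(
    "CNV discovery pipeline summary",
    sprintf("config fingerprint: %s", result$log$config_fingerprint),
    sprintf("raw calls: %d; after QC + exclusion zones: %d",
            result$log$n_raw, result$log$n_filtered),
    sprintf("consensus calls: %d (%d gain / %d loss); mean %.1f per genome",
            pg$nTotal, pg$nGain, pg$nLoss, pg$meanPerGenome),
    sprintf("CNVRs: %d (%d loss / %d gain / %d multi-allelic)",
            cc[["n_total"]], cc[["n_loss"]], cc[["n_gain"]],
            cc[["n_multi"]]),
    sprintf("population-specific CNVs: %d at %d loci (%d singleton)",
            result$log$n_specific, result$log$n_specific_loci,
            sum(!result$recurrence$recurrent)))
  if (!is.null(histo))
    lines <- c(lines, sprintf("CNVR size bins [%s): %s",
                              paste(sizeBinEdges, collapse = ", "),
                              paste(histo, collapse = " / ")))
  writeLines(lines, p("summary.txt"))
  invisible(NULL)
}
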