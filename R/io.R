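## File dialects. Internal coordinates are always 1-based inclusive;
## BED-style and UCSC gap-table inputs (0-based half-open) are converted
## here, at the boundary, and nowhere else.

#' Read a raw CNV call table
#'
#' TSV with header columns `sample_id`, `algorithm`, `chrom`, `start`,
#' `end`, `type`, `n_probes` and optionally `confidence`; coordinates are
#' 1-based inclusive.
#'
#' @param file path to the TSV.
#' @return a [CnvCallSet-class].
#' @export
readCnvCalls <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("sample_id", "algorithm", "chrom", "start", "end", "type",
            "n_probes")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stopNamed("callTableError",
              paste("missing columns:", paste(missing, collapse = ", ")))
  CnvCallSet(df$chrom, df$start, df$end, df$sample_id, df$algorithm,
             df$type, df$n_probes,
             if ("confidence" %in% names(df)) df$confidence else NA_real_)
}

#' Write raw or consensus calls as TSV
#'
#' Consensus sets gain a `support` column (comma-joined algorithm labels).
#' Coordinates are written 1-based inclusive, matching [readCnvCalls()].
#'
#' @param x a [CnvCallSet-class] or [ConsensusCnvSet-class].
#' @param file destination path.
#' @return the written `data.frame`, invisibly.
#' @export
writeCnvCalls <- function(x, file) {
  gr <- granges2(x)
  df <- data.frame(sample_id = gr$sample_id,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   size = GenomicRanges::width(gr),
                   type = gr$cn_type, stringsAsFactors = FALSE)
  if (is(x, "ConsensusCnvSet")) {
    df$support <- vapply(gr$support, paste, character(1), collapse = ",")
    df$n_members <- gr$n_members
  } else {
    df$algorithm <- gr$algorithm
    df$n_probes <- gr$n_probes
    df$confidence <- gr$confidence
  }
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}

#' Read chromosome sizes (two-column TSV, no header)
#'
#' @param file path; column 1 chromosome label, column 2 length in bp.
#' @return named integer vector of normalized chromosome lengths.
#' @export
readChromSizes <- function(file) {
  df <- utils::read.delim(file, header = FALSE, stringsAsFactors = FALSE)
  stats::setNames(as.integer(df[[2]]), normalizeChrom(df[[1]]))
}

#' Read a UCSC-style gap table
#'
#' TSV with header columns `chrom`, `start` (0-based), `end` and `type`
#' (`centromere` or `telomere`); converted to 1-based inclusive.
#'
#' @param file path to the gap table.
#' @return a `GRanges` with a `gap_type` column, suitable for
#'   [GenomeBuild()].
#' @export
readGapTable <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$type), GAP_TYPES)
  if (length(bad))
    stopNamed("gapTypeError",
              paste("unknown gap types:", paste(bad, collapse = ", ")))
  gr <- GenomicRanges::GRanges(normalizeChrom(df$chrom),
                               IRanges::IRanges(df$start + 1L, df$end))
  gr$gap_type <- df$type
  gr
}

#' Assemble a GenomeBuild from files
#'
#' @param sizesFile two-column chromosome sizes TSV ([readChromSizes()]).
#' @param gapsFile UCSC-style gap table ([readGapTable()]), or `NULL`.
#' @param excludedChroms chromosomes excluded from analysis.
#' @return a [GenomeBuild-class].
#' @export
readGenomeBuild <- function(sizesFile, gapsFile = NULL,
                            excludedChroms = c("chrX", "chrY")) {
  GenomeBuild(readChromSizes(sizesFile),
              gaps = if (!is.null(gapsFile)) readGapTable(gapsFile),
              excludedChroms = excludedChroms)
}

#' Read a reference CNV tier from a BED-dialect file
#'
#' Three required columns (chrom, 0-based start, end) plus an optional
#' fourth column holding the copy-number type; converted to 1-based
#' inclusive coordinates.
#'
#' @param file path to the BED-dialect file (no header).
#' @param name tier label.
#' @return a [ReferenceSet-class].
#' @export
readReferenceSet <- function(file, name) {
  df <- utils::read.delim(file, header = FALSE, stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(normalizeChrom(df[[1]]),
                               IRanges::IRanges(df[[2]] + 1L, df[[3]]))
  if (ncol(df) >= 4) gr$cn_type <- as.character(df[[4]])
  ReferenceSet(name, gr)
}

#' Read gene models from BED or GFF3
#'
#' BED input (`.bed`): columns chrom, 0-based start, end, name. GFF3 input
#' (`.gff`/`.gff3`): imported via rtracklayer, keeping `gene` features (or
#' all features when none are typed `gene`) and taking the symbol from
#' `Name`, `gene_name` or `ID`, in that order.
#'
#' @param file path.
#' @return a `GRanges` with a `name` column (1-based inclusive).
#' @export
readGenes <- function(file) {
  if (grepl("\\.gff3?$", file, ignore.case = TRUE)) {
    gr <- rtracklayer::import(file)
    if ("type" %in% colnames(S4Vectors::mcols(gr)) &&
        any(gr$type == "gene"))
      gr <- gr[gr$type == "gene"]
    nm <- rep(NA_character_, length(gr))
    for (col in c("Name", "gene_name", "ID")) {
      if (col %in% colnames(S4Vectors::mcols(gr)))
        nm <- ifelse(is.na(nm), as.character(S4Vectors::mcols(gr)[[col]]),
                     nm)
    }
    out <- GenomicRanges::GRanges(
      normalizeChrom(GenomicRanges::seqnames(gr)),
      IRanges::IRanges(GenomicRanges::start(gr), GenomicRanges::end(gr)))
    out$name <- nm
    return(out)
  }
  df <- utils::read.delim(file, header = FALSE, stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(normalizeChrom(df[[1]]),
                               IRanges::IRanges(df[[2]] + 1L, df[[3]]))
  gr$name <- if (ncol(df) >= 4) as.character(df[[4]]) else
    paste0("gene", seq_len(nrow(df)))
  gr
}

#' Write a CNVR table as TSV
#'
#' Columns: chrom, start, end, size, type_class, n_carriers, frequency
#' (full precision) and the comma-joined carrier list.
#'
#' @param x a [CnvrSet-class].
#' @param file destination path.
#' @return the written `data.frame`, invisibly.
#' @export
writeCnvrTable <- function(x, file) {
  gr <- granges2(x)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   size = GenomicRanges::width(gr),
                   type_class = gr$type_class,
                   n_carriers = gr$n_carriers,
                   frequency = gr$frequency,
                   carriers = vapply(gr$carriers, paste, character(1),
                                     collapse = ","),
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}

#' Export CNVRs as a BED9 genome-browser custom track
#'
#' Coordinates are converted to BED's 0-based half-open convention; items
#' are coloured by type class (loss red, gain blue, multi-allelic green).
#'
#' @param x a [CnvrSet-class].
#' @param file destination path.
#' @param trackName track label written in the header line.
#' @return invisibly, the number of records written.
#' @export
exportCnvrBed <- function(x, file, trackName = "CNVRs") {
  gr <- granges2(x)
  rgb <- c(loss = "255,0,0", gain = "0,0,255",
           multi_allelic = "0,160,0")[gr$type_class]
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t.\t%d\t%d\t%s",
                   as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
                   paste0(gr$type_class, "_", seq_along(gr)),
                   GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
                   rgb)
  writeLines(c(sprintf(
    'track name="%s" itemRgb="On" visibility=2', trackName), lines), file)
  invisible(length(lines))
}
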