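## Stage 4: comparative-CT (2^-ddCt) copy-number estimation and assay QC.

#' Amplification efficiency from a standard curve
#'
#' Least-squares slope of mean Ct against log10 template concentration over
#' the dilution series; efficiency = 10^(-1/slope) - 1, so a perfect
#' per-cycle doubling (slope -1/log10(2) ~ -3.32) gives 1.0. Efficiencies
#' outside 0.9–1.1 trigger an advisory warning, not a hard failure.
#'
#' @param curve a [StandardCurve-class].
#' @return the efficiency fraction.
#' @examples
#' sc <- StandardCurve(50 / 5^(0:4), 20 + 1 / log10(2) * log10(5) * (0:4))
#' amplificationEfficiency(sc)  # ~1
#' @export
amplificationEfficiency <- function(curve) {
  lc <- log10(curve@concentrations)
  if (stats::var(lc) == 0)
    stopNamed("degenerateCurveError",
              "zero variance in log10 concentrations")
  slope <- unname(stats::coef(stats::lm(curve@meanCts ~ lc))[2])
  if (!is.finite(slope) || abs(slope) < 1e-8)
    stopNamed("degenerateCurveError",
              "flat standard curve: Ct does not respond to dilution")
  eff <- 10^(-1 / slope) - 1
  if (eff < 0.9 || eff > 1.1)
    warning(sprintf("amplification efficiency %.3f outside 0.9-1.1", eff))
  eff
}

#' Comparative-CT copy-number estimate
#'
#' dCt(test) = mean(target Ct) - mean(reference-gene Ct); dCt(calibrator)
#' likewise; ddCt = dCt(test) - dCt(calibrator); the copy number estimate
#' is 2 * 2^-ddCt, the calibrator being assumed diploid. Replicate-level
#' estimates (replicate i of the target series paired with replicate i of
#' the reference series, against the calibrator means) yield the standard
#' deviation and CV% = 100 * sd / mean.
#'
#' @param assay a [QpcrAssay-class]; target and reference series of the
#'   test sample must have equal replicate counts.
#' @return a [CnEstimate-class].
#' @examples
#' a <- QpcrAssay("L", c(24.5, 24.6, 24.4), c(25.1, 25.0, 25.2),
#'                c(25.0, 25.1, 24.9), c(25.0, 25.0, 25.1))
#' estimateCopyNumber(a)
#' @export
estimateCopyNumber <- function(assay) {
  if (length(assay@targetCts) != length(assay@refCts))
    stopNamed("replicateMismatchError",
              "target and reference replicate counts differ")
  dctCalib <- mean(assay@calibTargetCts) - mean(assay@calibRefCts)
  ddct <- (mean(assay@targetCts) - mean(assay@refCts)) - dctCalib
  estimate <- 2 * 2^(-ddct)
  repDdct <- (assay@targetCts - assay@refCts) - dctCalib
  repEst <- 2 * 2^(-repDdct)
  sdEst <- stats::sd(repEst)
  new("CnEstimate", estimate = estimate, sd = sdEst,
      cvPercent = 100 * sdEst / mean(repEst),
      integerCall = callIntegerCn(estimate), ddct = ddct)
}

#' Integer copy-number call from an unrounded estimate
#'
#' Fixed thresholds rather than nearest-integer rounding: below 1.5 is a
#' one-copy loss, 2.5 and above is a three-copy gain (boundary inclusive),
#' anything between is diploid. Deep losses (e.g. 0.45) therefore still
#' call 1, and an estimate of exactly 2.50 calls 3.
#'
#' @param estimate positive unrounded copy number(s).
#' @return integer vector of calls in `{1, 2, 3}`.
#' @examples
#' callIntegerCn(c(2.80, 0.45, 2.50, 2.10))  # 3 1 3 2
#' @export
callIntegerCn <- function(estimate) {
  if (any(estimate <= 0))
    stopNamed("estimateRangeError", "estimate must be > 0")
  ifelse(estimate < 1.5, 1L, ifelse(estimate >= 2.5, 3L, 2L))
}

#' Concordance of an array call with the qPCR integer call
#'
#' A gain validates only as copy number 3, a loss only as copy number 1;
#' anything else (including copy-number-normal results) is a false
#' positive of the array call.
#'
#' @param arrayCall `"gain"` or `"loss"` (vectorized).
#' @param integerCall integer call in `{1, 2, 3}` (vectorized).
#' @return character vector, `"true_positive"` or `"false_positive"`.
#' @export
concordance <- function(arrayCall, integerCall) {
  ok <- (arrayCall == "gain" & integerCall == 3L) |
    (arrayCall == "loss" & integerCall == 1L)
  ifelse(ok, "true_positive", "false_positive")
}

#' Validation summary across assays
#'
#' Overall true-positive rate (percent, one decimal) and the same rate
#' stratified by size class below/at-or-above `minNovelSizeBp`.
#'
#' @param status character vector of concordance results.
#' @param sizes CNV sizes (bp), parallel to `status`; may be `NULL` for an
#'   unstratified summary.
#' @param minNovelSizeBp stratum boundary (default 10 kb).
#' @return a list: `nAssays`, `nTruePositive`, `tpRatePercent`, and when
#'   sizes are given `tpRateSmallPercent` / `tpRateLargePercent` with the
#'   stratum sizes (`NA` rate for an empty stratum).
#' @export
validationSummary <- function(status, sizes = NULL,
                              minNovelSizeBp = 10000) {
  if (!length(status))
    stopNamed("emptyValidationError", "no validation results")
  rate <- function(s) if (length(s))
    roundHalfUp(100 * mean(s == "true_positive"), 1) else NA_real_
  out <- list(nAssays = length(status),
              nTruePositive = sum(status == "true_positive"),
              tpRatePercent = rate(status))
  if (!is.null(sizes)) {
    stopifnot(length(sizes) == length(status))
    small <- sizes < minNovelSizeBp
    out$nSmall <- sum(small)
    out$nLarge <- sum(!small)
    out$tpRateSmallPercent <- rate(status[small])
    out$tpRateLargePercent <- rate(status[!small])
  }
  out
}

#' Read a Ct replicate table into assays
#'
#' Expects a CSV with columns `locus`, `sample_role` (`test`/`calibrator`),
#' `gene_role` (`target`/`reference`), `replicate`, `ct`, plus optionally
#' `array_call`; one [QpcrAssay-class] is built per locus.
#'
#' @param file CSV path.
#' @return named list of `QpcrAssay` objects.
#' @export
readCtTable <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("locus", "sample_role", "gene_role", "replicate", "ct")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stopNamed("ctTableError",
              paste("missing columns:", paste(missing, collapse = ", ")))
  lapply(split(df, df$locus), function(d) {
    pick <- function(sr, gr)
      d$ct[d$sample_role == sr & d$gene_role == gr][
        order(d$replicate[d$sample_role == sr & d$gene_role == gr])]
    QpcrAssay(d$locus[1],
              targetCts = pick("test", "target"),
              refCts = pick("test", "reference"),
              calibTargetCts = pick("calibrator", "target"),
              calibRefCts = pick("calibrator", "reference"),
              arrayCall = if ("array_call" %in% names(d))
                d$array_call[1] else NA_character_)
  })
}
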