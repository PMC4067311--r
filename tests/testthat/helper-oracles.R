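# Brute-force oracles over explicit base sets. Deliberately independent of
# the GenomicRanges-backed code paths they check: plain integer vectors and
# quadratic loops, usable only at toy coordinates.

oracleCoveredBases <- function(chrom, start, end) {
  keys <- unlist(lapply(seq_along(start), function(i)
    paste0(chrom[i], ":", seq.int(start[i], end[i]))))
  unique(keys)
}

oracleOverlapBp <- function(c1, s1, e1, c2, s2, e2) {
  if (c1 != c2) return(0L)
  length(intersect(seq.int(s1, e1), seq.int(s2, e2)))
}

oracleReciprocalOverlap <- function(c1, s1, e1, c2, s2, e2) {
  ov <- oracleOverlapBp(c1, s1, e1, c2, s2, e2)
  min(ov / (e1 - s1 + 1), ov / (e2 - s2 + 1))
}

# Connected components of the >=1 bp overlap graph by explicit transitive
# closure (repeated matrix squaring of the adjacency relation).
oracleOverlapComponents <- function(chrom, start, end) {
  n <- length(start)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    adj[i, j] <- oracleOverlapBp(chrom[i], start[i], end[i],
                                 chrom[j], start[j], end[j]) > 0
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0 | reach
    if (all(nxt == reach)) break
    reach <- nxt
  }
  comp <- integer(n)
  nextId <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      nextId <- nextId + 1L
      comp[reach[i, ]] <- nextId
    }
  }
  comp
}

# Two-sided doubled binomial tail by explicit summation.
oracleSignTest <- function(a, b) {
  n <- a + b
  k <- max(a, b)
  min(1, 2 * sum(choose(n, k:n)) / 2^n)
}

randomGRanges <- function(n, maxPos = 2000, chroms = c("chr1", "chr2")) {
  st <- sample.int(maxPos, n, replace = TRUE)
  w <- sample.int(50, n, replace = TRUE)
  GenomicRanges::GRanges(sample(chroms, n, replace = TRUE),
                         IRanges::IRanges(st, st + w))
}

makeCalls <- function(df) {
  CnvCallSet(df$chrom, df$start, df$end, df$sample_id, df$algorithm,
             df$cn_type,
             if ("n_probes" %in% names(df)) df$n_probes else 10L)
}

# Small two-chromosome build with one centromere each and telomere gaps on
# chr1 only (chr2 exercises the synthetic 1 bp telomere anchors).
toyBuild <- function() {
  gaps <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr1", "chr2"),
    IRanges::IRanges(start = c(1, 9990001, 4995001, 4995001),
                     end = c(10000, 10000000, 5005000, 5005000)))
  gaps$gap_type <- c("telomere", "telomere", "centromere", "centromere")
  GenomeBuild(c(chr1 = 1e7, chr2 = 1e7, chrX = 5e6), gaps = gaps,
              excludedChroms = "chrX")
}

# Ct series whose means produce a prescribed ddCt against a flat diploid
# calibrator (target/reference base Cts 27/25).
assayWithDdct <- function(ddct, spread = 0) {
  QpcrAssay("locus",
            targetCts = 27 + ddct + c(-spread, 0, spread),
            refCts = 25 + c(-spread, 0, spread),
            calibTargetCts = rep(27, 3), calibRefCts = rep(25, 3),
            arrayCall = "gain")
}
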