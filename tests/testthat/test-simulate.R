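smallCfg <- function(seed, n = 80, ...) {
  SimulationConfig(seed = seed, nTruthLoci = n, ...)
}

test_that("truth simulation is seeded, bounded and non-overlapping", {
  cfg <- smallCfg(seed = 42)
  t1 <- simulateTruth(cfg)
  t2 <- simulateTruth(cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_equal(length(t1), 80L)
  # no overlap between loci
  srt <- sort(GenomicRanges::granges(t1))
  expect_true(all(overlapBp(srt[-length(srt)], srt[-1]) == 0))
  # all loci clear of exclusion zones and excluded chromosomes
  zones <- exclusionZones(cfg@genome)
  expect_equal(length(GenomicRanges::findOverlaps(
    GenomicRanges::granges(t1), zones)), 0L)
  expect_false("chrX" %in% as.character(GenomicRanges::seqnames(t1)))
  # sizes respect the configured spectrum
  w <- GenomicRanges::width(t1)
  expect_true(all(w >= 1e3 & w <= 1e6 + 1))
  # empty config
  expect_equal(length(simulateTruth(smallCfg(seed = 1, n = 0))), 0L)
})

test_that("singleton fraction matches the carrier spectrum", {
  cfg <- SimulationConfig(seed = 7, nTruthLoci = 500)
  truth <- simulateTruth(cfg)
  singletons <- mean(lengths(truth$carriers) == 1)
  # within 3 binomial sd of the configured 0.65
  expect_lt(abs(singletons - 0.65), 3 * sqrt(0.65 * 0.35 / 500))
})

test_that("caller sensitivity and jitter behave as configured", {
  cfg <- smallCfg(seed = 11, n = 120)
  truth <- simulateTruth(cfg)
  calls <- granges2(simulateAlgorithmCalls(truth, cfg))
  real <- calls[!is.na(calls$truth_locus)]
  nEvents <- sum(lengths(truth$carriers))
  for (alg in cfg@algorithms) {
    det <- sum(real$algorithm == alg)
    expect_lt(abs(det - 0.9 * nEvents), 3 * sqrt(nEvents * 0.9 * 0.1))
  }
  # jitter clamped: every emitted call keeps >= 50% of the true span
  idx <- match(real$truth_locus, truth$locus_id)
  keptFrac <- overlapBp(real, truth[idx]) / GenomicRanges::width(truth[idx])
  expect_true(all(keptFrac >= 0.5))
  # complex calls come only from the designated (last) caller
  cx <- calls[calls$cn_type == "complex"]
  expect_true(all(cx$algorithm == "ipattern"))
})

test_that("noise-free callers reproduce carried truth intervals exactly", {
  cfg <- noiseFreeConfig(smallCfg(seed = 19, n = 40))
  truth <- simulateTruth(cfg)
  calls <- granges2(simulateAlgorithmCalls(truth, cfg))
  expect_equal(length(calls), 3 * sum(lengths(truth$carriers)))
  idx <- match(calls$truth_locus, truth$locus_id)
  expect_equal(GenomicRanges::start(calls), GenomicRanges::start(truth)[idx])
  expect_equal(GenomicRanges::end(calls), GenomicRanges::end(truth)[idx])
})

test_that("reference tiers stay within 50% reciprocal overlap of sources", {
  cfg <- smallCfg(seed = 23, n = 150)
  truth <- simulateTruth(cfg)
  refs <- simulateReferenceSets(truth, cfg, nDecoys = 30)
  expect_setequal(names(refs), c("arrayCNP", "DGV", "HapMap3", "SGVP"))
  for (tier in names(refs)) {
    inTier <- vapply(truth$known_in, function(t) tier %in% t, logical(1))
    rr <- granges2(refs[[tier]])
    known <- rr[!is.na(rr$cn_type)]
    expect_equal(length(known), sum(inTier))
    if (length(known)) {
      src <- GenomicRanges::granges(truth[inTier])
      bestRo <- vapply(seq_along(known), function(i)
        max(reciprocalOverlap(rep(known[i], length(src)), src)),
        numeric(1))
      expect_true(all(bestRo > 0.5))
    }
    # decoys overlap no truth locus
    decoys <- rr[is.na(rr$cn_type)]
    expect_equal(length(GenomicRanges::findOverlaps(
      decoys, GenomicRanges::granges(truth))), 0L)
  }
  # a locus known in no tier appears in no tier file
  private <- truth[lengths(truth$known_in) == 0]
  for (tier in names(refs)) {
    ro <- matchReference(GenomicRanges::granges(private), refs[[tier]])
    expect_true(all(ro$status == "novel"))
  }
})

test_that("qPCR simulation closes the loop on known copy numbers", {
  cfg <- SimulationConfig(seed = 31, ctNoiseSd = 0)
  df <- simulateQpcr(data.frame(locus = c("L1", "L2", "L3"),
                                cn = c(1L, 2L, 3L)), cfg)
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  assays <- readCtTable(f)
  ests <- vapply(assays[c("L1", "L2", "L3")], function(a)
    estimateCopyNumber(a)@estimate, numeric(1))
  expect_equal(unname(ests), c(1, 2, 3), tolerance = 1e-9)
  unlink(f)
})
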