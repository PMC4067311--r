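test_that("QC filter applies size, probe and type criteria exactly", {
  df <- data.frame(
    chrom = "chr1",
    start = c(2e6, 2e6, 2e6),
    end = c(2e6 + 998, 2e6 + 1133, 2e6 + 5e4),
    sample_id = "S1", algorithm = "gtc",
    cn_type = c("loss", "loss", "complex"),
    n_probes = c(6L, 5L, 50L))
  kept <- filterRawCalls(makeCalls(df))
  # 999 bp call dropped, 1,134 bp call (the smallest stringent survivor)
  # retained, complex call dropped
  expect_equal(length(kept), 1L)
  expect_equal(intervalLength(granges2(kept)), 1134L)

  set.seed(11)
  rnd <- data.frame(
    chrom = "chr1", start = seq(2e6, by = 1e5, length.out = 10),
    sample_id = "S1", algorithm = "gtc",
    cn_type = sample(c("gain", "loss", "complex"), 10, replace = TRUE),
    n_probes = sample(0:12, 10, replace = TRUE))
  rnd$end <- rnd$start + sample(c(500, 1500, 5000), 10, replace = TRUE)
  cfg <- FilterConfig()
  keepOracle <- (rnd$end - rnd$start + 1) >= 1000 & rnd$n_probes >= 5 &
    rnd$cn_type != "complex"
  got <- granges2(filterRawCalls(makeCalls(rnd), cfg))
  expect_equal(GenomicRanges::start(got), rnd$start[keepOracle])

  rnd$n_probes[3] <- NA
  expect_error(filterRawCalls(makeCalls(rnd)),
               class = "missingProbeCountError")
})

test_that("exclusion zones remove sex chromosomes and gap-adjacent calls", {
  build <- toyBuild()
  df <- data.frame(
    chrom = c("chr1", "chr1", "chrX", "chr2", "chr2"),
    #        far      250 kb from   any    overlaps    far from the
    #        from     the telomere         chr2 1bp    synthetic anchors
    #        gaps     gap                  anchor zone
    start = c(2e6, 10000 + 250000, 1e6, 1e5, 2e6),
    end = c(2.01e6, 10000 + 260000, 1.1e6, 2e5, 2.01e6),
    sample_id = "S1", algorithm = "gtc", cn_type = "loss",
    n_probes = 10L)
  kept <- granges2(applyExclusionZones(makeCalls(df), build))
  expect_equal(GenomicRanges::start(kept), c(2e6, 2e6))
  expect_setequal(unique(as.character(GenomicRanges::seqnames(kept))),
                  c("chr1", "chr2"))

  df$chrom[1] <- "chr9"
  expect_error(applyExclusionZones(makeCalls(df), build),
               class = "unknownChromosomeError")
})

test_that("2-of-3 consensus merges overlapping same-type calls per sample", {
  df <- data.frame(
    chrom = "chr1",
    start = c(1000, 5000, 100000, 300000, 300000),
    end = c(20000, 25000, 110000, 320000, 320000),
    sample_id = "S1",
    algorithm = c("gtc", "birdsuite", "ipattern", "gtc", "birdsuite"),
    cn_type = c("loss", "loss", "loss", "gain", "gain"),
    n_probes = 20L)
  cons <- consensusPerSample(makeCalls(df))
  gr <- granges2(cons)
  expect_equal(length(gr), 2L)
  # union span of the two loss calls; the singleton ipattern call dies
  loss <- gr[gr$cn_type == "loss"]
  expect_equal(GenomicRanges::start(loss), 1000L)
  expect_equal(GenomicRanges::end(loss), 25000L)
  expect_setequal(unlist(loss$support), c("birdsuite", "gtc"))
  # identical breakpoints: same region out
  gain <- gr[gr$cn_type == "gain"]
  expect_equal(GenomicRanges::start(gain), 300000L)
  expect_equal(GenomicRanges::end(gain), 320000L)
})

test_that("consensus components match brute-force transitive closure", {
  set.seed(23)
  for (rep in 1:6) {
    n <- 12
    st <- sample.int(1500, n, replace = TRUE)
    df <- data.frame(
      chrom = "chr1", start = st, end = st + sample.int(300, n, TRUE),
      sample_id = "S1",
      algorithm = sample(c("a", "b", "c"), n, replace = TRUE),
      cn_type = "loss", n_probes = 10L)
    comp <- oracleOverlapComponents(df$chrom, df$start, df$end)
    nExpected <- sum(vapply(unique(comp), function(cmp)
      length(unique(df$algorithm[comp == cmp])) >= 2, logical(1)))
    cons <- consensusPerSample(makeCalls(df))
    expect_equal(length(cons), nExpected)
    gr <- granges2(cons)
    # every member call is contained in its consensus span
    m <- cons@memberCalls
    expect_true(all(GenomicRanges::start(m) >=
                      GenomicRanges::start(gr)[m$consensus_id]))
    expect_true(all(GenomicRanges::end(m) <=
                      GenomicRanges::end(gr)[m$consensus_id]))
    # consensus never smaller than its largest member span
    if (length(gr))
      expect_true(all(GenomicRanges::width(gr) >=
        tapply(GenomicRanges::width(m), m$consensus_id, max)))
    # same-(sample,type) consensus regions are disjoint
    for (tp in unique(gr$cn_type)) {
      sub <- gr[gr$cn_type == tp]
      if (length(sub) > 1) {
        sub <- sort(sub)
        expect_true(all(overlapBp(sub[-length(sub)], sub[-1]) == 0))
      }
    }
  }
})

test_that("adding a call never removes an existing consensus region", {
  set.seed(31)
  st <- sample.int(2000, 10, replace = TRUE)
  df <- data.frame(chrom = "chr1", start = st, end = st + 150,
                   sample_id = "S1",
                   algorithm = sample(c("a", "b", "c"), 10, TRUE),
                   cn_type = "loss", n_probes = 10L)
  before <- granges2(consensusPerSample(makeCalls(df)))
  extra <- rbind(df, data.frame(chrom = "chr1", start = 900, end = 1400,
                                sample_id = "S1", algorithm = "c",
                                cn_type = "loss", n_probes = 10L))
  after <- granges2(consensusPerSample(makeCalls(extra)))
  if (length(before)) {
    hits <- GenomicRanges::findOverlaps(
      before, after, type = "within", ignore.strand = TRUE)
    expect_equal(length(unique(S4Vectors::queryHits(hits))),
                 length(before))
  }
})

test_that("per-genome summary arithmetic and degenerate inputs", {
  df <- data.frame(chrom = "chr1",
                   start = seq(1e5, by = 1e5, length.out = 6),
                   sample_id = rep(c("S1", "S2", "S3"), c(3, 2, 1)),
                   algorithm = "a",
                   cn_type = rep(c("gain", "loss"), 3), n_probes = 10L)
  df$end <- df$start + 9999
  calls <- makeCalls(df)
  s <- perGenomeSummary(calls, 3)
  expect_equal(s$nTotal, 6L)
  expect_equal(s$nGain, 3L)
  expect_equal(s$meanPerGenome, 2.0)
  expect_equal(s$perGenomeMin, 1L)
  expect_equal(s$perGenomeMax, 3L)
  expect_equal(s$minSize, 10000L)

  empty <- consensusPerSample(makeCalls(df[0, ]))
  s0 <- perGenomeSummary(empty, 34)
  expect_equal(s0$nTotal, 0L)
  expect_equal(s0$meanPerGenome, 0)
  expect_error(perGenomeSummary(calls, 0), class = "emptyCohortError")
})
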