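# Consensus fixtures for CNVR tests are built directly from data frames.
consensusFromDf <- function(df) {
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end))
  gr$sample_id <- df$sample_id
  gr$cn_type <- df$cn_type
  gr$support <- IRanges::CharacterList(
    rep(list(c("a", "b")), nrow(df)))
  gr$n_members <- rep(2L, nrow(df))
  members <- GenomicRanges::GRanges()
  members$consensus_id <- integer(0)
  new("ConsensusCnvSet", ranges = gr, memberCalls = members)
}

test_that("CNVRs are cross-sample overlap components with correct typing", {
  df <- data.frame(
    chrom = "chr1",
    start = c(1000, 1500, 50000, 50000, 90000),
    end = c(2000, 2600, 60000, 55000, 95000),
    sample_id = c("S1", "S2", "S1", "S2", "S3"),
    cn_type = c("loss", "loss", "gain", "loss", "gain"))
  set <- buildCnvrs(consensusFromDf(df), nGenomes = 34)
  gr <- granges2(set)
  expect_equal(length(gr), 3L)
  expect_equal(gr$type_class, c("loss", "multi_allelic", "gain"))
  expect_equal(GenomicRanges::start(gr), c(1000L, 50000L, 90000L))
  expect_equal(GenomicRanges::end(gr), c(2600L, 60000L, 95000L))
  expect_equal(gr$n_carriers, c(2L, 2L, 1L))
  expect_equal(gr$frequency, c(2, 2, 1) / 34)

  one <- buildCnvrs(consensusFromDf(df[1, ]), nGenomes = 34)
  expect_equal(granges2(one)$type_class, "loss")
  expect_equal(intervalLength(granges2(one)), 1001L)
})

test_that("CNVR partition matches brute-force closure, order-independent", {
  set.seed(57)
  for (rep in 1:5) {
    n <- 30
    st <- sample.int(3000, n, replace = TRUE)
    df <- data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                     start = st, end = st + sample.int(200, n, TRUE),
                     sample_id = sample(paste0("S", 1:5), n, TRUE),
                     cn_type = sample(c("gain", "loss"), n, TRUE))
    set <- buildCnvrs(consensusFromDf(df), nGenomes = 5)
    comp <- oracleOverlapComponents(df$chrom, df$start, df$end)
    expect_equal(length(set), length(unique(comp)))
    # membership is a partition
    expect_equal(sort(unique(set@members$cnvr_id)),
                 seq_len(length(set)))
    expect_equal(length(set@members), n)
    # no two CNVRs overlap
    gr <- sort(granges2(set))
    expect_true(all(overlapBp(gr[-length(gr)], gr[-1]) == 0))
    # shuffling input order yields the identical region set
    perm <- sample.int(n)
    set2 <- buildCnvrs(consensusFromDf(df[perm, ]), nGenomes = 5)
    key <- function(s) {
      g <- granges2(s)
      paste0(GenomicRanges::seqnames(g), ":", GenomicRanges::start(g),
             "-", GenomicRanges::end(g), ":", g$type_class)
    }
    expect_identical(key(set2), key(set))
  }
})

test_that("carrier frequency counts genomes once and rounds at report time", {
  df <- data.frame(chrom = "chr1", start = c(1000, 1200), end = c(2000, 2100),
                   sample_id = c("S1", "S1"), cn_type = "loss")
  set <- buildCnvrs(consensusFromDf(df), nGenomes = 34)
  # one genome contributing two member calls counts once
  expect_equal(granges2(set)$n_carriers, 1L)
  expect_equal(carrierFrequency(set), 1 / 34)
  expect_equal(formatFrequency(carrierFrequency(1, 34)), 0.03)
  expect_equal(formatFrequency(carrierFrequency(15, 34)), 0.44)
  expect_equal(formatPercent(carrierFrequency(19, 34)), 56)
  expect_equal(carrierFrequency(0, 34), 0)
  expect_error(carrierFrequency(5, 0), class = "emptyCohortError")
  expect_error(carrierFrequency(35, 34), class = "carrierCountError")
})

test_that("classification counts tally type classes", {
  df <- data.frame(
    chrom = "chr1", start = c(1e3, 1e5, 2e5, 2e5), end = c(2e3, 1.5e5, 2.5e5, 2.4e5),
    sample_id = c("S1", "S2", "S1", "S2"),
    cn_type = c("loss", "gain", "gain", "loss"))
  cc <- classifyCounts(buildCnvrs(consensusFromDf(df), nGenomes = 4))
  expect_equal(cc[["n_loss"]], 1L)
  expect_equal(cc[["n_gain"]], 1L)
  expect_equal(cc[["n_multi"]], 1L)
  expect_equal(cc[["n_total"]], 3L)
  empty <- buildCnvrs(consensusFromDf(df[0, ]), nGenomes = 4)
  expect_equal(unname(classifyCounts(empty)), rep(0L, 4))
})

test_that("size histogram uses half-open bins with upper-bin edge rule", {
  expect_equal(sizeDistribution(5000, c(1e3, 1e4, 1e5)), c(1L, 0L))
  # a size exactly on an interior edge falls in the upper bin
  expect_equal(sizeDistribution(1e4, c(1e3, 1e4, 1e5)), c(0L, 1L))
  expect_error(sizeDistribution(5000, c(1e4, 1e3)), class = "binEdgeError")
  expect_error(sizeDistribution(5, c(1e3, 1e4)), class = "binRangeError")
  set.seed(3)
  sizes <- sample(1000:99999, 100)
  edges <- c(1e3, 5e3, 2e4, 1e5)
  got <- sizeDistribution(sizes, edges)
  want <- c(sum(sizes >= 1e3 & sizes < 5e3),
            sum(sizes >= 5e3 & sizes < 2e4),
            sum(sizes >= 2e4 & sizes < 1e5))
  expect_equal(got, want)
  expect_equal(sum(got), 100L)
})
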