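specificFixture <- function(df) {
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end))
  gr$sample_id <- df$sample_id
  gr$cn_type <- df$cn_type
  gr$support <- IRanges::CharacterList(rep(list("a"), nrow(df)))
  gr$n_members <- 1L
  members <- GenomicRanges::GRanges()
  members$consensus_id <- integer(0)
  new("ConsensusCnvSet", ranges = gr, memberCalls = members)
}

refFixture <- function(name, chrom, start, end, type = NA) {
  ReferenceSet(name, GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start, end), cn_type = type))
}

test_that("reference matching is strict at the 50% boundary", {
  cnv <- specificFixture(data.frame(chrom = "chr1", start = 1, end = 100000,
                                    sample_id = "S1", cn_type = "loss"))
  # identical entry: known with RO 1
  m <- matchReference(cnv, refFixture("DGV", "chr1", 1, 100000))
  expect_equal(m$status, "known")
  expect_equal(m$best_ro, 1.0)
  # empty reference: novel
  m <- matchReference(cnv, ReferenceSet("DGV", GenomicRanges::GRanges()))
  expect_equal(m$status, "novel")
  # RO exactly 0.5 (overlap 50,000 of two 100,000 bp intervals): novel
  m <- matchReference(cnv, refFixture("DGV", "chr1", 50001, 150000))
  expect_equal(m$best_ro, 0.5)
  expect_equal(m$status, "novel")
})

test_that("raising the threshold can only move CNVs from known to novel", {
  set.seed(99)
  st <- sample.int(5000, 40, replace = TRUE)
  cnvs <- specificFixture(data.frame(chrom = "chr1", start = st,
                                     end = st + 199, sample_id = "S1",
                                     cn_type = "loss"))
  shift <- sample(-250:250, 40, TRUE)
  ref <- refFixture("DGV", "chr1", st + shift, st + shift + 199)
  lo <- matchReference(cnvs, ref, NoveltyConfig(roThreshold = 0.3))
  hi <- matchReference(cnvs, ref, NoveltyConfig(roThreshold = 0.8))
  expect_true(all(hi$status == "novel" | lo$status == "known"))
})

test_that("tiered screen eliminates known CNVs and small survivors", {
  df <- data.frame(
    chrom = "chr1",
    start = c(1e6, 2e6, 3e6),
    end = c(1e6 + 49999, 2e6 + 9546, 3e6 + 49999),
    sample_id = c("S1", "S2", "S3"),
    cn_type = c("loss", "gain", "gain"))
  cnvs <- specificFixture(df)
  refs <- list(
    refFixture("arrayCNP", "chr2", 1, 1000),
    refFixture("HapMap3", "chr1", 1e6, 1e6 + 49999),
    refFixture("SGVP", "chr2", 5e6, 6e6))
  out <- screenPopulationSpecific(cnvs, refs)
  expect_equal(out$provenance$eliminated_by,
               c("HapMap3", "size", "specific"))
  # the 9,547 bp CNV was novel in every tier but fails the 10 kb rule
  expect_equal(length(out$specific), 1L)
  expect_equal(GenomicRanges::start(granges2(out$specific)), 3e6)
})

test_that("tier order changes provenance labels, never the surviving set", {
  set.seed(101)
  n <- 60
  # grid spacing exceeds twice the maximum width, so a reference copy of
  # one CNV can never reach 50% reciprocal overlap with a different CNV
  st <- sample(seq(1e5, 9e6, by = 1e5), n)
  cnvs <- specificFixture(data.frame(
    chrom = "chr1", start = st,
    end = st + sample(c(5000, 15000, 40000), n, TRUE) - 1,
    sample_id = sample(paste0("S", 1:6), n, TRUE),
    cn_type = sample(c("gain", "loss"), n, TRUE)))
  gr <- granges2(cnvs)
  knownIdx <- sample(n, 20)
  half <- knownIdx[1:10]
  refs <- list(
    refFixture("DGV", "chr1", GenomicRanges::start(gr)[half],
               GenomicRanges::end(gr)[half]),
    refFixture("HapMap3", "chr1", GenomicRanges::start(gr)[knownIdx],
               GenomicRanges::end(gr)[knownIdx]))
  out1 <- screenPopulationSpecific(cnvs, refs)
  out2 <- screenPopulationSpecific(cnvs, rev(refs))
  expect_equal(granges2(out1$specific), granges2(out2$specific))
  # brute-force per-CNV predicate: novel everywhere and >= 10 kb
  w <- GenomicRanges::width(gr)
  knownAny <- seq_len(n) %in% knownIdx
  expect_equal(out1$provenance$eliminated_by == "specific",
               !knownAny & w >= 10000)
})

test_that("recurrence distinguishes singleton and recurrent loci", {
  df <- data.frame(
    chrom = "chr1",
    start = c(1e6, 1.00002e6, 5e6, 7e6),
    end = c(1.05e6, 1.04e6, 5.02e6, 7.01e6),
    sample_id = c("S1", "S2", "S3", "S3"),
    cn_type = "loss")
  tab <- recurrenceTable(specificFixture(df))
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$n_carriers, c(2L, 1L, 1L))
  expect_equal(tab$recurrent, c(TRUE, FALSE, FALSE))
  # brute-force grouping agrees
  comp <- oracleOverlapComponents(df$chrom, df$start, df$end)
  expect_equal(nrow(tab), length(unique(comp)))
})
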