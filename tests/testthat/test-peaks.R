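# Peak set algebra against per-base painting oracles.

test_that("mergePeaks needs a shared base; adjacency does not merge", {
  # [0,10) + [5,20) overlap -> one region [0,20)
  gr <- GRanges("chr1", IRanges(c(1, 6), c(10, 20)))
  m <- mergePeaks(gr)
  expect_equal(length(m), 1L)
  expect_equal(c(start(m), end(m)), c(1L, 20L))
  # [0,10) + [10,20) are adjacent in half-open coordinates -> unchanged
  gr <- GRanges("chr1", IRanges(c(1, 11), c(10, 20)))
  expect_equal(length(mergePeaks(gr)), 2L)
  expect_equal(length(mergePeaks(GRanges())), 0L)
})

test_that("mergePeaks matches per-base painting on random sets", {
  set.seed(11)
  for (rep in 1:25) {
    gr <- randomIntervalsSafe(sample.int(40, 1))
    m <- mergePeaks(gr)
    o <- paintMerge(gr)
    expect_equal(start(m), start(o))
    expect_equal(end(m), end(o))
  }
})

test_that("consensus keeps regions supported by enough distinct samples", {
  pk <- GRanges("chr1", IRanges(100, 200))
  cs <- buildGroupConsensus(list(s1 = pk, s2 = pk), minSamples = 2)
  expect_equal(length(peaks(cs)), 1L)
  expect_equal(peaks(cs)$support, 2L)

  only1 <- list(s1 = pk, s2 = GRanges(), s3 = GRanges(), s4 = GRanges())
  cs <- buildGroupConsensus(only1, minSamples = 2)
  expect_equal(length(peaks(cs)), 0L)

  expect_error(buildGroupConsensus(list(s1 = pk), minSamples = 2),
               "exceeds")
  expect_error(buildGroupConsensus(list(), minSamples = 1), "at least one")
})

test_that("consensus equals the per-base support oracle and ignores sample order", {
  set.seed(12)
  for (rep in 1:15) {
    repeat {
      sampleList <- lapply(1:4, function(i)
        randomIntervals(sample.int(25, 1)))
      if (!hasAdjacency(do.call(c, unname(sampleList)))) break
    }
    names(sampleList) <- sprintf("s%d", 1:4)
    k <- sample(1:3, 1)
    cs <- buildGroupConsensus(sampleList, minSamples = k)
    o <- paintConsensus(sampleList, k)
    expect_equal(start(peaks(cs)), start(o))
    expect_equal(end(peaks(cs)), end(o))
    expect_equal(peaks(cs)$support, o$support)
    csR <- buildGroupConsensus(rev(sampleList), minSamples = k)
    expect_equal(GenomicRanges::granges(peaks(csR)), GenomicRanges::granges(peaks(cs)))
    expect_equal(peaks(csR)$support, peaks(cs)$support)
  }
})

test_that("vennClassify partitions the merged union by group overlap", {
  a <- GRanges("chr1", IRanges(1, 100))    # [0,100)
  b <- GRanges("chr1", IRanges(51, 150))   # [50,150)
  v <- vennClassify(a, b)
  expect_equal(unname(vennCounts(v)), c(1L, 0L, 0L))
  expect_equal(c(start(v@shared), end(v@shared)), c(1L, 150L))

  a2 <- GRanges("chr1", IRanges(c(1, 201), c(100, 300)))
  v <- vennClassify(a2, b)
  expect_equal(unname(vennCounts(v)), c(1L, 1L, 0L))

  v <- vennClassify(a2, a2)
  expect_equal(unname(vennCounts(v))[2:3], c(0L, 0L))
})

test_that("vennClassify is symmetric and conserves coverage (per-base oracle)", {
  set.seed(13)
  for (rep in 1:20) {
    repeat {
      a <- randomIntervals(sample.int(30, 1))
      b <- randomIntervals(sample.int(30, 1))
      if (!hasAdjacency(c(a, b))) break
    }
    v <- vennClassify(a, b)
    o <- paintVenn(a, b)
    expect_equal(unname(vennCounts(v)),
                 unname(c(sum(o$label == "shared"),
                          sum(o$label == "unique_a"),
                          sum(o$label == "unique_b"))))
    # the three lists tile the merged union exactly
    all3 <- sort(c(v@shared, v@uniqueA, v@uniqueB))
    expect_true(GenomicRanges::isDisjoint(all3))
    expect_equal(start(all3), start(o$regions))
    expect_equal(end(all3), end(o$regions))
    # swap symmetry
    vs <- vennClassify(b, a)
    expect_equal(GenomicRanges::granges(vs@uniqueA), GenomicRanges::granges(v@uniqueB))
    expect_equal(GenomicRanges::granges(vs@uniqueB), GenomicRanges::granges(v@uniqueA))
    expect_equal(GenomicRanges::granges(vs@shared), GenomicRanges::granges(v@shared))
  }
})

test_that("peakSizeSummary reports width statistics", {
  gr <- GRanges("chr1", IRanges(c(1, 1001), width = c(100, 300)))
  s <- peakSizeSummary(gr)
  expect_equal(unname(s[c("n", "mean", "median")]), c(2, 200, 200))
  one <- peakSizeSummary(GRanges("chr1", IRanges(1, 50)))
  expect_true(all(one[c("mean", "median", "q25", "q75")] == 50))
  expect_error(peakSizeSummary(GRanges()), "empty")
  set.seed(14)
  gr <- randomIntervals(60)
  s <- peakSizeSummary(gr)
  expect_equal(unname(s["mean"]), mean(end(gr) - start(gr) + 1))
  expect_equal(unname(s["median"]), median(end(gr) - start(gr) + 1))
})

test_that("annotatePeaks follows the promoter window and precedence rules", {
  gm <- makeGeneModels(
    data.frame(chrom = "chr1", start = 1001, end = 3000, strand = "+",
               gene_id = "gA"),
    list(gA = GRanges("chr1", IRanges(c(1001, 2401), c(1200, 2600)),
                      strand = "+")))
  # peak [400,600) -> midpoint 500 (0-based); tss0 = 1000; d = -500
  pk <- GRanges("chr1", IRanges(401, 600), peak_id = "p1")
  ann <- annotatePeaks(pk, gm)
  expect_equal(ann$class, "promoter")
  expect_equal(ann$dist_to_tss, -500)
  expect_equal(ann$nearest_gene_id, "gA")

  # midpoint inside the gene body but outside every exon -> intron
  pk <- GRanges("chr1", IRanges(1901, 2100), peak_id = "p2")
  expect_equal(annotatePeaks(pk, gm)$class, "intron")
  # midpoint inside an exon (past the promoter window, outside the TTS)
  pk <- GRanges("chr1", IRanges(2401, 2600), peak_id = "p3")
  expect_equal(annotatePeaks(pk, gm)$class, "exon")
  # midpoint within 100 bp of the transcription end -> tts
  pk <- GRanges("chr1", IRanges(2851, 3050), peak_id = "p5")
  expect_equal(annotatePeaks(pk, gm)$class, "tts")
  # far away -> intergenic
  pk <- GRanges("chr1", IRanges(500001, 500200), peak_id = "p4")
  expect_equal(annotatePeaks(pk, gm)$class, "intergenic")
})

test_that("annotatePeaks matches an exhaustive per-gene scan on random layouts", {
  oracleClassify <- function(pos0, gm, up = 1000, down = 100, tw = 100) {
    g <- genes(gm); exl <- exons(gm)
    cls <- "intergenic"; best <- NA
    gstr <- as.character(strand(g))
    tss0 <- g$tss - 1
    tts0 <- ifelse(gstr == "+", end(g) - 1, start(g) - 1)
    d <- ifelse(gstr == "+", pos0 - tss0, tss0 - pos0)
    dt <- ifelse(gstr == "+", pos0 - tts0, tts0 - pos0)
    p1 <- pos0 + 1
    inBody <- start(g) <= p1 & end(g) >= p1
    inEx <- vapply(seq_along(g), function(k) {
      ex <- exl[[g$gene_id[k]]]
      !is.null(ex) && any(start(ex) <= p1 & end(ex) >= p1)
    }, logical(1))
    if (any(d >= -up & d < down)) "promoter"
    else if (any(abs(dt) <= tw)) "tts"
    else if (any(inBody & inEx)) "exon"
    else if (any(inBody)) "intron"
    else "intergenic"
  }
  set.seed(15)
  for (rep in 1:8) {
    ng <- 6
    st <- sample(seq(1000, 8000, by = 50), ng)
    strand <- sample(c("+", "-"), ng, replace = TRUE)
    gm <- makeGeneModels(
      data.frame(chrom = "chr1", start = st, end = st + 800,
                 strand = strand, gene_id = sprintf("g%02d", 1:ng)),
      setNames(lapply(1:ng, function(i)
        GRanges("chr1", IRanges(st[i], st[i] + 150), strand = strand[i])),
        sprintf("g%02d", 1:ng)))
    pk <- randomIntervals(40, glen = 10000, maxw = 150)
    pk$peak_id <- sprintf("p%02d", seq_along(pk))
    ann <- annotatePeaks(pk, gm)
    mid0 <- (start(pk) - 1 + end(pk)) %/% 2
    for (i in seq_along(pk))
      expect_equal(ann$class[i], oracleClassify(mid0[i], gm),
                   info = sprintf("rep %d peak %d", rep, i))
    # translation invariance of classes
    shift <- 5000L
    pk2 <- GenomicRanges::shift(pk, shift)
    g2 <- GenomicRanges::shift(genes(gm), shift)
    g2$tss <- g2$tss + shift
    gm2 <- new("GeneModels", genes = g2,
               exons = GenomicRanges::shift(exons(gm), shift))
    expect_equal(annotatePeaks(pk2, gm2)$class, ann$class)
  }
})

test_that("tie between equidistant genes breaks to the smaller gene_id", {
  gm <- makeGeneModels(
    data.frame(chrom = "chr1", start = c(2000, 2000), end = c(2500, 2500),
               strand = c("+", "+"), gene_id = c("gB", "gA")))
  pk <- GRanges("chr1", IRanges(1801, 1800 + 199), peak_id = "p1")
  ann <- annotatePeaks(pk, gm)
  expect_equal(ann$nearest_gene_id, "gA")
})
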