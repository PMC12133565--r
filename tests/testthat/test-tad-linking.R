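# TAD assignment, pair enumeration, pooled-sample correlation linking.

.tadFixture <- function() {
  TadPartition(GRanges("chr1", IRanges(c(1, 151), c(150, 300)),
                       tad_id = c("t1", "t2")), repair = FALSE)
}

test_that("anchors on a shared boundary fall in the downstream TAD", {
  tp <- .tadFixture()
  # TADs [0,150) and [150,300) in file coordinates; anchor at 0-based 150
  a <- assignToTads("pk", "chr1", 150L, tp, "peak")
  expect_equal(a$tad_id, "t2")
  a <- assignToTads("g", "chr1", 149L, tp, "gene")
  expect_equal(a$tad_id, "t1")
  a <- assignToTads("far", "chr1", 5000L, tp, "peak")
  expect_true(is.na(a$tad_id))
})

test_that("peak midpoints and gene TSSs are the anchors", {
  tp <- .tadFixture()
  pk <- GRanges("chr1", IRanges(101, 200), peak_id = "p1")  # [100,200)
  pa <- assignPeaksToTads(pk, tp)
  expect_equal(pa$anchor, 150L)   # (100 + 200) %/% 2 in 0-based space
  expect_equal(pa$tad_id, "t2")
  gm <- makeGeneModels(data.frame(chrom = "chr1", start = 150, end = 600,
                                  strand = "+", gene_id = "gA"))
  ga <- assignGenesToTads(gm, tp)
  expect_equal(ga$anchor, 149L)
  expect_equal(ga$tad_id, "t1")
})

test_that("assignment matches a linear-scan oracle on random layouts", {
  set.seed(31)
  for (rep in 1:10) {
    k <- sample(3:8, 1)
    bnd <- sort(sample(seq(100, 9900, by = 100), k + 1))
    tp <- TadPartition(GRanges("chr1", IRanges(bnd[-(k + 1)] + 1, bnd[-1]),
                               tad_id = sprintf("t%d", 1:k)),
                       repair = FALSE)
    pos0 <- sample.int(10000, 60) - 1L
    got <- assignToTads(sprintf("e%d", 1:60), "chr1", pos0, tp, "peak")
    td <- tads(tp)
    want <- vapply(pos0, function(p) {
      hit <- which(start(td) <= p + 1 & end(td) >= p + 1)
      if (length(hit)) td$tad_id[hit] else NA_character_
    }, character(1))
    expect_equal(got$tad_id, want)
  }
})

test_that("pair enumeration is the within-TAD Cartesian product", {
  pa <- data.frame(element_id = sprintf("p%d", 1:3), kind = "peak",
                   tad_id = c("t1", "t1", NA), anchor = 0L)
  ga <- data.frame(element_id = sprintf("g%d", 1:4), kind = "gene",
                   tad_id = c("t1", "t1", "t1", "t2"), anchor = 0L)
  pr <- enumerateTadPairs(pa, ga)
  expect_equal(nrow(pr), 6L)   # 2 assigned peaks x 3 genes in t1
  expect_true(all(pr$tad_id == "t1"))
  expect_false("p3" %in% pr$peak_id)  # unassigned contributes nothing
  # deterministic (tad, peak, gene) ordering
  expect_equal(pr$peak_id, rep(c("p1", "p2"), each = 3))
  expect_equal(pr$gene_id, rep(sprintf("g%d", 1:3), 2))
})

test_that("pair totals follow the per-TAD product counting oracle", {
  set.seed(32)
  for (rep in 1:10) {
    tds <- sprintf("t%d", 1:5)
    pa <- data.frame(element_id = sprintf("p%d", 1:40), kind = "peak",
                     tad_id = sample(c(tds, NA), 40, replace = TRUE),
                     anchor = 0L)
    ga <- data.frame(element_id = sprintf("g%d", 1:30), kind = "gene",
                     tad_id = sample(c(tds, NA), 30, replace = TRUE),
                     anchor = 0L)
    pr <- enumerateTadPairs(pa, ga)
    want <- sum(vapply(tds, function(t)
      sum(pa$tad_id == t, na.rm = TRUE) *
        sum(ga$tad_id == t, na.rm = TRUE), 0))
    expect_equal(nrow(pr), want)
  }
})

test_that("correlatePair reproduces hand-computed r and flags degeneracies", {
  out <- correlatePair(c(1, 2, 3), c(2, 4, 6))
  expect_equal(out$r, 1)
  expect_equal(out$p, 0)
  expect_true(out$perfect)

  out <- correlatePair(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(out$r, 0.8)
  expect_equal(out$p, cor.test(c(1, 2, 3, 4), c(1, 3, 2, 4))$p.value)

  out <- correlatePair(c(1, 1, 1), c(1, 2, 3))
  expect_true(is.na(out$r))
  expect_equal(out$reason, "zero_variance")
  expect_error(correlatePair(c(1, 2), c(1, 2)), "n >= 3")
  expect_error(correlatePair(1:4, 1:5), "equal length")
})

test_that("t-based p tracks the exhaustive permutation null for n <= 6", {
  # The permutation null is conditional on the drawn values, so single
  # pairs can deviate from the unconditional t reference by more than the
  # nominal bound even at n = 6 (observed ~10% of Gaussian pairs); the
  # bound is asserted on the typical (mean) discrepancy.
  set.seed(33)
  ds <- replicate(40, {
    n <- sample(5:6, 1)
    x <- rnorm(n); y <- rnorm(n)
    abs(correlatePair(x, y)$p - permCorP(x, y))
  })
  expect_lt(mean(ds), 0.05)
  expect_lt(max(ds), 0.2)
})

test_that("linkPeaksGenes requires matching samples and applies alpha", {
  A <- matrix(rnorm(20), 4, 5,
              dimnames = list(sprintf("p%d", 1:4), sprintf("s%d", 1:5)))
  R <- matrix(rnorm(20), 4, 5,
              dimnames = list(sprintf("g%d", 1:4), sprintf("s%d", 1:5)))
  pr <- data.frame(tad_id = "t1", peak_id = "p1", gene_id = "g1")
  expect_error(linkPeaksGenes(pr, A, R[, 5:1]), "sample mismatch")

  # alpha = 1 makes every testable pair significant
  pr <- expand.grid(peak_id = rownames(A), gene_id = rownames(R),
                    stringsAsFactors = FALSE)
  pr$tad_id <- "t1"
  ls1 <- linkPeaksGenes(pr, A, R, alpha = 1)
  expect_true(all(links(ls1)$significant))
})

test_that("a planted common group shift yields a significant positive link", {
  set.seed(34)
  shift <- rep(c(0, 6), each = 4)
  A <- rbind(p1 = rnorm(8, 10 + shift, 0.5),
             p2 = rep(3, 8))                 # constant: zero variance
  R <- rbind(g1 = rnorm(8, 20 + shift, 0.5))
  colnames(A) <- colnames(R) <- sprintf("s%d", 1:8)
  pr <- data.frame(tad_id = "t1", peak_id = c("p1", "p2"),
                   gene_id = c("g1", "g1"))
  ls <- linkPeaksGenes(pr, A, R, alpha = 0.05)
  lk <- links(ls)
  expect_equal(nrow(lk), 1L)
  expect_true(lk$significant & lk$sign == "positive")
  dp <- droppedPairs(ls)
  expect_equal(dp$peak_id, "p2")
  expect_equal(dp$reason, "zero_variance")
})

test_that("links are invariant to sample order and group relabeling", {
  set.seed(35)
  A <- matrix(rnorm(80), 10, 8,
              dimnames = list(sprintf("p%d", 1:10), sprintf("s%d", 1:8)))
  R <- matrix(rnorm(80), 10, 8,
              dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:8)))
  pr <- data.frame(tad_id = "t1",
                   peak_id = sprintf("p%d", 1:10),
                   gene_id = sprintf("g%d", 1:10))
  l1 <- links(linkPeaksGenes(pr, A, R))
  perm <- sample(8)
  l2 <- links(linkPeaksGenes(pr, A[, perm], R[, perm]))
  expect_equal(l2$r, l1$r, tolerance = 1e-12)
  expect_equal(l2$significant, l1$significant)
})

test_that("summaries conserve counts and match recomputation", {
  lk <- data.frame(
    tad_id = "t1", peak_id = sprintf("p%d", 1:5),
    gene_id = sprintf("g%d", 1:5),
    r = c(0.9, 0.8, -0.85, 0.2, -0.1),
    p_raw = c(0.01, 0.02, 0.03, 0.5, 0.9),
    significant = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    sign = c("positive", "positive", "negative", "positive", "negative"),
    n_samples = 8, perfect = FALSE,
    annotation_class = c("promoter", "promoter", "intron", "exon",
                         "intergenic"))
  ls <- new("LinkSet", links = lk,
            dropped = data.frame(peak_id = character(0),
                                 gene_id = character(0),
                                 tad_id = character(0),
                                 reason = character(0)),
            alpha = 0.05, adjust = "none")
  s <- summarizeLinks(ls)
  expect_equal(s$n_significant, 3L)
  expect_equal(s$n_positive + s$n_negative, s$n_significant)
  pos <- s$class_proportions[s$class_proportions$sign == "positive", ]
  expect_equal(sum(pos$proportion), 1)
  expect_equal(pos$proportion[pos$class == "promoter"], 1)
  neg <- s$class_proportions[s$class_proportions$sign == "negative", ]
  expect_equal(neg$proportion[neg$class == "intron"], 1)
})

test_that("correlated DE gene selection is the set intersection", {
  lk <- data.frame(peak_id = c("p1", "p2", "p3"),
                   gene_id = c("g1", "g2", "g2"),
                   p_raw = c(0.01, 0.2, 0.6))
  expect_equal(selectCorrelatedDeGenes(lk, c("g1", "g2", "g9")), "g1")
  expect_equal(selectCorrelatedDeGenes(lk, c("g1", "g2"), 0.3),
               c("g1", "g2"))
  expect_equal(selectCorrelatedDeGenes(lk, character(0)), character(0))
})
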