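# PWM scanning, exact score-distribution thresholds, GC-matched
# backgrounds and hypergeometric enrichment.

.uniformPwm1 <- function() {
  PWMotif(matrix(c(1, 1, 1, 1), 4, 1), id = "flat", pseudocount = 0)
}

.randomPwm <- function(L, conc = 6) {
  counts <- matrix(rgamma(4 * L, shape = 0.5) * conc, 4, L)
  PWMotif(round(counts * 10) + 1, id = sprintf("rand%d", L),
          pseudocount = 0.8)
}

test_that("score threshold handles the flat degenerate matrix", {
  pwm <- .uniformPwm1()
  expect_equal(scoreThreshold(pwm, 0.5), 0)
  expect_equal(scoreThreshold(pwm, 1e-4), 0)
})

test_that("DP tail probabilities equal exhaustive dimer enumeration (L = 2)", {
  set.seed(51)
  pwm <- .randomPwm(2)
  dist <- tadlink:::.scoreDistribution(pwm, 0.01)
  # every distinct achievable score's tail must match brute-force
  # enumeration over all 16 dimers on the same score bins
  for (i in seq_len(nrow(dist))) {
    t_ <- dist$score[i]
    dpTail <- sum(dist$prob[dist$score >= t_ - 1e-9])
    expect_equal(dpTail, enumTail(pwm, t_), tolerance = 1e-9)
  }
})

test_that("DP matches enumeration for random PWMs up to L = 6", {
  set.seed(52)
  for (L in 3:6) {
    pwm <- .randomPwm(L)
    dist <- tadlink:::.scoreDistribution(pwm, 0.01)
    minTail <- dist$prob[nrow(dist)]   # P(score = max): smallest tail
    for (p0 in c(0.25, 0.05, 1e-3)) {
      t_ <- scoreThreshold(pwm, p0, binWidth = 0.01)
      if (minTail > p0) {
        # unreachable target: the maximal achievable score is returned
        expect_equal(t_, dist$score[nrow(dist)])
        next
      }
      # the enumerated tail at the binned threshold respects the target
      expect_lte(enumTail(pwm, t_), p0 + 1e-12)
      # minimality over achievable scores: the next achievable score
      # below the threshold would exceed the target
      below <- dist$score[dist$score < t_ - 1e-9]
      if (length(below))
        expect_gt(enumTail(pwm, max(below)), p0)
    }
  }
})

test_that("threshold is non-increasing in the target p", {
  set.seed(53)
  pwm <- .randomPwm(5)
  ps <- c(1e-5, 1e-4, 1e-3, 0.01, 0.1, 0.5)
  ts <- vapply(ps, function(p) scoreThreshold(pwm, p), numeric(1))
  expect_true(all(diff(ts) <= 1e-12))
  expect_error(scoreThreshold(pwm, 0), "targetP")
  expect_error(scoreThreshold(pwm, 1), "targetP")
})

test_that("the consensus sequence scores maximally on the + strand", {
  set.seed(54)
  pwm <- .randomPwm(8)
  cons <- paste(c("A", "C", "G", "T")[apply(probs(pwm), 2, which.max)],
                collapse = "")
  maxScore <- sum(apply(logOdds(pwm), 2, max))
  hits <- scanSequences(c(s1 = cons), pwm, threshold = maxScore - 1e-9)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$offset, 0L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$score, maxScore)

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
  hits <- scanSequences(c(s1 = rc), pwm, threshold = maxScore - 1e-9)
  expect_equal(hits$strand, "-")
  expect_equal(hits$score, maxScore)
})

test_that("scan equals brute-force window rescoring and skips N windows", {
  set.seed(55)
  pwm <- .randomPwm(5)
  lo <- logOdds(pwm)
  seqs <- c(a = paste0(randDNA(60), "N", randDNA(40)), b = randDNA(80))
  th <- scoreThreshold(pwm, 0.05)
  hits <- scanSequences(seqs, pwm, th)
  # independent rescoring of every window on both strands
  brute <- list()
  for (nm in names(seqs)) {
    s <- seqs[[nm]]
    for (o in 0:(nchar(s) - 5)) {
      win <- substr(s, o + 1, o + 5)
      if (grepl("N", win)) next
      for (strand in c("+", "-")) {
        w <- if (strand == "+") win else
          as.character(Biostrings::reverseComplement(Biostrings::DNAString(win)))
        idx <- match(strsplit(w, "")[[1]], c("A", "C", "G", "T"))
        sc <- sum(lo[cbind(idx, 1:5)])
        if (sc >= th)
          brute[[length(brute) + 1L]] <- data.frame(
            sequence_id = nm, offset = o, strand = strand, score = sc)
      }
    }
  }
  brute <- do.call(rbind, brute)
  brute <- brute[order(match(brute$sequence_id, names(seqs)), brute$offset,
                       brute$strand), ]
  rownames(brute) <- NULL
  expect_equal(hits, brute, tolerance = 1e-12)
  # no hit overlaps the N position
  expect_true(all(hits$offset + 5 <= 60 | hits$offset >= 61 |
                    hits$sequence_id != "a"))
})

test_that("scanning is strand-symmetric on reverse-complemented input", {
  set.seed(56)
  pwm <- .randomPwm(6)
  s <- randDNA(120)
  th <- scoreThreshold(pwm, 0.02)
  h1 <- scanSequences(c(x = s), pwm, th)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  h2 <- scanSequences(c(x = rc), pwm, th)
  # map reverse hits back to forward coordinates and swap strand labels
  h2$offset <- nchar(s) - 6 - h2$offset
  h2$strand <- ifelse(h2$strand == "+", "-", "+")
  h2 <- h2[order(h2$offset, h2$strand), ]
  h1 <- h1[order(h1$offset, h1$strand), ]
  rownames(h1) <- rownames(h2) <- NULL
  expect_equal(h1, h2, tolerance = 1e-12)
  # sequences shorter than the motif yield no hits, not an error
  expect_equal(nrow(scanSequences(c(tiny = "ACG"), pwm, 0)), 0L)
})

test_that("GC-matched background sampling is seeded and respects constraints", {
  set.seed(57)
  genome <- Biostrings::DNAStringSet(c(chr1 = randDNA(50000, gc = 0.45)))
  targets <- GRanges("chr1", IRanges(c(1000, 9000, 30000), width = 300))
  b1 <- sampleGCMatchedBackground(targets, genome, 30, seed = 99)
  b2 <- sampleGCMatchedBackground(targets, genome, 30, seed = 99)
  expect_identical(as.character(b1$seqs), as.character(b2$seqs))
  expect_false(any(overlapsAny(b1$regions, targets)))
  gcOf <- function(ss) {
    f <- Biostrings::alphabetFrequency(ss)
    mean((f[, "C"] + f[, "G"]) / rowSums(f[, 1:4]))
  }
  tseq <- extractSequences(genome, targets)
  expect_lt(abs(gcOf(b1$seqs) - gcOf(tseq)), 0.05)
  # an impossible GC demand reports the achieved tolerance
  # a pure-GC target in an AT genome cannot be matched at tol 0.01
  expect_error(
    sampleGCMatchedBackground(
      GRanges("chr1", IRanges(1, 3)),
      Biostrings::DNAStringSet(c(chr1 = paste0("GGG", strrep("A", 200)))),
      5, gcTol = 0.01, maxTries = 50, seed = 1),
    "tolerance")
})

test_that("hypergeometric enrichment reproduces the exact combinatorial case", {
  pwm <- PWMotif(matrix(c(0, 0, 0, 40,
                          0, 0, 40, 0,
                          40, 0, 0, 0,
                          0, 40, 0, 0,
                          0, 0, 0, 40,
                          0, 0, 40, 0), 4, 6), id = "tgactg",
                 pseudocount = 0.1)
  instance <- "TGACTG"
  tg <- c(t1 = paste0("AAAAAA", instance, "AAAAAA"),
          t2 = paste0("CCCCCC", instance, "CCCCCC"))
  bg <- c(b1 = paste(rep("A", 18), collapse = ""),
          b2 = paste(rep("C", 18), collapse = ""))
  # explicit mid-range threshold: consensus scores ~12 bits, the best
  # single-mismatch word ~3 bits
  res <- motifEnrichment(tg, bg, pwm, threshold = 6)
  expect_equal(res$k_target, 2L)
  expect_equal(res$k_background, 0L)
  expect_equal(res$p_hyper, 1 / 6)   # C(2,2) C(2,0) / C(4,2)

  res0 <- motifEnrichment(bg, bg2 <- c(b3 = bg[[1]], b4 = bg[[2]]), pwm)
  expect_equal(res0$p_hyper, 1)
  expect_error(motifEnrichment(character(0), bg, pwm), "empty")
  expect_error(motifEnrichment(c(x = "AAAA"), c(x = "CCCC"), pwm),
               "overlap")
})

test_that("a planted motif at 60% vs 5% is detected far below 1e-6", {
  set.seed(58)
  pwm <- tadlinkMotif()
  plantInto <- function(s, inst) {
    o <- sample.int(nchar(s) - nchar(inst), 1)
    paste0(substr(s, 1, o), inst, substr(s, o + nchar(inst) + 1, nchar(s)))
  }
  cons <- paste(c("A", "C", "G", "T")[apply(probs(pwm), 2, which.max)],
                collapse = "")
  tg <- vapply(1:200, function(i) {
    s <- randDNA(200)
    if (i <= 120) plantInto(s, cons) else s
  }, character(1))
  names(tg) <- sprintf("t%d", 1:200)
  bg <- vapply(1:2000, function(i) {
    s <- randDNA(200)
    if (i <= 100) plantInto(s, cons) else s
  }, character(1))
  names(bg) <- sprintf("b%d", 1:2000)
  res <- motifEnrichment(tg, bg, pwm, scanP = 1e-4)
  expect_lt(res$p_hyper, 1e-6)
  expect_gt(res$fold_enrichment, 4)
})
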