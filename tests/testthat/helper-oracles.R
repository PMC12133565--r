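# Independent brute-force oracles and fixture builders used across the
# suite. The oracles deliberately avoid the package's own code paths
# (per-base boolean painting instead of interval algebra, explicit
# step-up loops instead of vectorized cummin, exhaustive enumeration
# instead of dynamic programming).

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

tmpf <- function(ext = "") tempfile(fileext = ext)

# random interval set on a toy genome of `glen` bp (single chromosome)
randomIntervals <- function(n, glen = 10000L, maxw = 400L, chrom = "chr1") {
  s <- sample.int(glen - 10L, n, replace = TRUE)
  w <- sample.int(maxw, n, replace = TRUE)
  GRanges(chrom, IRanges(s, pmin(s + w, glen)))
}

# TRUE when the merged union of `gr` contains exactly-adjacent regions
# (the one case where region counting by per-base painting is ambiguous;
# the adjacency convention has its own directed test)
hasAdjacency <- function(gr) {
  length(GenomicRanges::reduce(gr, min.gapwidth = 0L)) !=
    length(GenomicRanges::reduce(gr, min.gapwidth = 1L))
}

# resample until the combined union is adjacency-free
randomIntervalsSafe <- function(n, glen = 10000L, maxw = 400L) {
  repeat {
    gr <- randomIntervals(n, glen, maxw)
    if (!hasAdjacency(gr)) return(gr)
  }
}

# per-base painting: merged regions of a coverage vector (>=1 bp overlap
# semantics arise naturally from painting closed 1-based intervals)
paintMerge <- function(gr, glen = 10000L) {
  cov <- logical(glen)
  for (i in seq_along(gr)) cov[start(gr)[i]:end(gr)[i]] <- TRUE
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) return(GRanges())
  GRanges(as.character(seqnames(gr))[1],
          IRanges(starts[keep], ends[keep]))
}

# per-base consensus oracle: merged union regions supported by >= k of
# the sample sets (a sample supports a region when it covers any base)
paintConsensus <- function(sampleList, k, glen = 10000L) {
  un <- paintMerge(do.call(c, unname(sampleList)), glen)
  if (length(un) == 0L) return(un)
  supp <- vapply(seq_along(un), function(i) {
    bases <- start(un)[i]:end(un)[i]
    sum(vapply(sampleList, function(g) {
      cov <- logical(glen)
      for (j in seq_along(g)) cov[start(g)[j]:end(g)[j]] <- TRUE
      any(cov[bases])
    }, logical(1)))
  }, integer(1))
  un$support <- supp
  un[supp >= k]
}

# per-base Venn label oracle on the merged union of two sets
paintVenn <- function(a, b, glen = 10000L) {
  covA <- logical(glen); covB <- logical(glen)
  for (i in seq_along(a)) covA[start(a)[i]:end(a)[i]] <- TRUE
  for (i in seq_along(b)) covB[start(b)[i]:end(b)[i]] <- TRUE
  un <- paintMerge(c(GenomicRanges::granges(a), GenomicRanges::granges(b)), glen)
  lab <- vapply(seq_along(un), function(i) {
    bases <- start(un)[i]:end(un)[i]
    hasA <- any(covA[bases]); hasB <- any(covB[bases])
    if (hasA && hasB) "shared" else if (hasA) "unique_a" else "unique_b"
  }, character(1))
  list(regions = un, label = lab)
}

# explicit step-up BH, written as the definition reads
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) ps[j] * m / j, numeric(1))
    q[i] <- min(1, min(cand))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# exhaustive two-sided permutation p for Pearson correlation (n <= 6)
permCorP <- function(x, y) {
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  robs <- abs(cor(x, y))
  rs <- vapply(perms(seq_along(y)), function(ix) abs(cor(x, y[ix])),
               numeric(1))
  mean(rs >= robs - 1e-12)
}

# exhaustive L-mer tail probabilities for a PWM under its background.
# Column scores are rounded to the same bins the DP uses, so the oracle
# enumerates exactly the distribution the DP computes.
enumTail <- function(pwm, threshold, binWidth = 0.01) {
  lo <- round(logOdds(pwm) / binWidth) * binWidth
  bg <- pwm@background
  L <- ncol(lo)
  kmers <- expand.grid(rep(list(1:4), L))
  tot <- 0
  for (r in seq_len(nrow(kmers))) {
    idx <- as.integer(kmers[r, ])
    sc <- sum(lo[cbind(idx, seq_len(L))])
    if (sc >= threshold - 1e-9) tot <- tot + prod(bg[idx])
  }
  tot
}

# random DNA as a character string
randDNA <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# small deterministic gene-model builder
makeGeneModels <- function(df, exonList = list()) {
  g <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand,
               gene_id = df$gene_id,
               tss = ifelse(df$strand == "+", df$start, df$end))
  exl <- GRangesList(exonList)
  new("GeneModels", genes = g, exons = exl)
}

binomCI95 <- function(p0, n) {
  p0 + c(-1, 1) * 1.96 * sqrt(p0 * (1 - p0) / n)
}
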