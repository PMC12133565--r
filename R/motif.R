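## PWM motif machinery: exact score-distribution thresholds by dynamic
## programming, two-strand log-odds scanning, GC-matched background
## sampling, and hypergeometric over-representation testing.

.BASES <- c("A", "C", "G", "T")

.encodeSeq <- function(s) {
  # 1..4 for A,C,G,T; NA for N or anything else
  match(strsplit(toupper(s), "")[[1]], .BASES)
}

#' Score threshold for a target p-value under the background model
#'
#' The exact distribution of the log-odds score of a random L-mer drawn
#' from the background model is computed by dynamic programming over the
#' per-column score distributions, discretized at `binWidth` bits. The
#' returned threshold is the smallest achievable (discretized) score `t`
#' with `P(score >= t) <= targetP`; when even the maximal score exceeds
#' `targetP` (degenerate flat matrices) the maximal achievable score is
#' returned.
#'
#' @param pwm A [PWMotif-class].
#' @param targetP Tail probability in (0, 1) (default 1e-4).
#' @param binWidth Discretization bin width in bits (default 0.01).
#' @return Threshold in bits.
#' @export
scoreThreshold <- function(pwm, targetP = 1e-4, binWidth = 0.01) {
  if (targetP <= 0 || targetP >= 1)
    stop("targetP must lie in (0, 1)", call. = FALSE)
  dist <- .scoreDistribution(pwm, binWidth)
  tail <- rev(cumsum(rev(dist$prob)))
  ok <- which(tail <= targetP)
  if (length(ok) == 0L) return(dist$score[length(dist$score)])
  dist$score[ok[1]]
}

## exact binned distribution of the background-model score
.scoreDistribution <- function(pwm, binWidth = 0.01) {
  lo <- logOdds(pwm)
  bg <- pwm@background
  L <- ncol(lo)
  bins <- round(lo / binWidth)
  # dist as vector indexed by bin offset; track min bin
  probVec <- 1
  minBin <- 0L
  for (j in seq_len(L)) {
    bj <- bins[, j]
    lo_j <- min(bj); hi_j <- max(bj)
    newMin <- minBin + lo_j
    newLen <- length(probVec) + (hi_j - lo_j)
    newVec <- numeric(newLen)
    for (b in 1:4) {
      off <- bj[b] - lo_j
      idx <- seq_along(probVec) + off
      newVec[idx] <- newVec[idx] + probVec * bg[b]
    }
    probVec <- newVec
    minBin <- newMin
  }
  keep <- probVec > 0
  data.frame(score = (minBin + which(keep) - 1L) * binWidth,
             prob = probVec[keep])
}

#' Scan sequences with a PWM on both strands
#'
#' Every window of length L is scored with the log-odds matrix on the
#' forward strand and on the reverse complement; windows containing `N`
#' are skipped. Hits are windows scoring at least `threshold`. The
#' reported offset is 0-based and refers to the window's leftmost
#' position on the forward sequence for both strands.
#'
#' @param sequences A named `DNAStringSet` or named character vector.
#' @param pwm A [PWMotif-class].
#' @param threshold Minimum score in bits; computed from `scanP` when
#'   `NULL`.
#' @param scanP Tail probability used when `threshold` is `NULL`
#'   (default 1e-4).
#' @return data.frame with columns `sequence_id`, `offset`, `strand`,
#'   `score`.
#' @export
scanSequences <- function(sequences, pwm, threshold = NULL, scanP = 1e-4) {
  if (is.null(threshold)) threshold <- scoreThreshold(pwm, scanP)
  if (is(sequences, "DNAStringSet"))
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq_%d", seq_along(sequences))
  lo <- logOdds(pwm)
  L <- ncol(lo)
  # reverse-complement scoring matrix: scanning forward windows with
  # loRC equals scoring the window's reverse complement with lo
  loRC <- lo[4:1, L:1, drop = FALSE]
  hits <- vector("list", length(sequences))
  for (si in seq_along(sequences)) {
    v <- .encodeSeq(sequences[[si]])
    W <- length(v) - L + 1L
    if (W < 1L) next
    fwd <- numeric(W); rev_ <- numeric(W); bad <- logical(W)
    for (j in seq_len(L)) {
      vj <- v[j:(j + W - 1L)]
      isna <- is.na(vj)
      bad <- bad | isna
      vj[isna] <- 1L
      fwd <- fwd + lo[cbind(vj, j)]
      rev_ <- rev_ + loRC[cbind(vj, j)]
    }
    fwd[bad] <- -Inf; rev_[bad] <- -Inf
    hf <- which(fwd >= threshold)
    hr <- which(rev_ >= threshold)
    if (length(hf) + length(hr) == 0L) next
    hits[[si]] <- data.frame(
      sequence_id = names(sequences)[si],
      offset = c(hf, hr) - 1L,
      strand = c(rep("+", length(hf)), rep("-", length(hr))),
      score = c(fwd[hf], rev_[hr]),
      stringsAsFactors = FALSE)
  }
  hits <- hits[!vapply(hits, is.null, TRUE)]
  if (length(hits) == 0L)
    return(data.frame(sequence_id = character(0), offset = integer(0),
                      strand = character(0), score = numeric(0)))
  out <- do.call(rbind, hits)
  out <- out[order(match(out$sequence_id, names(sequences)), out$offset,
                   out$strand), ]
  rownames(out) <- NULL
  out
}

#' Sample GC-matched background regions from a genome
#'
#' Random genomic windows, each length-matched to a randomly chosen
#' target region and accepted only when its GC fraction is within
#' `gcTol` of that target's GC. Windows overlapping any target region or
#' containing `N` are rejected. Fully reproducible for a given RNG state
#' (or `seed`).
#'
#' @param targetRegions `GRanges` of the target (foreground) regions.
#' @param genome A named `DNAStringSet`.
#' @param nBackground Number of background regions (>= number of targets
#'   recommended).
#' @param gcTol GC tolerance (default 0.05).
#' @param maxTries Total rejection-sampling budget (default
#'   `200 * nBackground`).
#' @param seed Optional integer seed.
#' @return List with `regions` (`GRanges`) and `seqs` (`DNAStringSet`,
#'   ids `bg_1..bg_n`).
#' @export
sampleGCMatchedBackground <- function(targetRegions, genome, nBackground,
                                      gcTol = 0.05, maxTries = NULL,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(maxTries)) maxTries <- 200L * nBackground
  tseq <- extractSequences(genome, targetRegions)
  gcOf <- function(ss) {
    f <- Biostrings::alphabetFrequency(ss)
    (f[, "C"] + f[, "G"]) / pmax(rowSums(f[, c("A", "C", "G", "T"),
                                           drop = FALSE]), 1)
  }
  tgc <- gcOf(tseq)
  tlen <- width(targetRegions)
  chroms <- names(genome)
  clen <- Biostrings::width(genome)
  got <- 0L; tries <- 0L
  bestMiss <- Inf
  regs <- vector("list", nBackground)
  seqs <- character(nBackground)
  while (got < nBackground && tries < maxTries) {
    tries <- tries + 1L
    k <- sample.int(length(tlen), 1L)
    ci <- sample.int(length(chroms), 1L)
    if (clen[ci] < tlen[k]) next
    s1 <- sample.int(clen[ci] - tlen[k] + 1L, 1L)
    cand <- GRanges(chroms[ci], IRanges(s1, s1 + tlen[k] - 1L))
    if (any(overlapsAny(cand, targetRegions, ignore.strand = TRUE))) next
    sq <- as.character(Biostrings::subseq(genome[[chroms[ci]]], s1,
                                          s1 + tlen[k] - 1L))
    if (grepl("N", sq, fixed = TRUE)) next
    gc <- (lengths(regmatches(sq, gregexpr("[GC]", sq)))) / nchar(sq)
    miss <- abs(gc - tgc[k])
    bestMiss <- min(bestMiss, miss)
    if (miss > gcTol) next
    got <- got + 1L
    regs[[got]] <- cand
    seqs[got] <- sq
  }
  if (got < nBackground)
    stop(sprintf(paste0("could not sample %d GC-matched backgrounds in %d",
                        " tries (best achieved tolerance %.3f)"),
                 nBackground, maxTries, bestMiss), call. = FALSE)
  regions <- suppressWarnings(do.call(c, regs))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sprintf("bg_%d", seq_len(nBackground))
  regions$name <- names(out)
  list(regions = regions, seqs = out)
}

#' Hypergeometric motif over-representation test
#'
#' Sequence-level presence/absence: a sequence counts as positive when it
#' has at least one hit at the scan threshold. The one-sided upper-tail
#' hypergeometric p asks whether the targets hold more positives than
#' expected when drawing `n_target` sequences from the pooled
#' target + background universe. Fold enrichment uses a Haldane +0.5
#' continuity guard so it is finite when the background has no positives.
#'
#' @param targetSeqs,backgroundSeqs Named `DNAStringSet` or character
#'   vectors with disjoint id spaces.
#' @param pwm A [PWMotif-class].
#' @param scanP Tail probability defining the scan threshold
#'   (default 1e-4).
#' @param threshold Explicit score threshold in bits (overrides `scanP`).
#' @return List with `motif_id`, `n_target`, `k_target`, `n_background`,
#'   `k_background`, `fold_enrichment`, `p_hyper`, `threshold`.
#' @export
motifEnrichment <- function(targetSeqs, backgroundSeqs, pwm, scanP = 1e-4,
                            threshold = NULL) {
  if (length(targetSeqs) == 0L || length(backgroundSeqs) == 0L)
    stop("empty target or background set", call. = FALSE)
  tn <- if (is.null(names(targetSeqs)))
    sprintf("t_%d", seq_along(targetSeqs)) else names(targetSeqs)
  bn <- if (is.null(names(backgroundSeqs)))
    sprintf("b_%d", seq_along(backgroundSeqs)) else names(backgroundSeqs)
  if (length(intersect(tn, bn)))
    stop("target and background id spaces overlap", call. = FALSE)
  if (is.null(threshold)) threshold <- scoreThreshold(pwm, scanP)
  ht <- scanSequences(targetSeqs, pwm, threshold)
  hb <- scanSequences(backgroundSeqs, pwm, threshold)
  nT <- length(targetSeqs); nB <- length(backgroundSeqs)
  kT <- length(unique(ht$sequence_id))
  kB <- length(unique(hb$sequence_id))
  K <- kT + kB; N <- nT + nB
  p <- stats::phyper(kT - 1, K, N - K, nT, lower.tail = FALSE)
  fold <- ((kT + 0.5) / (nT + 1)) / ((kB + 0.5) / (nB + 1))
  list(motif_id = pwm@id, n_target = nT, k_target = kT,
       n_background = nB, k_background = kB,
       fold_enrichment = fold, p_hyper = p, threshold = threshold)
}
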