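## Peak set algebra: union-merge, replicate consensus, shared/unique
## (Venn) classification, size statistics, genomic-context annotation.

#' Union-merge intervals that share at least one base
#'
#' Overlap of >= 1 bp is required to merge; intervals that are merely
#' adjacent (end of one equals start of the next in half-open coordinates)
#' stay separate.
#'
#' @param gr A `GRanges`.
#' @return A sorted disjoint `GRanges`.
#' @export
mergePeaks <- function(gr) {
  GenomicRanges::reduce(gr, min.gapwidth = 0L, ignore.strand = TRUE)
}

#' Build a replicate-supported consensus peak set for one group
#'
#' All samples' peaks are union-merged; a merged region is retained when
#' peaks from at least `minSamples` distinct samples overlap it. The number
#' of supporting samples is recorded per region.
#'
#' @param samplePeaks A named list of `GRanges`, one per replicate sample.
#' @param minSamples Minimum number of distinct supporting samples
#'   (default 2).
#' @param group Group label.
#' @return A [ConsensusPeakSet-class].
#' @export
buildGroupConsensus <- function(samplePeaks, minSamples = 2L,
                                group = "group") {
  if (length(samplePeaks) < 1L) stop("need at least one sample", call. = FALSE)
  minSamples <- as.integer(minSamples)
  if (minSamples < 1L) stop("minSamples must be >= 1", call. = FALSE)
  if (minSamples > length(samplePeaks))
    stop(sprintf("minSamples (%d) exceeds number of samples (%d)",
                 minSamples, length(samplePeaks)), call. = FALSE)
  merged <- mergePeaks(suppressWarnings(
    do.call(c, unname(lapply(samplePeaks, function(g)
      GRanges(seqnames(g), IRanges(start(g), end(g))))))))
  support <- Reduce(`+`, lapply(samplePeaks, function(g)
    as.integer(countOverlaps(merged, g, minoverlap = 1L,
                             ignore.strand = TRUE) > 0L)))
  keep <- support >= minSamples
  out <- merged[keep]
  out$peak_id <- sprintf("%s_peak_%d", group, seq_along(out))
  out$support <- support[keep]
  new("ConsensusPeakSet", group = group, peaks = out,
      minSamples = minSamples, nSamples = length(samplePeaks))
}

.asPeakGRanges <- function(x) {
  if (is(x, "ConsensusPeakSet")) peaks(x) else x
}

#' Classify the union of two peak sets into shared and unique regions
#'
#' The merged union of both sets is the counting unit: each merged region
#' is labelled `shared` when overlapped by peaks from both inputs, else
#' unique to the input that covers it. The three outputs tile the union
#' exactly.
#'
#' @param a,b [ConsensusPeakSet-class] or `GRanges`.
#' @return A [VennClassification-class].
#' @export
vennClassify <- function(a, b) {
  la <- if (is(a, "ConsensusPeakSet")) a@group else "A"
  lb <- if (is(b, "ConsensusPeakSet")) b@group else "B"
  ga <- .asPeakGRanges(a); gb <- .asPeakGRanges(b)
  un <- mergePeaks(c(GRanges(seqnames(ga), IRanges(start(ga), end(ga))),
                     GRanges(seqnames(gb), IRanges(start(gb), end(gb)))))
  inA <- overlapsAny(un, ga, minoverlap = 1L, ignore.strand = TRUE)
  inB <- overlapsAny(un, gb, minoverlap = 1L, ignore.strand = TRUE)
  new("VennClassification",
      shared = un[inA & inB], uniqueA = un[inA & !inB],
      uniqueB = un[!inA & inB], labels = c(la, lb))
}

#' Venn region counts
#' @param x A [VennClassification-class].
#' @return Named integer vector `(shared, unique_a, unique_b)`.
#' @export
vennCounts <- function(x) {
  c(shared = length(x@shared), unique_a = length(x@uniqueA),
    unique_b = length(x@uniqueB))
}

#' Summary statistics of peak widths
#'
#' @param x A `GRanges` or [ConsensusPeakSet-class].
#' @return Named numeric vector: `n`, `mean`, `median`, `q25`, `q75` of
#'   the peak widths in bp.
#' @export
peakSizeSummary <- function(x) {
  gr <- .asPeakGRanges(x)
  if (length(gr) == 0L) stop("empty peak set", call. = FALSE)
  w <- width(gr)
  q <- stats::quantile(w, c(0.25, 0.5, 0.75), names = FALSE)
  c(n = length(w), mean = mean(w), median = q[2], q25 = q[1], q75 = q[3])
}

.signedTssDist <- function(pos0, tss0, strand) {
  ifelse(strand == "+", pos0 - tss0, tss0 - pos0)
}

#' Annotate peaks by genomic context
#'
#' Each peak is classified at a single anchor position (its midpoint, or
#' the summit when present and `anchor = "summit"`) with precedence
#' promoter > TTS > exon > intron > intergenic. The promoter is
#' `[tss - promoterUp, tss + promoterDown)` in transcription orientation;
#' the TTS window is `+/- ttsWindow` around the transcription end. The
#' reported gene is the nearest (by absolute signed TSS distance) among
#' genes compatible with the assigned class; ties break to the
#' lexicographically smaller `gene_id`.
#'
#' @param x Peaks as `GRanges` (with `peak_id` metadata) or a
#'   [ConsensusPeakSet-class].
#' @param geneModels A [GeneModels-class].
#' @param promoterUp,promoterDown Promoter window in bp upstream /
#'   downstream of the TSS (defaults 1000 / 100).
#' @param ttsWindow Half-width of the TTS window in bp (default 100).
#' @param anchor `"midpoint"` (default) or `"summit"` (falls back to the
#'   midpoint when no summit is recorded).
#' @return A data.frame with columns `peak_id`, `class`,
#'   `nearest_gene_id`, `dist_to_tss` (signed bp; negative = upstream in
#'   transcription orientation).
#' @export
annotatePeaks <- function(x, geneModels, promoterUp = 1000L,
                          promoterDown = 100L, ttsWindow = 100L,
                          anchor = c("midpoint", "summit")) {
  anchor <- match.arg(anchor)
  gr <- .asPeakGRanges(x)
  ids <- if (!is.null(gr$peak_id)) gr$peak_id else
    if (!is.null(gr$name)) gr$name else sprintf("peak_%d", seq_along(gr))
  g <- genes(geneModels)
  exl <- exons(geneModels)
  # 0-based anchor position: midpoint of the half-open interval
  pos0 <- (start(gr) - 1L + end(gr)) %/% 2L
  if (anchor == "summit" && !is.null(gr$summit_offset)) {
    s <- gr$summit_offset
    pos0 <- ifelse(is.na(s), pos0, start(gr) - 1L + s)
  }
  gch <- as.character(seqnames(g))
  gstr <- as.character(strand(g))
  tss0 <- g$tss - 1L
  tts0 <- ifelse(gstr == "+", end(g) - 1L, start(g) - 1L)
  pch <- as.character(seqnames(gr))

  n <- length(gr)
  cls <- character(n); ngene <- rep(NA_character_, n)
  dist <- rep(NA_integer_, n)
  exonHit <- function(gid, chrom, p1) {
    if (!gid %in% names(exl)) return(FALSE)
    ex <- exl[[gid]]
    any(as.character(seqnames(ex)) == chrom & start(ex) <= p1 & end(ex) >= p1)
  }
  for (i in seq_len(n)) {
    same <- which(gch == pch[i])
    if (length(same) == 0L) { cls[i] <- "intergenic"; next }
    d <- .signedTssDist(pos0[i], tss0[same], gstr[same])
    dt <- .signedTssDist(pos0[i], tts0[same], gstr[same])
    p1 <- pos0[i] + 1L
    inProm <- d >= -promoterUp & d < promoterDown
    inTts <- abs(dt) <= ttsWindow
    inBody <- start(g)[same] <= p1 & end(g)[same] >= p1
    pick <- function(idx) {
      o <- idx[order(abs(d[idx]), g$gene_id[same][idx])][1]
      ngene[i] <<- g$gene_id[same][o]
      dist[i] <<- d[o]
    }
    if (any(inProm)) { cls[i] <- "promoter"; pick(which(inProm)) }
    else if (any(inTts)) { cls[i] <- "tts"; pick(which(inTts)) }
    else if (any(inBody)) {
      inEx <- vapply(which(inBody), function(k)
        exonHit(g$gene_id[same][k], pch[i], p1), logical(1))
      if (any(inEx)) { cls[i] <- "exon"; pick(which(inBody)[inEx]) }
      else { cls[i] <- "intron"; pick(which(inBody)) }
    } else { cls[i] <- "intergenic"; pick(seq_along(same)) }
  }
  data.frame(peak_id = ids, class = cls, nearest_gene_id = ngene,
             dist_to_tss = dist, stringsAsFactors = FALSE)
}
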