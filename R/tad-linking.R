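## TAD-constrained peak-to-gene linking: anchor assignment, within-TAD
## pair enumeration, Pearson correlation with t-based p-values, signed
## link classification and annotation-class summaries.

#' Assign anchor positions to TADs
#'
#' An element is assigned to the unique TAD containing its anchor (the
#' peak midpoint or the gene TSS); anchors on no TAD stay unassigned. In
#' the file convention TADs are half-open, so an anchor exactly on a
#' shared boundary belongs to the downstream TAD.
#'
#' @param ids Element identifiers.
#' @param chrom Chromosome per element.
#' @param pos0 0-based anchor position per element.
#' @param tadPartition A [TadPartition-class].
#' @param kind `"peak"` or `"gene"` (recorded in the output).
#' @return data.frame with columns `element_id`, `kind`, `tad_id` (`NA`
#'   when unassigned), `anchor` (0-based bp).
#' @export
assignToTads <- function(ids, chrom, pos0, tadPartition,
                         kind = c("peak", "gene")) {
  kind <- match.arg(kind)
  td <- tads(tadPartition)
  anchors <- GRanges(chrom, IRanges(pos0 + 1L, pos0 + 1L))
  hit <- findOverlaps(anchors, td, ignore.strand = TRUE)
  tad_id <- rep(NA_character_, length(ids))
  tad_id[queryHits(hit)] <- td$tad_id[subjectHits(hit)]
  data.frame(element_id = ids, kind = kind, tad_id = tad_id,
             anchor = pos0, stringsAsFactors = FALSE)
}

#' Assign peaks to TADs by their midpoint
#'
#' @param x Peaks as `GRanges` (metadata `peak_id`) or a
#'   [ConsensusPeakSet-class].
#' @param tadPartition A [TadPartition-class].
#' @return See [assignToTads()].
#' @export
assignPeaksToTads <- function(x, tadPartition) {
  gr <- .asPeakGRanges(x)
  ids <- if (!is.null(gr$peak_id)) gr$peak_id else
    if (!is.null(gr$name)) gr$name else sprintf("peak_%d", seq_along(gr))
  mid0 <- (start(gr) - 1L + end(gr)) %/% 2L
  assignToTads(ids, as.character(seqnames(gr)), mid0, tadPartition, "peak")
}

#' Assign genes to TADs by their TSS
#'
#' @param geneModels A [GeneModels-class].
#' @param tadPartition A [TadPartition-class].
#' @return See [assignToTads()].
#' @export
assignGenesToTads <- function(geneModels, tadPartition) {
  g <- genes(geneModels)
  assignToTads(g$gene_id, as.character(seqnames(g)), g$tss - 1L,
               tadPartition, "gene")
}

#' Enumerate within-TAD peak-gene pairs
#'
#' The Cartesian product of assigned peaks and assigned genes inside each
#' TAD; no pair crosses a TAD boundary. Output order is deterministic:
#' by TAD, then peak, then gene.
#'
#' @param peakAssign,geneAssign data.frames from [assignPeaksToTads()] /
#'   [assignGenesToTads()].
#' @return data.frame with columns `tad_id`, `peak_id`, `gene_id`.
#' @export
enumerateTadPairs <- function(peakAssign, geneAssign) {
  pk <- peakAssign[!is.na(peakAssign$tad_id), ]
  gn <- geneAssign[!is.na(geneAssign$tad_id), ]
  shared <- sort(intersect(unique(pk$tad_id), unique(gn$tad_id)))
  out <- lapply(shared, function(td) {
    p <- sort(pk$element_id[pk$tad_id == td])
    g <- sort(gn$element_id[gn$tad_id == td])
    expand.grid(gene_id = g, peak_id = p, stringsAsFactors = FALSE,
                KEEP.OUT.ATTRS = FALSE)[, c("peak_id", "gene_id")]
  })
  if (length(out) == 0L)
    return(data.frame(tad_id = character(0), peak_id = character(0),
                      gene_id = character(0), stringsAsFactors = FALSE))
  n <- vapply(out, nrow, 0L)
  res <- do.call(rbind, out)
  res <- data.frame(tad_id = rep(shared, n), res,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Pearson correlation with t-based p-value for one pair
#'
#' Two-sided p from `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2`
#' degrees of freedom. A numerically perfect correlation (`|r| = 1`) is
#' reported as `p = 0` with `perfect = TRUE` rather than numerical noise;
#' a zero-variance vector yields `r = NA` with a reason code.
#'
#' @param x,y Equal-length numeric vectors (`n >= 3`).
#' @return List with `r`, `p`, `n`, `perfect`, `reason` (`NA` or
#'   `"zero_variance"`).
#' @export
correlatePair <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("vectors must have equal length", call. = FALSE)
  if (n < 3L) stop("need n >= 3 samples", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, perfect = FALSE,
                reason = "zero_variance"))
  r <- stats::cor(x, y)
  if (abs(r) >= 1 - 1e-12)
    return(list(r = sign(r), p = 0, n = n, perfect = TRUE, reason = NA))
  tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, p = 2 * stats::pt(-abs(tval), df = n - 2), n = n,
       perfect = FALSE, reason = NA)
}

#' Correlate within-TAD peak-gene pairs across pooled samples
#'
#' For every enumerated pair, Pearson correlation between the peak's
#' normalized accessibility and the gene's normalized expression across
#' all samples (both groups pooled; no group labels enter). Significance
#' is called on the raw p-value at `alpha` by default, mirroring the
#' raw-p convention of the upstream analysis; `adjust = "BH"` switches to
#' FDR-adjusted calling.
#'
#' @param pairs data.frame from [enumerateTadPairs()].
#' @param atacNorm,rnaNorm [NormalizedCounts-class] or matrices with peak /
#'   gene rownames; columns (samples) must match exactly.
#' @param annotations Optional data.frame from [annotatePeaks()]; copies
#'   the peak's `class` onto each link.
#' @param alpha Significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A [LinkSet-class].
#' @export
linkPeaksGenes <- function(pairs, atacNorm, rnaNorm, annotations = NULL,
                           alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  A <- if (is(atacNorm, "NormalizedCounts")) normValues(atacNorm) else
    as.matrix(atacNorm)
  R <- if (is(rnaNorm, "NormalizedCounts")) normValues(rnaNorm) else
    as.matrix(rnaNorm)
  if (ncol(A) != ncol(R) || !identical(colnames(A), colnames(R)))
    stop("sample mismatch between accessibility and expression matrices",
         call. = FALSE)
  n <- ncol(A)
  if (n < 3L) stop("need >= 3 samples", call. = FALSE)
  miss <- setdiff(pairs$peak_id, rownames(A))
  if (length(miss)) stop("peak absent from matrix: ", miss[1], call. = FALSE)
  miss <- setdiff(pairs$gene_id, rownames(R))
  if (length(miss)) stop("gene absent from matrix: ", miss[1], call. = FALSE)

  X <- A[pairs$peak_id, , drop = FALSE]
  Y <- R[pairs$gene_id, , drop = FALSE]
  sdx <- apply(X, 1, stats::sd)
  sdy <- apply(Y, 1, stats::sd)
  ok <- sdx > 0 & sdy > 0
  dropped <- data.frame(pairs[!ok, , drop = FALSE],
                        reason = rep("zero_variance", sum(!ok)),
                        stringsAsFactors = FALSE)
  lk <- pairs[ok, , drop = FALSE]
  Xs <- (X[ok, , drop = FALSE] - rowMeans(X[ok, , drop = FALSE])) /
    sdx[ok]
  Ys <- (Y[ok, , drop = FALSE] - rowMeans(Y[ok, , drop = FALSE])) /
    sdy[ok]
  r <- rowSums(Xs * Ys) / (n - 1)
  r <- pmin(pmax(r, -1), 1)
  perfect <- abs(r) >= 1 - 1e-12
  tval <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  p <- ifelse(perfect, 0, 2 * stats::pt(-abs(tval), df = n - 2))
  pSig <- if (adjust == "BH") bhAdjust(p) else p
  lk <- data.frame(lk, r = r, p_raw = p, significant = pSig < alpha,
                   sign = ifelse(r > 0, "positive",
                                 ifelse(r < 0, "negative", "zero")),
                   n_samples = n, perfect = perfect,
                   stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    lk$annotation_class <-
      annotations$class[match(lk$peak_id, annotations$peak_id)]
  } else lk$annotation_class <- NA_character_
  rownames(lk) <- NULL
  rownames(dropped) <- NULL
  new("LinkSet", links = lk, dropped = dropped, alpha = alpha,
      adjust = adjust)
}

#' Summarize a link set
#'
#' Counts of tested / significant / positive / negative links plus the
#' annotation-class composition of significant links split by sign; the
#' per-sign proportions each sum to 1.
#'
#' @param x A [LinkSet-class].
#' @return List with `n_tested`, `n_dropped`, `n_significant`,
#'   `n_positive`, `n_negative` and `class_proportions` (data.frame with
#'   `sign`, `class`, `count`, `proportion`).
#' @export
summarizeLinks <- function(x) {
  lk <- links(x)
  sig <- lk[lk$significant, , drop = FALSE]
  props <- do.call(rbind, lapply(split(sig, sig$sign), function(d) {
    tab <- table(factor(d$annotation_class,
                        levels = c("promoter", "tts", "exon", "intron",
                                   "intergenic")))
    data.frame(sign = d$sign[1], class = names(tab),
               count = as.integer(tab),
               proportion = as.integer(tab) / nrow(d),
               stringsAsFactors = FALSE)
  }))
  if (is.null(props))
    props <- data.frame(sign = character(0), class = character(0),
                        count = integer(0), proportion = numeric(0))
  rownames(props) <- NULL
  list(n_tested = nrow(lk), n_dropped = nrow(droppedPairs(x)),
       n_significant = nrow(sig),
       n_positive = sum(sig$sign == "positive"),
       n_negative = sum(sig$sign == "negative"),
       class_proportions = props)
}

#' Upregulated genes supported by a correlated chromatin change
#'
#' Intersects a set of differentially upregulated genes with the genes
#' that have at least one peak link below the correlation-p threshold.
#' The threshold is an explicit parameter (default 0.05).
#'
#' @param x A [LinkSet-class] or its `links()` data.frame.
#' @param deGenes Character vector of differential gene ids.
#' @param corrPThreshold Correlation p threshold (default 0.05).
#' @return Sorted character vector of gene ids.
#' @export
selectCorrelatedDeGenes <- function(x, deGenes, corrPThreshold = 0.05) {
  lk <- if (is(x, "LinkSet")) links(x) else x
  linked <- unique(lk$gene_id[lk$p_raw < corrPThreshold])
  sort(intersect(deGenes, linked))
}
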