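#' @import methods
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width
#'   strand mcols mcols<- reduce findOverlaps countOverlaps sort
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny
#' @importFrom S4Vectors DataFrame queryHits subjectHits metadata metadata<-
#' @importFrom GenomeInfoDb seqlevels seqlevelsInUse seqnames<-
NULL

#' TadPartition: a disjoint set of topologically associating domains
#'
#' Holds the TAD intervals that bound the peak-to-gene correlation search.
#' Within each chromosome the TADs are sorted and pairwise disjoint; the
#' constructor can repair overlapping input calls (public TAD calls often
#' overlap slightly) by truncating both domains at the midpoint of their
#' overlap.
#'
#' @slot tads A [GenomicRanges::GRanges] with a `tad_id` metadata column.
#' @slot nRepaired Number of overlaps repaired on construction.
#' @slot nDropped Number of zero-length domains dropped after repair.
#' @export
setClass("TadPartition",
  slots = c(tads = "GRanges", nRepaired = "integer", nDropped = "integer"))

setValidity("TadPartition", function(object) {
  gr <- object@tads
  if (length(gr) == 0L) return(TRUE)
  if (is.null(gr$tad_id) || anyDuplicated(gr$tad_id))
    return("tads must carry unique 'tad_id' metadata")
  if (!GenomicRanges::isDisjoint(gr))
    return("TADs must be pairwise disjoint within each chromosome")
  TRUE
})

#' GeneModels: gene bodies, TSS positions and exon structure
#'
#' @slot genes A [GenomicRanges::GRanges] of gene bodies with metadata
#'   columns `gene_id` (unique) and `tss` (1-based genomic position of the
#'   transcription start: `start` on `+`, `end` on `-`).
#' @slot exons A [GenomicRanges::GRangesList] named by `gene_id`, exons
#'   sorted and non-overlapping within each gene.
#' @export
setClass("GeneModels", slots = c(genes = "GRanges", exons = "GRangesList"))

setValidity("GeneModels", function(object) {
  g <- object@genes
  if (length(g) == 0L) return(TRUE)
  if (is.null(g$gene_id) || anyDuplicated(g$gene_id))
    return("genes must carry unique 'gene_id'")
  if (is.null(g$tss)) return("genes must carry 'tss'")
  bad <- g$tss < start(g) | g$tss > end(g)
  if (any(bad))
    return(sprintf("tss outside gene body for %s", g$gene_id[which(bad)[1]]))
  if (!all(names(object@exons) %in% g$gene_id))
    return("exon list names must be gene_ids")
  for (id in names(object@exons)) {
    ex <- object@exons[[id]]
    if (length(ex) == 0L) next
    body <- g[g$gene_id == id]
    if (any(start(ex) < start(body)) || any(end(ex) > end(body)))
      return(sprintf("exon outside gene body for %s", id))
    if (!GenomicRanges::isDisjoint(ex))
      return(sprintf("overlapping exons in %s", id))
  }
  TRUE
})

#' ConsensusPeakSet: replicate-supported consensus peaks for one group
#'
#' A merged, disjoint peak set in which every region is overlapped by peaks
#' from at least `minSamples` distinct replicate samples.
#'
#' @slot group Group label.
#' @slot peaks Sorted disjoint [GenomicRanges::GRanges] with `peak_id` and
#'   `support` (number of contributing samples) metadata.
#' @slot minSamples Minimum per-region sample support enforced.
#' @slot nSamples Number of replicate samples supplied.
#' @export
setClass("ConsensusPeakSet",
  slots = c(group = "character", peaks = "GRanges",
            minSamples = "integer", nSamples = "integer"))

setValidity("ConsensusPeakSet", function(object) {
  gr <- object@peaks
  if (length(gr) == 0L) return(TRUE)
  if (is.null(gr$support)) return("peaks must carry 'support'")
  if (any(gr$support < object@minSamples))
    return("support below minSamples")
  if (any(gr$support > object@nSamples))
    return("support exceeds number of samples")
  if (!GenomicRanges::isDisjoint(gr)) return("consensus peaks must be disjoint")
  if (is.unsorted(order(as.factor(seqnames(gr)), start(gr))))
    return("consensus peaks must be sorted")
  TRUE
})

#' VennClassification: shared and group-unique regions of two peak sets
#'
#' The merged union of two consensus sets partitioned into regions
#' overlapped by both sets (`shared`), only the first (`uniqueA`) or only
#' the second (`uniqueB`). The counting unit is the merged region of the
#' union, so a shared region is counted once.
#'
#' @slot shared,uniqueA,uniqueB Disjoint [GenomicRanges::GRanges].
#' @slot labels Labels of the two input groups.
#' @export
setClass("VennClassification",
  slots = c(shared = "GRanges", uniqueA = "GRanges", uniqueB = "GRanges",
            labels = "character"))

#' NormalizedCounts: variance-stabilized count matrix
#'
#' @slot values Numeric matrix, same shape as the input counts.
#' @slot sizeFactors Per-sample positive size factors (geometric mean 1).
#' @slot method `"log2p1"` or `"asinh_nb"`.
#' @slot dispersion Common dispersion used by `asinh_nb` (NA for log2p1).
#' @export
setClass("NormalizedCounts",
  slots = c(values = "matrix", sizeFactors = "numeric",
            method = "character", dispersion = "numeric"))

setValidity("NormalizedCounts", function(object) {
  if (any(object@sizeFactors <= 0)) return("size factors must be positive")
  if (length(object@sizeFactors) != ncol(object@values))
    return("one size factor per sample required")
  TRUE
})

#' PWMotif: position weight matrix with background model
#'
#' Column-stochastic base probabilities plus a background composition; the
#' log-odds matrix `log2(prob / background)` is derived on construction and
#' scores are in bits.
#'
#' @slot id,name Identifier and display name.
#' @slot probs 4 x L probability matrix, rows A, C, G, T.
#' @slot background Length-4 background base frequencies summing to 1.
#' @slot logOdds Derived 4 x L log2-odds matrix.
#' @export
setClass("PWMotif",
  slots = c(id = "character", name = "character", probs = "matrix",
            background = "numeric", logOdds = "matrix"))

setValidity("PWMotif", function(object) {
  p <- object@probs
  if (nrow(p) != 4L || ncol(p) < 1L) return("probs must be 4 x L with L >= 1")
  if (any(abs(colSums(p) - 1) > 1e-9)) return("probs columns must sum to 1")
  if (length(object@background) != 4L ||
      abs(sum(object@background) - 1) > 1e-9)
    return("background must be 4 frequencies summing to 1")
  if (any(object@background <= 0)) return("background must be positive")
  TRUE
})

#' LinkSet: TAD-constrained peak-to-gene correlation links
#'
#' One row per testable within-TAD peak-gene pair with Pearson r, the
#' t-based two-sided p, significance at the configured alpha, the sign of
#' the association, and the peak's genomic-context class when annotations
#' were supplied. Pairs whose peak or gene has zero variance across samples
#' are recorded in `dropped` with a reason code.
#'
#' @slot links data.frame with columns peak_id, gene_id, tad_id, r, p_raw,
#'   significant, sign, annotation_class, n_samples, perfect.
#' @slot dropped data.frame with columns peak_id, gene_id, tad_id, reason.
#' @slot alpha Significance level applied.
#' @slot adjust `"none"` (raw p, the default) or `"BH"`.
#' @export
setClass("LinkSet",
  slots = c(links = "data.frame", dropped = "data.frame",
            alpha = "numeric", adjust = "character"))

setValidity("LinkSet", function(object) {
  lk <- object@links
  need <- c("peak_id", "gene_id", "tad_id", "r", "p_raw", "significant",
            "sign", "n_samples")
  if (nrow(lk) && !all(need %in% names(lk)))
    return("links is missing required columns")
  if (nrow(lk)) {
    if (any(abs(lk$r) > 1 + 1e-12)) return("|r| must be <= 1")
    if (any(lk$p_raw < 0 | lk$p_raw > 1)) return("p_raw must lie in [0,1]")
    if (any(lk$sign[lk$r > 0] != "positive") ||
        any(lk$sign[lk$r < 0] != "negative"))
      return("sign must follow the sign of r")
  }
  TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "TadPartition", function(object) {
  cat(sprintf("TadPartition with %d TADs on %d chromosome(s)\n",
              length(object@tads),
              length(seqlevelsInUse(object@tads))))
  if (object@nRepaired > 0L || object@nDropped > 0L)
    cat(sprintf("  input repair: %d overlap(s) truncated, %d dropped\n",
                object@nRepaired, object@nDropped))
})

setMethod("show", "GeneModels", function(object) {
  cat(sprintf("GeneModels with %d genes (%d with exon structure)\n",
              length(object@genes), length(object@exons)))
})

setMethod("show", "ConsensusPeakSet", function(object) {
  cat(sprintf(
    "ConsensusPeakSet '%s': %d peaks from %d samples (minSamples = %d)\n",
    object@group, length(object@peaks), object@nSamples, object@minSamples))
})

setMethod("show", "VennClassification", function(object) {
  cat(sprintf("VennClassification [%s | %s]\n",
              object@labels[1], object@labels[2]))
  cat(sprintf("  shared: %d  unique %s: %d  unique %s: %d\n",
              length(object@shared), object@labels[1], length(object@uniqueA),
              object@labels[2], length(object@uniqueB)))
})

setMethod("show", "NormalizedCounts", function(object) {
  cat(sprintf("NormalizedCounts (%s): %d features x %d samples\n",
              object@method, nrow(object@values), ncol(object@values)))
})

setMethod("show", "PWMotif", function(object) {
  cat(sprintf("PWMotif %s (%s), length %d, max score %.2f bits\n",
              object@id, object@name, ncol(object@probs),
              sum(apply(object@logOdds, 2, max))))
})

setMethod("show", "LinkSet", function(object) {
  lk <- object@links
  cat(sprintf(
    "LinkSet: %d pairs tested (%d dropped), %d significant at %s p < %g\n",
    nrow(lk), nrow(object@dropped), sum(lk$significant),
    if (object@adjust == "BH") "BH-adjusted" else "raw", object@alpha))
  if (nrow(lk))
    cat(sprintf("  positive: %d  negative: %d\n",
                sum(lk$significant & lk$sign == "positive"),
                sum(lk$significant & lk$sign == "negative")))
})

## ---- accessors ----------------------------------------------------------

#' Accessors for tadlink S4 containers
#'
#' @param x A tadlink S4 object.
#' @return `tads()`, `genes()`, `peaks()` return `GRanges`; `exons()` a
#'   `GRangesList`; `links()` and `droppedPairs()` data.frames; `values()`
#'   a numeric matrix; `sizeFactors()` a numeric vector; `logOdds()` and
#'   `probs()` matrices.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("tads", function(x) standardGeneric("tads"))
#' @rdname accessors
#' @export
setMethod("tads", "TadPartition", function(x) x@tads)

#' @rdname accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @rdname accessors
#' @export
setMethod("genes", "GeneModels", function(x) x@genes)

#' @rdname accessors
#' @export
setGeneric("exons", function(x) standardGeneric("exons"))
#' @rdname accessors
#' @export
setMethod("exons", "GeneModels", function(x) x@exons)

#' @rdname accessors
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))
#' @rdname accessors
#' @export
setMethod("peaks", "ConsensusPeakSet", function(x) x@peaks)

#' @rdname accessors
#' @export
setGeneric("links", function(x) standardGeneric("links"))
#' @rdname accessors
#' @export
setMethod("links", "LinkSet", function(x) x@links)

#' @rdname accessors
#' @export
setGeneric("droppedPairs", function(x) standardGeneric("droppedPairs"))
#' @rdname accessors
#' @export
setMethod("droppedPairs", "LinkSet", function(x) x@dropped)

#' @rdname accessors
#' @export
setGeneric("normValues", function(x) standardGeneric("normValues"))
#' @rdname accessors
#' @export
setMethod("normValues", "NormalizedCounts", function(x) x@values)

#' @rdname accessors
#' @importFrom BiocGenerics sizeFactors
#' @export
setMethod("sizeFactors", "NormalizedCounts", function(object) object@sizeFactors)

#' @rdname accessors
#' @export
setGeneric("probs", function(x) standardGeneric("probs"))
#' @rdname accessors
#' @export
setMethod("probs", "PWMotif", function(x) x@probs)

#' @rdname accessors
#' @export
setGeneric("logOdds", function(x) standardGeneric("logOdds"))
#' @rdname accessors
#' @export
setMethod("logOdds", "PWMotif", function(x) x@logOdds)
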