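## Readers and writers for the standard formats the pipeline touches.
## Files use their native conventions (BED 0-based half-open, GTF 1-based
## closed); everything is converted to GRanges (1-based closed) on ingest
## and converted back on write, so reader/writer pairs round-trip exactly.

.bedCols <- list(bed3 = 3L, bed6 = 6L, narrowpeak = 10L)

.readTsvLines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines[nzchar(lines) & !startsWith(lines, "#") &
          !startsWith(lines, "track") & !startsWith(lines, "browser")]
}

.checkInt <- function(x, what, lineno) {
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v)) || any(v != floor(v)))
    stop(sprintf("line %d: non-integer %s '%s'", lineno[which(is.na(v) | v != floor(v))[1]],
                 what, x[which(is.na(v) | v != floor(v))[1]]), call. = FALSE)
  as.integer(v)
}

#' Read peak or interval files (BED3, BED6, ENCODE narrowPeak)
#'
#' Coordinates in the file are 0-based half-open (BED convention) and are
#' converted to 1-based closed `GRanges`. For narrowPeak the 10th column
#' (summit offset from the region start, `-1` meaning absent) is stored in
#' the `summit_offset` metadata column (`NA` when absent).
#'
#' @param path Path to the file.
#' @param dialect One of `"bed3"`, `"bed6"`, `"narrowpeak"`.
#' @param sample Optional sample-of-origin label stored in `mcols()$sample`.
#' @return A `GRanges` with metadata columns `name` (bed6/narrowpeak),
#'   `score`, `summit_offset` (narrowpeak) and `sample`.
#' @export
readPeaks <- function(path, dialect = c("narrowpeak", "bed6", "bed3"),
                      sample = NA_character_) {
  dialect <- match.arg(dialect)
  need <- .bedCols[[dialect]]
  lines <- .readTsvLines(path)
  if (length(lines) == 0L)
    return(GRanges(sample = character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < need))
    stop(sprintf("line %d: expected >= %d columns for %s, found %d",
                 which(nf < need)[1], need, dialect, nf[which(nf < need)[1]]),
         call. = FALSE)
  lineno <- seq_along(fields)
  chrom <- vapply(fields, `[[`, "", 1L)
  if (any(grepl("\\s", chrom)))
    stop(sprintf("line %d: chromosome name contains whitespace",
                 which(grepl("\\s", chrom))[1]), call. = FALSE)
  start0 <- .checkInt(vapply(fields, `[[`, "", 2L), "start", lineno)
  end0 <- .checkInt(vapply(fields, `[[`, "", 3L), "end", lineno)
  if (any(start0 < 0))
    stop(sprintf("line %d: negative start", which(start0 < 0)[1]), call. = FALSE)
  if (any(end0 <= start0))
    stop(sprintf("line %d: end <= start", which(end0 <= start0)[1]),
         call. = FALSE)
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0))
  if (dialect %in% c("bed6", "narrowpeak")) {
    gr$name <- vapply(fields, `[[`, "", 4L)
    gr$score <- as.numeric(vapply(fields, `[[`, "", 5L))
    gr$bed_strand <- vapply(fields, `[[`, "", 6L)
  }
  if (dialect == "narrowpeak") {
    gr$signalValue <- as.numeric(vapply(fields, `[[`, "", 7L))
    gr$pValue <- as.numeric(vapply(fields, `[[`, "", 8L))
    gr$qValue <- as.numeric(vapply(fields, `[[`, "", 9L))
    summit <- .checkInt(vapply(fields, `[[`, "", 10L), "summit", lineno)
    bad <- summit != -1L & (summit < 0L | summit >= width(gr))
    if (any(bad))
      stop(sprintf("line %d: summit offset outside peak", which(bad)[1]),
           call. = FALSE)
    gr$summit_offset <- ifelse(summit == -1L, NA_integer_, summit)
  }
  gr$sample <- sample
  gr
}

#' Write peaks in a BED dialect
#'
#' Inverse of [readPeaks()]: `GRanges` are converted back to 0-based
#' half-open coordinates.
#'
#' @param gr A `GRanges`, typically from [readPeaks()].
#' @param path Output path.
#' @param dialect One of `"bed3"`, `"bed6"`, `"narrowpeak"`.
#' @return `path`, invisibly.
#' @export
writePeaks <- function(gr, path, dialect = c("narrowpeak", "bed6", "bed3")) {
  dialect <- match.arg(dialect)
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  if (dialect %in% c("bed6", "narrowpeak")) {
    df$name <- if (!is.null(gr$name)) gr$name else
      sprintf("peak_%d", seq_along(gr))
    df$score <- if (!is.null(gr$score)) gr$score else 0
    df$strand <- if (!is.null(gr$bed_strand)) gr$bed_strand else "."
  }
  if (dialect == "narrowpeak") {
    df$signalValue <- if (!is.null(gr$signalValue)) gr$signalValue else 0
    df$pValue <- if (!is.null(gr$pValue)) gr$pValue else -1
    df$qValue <- if (!is.null(gr$qValue)) gr$qValue else -1
    summit <- if (!is.null(gr$summit_offset)) gr$summit_offset else
      rep(NA_integer_, length(gr))
    df$peak <- ifelse(is.na(summit), -1L, summit)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a TadPartition, repairing overlapping input domains
#'
#' Public TAD calls can overlap slightly; because the linking step treats
#' TADs as disjoint search boundaries, overlapping neighbours are truncated
#' at the midpoint of their overlap and domains that become empty are
#' dropped. Repairs are counted on the object.
#'
#' @param gr A `GRanges` of TADs; a `tad_id` metadata column is added when
#'   absent.
#' @param repair Repair overlaps (default `TRUE`); with `repair = FALSE`
#'   overlapping input is an error.
#' @return A [TadPartition-class].
#' @export
TadPartition <- function(gr, repair = TRUE) {
  if (is.null(gr$tad_id)) gr$tad_id <- sprintf("tad_%d", seq_along(gr))
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  nRep <- 0L; nDrop <- 0L
  if (!GenomicRanges::isDisjoint(gr)) {
    if (!repair) stop("input TADs overlap and repair = FALSE", call. = FALSE)
    chs <- as.character(seqnames(gr))
    for (ch in unique(chs)) {
      idx <- which(chs == ch)
      for (k in seq_along(idx)[-1]) {
        i <- idx[k - 1L]; j <- idx[k]
        if (start(gr)[j] <= end(gr)[i]) {
          mid <- (start(gr)[j] + end(gr)[i]) %/% 2L
          end(gr)[i] <- mid
          start(gr)[j] <- mid + 1L
          nRep <- nRep + 1L
        }
      }
    }
    drop <- width(gr) < 1L
    nDrop <- sum(drop)
    gr <- gr[!drop]
  }
  new("TadPartition", tads = gr, nRepaired = nRep, nDropped = nDrop)
}

#' Read a TAD partition from a BED file
#'
#' BED3 or BED6-style input; the name column, when present, becomes
#' `tad_id`. Overlapping domains are repaired per [TadPartition()].
#'
#' @inheritParams TadPartition
#' @param path Path to the BED file.
#' @return A [TadPartition-class].
#' @export
readTads <- function(path, repair = TRUE) {
  gr <- readPeaks(path, "bed3")
  lines <- .readTsvLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  tad_id <- if (length(fields) && all(lengths(fields) >= 4L))
    vapply(fields, `[[`, "", 4L) else sprintf("tad_%d", seq_along(gr))
  out <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)), tad_id = tad_id)
  TadPartition(out, repair = repair)
}

#' Write a TAD partition as BED
#' @param tp A [TadPartition-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTads <- function(tp, path) {
  gr <- tads(tp)
  df <- data.frame(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                   gr$tad_id)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from a GTF subset
#'
#' Consumes `gene` and `exon` features with a `gene_id` attribute (the
#' Gencode-style subset the pipeline needs). GTF 1-based closed coordinates
#' map directly onto `GRanges`; the TSS is `start` for `+` genes and `end`
#' for `-` genes.
#'
#' @param path Path to the GTF file.
#' @return A [GeneModels-class].
#' @export
readGeneModels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gtf")
  if (is.null(gr$type)) stop("GTF has no feature type column", call. = FALSE)
  gg <- gr[gr$type == "gene"]
  ee <- gr[gr$type == "exon"]
  if (length(gg) == 0L) stop("no 'gene' features in ", path, call. = FALSE)
  if (is.null(gg$gene_id) || any(is.na(gg$gene_id)) || any(gg$gene_id == ""))
    stop("gene feature missing gene_id attribute", call. = FALSE)
  if (length(ee) && (is.null(ee$gene_id) || any(is.na(ee$gene_id))))
    stop("exon feature missing gene_id attribute", call. = FALSE)
  if (!all(as.character(strand(gg)) %in% c("+", "-")))
    stop("gene strand must be + or -", call. = FALSE)
  tss <- ifelse(as.character(strand(gg)) == "+", start(gg), end(gg))
  genes <- GRanges(seqnames(gg), IRanges(start(gg), end(gg)),
                   strand = strand(gg), gene_id = gg$gene_id, tss = tss)
  exl <- GRangesList()
  if (length(ee)) {
    if (!all(ee$gene_id %in% genes$gene_id))
      stop("exon with unknown gene_id: ",
           setdiff(ee$gene_id, genes$gene_id)[1], call. = FALSE)
    ee <- GenomicRanges::sort(ee, ignore.strand = TRUE)
    # exon groups follow the gene order so write/read cycles are stable
    exl <- GenomicRanges::split(
      GRanges(seqnames(ee), IRanges(start(ee), end(ee)), strand = strand(ee)),
      factor(ee$gene_id,
             levels = intersect(genes$gene_id, unique(ee$gene_id))))
  }
  gm <- new("GeneModels", genes = genes, exons = exl)
  validObject(gm)
  gm
}

#' Write gene models as GTF
#'
#' Inverse of [readGeneModels()]; printed coordinates are 1-based closed.
#'
#' @param gm A [GeneModels-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGeneModels <- function(gm, path) {
  g <- genes(gm)
  rows <- sprintf(
    "%s\ttadlink\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
    as.character(seqnames(g)), start(g), end(g), as.character(strand(g)),
    g$gene_id)
  exl <- exons(gm)
  for (id in names(exl)) {
    ex <- exl[[id]]
    if (length(ex) == 0L) next
    rows <- c(rows, sprintf(
      "%s\ttadlink\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
      as.character(seqnames(ex)), start(ex), end(ex),
      as.character(strand(ex)), id))
  }
  writeLines(rows, path)
  invisible(path)
}

#' Read a feature x sample count table
#'
#' TSV with feature ids in the first column and sample ids in the header;
#' all cells must be non-negative integers.
#'
#' @param path Path to the TSV file.
#' @return An integer matrix with feature rownames and sample colnames.
#' @export
readCounts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no features in ", path, call. = FALSE)
  if (ncol(df) < 2L) stop("no sample columns in ", path, call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate feature id: ", ids[duplicated(ids)][1], call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m)))
  bad <- which(is.na(num) | num < 0 | num != floor(num), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid count at row %d (feature '%s'), column '%s'",
                 bad[1, 1], ids[bad[1, 1]], colnames(m)[bad[1, 2]]),
         call. = FALSE)
  storage.mode(num) <- "integer"
  dimnames(num) <- list(ids, colnames(m))
  num
}

#' Write a count matrix as TSV
#' @param counts Integer matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeCounts <- function(counts, path) {
  df <- data.frame(feature_id = rownames(counts), counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundle counts and group labels into a SummarizedExperiment
#'
#' @param counts Integer feature x sample matrix.
#' @param group Per-sample group labels (length `ncol(counts)`).
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"counts"` and `colData(x)$group`.
#' @export
countsExperiment <- function(counts, group) {
  if (length(group) != ncol(counts))
    stop("one group label per sample required", call. = FALSE)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(group = factor(group), row.names = colnames(counts)))
}

#' Read a genome (or any sequence set) from FASTA
#'
#' Sequences are uppercased on ingest; only A/C/G/T/N are permitted.
#'
#' @param path Path to an uncompressed FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
readGenomeFasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (any(Biostrings::width(ss) == 0L))
    stop("zero-length sequence in ", path, call. = FALSE)
  ss <- Biostrings::DNAStringSet(toupper(as.character(ss)))
  freq <- Biostrings::alphabetFrequency(ss)
  extra <- rowSums(freq) - rowSums(freq[, c("A", "C", "G", "T", "N"),
                                       drop = FALSE])
  if (any(extra > 0))
    stop("sequence contains letters outside A/C/G/T/N: ",
         names(ss)[which(extra > 0)[1]], call. = FALSE)
  names(ss) <- sub("\\s.*$", "", names(ss))
  ss
}

#' Extract sequences under genomic regions
#'
#' @param genome A `DNAStringSet` keyed by chromosome name.
#' @param gr Regions to extract; metadata column `peak_id` or `name`, when
#'   present, names the output.
#' @return A `DNAStringSet` of region sequences (plus strand).
#' @export
extractSequences <- function(genome, gr) {
  ch <- as.character(seqnames(gr))
  missing <- setdiff(unique(ch), names(genome))
  if (length(missing))
    stop("chromosome absent from genome: ", missing[1], call. = FALSE)
  out <- Biostrings::DNAStringSet(vapply(seq_along(gr), function(i) {
    as.character(Biostrings::subseq(genome[[ch[i]]], start(gr)[i], end(gr)[i]))
  }, character(1)))
  nm <- if (!is.null(gr$peak_id)) gr$peak_id else
    if (!is.null(gr$name)) gr$name else sprintf("region_%d", seq_along(gr))
  names(out) <- nm
  out
}

## ---- JASPAR PFM text ----------------------------------------------------
## No JASPAR parser ships with the installed stack, so the 2016+ text
## format (">ID name" header, four bracketed count rows A/C/G/T) is read
## directly.

#' Construct a PWMotif from a count or probability matrix
#'
#' Counts are converted to column-stochastic probabilities after adding a
#' pseudocount split across bases by background frequency (Homer-style):
#' each column gains a total of `4 * pseudocount`, distributed as
#' `4 * pseudocount * bg_i` per base, so with a uniform background every
#' cell gains `pseudocount`:
#' `(count_ij + 4 * pseudocount * bg_i) / (colsum_j + 4 * pseudocount)`.
#'
#' @param counts 4 x L numeric matrix (rows A, C, G, T).
#' @param id,name Identifier and display name.
#' @param pseudocount Total pseudocount added per column (default 0.8).
#' @param background Background base frequencies (default uniform).
#' @return A [PWMotif-class].
#' @export
PWMotif <- function(counts, id = "pwm", name = id, pseudocount = 0.8,
                    background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("PWM needs 4 rows (A,C,G,T)", call. = FALSE)
  if (any(counts < 0)) stop("negative PWM counts", call. = FALSE)
  cs <- colSums(counts)
  if (any(cs + pseudocount <= 0))
    stop("all-zero PWM column with zero pseudocount", call. = FALSE)
  probs <- sweep(counts + 4 * pseudocount * background, 2,
                 cs + 4 * pseudocount, "/")
  rownames(probs) <- c("A", "C", "G", "T")
  lo <- log2(probs / background)
  new("PWMotif", id = id, name = name, probs = probs,
      background = background, logOdds = lo)
}

#' Read position frequency matrices in JASPAR text format
#'
#' @param path Path to a JASPAR 2016+ PFM text file (possibly multiple
#'   records).
#' @inheritParams PWMotif
#' @return A named list of [PWMotif-class] objects.
#' @export
readJaspar <- function(path, pseudocount = 0.8, background = rep(0.25, 4)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- which(startsWith(lines, ">"))
  if (length(starts) == 0L) stop("no JASPAR records in ", path, call. = FALSE)
  out <- list()
  for (k in seq_along(starts)) {
    i0 <- starts[k]
    i1 <- if (k < length(starts)) starts[k + 1] - 1L else length(lines)
    hdr <- strsplit(sub("^>", "", lines[i0]), "\\s+")[[1]]
    id <- hdr[1]
    name <- if (length(hdr) > 1) paste(hdr[-1], collapse = " ") else id
    body <- lines[(i0 + 1L):i1]
    if (length(body) != 4L)
      stop(sprintf("record %s: expected 4 base rows, found %d", id,
                   length(body)), call. = FALSE)
    bases <- toupper(sub("^([ACGTacgt]).*", "\\1", body))
    if (!setequal(bases, c("A", "C", "G", "T")))
      stop(sprintf("record %s: missing base row (need A,C,G,T)", id),
           call. = FALSE)
    rows <- lapply(body, function(b) {
      s <- sub("^[ACGTacgt]", "", b)
      as.numeric(regmatches(s, gregexpr("[0-9][0-9.eE+-]*", s))[[1]])
    })
    if (length(unique(lengths(rows))) != 1L)
      stop(sprintf("record %s: rows of unequal length", id), call. = FALSE)
    m <- do.call(rbind, rows)[order(match(bases, c("A", "C", "G", "T"))), ,
                              drop = FALSE]
    if (pseudocount == 0 && any(colSums(m) == 0))
      stop(sprintf("record %s: all-zero column", id), call. = FALSE)
    out[[id]] <- PWMotif(m, id = id, name = name, pseudocount = pseudocount,
                         background = background)
  }
  out
}

#' Write count matrices in JASPAR text format
#'
#' @param pwms A list of 4 x L count matrices (or [PWMotif-class] objects,
#'   in which case probabilities scaled by 100 are written).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeJaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(pwms)) {
    x <- pwms[[id]]
    m <- if (is(x, "PWMotif")) round(probs(x) * 100, 4) else as.matrix(x)
    nm <- if (is(x, "PWMotif")) x@name else id
    writeLines(sprintf(">%s %s", id, nm), con)
    for (i in 1:4)
      writeLines(sprintf("%s  [ %s ]", c("A", "C", "G", "T")[i],
                         paste(format(m[i, ], trim = TRUE), collapse = " ")),
                 con)
  }
  invisible(path)
}

#' Check chromosome-name consistency across inputs
#'
#' Chromosome naming must match exactly across files ("chr1" vs "1" is a
#' common dialect mismatch). Optionally harmonizes by adding or stripping
#' the "chr" prefix before comparing.
#'
#' @param ... Named objects: `GRanges`, [TadPartition-class],
#'   [GeneModels-class] or `DNAStringSet`.
#' @param harmonize Apply "chr"-prefix harmonization (`"none"`, `"add"`,
#'   `"strip"`).
#' @return Invisibly, a list with per-input chromosome sets and the common
#'   intersection; warns on inputs with private chromosomes.
#' @export
validateChromosomes <- function(..., harmonize = c("none", "add", "strip")) {
  harmonize <- match.arg(harmonize)
  inputs <- list(...)
  getChroms <- function(x) {
    if (is(x, "TadPartition")) x <- tads(x)
    if (is(x, "GeneModels")) x <- genes(x)
    if (is(x, "DNAStringSet")) return(names(x))
    as.character(unique(seqnames(x)))
  }
  fix <- function(ch) switch(harmonize,
    none = ch,
    add = ifelse(startsWith(ch, "chr"), ch, paste0("chr", ch)),
    strip = sub("^chr", "", ch))
  sets <- lapply(inputs, function(x) sort(fix(getChroms(x))))
  common <- Reduce(intersect, sets)
  for (nm in names(sets)) {
    extra <- setdiff(sets[[nm]], common)
    if (length(extra))
      warning(sprintf("input '%s' has chromosomes absent elsewhere: %s",
                      nm, paste(extra, collapse = ",")), call. = FALSE)
  }
  invisible(list(per_input = sets, common = common))
}

#' Apply "chr"-prefix harmonization to a ranged object
#'
#' @param x A `GRanges`, [TadPartition-class], [GeneModels-class] or
#'   `DNAStringSet`.
#' @param action `"add"` or `"strip"`.
#' @return The object with renamed chromosomes.
#' @export
harmonizeChromNames <- function(x, action = c("add", "strip")) {
  action <- match.arg(action)
  fix <- function(ch) if (action == "add")
    ifelse(startsWith(ch, "chr"), ch, paste0("chr", ch)) else
    sub("^chr", "", ch)
  if (is(x, "DNAStringSet")) { names(x) <- fix(names(x)); return(x) }
  if (is(x, "TadPartition")) {
    gr <- tads(x); seqlevels(gr) <- fix(seqlevels(gr))
    return(TadPartition(gr, repair = FALSE))
  }
  if (is(x, "GeneModels")) {
    g <- genes(x); ex <- exons(x)
    seqlevels(g) <- fix(seqlevels(g))
    seqlevels(ex) <- fix(seqlevels(ex))
    return(new("GeneModels", genes = g, exons = ex))
  }
  seqlevels(x) <- fix(seqlevels(x))
  x
}
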