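## Truth-annotated synthetic multi-omics generator: genome + gene models +
## TAD partition, per-sample peak calls with group-unique regions, NB
## count matrices with planted group effects and planted within-TAD
## peak-gene correlations, and motif instances written into one group's
## unique peaks. Everything is seeded and reproducible byte for byte.

#' Simulation configuration
#'
#' Defaults emulate the study design the pipeline targets: two genotype
#' groups with four biological replicates each, a desk-scale genome
#' (2 chromosomes x 1 Mb, 20 TADs, 300 genes, 1000 peaks) that runs the
#' full pipeline in seconds, NB counts at mouse-tissue-like dispersion,
#' and planted links at |r| = 0.9 with 20% negative sign.
#'
#' @param nChromosomes,chromLength Genome shape.
#' @param nTads Total number of TADs (tiled disjointly, split across
#'   chromosomes).
#' @param nGenes,nPeaks Feature counts; both are spread round-robin across
#'   TADs so every TAD is populated.
#' @param nSamplesPerGroup Biological replicates per group (default 4).
#' @param nbMeanRange Log-uniform range of NB base means.
#' @param nbDispersion Common NB dispersion `a` (`var = mu + a mu^2`).
#' @param fracLinkedPairs Fraction of within-TAD peak-gene pairs that get
#'   a planted correlation.
#' @param linkRTarget Target |Pearson r| of planted links on VST values.
#' @param fracLinkNegative Fraction of planted links with negative sign.
#' @param linkMeanMin Minimum base mean for linked features (keeps count
#'   noise from washing out the planted correlation).
#' @param fracDeGenes Fraction of genes made differential (group B mean
#'   multiplied by `2^deLfc`).
#' @param deLfc Planted log2 fold change.
#' @param fracGroupUniquePeaks Fraction of peaks present in only one
#'   group's samples (split evenly between groups); the absent group's
#'   count mean is divided by `2^deLfc`.
#' @param fracPromoterPeaks Fraction of peaks placed over a TSS.
#' @param peakWidthRange,geneWidthRange Feature sizes in bp.
#' @param jitter Per-sample peak-boundary jitter in bp.
#' @param gc Genome GC fraction (default 0.41, mouse-like).
#' @param libSizeSd SD of per-sample log-normal library-size factors.
#' @param motifPlantRateTarget,motifPlantRateBackground Probability of
#'   writing a motif instance into a group-B-unique peak vs any other
#'   peak.
#' @param seed Integer seed governing every random draw.
#' @return A list of class `tadlink_sim_config`.
#' @export
simConfig <- function(nChromosomes = 2L, chromLength = 1e6, nTads = 20L,
                      nGenes = 300L, nPeaks = 1000L, nSamplesPerGroup = 4L,
                      nbMeanRange = c(20, 2000), nbDispersion = 0.05,
                      fracLinkedPairs = 0.01, linkRTarget = 0.9,
                      fracLinkNegative = 0.2, linkMeanMin = 100,
                      fracDeGenes = 0.1, deLfc = 2,
                      fracGroupUniquePeaks = 0.2, fracPromoterPeaks = 0.3,
                      peakWidthRange = c(200L, 400L),
                      geneWidthRange = c(1000L, 4000L), jitter = 10L,
                      gc = 0.41, libSizeSd = 0.2,
                      motifPlantRateTarget = 0.6,
                      motifPlantRateBackground = 0.05, seed = 1L) {
  cfg <- as.list(environment())
  fr <- c(cfg$fracLinkedPairs, cfg$fracLinkNegative, cfg$fracDeGenes,
          cfg$fracGroupUniquePeaks, cfg$fracPromoterPeaks,
          cfg$motifPlantRateTarget, cfg$motifPlantRateBackground)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0,1]", call. = FALSE)
  if (cfg$nbDispersion <= 0) stop("dispersion must be > 0", call. = FALSE)
  if (cfg$nSamplesPerGroup < 2L)
    stop("need >= 2 samples per group", call. = FALSE)
  class(cfg) <- "tadlink_sim_config"
  cfg
}

.randSeq <- function(n, gc) {
  paste(sample(.BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a synthetic genome, gene models and TAD partition
#'
#' Chromosomes are i.i.d. background DNA at the configured GC; TADs tile
#' each chromosome disjointly and completely; genes are assigned to TADs
#' round-robin with the TSS placed uniformly inside the TAD (so every TSS
#' lies inside exactly one TAD) and a simple 1-3 exon structure.
#'
#' @param cfg A [simConfig()] list.
#' @return List with `genome` (`DNAStringSet`), `geneModels`
#'   ([GeneModels-class]), `tads` ([TadPartition-class]).
#' @export
generateGenome <- function(cfg) {
  set.seed(cfg$seed)
  L <- as.integer(cfg$chromLength)
  if (L < 1000L * cfg$nTads / cfg$nChromosomes)
    stop(sprintf("chromLength too small: need >= %d bp per chromosome",
                 1000L * as.integer(ceiling(cfg$nTads / cfg$nChromosomes))),
         call. = FALSE)
  chroms <- sprintf("chr%d", seq_len(cfg$nChromosomes))
  genome <- Biostrings::DNAStringSet(
    vapply(chroms, function(ch) .randSeq(L, cfg$gc), character(1)))
  names(genome) <- chroms

  # TADs: split across chromosomes, tile each completely
  perChrom <- rep(cfg$nTads %/% cfg$nChromosomes, cfg$nChromosomes)
  extra <- cfg$nTads %% cfg$nChromosomes
  if (extra > 0) perChrom[seq_len(extra)] <- perChrom[seq_len(extra)] + 1L
  tlist <- lapply(seq_along(chroms), function(ci) {
    k <- perChrom[ci]
    bnd <- round(seq(0L, L, length.out = k + 1L))
    GRanges(chroms[ci], IRanges(bnd[-(k + 1L)] + 1L, bnd[-1L]),
            tad_id = sprintf("tad_%s_%d", chroms[ci], seq_len(k)))
  })
  tp <- TadPartition(suppressWarnings(do.call(c, tlist)), repair = FALSE)
  td <- tads(tp)

  # genes round-robin across TADs
  n <- cfg$nGenes
  tadIdx <- rep(seq_along(td), length.out = n)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  w <- sample(cfg$geneWidthRange[1]:cfg$geneWidthRange[2], n, replace = TRUE)
  tss <- start(td)[tadIdx] +
    floor(stats::runif(n) * width(td)[tadIdx])
  chrom <- as.character(seqnames(td))[tadIdx]
  gstart <- ifelse(strand == "+", tss, pmax(tss - w + 1L, 1L))
  gend <- ifelse(strand == "+", pmin(tss + w - 1L, L), tss)
  ids <- sprintf("gene_%04d", seq_len(n))
  genes <- GRanges(chrom, IRanges(gstart, gend), strand = strand,
                   gene_id = ids, tss = tss)
  exl <- GRangesList(lapply(seq_len(n), function(i) {
    s <- gstart[i]; e <- gend[i]; wd <- e - s + 1L
    if (wd <= 600L) {
      ir <- IRanges(s, e)
    } else {
      ir <- IRanges(c(s, s + wd %/% 2L - 100L, e - 199L),
                    c(s + 199L, s + wd %/% 2L + 99L, e))
    }
    GRanges(chrom[i], ir, strand = strand[i])
  }))
  names(exl) <- ids
  gm <- new("GeneModels", genes = genes, exons = exl)
  validObject(gm)
  list(genome = genome, geneModels = gm, tads = tp)
}

.sampleMotifInstance <- function(pwm) {
  p <- probs(pwm)
  paste(vapply(seq_len(ncol(p)), function(j)
    sample(.BASES, 1L, prob = p[, j]), character(1)), collapse = "")
}

#' Generate master and per-sample peaks plus the truth ledger
#'
#' Builds a master peak set (a configurable fraction promoter-proximal,
#' the rest distal), marks a fraction of peaks as unique to one group,
#' selects planted peak-gene link pairs within shared TADs (each peak and
#' gene used at most once, group-unique peaks and DE genes excluded so
#' every planted effect is attributable), plants motif instances into the
#' genome sequence preferentially under group-B-unique peaks, and emits
#' per-sample peak calls with boundary jitter.
#'
#' @param genomeArt Output of [generateGenome()].
#' @param cfg A [simConfig()] list.
#' @param pwm Optional [PWMotif-class] to plant; default is the synthetic
#'   NFAT:AP1 composite shipped with the package.
#' @return List with `masterPeaks` (`GRanges` with `peak_id`), `samplePeaks`
#'   (named list of `GRanges`), `groups`, `truth` (link table, DE gene
#'   table, group-unique peak ids, motif placements), and the (modified)
#'   `genome`.
#' @export
generatePeaksAndTruth <- function(genomeArt, cfg, pwm = NULL) {
  set.seed(cfg$seed + 1L)
  if (is.null(pwm)) pwm <- tadlinkMotif()
  td <- tads(genomeArt$tads)
  g <- genes(genomeArt$geneModels)
  genome <- genomeArt$genome
  L <- as.integer(cfg$chromLength)
  n <- cfg$nPeaks

  tadIdx <- rep(seq_along(td), length.out = n)
  w <- sample(cfg$peakWidthRange[1]:cfg$peakWidthRange[2], n, replace = TRUE)
  nProm <- round(cfg$fracPromoterPeaks * n)
  isProm <- seq_len(n) <= nProm
  chrom <- as.character(seqnames(td))[tadIdx]
  geneTad <- rep(seq_along(td), length.out = length(g))  # gene i -> TAD
  mid <- integer(n)
  for (i in seq_len(n)) {
    if (isProm[i]) {
      cand <- which(geneTad == tadIdx[i])
      if (length(cand)) {
        gi <- cand[sample.int(length(cand), 1L)]
        sgn <- ifelse(as.character(strand(g))[gi] == "+", -1L, 1L)
        mid[i] <- g$tss[gi] + sgn * sample.int(500L, 1L)  # upstream of TSS
        next
      }
    }
    mid[i] <- start(td)[tadIdx[i]] +
      floor(stats::runif(1) * width(td)[tadIdx[i]])
  }
  s <- pmax(mid - w %/% 2L, 1L)
  e <- pmin(s + w - 1L, L)
  master <- GRanges(chrom, IRanges(s, e),
                    peak_id = sprintf("peak_%04d", seq_len(n)))

  # actual TAD membership from realized anchors (a promoter peak near a
  # boundary can drift into the neighbouring TAD)
  mid0 <- (start(master) - 1L + end(master)) %/% 2L
  pkAnchor <- GRanges(chrom, IRanges(mid0 + 1L, mid0 + 1L))
  hitP <- findOverlaps(pkAnchor, td)
  peakTad <- rep(NA_integer_, n)
  peakTad[queryHits(hitP)] <- subjectHits(hitP)
  gAnchor <- GRanges(as.character(seqnames(g)), IRanges(g$tss, g$tss))
  hitG <- findOverlaps(gAnchor, td)
  geneTadActual <- rep(NA_integer_, length(g))
  geneTadActual[queryHits(hitG)] <- subjectHits(hitG)

  # group-unique peaks
  nUniq <- round(cfg$fracGroupUniquePeaks * n)
  uniq <- sample.int(n, nUniq)
  uniqA <- uniq[seq_len(nUniq %/% 2L)]
  uniqB <- setdiff(uniq, uniqA)
  peakGroup <- rep("shared", n)
  peakGroup[uniqA] <- "A_unique"; peakGroup[uniqB] <- "B_unique"

  # DE genes
  nDe <- round(cfg$fracDeGenes * length(g))
  deIdx <- sample.int(length(g), nDe)

  # planted links: within-TAD pairs of non-unique peaks x non-DE genes,
  # each element used once
  candPeaks <- which(peakGroup == "shared" & !is.na(peakTad))
  candGenes <- setdiff(which(!is.na(geneTadActual)), deIdx)
  pairPool <- do.call(rbind, lapply(seq_along(td), function(t) {
    pp <- candPeaks[peakTad[candPeaks] == t]
    gg <- candGenes[geneTadActual[candGenes] == t]
    if (!length(pp) || !length(gg)) return(NULL)
    expand.grid(peak = pp, gene = gg)
  }))
  nPairsAll <- sum(vapply(seq_along(td), function(t)
    sum(peakTad == t, na.rm = TRUE) *
      sum(geneTadActual == t, na.rm = TRUE), 0))
  nLink <- round(cfg$fracLinkedPairs * nPairsAll)
  if (is.null(pairPool) || nLink > nrow(pairPool))
    stop(sprintf("fracLinkedPairs demands %d links but only %d usable pairs",
                 nLink, if (is.null(pairPool)) 0L else nrow(pairPool)),
         call. = FALSE)
  linkRows <- integer(0)
  if (nLink > 0) {
    ord <- sample.int(nrow(pairPool))
    usedP <- logical(n); usedG <- logical(length(g))
    for (k in ord) {
      if (length(linkRows) >= nLink) break
      pk <- pairPool$peak[k]; gn <- pairPool$gene[k]
      if (usedP[pk] || usedG[gn]) next
      usedP[pk] <- TRUE; usedG[gn] <- TRUE
      linkRows <- c(linkRows, k)
    }
    if (length(linkRows) < nLink)
      stop("could not place requested links without reusing elements",
           call. = FALSE)
  }
  linkSign <- rep("positive", length(linkRows))
  nNeg <- round(cfg$fracLinkNegative * length(linkRows))
  if (nNeg > 0) linkSign[sample.int(length(linkRows), nNeg)] <- "negative"
  linkTruth <- data.frame(
    peak_id = master$peak_id[pairPool$peak[linkRows]],
    gene_id = g$gene_id[pairPool$gene[linkRows]],
    tad_id = td$tad_id[peakTad[pairPool$peak[linkRows]]],
    sign = linkSign, r_target = rep(cfg$linkRTarget, length(linkRows)),
    stringsAsFactors = FALSE)

  # motif planting into genome sequence under peaks
  plantP <- ifelse(peakGroup == "B_unique", cfg$motifPlantRateTarget,
                   cfg$motifPlantRateBackground)
  plant <- stats::runif(n) < plantP
  Lm <- ncol(probs(pwm))
  placements <- list()
  seqs <- as.list(as.character(genome))
  for (i in which(plant)) {
    if (width(master)[i] <= Lm) next
    off <- sample.int(width(master)[i] - Lm, 1L)  # 1-based within peak
    inst <- .sampleMotifInstance(pwm)
    strand_i <- sample(c("+", "-"), 1L)
    if (strand_i == "-")
      inst <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(inst)))
    p1 <- start(master)[i] + off - 1L
    ch <- chrom[i]
    substr(seqs[[ch]], p1, p1 + Lm - 1L) <- inst
    placements[[length(placements) + 1L]] <- data.frame(
      peak_id = master$peak_id[i], chrom = ch, start0 = p1 - 1L,
      strand = strand_i, group = peakGroup[i], stringsAsFactors = FALSE)
  }
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- names(genomeArt$genome)
  motifTruth <- if (length(placements)) do.call(rbind, placements) else
    data.frame(peak_id = character(0), chrom = character(0),
               start0 = integer(0), strand = character(0),
               group = character(0))

  # per-sample peak calls with boundary jitter
  ns <- cfg$nSamplesPerGroup
  sampleNames <- c(sprintf("A%d", seq_len(ns)), sprintf("B%d", seq_len(ns)))
  groups <- rep(c("A", "B"), each = ns)
  samplePeaks <- stats::setNames(lapply(seq_along(sampleNames), function(si) {
    grp <- groups[si]
    keep <- peakGroup == "shared" | peakGroup == paste0(grp, "_unique")
    gr <- master[keep]
    if (cfg$jitter > 0) {
      ds <- sample((-cfg$jitter):cfg$jitter, sum(keep), replace = TRUE)
      de <- sample((-cfg$jitter):cfg$jitter, sum(keep), replace = TRUE)
      ns2 <- pmax(start(gr) + ds, 1L)
      ne <- pmin(end(gr) + de, L)
      bad <- ne - ns2 < 50L
      ns2[bad] <- start(gr)[bad]; ne[bad] <- end(gr)[bad]
      gr <- GRanges(seqnames(gr), IRanges(ns2, ne), peak_id = gr$peak_id)
    }
    gr$sample <- sampleNames[si]
    gr
  }), sampleNames)

  truth <- list(
    links = linkTruth,
    de_genes = data.frame(gene_id = g$gene_id[deIdx],
                          true_lfc = rep(cfg$deLfc, length(deIdx)),
                          stringsAsFactors = FALSE),
    group_unique_peaks = data.frame(
      peak_id = master$peak_id[peakGroup != "shared"],
      group = sub("_unique", "", peakGroup[peakGroup != "shared"]),
      stringsAsFactors = FALSE),
    motif_placements = motifTruth)
  list(masterPeaks = master, samplePeaks = samplePeaks, groups = groups,
       sampleNames = sampleNames, truth = truth, genome = genome,
       peakGroup = peakGroup)
}

#' Generate NB count matrices with planted effects
#'
#' Counts are NB with `var = mu + a mu^2`. Group effects: DE genes have
#' the group-B mean multiplied by `2^deLfc`; group-unique peaks have the
#' absent group's mean divided by `2^deLfc`. Planted links share a
#' per-sample log-normal latent factor whose variance is calibrated (via
#' the delta-method noise variances `1/mu + a` of the two members) so the
#' expected Pearson r on VST values approximates `linkRTarget`; negative
#' links invert the latent exponent on the peak side. Per-sample library
#' factors are log-normal.
#'
#' @param peaksArt Output of [generatePeaksAndTruth()].
#' @param cfg A [simConfig()] list.
#' @return List with `atacCounts`, `rnaCounts` (integer matrices),
#'   `groups`, `sampleNames`.
#' @export
generateCounts <- function(peaksArt, cfg) {
  set.seed(cfg$seed + 2L)
  a <- cfg$nbDispersion
  ns <- cfg$nSamplesPerGroup
  sampleNames <- peaksArt$sampleNames
  groups <- peaksArt$groups
  nS <- length(sampleNames)
  master <- peaksArt$masterPeaks
  nP <- length(master)
  truth <- peaksArt$truth

  lu <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))
  peakBase <- lu(nP, cfg$nbMeanRange[1], cfg$nbMeanRange[2])
  # gene ids come from the gene models via the link/DE tables; count rows
  # cover all genes
  nG <- cfg$nGenes
  allGenes <- sprintf("gene_%04d", seq_len(nG))
  geneBase <- lu(nG, cfg$nbMeanRange[1], cfg$nbMeanRange[2])
  names(geneBase) <- allGenes
  names(peakBase) <- master$peak_id

  # linked features get comfortably high base means
  lmin <- max(cfg$linkMeanMin, cfg$nbMeanRange[1])
  lmax <- max(cfg$nbMeanRange[2], lmin * 2)
  if (nrow(truth$links)) {
    peakBase[truth$links$peak_id] <- lu(nrow(truth$links), lmin, lmax)
    geneBase[truth$links$gene_id] <- lu(nrow(truth$links), lmin, lmax)
  }

  libA <- exp(stats::rnorm(nS, 0, cfg$libSizeSd))
  libA <- libA / exp(mean(log(libA)))
  libR <- exp(stats::rnorm(nS, 0, cfg$libSizeSd))
  libR <- libR / exp(mean(log(libR)))

  peakMu <- matrix(peakBase, nP, nS)
  rownames(peakMu) <- master$peak_id
  geneMu <- matrix(geneBase, nG, nS)
  rownames(geneMu) <- allGenes
  isB <- groups == "B"

  gu <- truth$group_unique_peaks
  if (nrow(gu)) {
    offA <- gu$peak_id[gu$group == "B"]  # absent from group A samples
    offB <- gu$peak_id[gu$group == "A"]
    peakMu[offA, !isB] <- peakMu[offA, !isB] / 2^cfg$deLfc
    peakMu[offB, isB] <- peakMu[offB, isB] / 2^cfg$deLfc
  }
  if (nrow(truth$de_genes))
    geneMu[truth$de_genes$gene_id, isB] <-
      geneMu[truth$de_genes$gene_id, isB] * 2^cfg$deLfc

  if (nrow(truth$links)) {
    r <- cfg$linkRTarget
    for (k in seq_len(nrow(truth$links))) {
      pid <- truth$links$peak_id[k]; gid <- truth$links$gene_id[k]
      vp <- 1 / peakBase[pid] + a
      vg <- 1 / geneBase[gid] + a
      s2 <- (r / (1 - r)) * sqrt(vp * vg)
      z <- stats::rnorm(nS, 0, sqrt(s2))
      sgn <- if (truth$links$sign[k] == "negative") -1 else 1
      peakMu[pid, ] <- peakMu[pid, ] * exp(sgn * z - s2 / 2)
      geneMu[gid, ] <- geneMu[gid, ] * exp(z - s2 / 2)
    }
  }

  peakMu <- sweep(peakMu, 2, libA, "*")
  geneMu <- sweep(geneMu, 2, libR, "*")
  atac <- matrix(stats::rnbinom(nP * nS, mu = peakMu, size = 1 / a), nP, nS,
                 dimnames = list(master$peak_id, sampleNames))
  rna <- matrix(stats::rnbinom(nG * nS, mu = geneMu, size = 1 / a), nG, nS,
                dimnames = list(allGenes, sampleNames))
  list(atacCounts = atac, rnaCounts = rna, groups = groups,
       sampleNames = sampleNames)
}

#' Generate a complete synthetic dataset
#'
#' Runs [generateGenome()], [generatePeaksAndTruth()] and
#' [generateCounts()] under the configuration's seed.
#'
#' @param cfg A [simConfig()] list.
#' @param pwm Optional [PWMotif-class] to plant (default: shipped
#'   synthetic NFAT:AP1 composite).
#' @return A bundle list with all artifacts plus `config`.
#' @export
simulateDataset <- function(cfg = simConfig(), pwm = NULL) {
  ga <- generateGenome(cfg)
  pa <- generatePeaksAndTruth(ga, cfg, pwm = pwm)
  cn <- generateCounts(pa, cfg)
  list(genome = pa$genome, geneModels = ga$geneModels, tads = ga$tads,
       masterPeaks = pa$masterPeaks, samplePeaks = pa$samplePeaks,
       truth = pa$truth, atacCounts = cn$atacCounts,
       rnaCounts = cn$rnaCounts, groups = cn$groups,
       sampleNames = cn$sampleNames, config = cfg)
}

#' Write a simulated dataset to disk
#'
#' Emits every artifact in the formats the package readers consume:
#' genome FASTA, gene-model GTF, TAD BED, master and per-sample peak
#' narrowPeak files, count TSVs, a sample-to-group table, the truth
#' ledger as JSON, and a manifest (paths, seed, config, config MD5).
#'
#' @param bundle Output of [simulateDataset()].
#' @param outDir Output directory (created if needed).
#' @return The manifest list, invisibly; written to
#'   `file.path(outDir, "manifest.json")`.
#' @export
writeDataset <- function(bundle, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create ", outDir, call. = FALSE)
  pth <- function(...) file.path(outDir, ...)
  Biostrings::writeXStringSet(bundle$genome, pth("genome.fa"))
  writeGeneModels(bundle$geneModels, pth("genes.gtf"))
  writeTads(bundle$tads, pth("tads.bed"))
  mp <- bundle$masterPeaks
  mp$name <- mp$peak_id
  writePeaks(mp, pth("master_peaks.narrowPeak"), "narrowpeak")
  dir.create(pth("peaks"), showWarnings = FALSE)
  peakFiles <- list()
  for (sn in names(bundle$samplePeaks)) {
    gr <- bundle$samplePeaks[[sn]]
    gr$name <- gr$peak_id
    f <- pth("peaks", paste0(sn, ".narrowPeak"))
    writePeaks(gr, f, "narrowpeak")
    peakFiles[[sn]] <- f
  }
  writeCounts(bundle$atacCounts, pth("atac_counts.tsv"))
  writeCounts(bundle$rnaCounts, pth("rna_counts.tsv"))
  utils::write.table(
    data.frame(sample = bundle$sampleNames, group = bundle$groups),
    pth("groups.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$truth, pth("truth.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  cfgPath <- pth("sim_config.yaml")
  yaml::write_yaml(unclass(bundle$config), cfgPath)
  manifest <- list(
    seed = bundle$config$seed,
    config = "sim_config.yaml",
    config_md5 = unname(tools::md5sum(cfgPath)),
    genome = "genome.fa", genes = "genes.gtf", tads = "tads.bed",
    master_peaks = "master_peaks.narrowPeak",
    sample_peaks = lapply(peakFiles, function(f) file.path("peaks",
                                                           basename(f))),
    atac_counts = "atac_counts.tsv", rna_counts = "rna_counts.tsv",
    groups = "groups.tsv", truth = "truth.json")
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}

#' The synthetic NFAT:AP1 composite motif shipped with the package
#'
#' A synthetic stand-in for the composite NFAT (TTTCC core) plus AP-1
#' (TGASTCA) binding matrix, stored as a JASPAR-format fixture at
#' `inst/extdata/nfat_ap1_synthetic.jaspar`.
#'
#' @param pseudocount,background Passed to [readJaspar()].
#' @return A [PWMotif-class].
#' @export
tadlinkMotif <- function(pseudocount = 0.8, background = rep(0.25, 4)) {
  f <- system.file("extdata", "nfat_ap1_synthetic.jaspar",
                   package = "tadlink", mustWork = TRUE)
  readJaspar(f, pseudocount = pseudocount, background = background)[[1]]
}
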