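## End-to-end orchestration: parse -> consensus/Venn -> normalize -> DE ->
## annotate -> TAD-link -> summarize -> (optional) motif enrichment, with
## a machine-readable report whose every count is recomputable from the
## emitted tables.

#' Default pipeline parameters
#'
#' Every analysis threshold surfaced as a named key: `alpha_de` and
#' `lfc_min` for differential calling, `alpha_corr` for link
#' significance on the raw correlation p, promoter/TTS windows for peak
#' annotation, the replicate-support minimum for consensus peaks, the
#' fold-change pseudocount, the VST method and the motif scan p.
#'
#' @return Named list of defaults.
#' @export
defaultPipelineParams <- function() {
  list(min_samples = 2L, alpha_de = 0.05, lfc_min = 1, alpha_corr = 0.05,
       corr_adjust = "none", promoter_up = 1000L, promoter_down = 100L,
       tts_window = 100L, pseudocount = 0.5, vst_method = "log2p1",
       scan_p = 1e-4, n_background = 500L, gc_tol = 0.05, seed = 1L)
}

#' Read a pipeline configuration from YAML
#'
#' The file has an `inputs` section (paths to `atac_counts`, `rna_counts`,
#' `groups`, `master_peaks`, `sample_peaks` per sample with a
#' `sample_groups` mapping, `genes`, `tads`, optional `genome` and `pwm`)
#' and a `params` section overriding [defaultPipelineParams()]. Relative
#' paths resolve against the YAML file's directory.
#'
#' @param path Path to the YAML file.
#' @return A config list for [runPipeline()].
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (is.null(p) || file.exists(p)) p else
    file.path(base, p)
  pathKeys <- setdiff(names(cfg$inputs), "sample_groups")
  cfg$inputs[pathKeys] <- lapply(cfg$inputs[pathKeys], function(x)
    if (is.list(x)) lapply(x, resolve) else resolve(x))
  cfg
}

#' Pipeline configuration for a written synthetic dataset
#'
#' Builds the [runPipeline()] config pointing at the files a
#' [writeDataset()] call emitted.
#'
#' @param dataDir Directory holding `manifest.json`.
#' @param params Parameter overrides merged over
#'   [defaultPipelineParams()].
#' @return A config list.
#' @export
datasetConfig <- function(dataDir, params = list()) {
  man <- jsonlite::read_json(file.path(dataDir, "manifest.json"),
                             simplifyVector = TRUE)
  grp <- utils::read.delim(file.path(dataDir, man$groups))
  p <- utils::modifyList(defaultPipelineParams(), params)
  list(inputs = list(
         atac_counts = file.path(dataDir, man$atac_counts),
         rna_counts = file.path(dataDir, man$rna_counts),
         master_peaks = file.path(dataDir, man$master_peaks),
         sample_peaks = lapply(man$sample_peaks, function(f)
           file.path(dataDir, f)),
         sample_groups = stats::setNames(as.list(grp$group), grp$sample),
         genes = file.path(dataDir, man$genes),
         tads = file.path(dataDir, man$tads),
         genome = file.path(dataDir, man$genome)),
       params = p)
}

.stage <- function(report, name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the integrative ATAC/RNA pipeline
#'
#' Stages, in order: parse inputs; per-group consensus peaks and Venn
#' classification; size-factor + VST normalization of both matrices; PCA
#' of the accessibility matrix; NB Wald differential expression with BH
#' correction and threshold calls; peak annotation; TAD assignment and
#' within-TAD pair enumeration; pooled-sample Pearson linking; link
#' summary; differential genes supported by correlated accessibility;
#' and, when a genome and PWM are configured, motif enrichment of the
#' group-B-unique promoter peaks against a GC-matched background.
#' Intermediate tables are written to `outDir`; any stage error aborts
#' with the stage name, retaining files already written.
#'
#' @param config Config list (see [readPipelineConfig()] /
#'   [datasetConfig()]) or the path to a YAML file.
#' @param outDir Output directory.
#' @return The run report (list), also written to
#'   `file.path(outDir, "report.json")`.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- readPipelineConfig(config)
  params <- utils::modifyList(defaultPipelineParams(),
                              if (is.null(config$params)) list() else
                                config$params)
  ins <- config$inputs
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(outDir, ...)
  set.seed(params$seed)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  warningsLog <- character(0)

  atac <- .stage(NULL, "parse", readCounts(ins$atac_counts))
  rna <- .stage(NULL, "parse", readCounts(ins$rna_counts))
  gm <- .stage(NULL, "parse", readGeneModels(ins$genes))
  tp <- .stage(NULL, "parse", readTads(ins$tads))
  master <- .stage(NULL, "parse", {
    mp <- readPeaks(ins$master_peaks, "narrowpeak")
    mp$peak_id <- mp$name
    mp
  })
  groupsMap <- unlist(ins$sample_groups)
  samples <- names(ins$sample_peaks)
  samplePeaks <- .stage(NULL, "parse", lapply(ins$sample_peaks, function(f)
    readPeaks(f, "narrowpeak")))
  if (!identical(sort(colnames(atac)), sort(colnames(rna))))
    stop("pipeline stage 'parse' failed: count matrices disagree on samples",
         call. = FALSE)
  rna <- rna[, colnames(atac), drop = FALSE]
  groups <- as.character(groupsMap[colnames(atac)])

  lev <- sort(unique(groups))
  cons <- .stage(NULL, "consensus", {
    stats::setNames(lapply(lev, function(gl) {
      buildGroupConsensus(samplePeaks[samples[groupsMap[samples] == gl]],
                          minSamples = params$min_samples, group = gl)
    }), lev)
  })
  venn <- .stage(NULL, "consensus", vennClassify(cons[[1]], cons[[2]]))
  vc <- vennCounts(venn)
  sizeStats <- lapply(cons, peakSizeSummary)
  for (gl in lev) {
    gr <- peaks(cons[[gl]])
    gr$name <- gr$peak_id
    writePeaks(gr, pth(sprintf("consensus_%s.bed", gl)), "bed6")
  }

  atacNorm <- .stage(NULL, "normalize",
                     vstNormalize(atac, method = params$vst_method))
  rnaNorm <- .stage(NULL, "normalize",
                    vstNormalize(rna, method = params$vst_method))
  pca <- .stage(NULL, "normalize", pcaEmbed(atacNorm, 2L))

  de <- .stage(NULL, "differential",
               nbWaldTest(rna, groups, pseudocount = params$pseudocount,
                          alpha = params$alpha_de, lfcMin = params$lfc_min))
  calls <- callDifferential(de, params$alpha_de, params$lfc_min)
  utils::write.table(de, pth("differential_expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ann <- .stage(NULL, "annotate",
                annotatePeaks(master, gm, promoterUp = params$promoter_up,
                              promoterDown = params$promoter_down,
                              ttsWindow = params$tts_window))
  utils::write.table(ann, pth("peak_annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  pa <- .stage(NULL, "tad_link", assignPeaksToTads(master, tp))
  ga <- .stage(NULL, "tad_link", assignGenesToTads(gm, tp))
  nUnassigned <- c(peaks = sum(is.na(pa$tad_id)),
                   genes = sum(is.na(ga$tad_id)))
  if (any(nUnassigned > 0))
    warningsLog <- c(warningsLog,
                     sprintf("%d peak(s) and %d gene(s) outside every TAD",
                             nUnassigned[1], nUnassigned[2]))
  pairs <- .stage(NULL, "tad_link", enumerateTadPairs(pa, ga))
  linkset <- .stage(NULL, "tad_link",
                    linkPeaksGenes(pairs, atacNorm, rnaNorm,
                                   annotations = ann,
                                   alpha = params$alpha_corr,
                                   adjust = params$corr_adjust))
  lsum <- summarizeLinks(linkset)
  if (lsum$n_dropped > 0)
    warningsLog <- c(warningsLog,
                     sprintf("%d pair(s) dropped (zero variance)",
                             lsum$n_dropped))
  utils::write.table(links(linkset), pth("links.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  corrUp <- selectCorrelatedDeGenes(linkset, calls$up, params$alpha_corr)

  motif <- NULL
  if (!is.null(ins$genome)) {
    motif <- .stage(NULL, "motif", {
      genome <- readGenomeFasta(ins$genome)
      pwm <- if (!is.null(ins$pwm)) readJaspar(ins$pwm)[[1]] else
        tadlinkMotif()
      # targets: promoter peaks unique to the second group
      ub <- venn@uniqueB
      ubAnn <- annotatePeaks(
        { ub$peak_id <- sprintf("uB_%d", seq_along(ub)); ub }, gm,
        promoterUp = params$promoter_up,
        promoterDown = params$promoter_down,
        ttsWindow = params$tts_window)
      tgt <- ub[ubAnn$class == "promoter"]
      if (length(tgt) < 5L) {
        warningsLog <- c(warningsLog,
                         "fewer than 5 unique promoter peaks; motif stage skipped")
        NULL
      } else {
        tgtSeqs <- extractSequences(genome, tgt)
        names(tgtSeqs) <- sprintf("target_%d", seq_along(tgtSeqs))
        bg <- sampleGCMatchedBackground(tgt, genome,
                                        max(params$n_background,
                                            length(tgt)),
                                        gcTol = params$gc_tol)
        motifEnrichment(tgtSeqs, bg$seqs, pwm, scanP = params$scan_p)
      }
    })
  }

  report <- list(
    params = params,
    seed = params$seed,
    n_samples = length(groups),
    groups = as.list(table(groups)),
    consensus_peaks = lapply(cons, function(x) length(peaks(x))),
    peak_size = lapply(sizeStats, as.list),
    venn = as.list(vc),
    pca_variance_explained = pca$varianceExplained,
    genes_tested = nrow(de),
    de_up = length(calls$up), de_down = length(calls$down),
    pairs_tested = lsum$n_tested,
    pairs_dropped = lsum$n_dropped,
    links_significant = lsum$n_significant,
    links_positive = lsum$n_positive,
    links_negative = lsum$n_negative,
    annotation_class_proportions = lsum$class_proportions,
    correlated_de_genes = length(corrUp),
    motif_enrichment = motif,
    unassigned = as.list(nUnassigned),
    warnings = warningsLog,
    timestamps = list(started = started,
                      finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  jsonlite::write_json(report, pth("report.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", pretty = TRUE)
  invisible(report)
}
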