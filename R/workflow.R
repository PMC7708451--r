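#' Pipeline configuration
#'
#' Aggregates the per-stage defaults: generator settings, expression
#' filters (min TPM 5, RSD < 1), 80/10/10 split, model spec, relevance
#' settings (10-bp window, 2 SD cutoff), motif settings (identity 0.8,
#' cluster size 5, 0.2-bit trim), rule mining (>= 3 genes, FDR 0.05, up
#' to 6 motifs) and per-stage seeds derived from one master seed.
#'
#' @param seed master seed; per-stage seeds derive from it.
#' @param nGenes,nExperiments cohort size.
#' @param modelSpec a [modelSpec()] list.
#' @param relevanceGenes genes profiled in the relevance stage.
#' @param swapGenes promoter halves used in the swap stage.
#' @param orthologSpecies,orthologCorrelation coevolution stage
#'   settings.
#' @return nested configuration list.
#' @export
pipelineConfig <- function(seed = 1L, nGenes = 3000, nExperiments = 100,
                           modelSpec = regGrammar::modelSpec(
                             convFilters = c(48, 48, 48),
                             kernels = c(10, 1, 1), pools = c(2, 1, 97),
                             fcWidths = c(64, 32), dropout = 0.1,
                             batchnorm = FALSE, lr = 2e-3,
                             batchSize = 128, epochs = 45,
                             patience = 15, lrDecayPatience = 8),
                           relevanceGenes = 400, swapGenes = 60,
                           orthologSpecies = 14,
                           orthologCorrelation = 0.45) {
  ## one master seed fans out deterministically per stage
  stageSeeds <- as.list(seed * 1000L + 1:9)
  names(stageSeeds) <- c("genome", "expression", "split", "model",
                         "relevance", "motifs", "rules", "swap",
                         "orthologs")
  list(seed = seed, stageSeeds = stageSeeds,
       generator = syntheticConfig(nGenes = nGenes),
       nExperiments = nExperiments,
       filters = list(minTpm = 5, rsdMax = 1),
       split = c(0.8, 0.1, 0.1),
       model = modelSpec,
       relevance = list(window = 10L, cutoffSd = 2,
                        nGenes = relevanceGenes),
       motifs = list(identity = 0.8, minCluster = 5, trimBits = 0.2,
                     maxShift = 2L),
       rules = list(minGenes = 3, alpha = 0.05, maxSize = 6),
       swap = list(nGenes = swapGenes, nPartners = 20),
       orthologs = list(nSpecies = orthologSpecies,
                        correlation = orthologCorrelation,
                        regions = c("promoter", "cds"),
                        maskCutoff = 0.2))
}

logStage <- function(log, stage, t0, ...) {
  entry <- list(stage = stage,
                seconds = round(as.numeric(Sys.time() - t0,
                                           units = "secs"), 2), ...)
  message(sprintf("[%s] done in %.1fs", stage, entry$seconds))
  c(log, list(entry))
}

#' Run the synthetic end-to-end pipeline
#'
#' Generate -> expression -> features -> train -> relevance -> motifs ->
#' rules -> swap -> coevolution, writing versioned outputs and a JSON
#' manifest (config echo, per-stage seeds and metrics, file checksums)
#' into `dir`. Rerunning with identical config and seeds reproduces the
#' metrics.
#'
#' @param config list from [pipelineConfig()].
#' @param dir output directory.
#' @return list with `metrics` and `manifest` (also written to
#'   `manifest.json`).
#' @export
runPipeline <- function(config = pipelineConfig(), dir = tempfile("rgrun")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ss <- config$stageSeeds
  log <- list()
  metrics <- list()

  t0 <- Sys.time()
  cohort <- generateGenome(config$generator, seed = ss$genome)
  cohort <- generateExpression(cohort, config$nExperiments,
                               seed = ss$expression)
  writeCohort(cohort, file.path(dir, "cohort"))
  tpm <- expressionMatrix(cohort)
  metrics$frac_rsd_below_1 <- mean(rsdVec(tpm) < 1)
  metrics$median_variance_ratio <- varianceRatio(tpm)$median
  med <- apply(tpm, 1, stats::median)
  metrics$log10_median_range <- log10(max(med) / min(med))
  log <- logStage(log, "generate", t0)

  t0 <- Sys.time()
  orf <- stats::setNames(cohort@geneData$len_cds, geneIds(cohort))
  mt <- medianTarget(tpm, orf, minTpm = config$filters$minTpm,
                     rsdMax = config$filters$rsdMax)
  utils::write.table(as.data.frame(mt$summary),
                     file.path(dir, "targets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  metrics$genes_kept <- length(mt$kept)
  log <- logStage(log, "expr", t0)

  t0 <- Sys.time()
  feats <- cohortFeatures(cohort)
  keep <- match(mt$kept, feats$geneIds)
  feats <- list(seq = feats$seq[keep, , , drop = FALSE],
                num = feats$num[keep, , drop = FALSE],
                regions = feats$regions, geneIds = mt$kept,
                regionLengths = feats$regionLengths)
  log <- logStage(log, "features", t0)

  t0 <- Sys.time()
  y <- stats::setNames(mt$summary$target, mt$kept)
  sp <- splitPlan(mt$kept, config$split, seed = ss$split)
  model <- trainConsecutive(config$model, feats, y, sp,
                            seed = ss$model, nRestarts = 2)
  ev <- evaluateModel(predictExpression(model, feats, idx = sp$test),
                      y[sp$test])
  metrics$test_r2 <- ev$r_squared
  metrics$test_f_pvalue <- ev$f_pvalue
  utils::write.table(model@history, file.path(dir, "history.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log <- logStage(log, "train", t0)

  t0 <- Sys.time()
  set.seed(ss$relevance)
  relGenes <- sample(mt$kept, min(config$relevance$nGenes,
                                  length(mt$kept)))
  inv <- function(p) invertTarget(p, orf[names(p)], mt$lambda,
                                  mt$lengthFit)
  rp <- relevanceProfiles(model, feats, window = config$relevance$window,
                          transform = inv, idx = relGenes)
  rp <- significantPositions(rp, config$relevance$cutoffSd)
  writeRelevanceTSV(rp, file.path(dir, "relevance.tsv"))
  log <- logStage(log, "relevance", t0)

  t0 <- Sys.time()
  wins <- extractWindows(rp, cohort)
  ms <- discoverMotifs(wins, config$motifs$identity,
                       config$motifs$minCluster,
                       config$motifs$maxShift, config$motifs$trimBits)
  writeMEME(ms, file.path(dir, "motifs.meme"))
  metrics$n_windows <- nrow(wins)
  metrics$n_motifs <- nMotifs(ms)
  log <- logStage(log, "motifs", t0)

  t0 <- Sys.time()
  medTpm <- stats::setNames(mt$summary$median_tpm, mt$kept)
  occ <- occurrenceMatrix(ms, relGenes)
  rules <- mineRules(occ, medTpm, config$rules$minGenes,
                     config$rules$maxSize)
  sig <- significantRules(rules, occ, config$rules$alpha,
                          config$rules$minGenes)
  utils::write.table(sig$rules, file.path(dir, "rules.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  metrics$n_significant_rules <- nrow(sig$rules)
  metrics$rule_coverage <- sig$coverage
  log <- logStage(log, "rules", t0)

  t0 <- Sys.time()
  set.seed(ss$swap)
  swapIds <- sample(mt$kept, min(config$swap$nGenes, length(mt$kept)))
  sc <- shuffleControl(model, cohort, feats, mt$lambda, mt$lengthFit,
                       genes = swapIds,
                       nPartners = config$swap$nPartners,
                       seed = ss$swap)
  metrics$swap_levene_p <- sc$levene_p
  metrics$swap_variance_ratio <- sc$variance_ratio
  log <- logStage(log, "swap", t0)

  t0 <- Sys.time()
  orth <- generateOrthologs(cohort,
                            nSpecies = config$orthologs$nSpecies,
                            regionRateCorrelation =
                              config$orthologs$correlation,
                            regions = config$orthologs$regions,
                            seed = ss$orthologs)
  rates <- regionRates(orth$alignments,
                       cutoff = config$orthologs$maskCutoff)
  cr <- correlateRegions(rates, "promoter", "cds")
  metrics$coevolution_r <- cr$r
  utils::write.table(data.frame(gene_id = rownames(rates), rates),
                     file.path(dir, "substitution_rates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log <- logStage(log, "coevo", t0)

  files <- list.files(dir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    config = list(seed = config$seed, nGenes = config$generator$nGenes,
                  nExperiments = config$nExperiments,
                  stageSeeds = ss),
    metrics = metrics, stages = log,
    files = lapply(files, function(f)
      list(path = sub(paste0("^", dir, "/?"), "", f),
           md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(metrics = metrics, manifest = manifest, dir = dir)
}

#' Write relevance profiles as tidy TSV
#'
#' @param profiles a [RelevanceProfileSet-class] with masks.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeRelevanceTSV <- function(profiles, path) {
  rows <- list()
  for (r in names(profiles@values)) {
    V <- profiles@values[[r]]
    M <- if (length(profiles@mask)) profiles@mask[[r]] else
      matrix(FALSE, nrow(V), ncol(V))
    rows[[r]] <- data.frame(
      gene_id = rep(profiles@geneIds, ncol(V)),
      region = r,
      position = rep(seq_len(ncol(V)), each = nrow(V)),
      relevance = as.numeric(V),
      significant = as.logical(M))
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialise and reload a pipeline configuration
#'
#' JSON round trip for [pipelineConfig()] objects; reloading reproduces
#' an equal configuration.
#'
#' @param config list from [pipelineConfig()].
#' @param path JSON file path.
#' @return `writePipelineConfig`: the path, invisibly;
#'   `readPipelineConfig`: the configuration list.
#' @export
writePipelineConfig <- function(config, path) {
  ## named atomic vectors become JSON objects (names kept) via as.list
  nameSafe <- function(x) {
    if (is.list(x)) return(lapply(x, nameSafe))
    if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
    x
  }
  jsonlite::write_json(nameSafe(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("regionLengths", "gc"))
    cfg$generator[[nm]] <- unlist(cfg$generator[[nm]])
  cfg$generator$ruleSizeProbs <- unlist(cfg$generator$ruleSizeProbs)
  cfg$split <- as.numeric(cfg$split)
  cfg
}
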