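## small shared fixtures; everything is generated in code

tinyCohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- syntheticConfig(nGenes = 120, nMotifs = 6, nRules = 8,
                             cdsCodonRange = c(60L, 120L),
                             adoptProbRange = c(0.15, 0.3))
      co <- generateGenome(cfg, seed = 101)
      co <- generateExpression(co, nExperiments = 20, seed = 102)
      cache <<- co
    }
    cache
  }
})

tinyModelSpec <- function(...) {
  args <- list(convFilters = c(4, 4, 6), kernels = c(6, 3, 3),
               pools = c(3, 2, 2), fcWidths = c(12, 8), dropout = 0,
               epochs = 3, patience = 3, batchSize = 32)
  args[names(list(...))] <- list(...)
  do.call(modelSpec, args)
}

truthOccurrence <- function(cohort) {
  ids <- geneIds(cohort)
  motifs <- names(grammarTruth(cohort)@motifs)
  occ <- matrix(FALSE, length(ids), length(motifs),
                dimnames = list(ids, motifs))
  pl <- plantedPositions(cohort)
  occ[cbind(pl$gene_id, pl$motif_id)] <- TRUE
  attr(occ, "regions") <- vapply(grammarTruth(cohort)@motifs, `[[`,
                                 "", "region")
  occ
}

randomOccurrence <- function(n, m, density = 0.3, seed = 1) {
  set.seed(seed)
  matrix(runif(n * m) < density, n, m,
         dimnames = list(sprintf("g%03d", 1:n), sprintf("m%02d", 1:m)))
}
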