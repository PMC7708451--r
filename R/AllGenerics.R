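#' @include AllClasses.R
NULL

#' Accessors for cohort, truth, model and motif objects
#'
#' `geneIds` returns gene identifiers; `regionSequences` the per-region
#' `DNAStringSet` list (or one region); `expressionMatrix` the genes x
#' experiments TPM matrix; `grammarTruth` the planted grammar;
#' `plantedPositions` the planted-instance table; `motifMatrices` the list
#' of probability matrices in a [MotifSet-class]; `nMotifs` its size;
#' `trainingHistory` the per-epoch MSE table of a [SeqExprModel-class].
#'
#' @param x the object.
#' @param region optional region name.
#' @return See individual descriptions.
#' @name accessors
#' @aliases geneIds regionSequences expressionMatrix grammarTruth
#'   plantedPositions motifMatrices nMotifs trainingHistory
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("regionSequences", function(x, region = NULL)
  standardGeneric("regionSequences"))
#' @rdname accessors
#' @export
setGeneric("expressionMatrix", function(x) standardGeneric("expressionMatrix"))
#' @rdname accessors
#' @export
setGeneric("grammarTruth", function(x) standardGeneric("grammarTruth"))
#' @rdname accessors
#' @export
setGeneric("plantedPositions", function(x) standardGeneric("plantedPositions"))
#' @rdname accessors
#' @export
setGeneric("motifMatrices", function(x) standardGeneric("motifMatrices"))
#' @rdname accessors
#' @export
setGeneric("nMotifs", function(x) standardGeneric("nMotifs"))
#' @rdname accessors
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' @rdname accessors
setMethod("geneIds", "SyntheticCohort", function(x) x@geneData$gene_id)
#' @rdname accessors
setMethod("regionSequences", "SyntheticCohort", function(x, region = NULL) {
  if (is.null(region)) x@regions else x@regions[[match.arg(region, names(x@regions))]]
})
#' @rdname accessors
setMethod("expressionMatrix", "SyntheticCohort", function(x) x@expression)
#' @rdname accessors
setMethod("grammarTruth", "SyntheticCohort", function(x) x@truth)
#' @rdname accessors
setMethod("plantedPositions", "SyntheticCohort", function(x) x@plantings)
#' @rdname accessors
setMethod("motifMatrices", "MotifSet", function(x)
  lapply(x@motifs, `[[`, "pwm"))
#' @rdname accessors
setMethod("nMotifs", "MotifSet", function(x) length(x@motifs))
#' @rdname accessors
setMethod("trainingHistory", "SeqExprModel", function(x) x@history)

setMethod("show", "GrammarTruth", function(object) {
  cat("GrammarTruth:", length(object@motifs), "planted motifs,",
      length(object@rules), "rules\n")
  cat(sprintf("  codon coupling %.2f, baseline %.2f log10, residual SD %.2f\n",
              object@codonCoupling, object@baselineLogExpr,
              object@noiseSdResidual))
  cat(sprintf("  %.0f%% of rules span >= 2 regions\n",
              100 * object@crossRegionFraction))
})

setMethod("show", "SyntheticCohort", function(object) {
  n <- nrow(object@geneData)
  cat("SyntheticCohort:", n, "genes; regions",
      paste(names(object@regions), collapse = "/"), "\n")
  if (length(object@expression))
    cat("  expression:", ncol(object@expression), "experiments (TPM)\n")
  else cat("  expression: not generated\n")
  cat("  planted instances:", nrow(object@plantings),
      "| seed:", object@seed, "\n")
})

setMethod("show", "SeqExprModel", function(object) {
  s <- object@spec
  cat("SeqExprModel: conv filters",
      paste(s$convFilters, collapse = "/"),
      "kernels", paste(s$kernels, collapse = "/"),
      "| FC", paste(s$fcWidths, collapse = "/"), "\n")
  if (nrow(object@history)) {
    best <- which.min(object@history$val_mse)
    cat(sprintf("  trained %d epochs; best validation MSE %.4f (epoch %d)\n",
                nrow(object@history), object@history$val_mse[best], best))
  } else cat("  untrained\n")
})

setMethod("show", "MotifSet", function(object) {
  cat("MotifSet:", length(object@motifs), "motifs (window",
      object@windowSize, "bp, identity cutoff",
      object@identityCutoff, ")\n")
  if (length(object@motifs)) {
    w <- vapply(object@motifs, function(m) ncol(m$pwm), 0L)
    reg <- table(vapply(object@motifs, `[[`, "", "region"))
    cat("  widths", min(w), "-", max(w), "| regions:",
        paste(names(reg), reg, sep = "=", collapse = " "), "\n")
  }
})

setMethod("show", "RelevanceProfileSet", function(object) {
  cat("RelevanceProfileSet:", length(object@geneIds), "genes,",
      "window", object@window, "bp\n")
  for (r in names(object@values)) {
    msk <- object@mask[[r]]
    cat(sprintf("  %s: %d bp%s\n", r, ncol(object@values[[r]]),
                if (length(msk)) sprintf(", mean %.1f significant bp/gene",
                                         mean(rowSums(msk))) else ""))
  }
})

#' Coerce a cohort to a SummarizedExperiment
#'
#' Packs the TPM matrix as the `"tpm"` assay with the per-gene metadata
#' (lengths, regulatory score, latent level) as row data.
#'
#' @param x a [SyntheticCohort-class] with generated expression.
#' @return a [SummarizedExperiment::SummarizedExperiment-class].
#' @export
setGeneric("asSummarizedExperiment", function(x)
  standardGeneric("asSummarizedExperiment"))

#' @rdname asSummarizedExperiment
setMethod("asSummarizedExperiment", "SyntheticCohort", function(x) {
  stopifnot(length(x@expression) > 0)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(tpm = x@expression),
    rowData = x@geneData)
})
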