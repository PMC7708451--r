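#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Planted regulatory grammar
#'
#' Ground truth emitted by [generateGenome()]: the planted position weight
#' matrices, the motif co-occurrence rules with their additive effects on
#' log10 expression, and the generator noise/coupling parameters.
#'
#' @slot motifs list; one element per planted motif with fields `id`,
#'   `region`, `pwm` (4 x w probability matrix, rows A/C/G/T), `consensus`
#'   and `threshold` (log-odds planting threshold; every planted instance
#'   scores at or above it).
#' @slot rules list; one element per planted rule with fields `id`,
#'   `motifs` (character vector of motif ids), `effect` (log10 units) and
#'   `adoptProb`.
#' @slot codonCoupling numeric in [0,1]; strength of the link between a
#'   gene's latent expression quantile and its codon-bias table mixture.
#' @slot baselineLogExpr numeric; baseline log10 expression.
#' @slot codonEffect numeric; additive log10 effect of the codon mixture
#'   weight on the latent level.
#' @slot noiseSdBetween numeric; median per-gene between-experiment noise
#'   SD (log10 units; per-gene SDs are drawn around it).
#' @slot noiseSdBetweenSpread numeric; lognormal spread of the per-gene
#'   noise SDs.
#' @slot noiseSdResidual numeric; SD of the sequence-independent residual
#'   on the latent log10 level.
#' @slot crossRegionFraction numeric; fraction of rules whose motifs span
#'   at least two regulatory regions.
#'
#' @exportClass GrammarTruth
setClass("GrammarTruth", representation(
  motifs = "list",
  rules = "list",
  codonCoupling = "numeric",
  codonEffect = "numeric",
  baselineLogExpr = "numeric",
  noiseSdBetween = "numeric",
  noiseSdBetweenSpread = "numeric",
  noiseSdResidual = "numeric",
  crossRegionFraction = "numeric"
))

setValidity("GrammarTruth", function(object) {
  msgs <- character()
  for (r in object@rules) {
    if (length(r$motifs) < 2)
      msgs <- c(msgs, sprintf("rule %s references < 2 motifs", r$id))
    if (!all(r$motifs %in% vapply(object@motifs, `[[`, "", "id")))
      msgs <- c(msgs, sprintf("rule %s references unknown motifs", r$id))
  }
  for (m in object@motifs) {
    if (!is.matrix(m$pwm) || nrow(m$pwm) != 4L)
      msgs <- c(msgs, sprintf("motif %s pwm is not a 4-row matrix", m$id))
    else if (any(abs(colSums(m$pwm) - 1) > 1e-8))
      msgs <- c(msgs, sprintf("motif %s pwm columns do not sum to 1", m$id))
  }
  if (length(msgs)) msgs else TRUE
})

#' Synthetic gene cohort with planted grammar
#'
#' Container produced by the synthetic generator: per-gene five-region
#' sequence decomposition (promoter, 5'UTR, CDS, 3'UTR, terminator), the
#' record of planted motif instances, the grammar truth, and (after
#' [generateExpression()]) a strictly positive genes x experiments
#' TPM matrix.
#'
#' @slot geneData `DataFrame` with one row per gene: `gene_id`, per-region
#'   lengths, the regulatory score (`reg_score`, log10 units), the latent
#'   codon mixture weight `codon_w`, and the latent log10 level once
#'   expression has been generated.
#' @slot regions named list of `DNAStringSet` (promoter, utr5, cds, utr3,
#'   terminator), each named by gene id.
#' @slot plantings `DataFrame` of planted instances: `gene_id`, `motif_id`,
#'   `region`, `start` (1-based within region), `sequence`.
#' @slot expression numeric matrix (genes x experiments, TPM units) or a
#'   0 x 0 matrix before expression has been generated.
#' @slot truth a [GrammarTruth-class] object.
#' @slot seed integer seed the cohort was generated from.
#'
#' @exportClass SyntheticCohort
setClass("SyntheticCohort", representation(
  geneData = "DataFrame",
  regions = "list",
  plantings = "DataFrame",
  expression = "matrix",
  truth = "GrammarTruth",
  seed = "integer"
))

setValidity("SyntheticCohort", function(object) {
  msgs <- character()
  need <- c("promoter", "utr5", "cds", "utr3", "terminator")
  if (!all(need %in% names(object@regions)))
    msgs <- c(msgs, "regions must contain promoter/utr5/cds/utr3/terminator")
  n <- nrow(object@geneData)
  for (nm in intersect(need, names(object@regions)))
    if (length(object@regions[[nm]]) != n)
      msgs <- c(msgs, sprintf("region %s has wrong length", nm))
  if (length(object@expression) && any(object@expression <= 0))
    msgs <- c(msgs, "expression matrix must be strictly positive")
  if (length(msgs)) msgs else TRUE
})

#' Trained sequence-to-expression network
#'
#' Handle for the convolutional + fully-connected regressor built by
#' [buildModel()] and fitted by [trainModel()]. Weights, the architecture
#' spec, feature standardisation constants and the per-epoch training
#' history are stored; use [predictExpression()] to score new inputs.
#'
#' @slot spec list; architecture and optimiser settings (see [modelSpec()]).
#' @slot weights list of weight matrices/vectors.
#' @slot norm list; input/target standardisation constants frozen on the
#'   training split.
#' @slot history data.frame with train/validation MSE per epoch.
#' @slot inputShape list describing the one-hot and numeric input dims.
#'
#' @exportClass SeqExprModel
setClass("SeqExprModel", representation(
  spec = "list",
  weights = "list",
  norm = "list",
  history = "data.frame",
  inputShape = "list"
))

#' Occlusion relevance profiles for a cohort
#'
#' Per-position occlusion relevance values, the cohort-level significance
#' masks, and the intact-input predictions they were scaled by.
#'
#' @slot values named list (per region) of genes x positions matrices of
#'   relevance values.
#' @slot mask named list (per region) of logical matrices, same shape;
#'   `TRUE` where |z| exceeds the cutoff (filled by
#'   [significantPositions()]).
#' @slot Y numeric; model prediction on the intact input, per gene, on the
#'   scale relevance was computed on.
#' @slot window integer occlusion window width (bp).
#' @slot flagged logical; genes where |Y| fell below the ratio guard and
#'   unscaled differences were reported instead.
#' @slot geneIds character.
#'
#' @exportClass RelevanceProfileSet
setClass("RelevanceProfileSet", representation(
  values = "list",
  mask = "list",
  Y = "numeric",
  window = "integer",
  flagged = "logical",
  geneIds = "character"
))

#' Discovered motif collection
#'
#' Motifs distilled from significant relevance windows: trimmed probability
#' matrices with per-column information content and their member windows.
#'
#' @slot motifs list; each element has `id`, `region`, `pwm` (4 x w), `ic`
#'   (bits per column) and `members` (`DataFrame` of gene_id, region,
#'   offset, sequence, relevance, shift).
#' @slot windowSize integer width of the source windows (bp).
#' @slot identityCutoff numeric clustering identity cutoff used.
#'
#' @exportClass MotifSet
setClass("MotifSet", representation(
  motifs = "list",
  windowSize = "integer",
  identityCutoff = "numeric"
))

setValidity("MotifSet", function(object) {
  msgs <- character()
  for (m in object@motifs) {
    if (any(abs(colSums(m$pwm) - 1) > 1e-6))
      msgs <- c(msgs, sprintf("motif %s columns do not sum to 1", m$id))
    if (any(m$ic < 0.2 - 1e-9) && ncol(m$pwm) > 0 &&
        (m$ic[1] < 0.2 - 1e-9 || m$ic[length(m$ic)] < 0.2 - 1e-9))
      msgs <- c(msgs, sprintf("motif %s has an untrimmed terminal column", m$id))
  }
  if (length(msgs)) msgs else TRUE
})
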