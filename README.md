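# regGrammar

Sequence-to-expression modeling and regulatory-grammar discovery for
gene regulatory structures.

## The problem

In microbial and model eukaryote transcriptomes, a gene's expression
varies far less across conditions than expression varies between
genes: the median mRNA level is, to a large extent, a property of the
gene's DNA. `regGrammar` treats the complete gene regulatory structure
— promoter, 5'UTR, coding sequence (as codon probabilities), 3'UTR and
terminator — as one unit and provides the full analysis chain around a
convolutional neural network regressor:

* **Expression targets.** TPM normalisation
  (`tpm_i = (c_i / l_i) / Σ_j (c_j / l_j) × 10⁶`), abundance
  (median TPM ≥ 5) and variability (RSD = σ/μ < 1) filters, Box-Cox
  transform `(x^λ − 1)/λ` with maximum-likelihood λ frozen on the
  training split, and removal of gene-length bias by OLS
  residualisation on log10 ORF length.
* **Model.** A CNN-FC regressor written from scratch (three conv
  blocks over one-hot DNA, two fully connected layers after joining
  64 codon probabilities and 8 mRNA-stability covariates; ReLU, MSE
  loss, Adam, dropout/batch-norm, early stopping on validation MSE),
  with `R² = 1 − SS_residual/SS_total` and an F-test for evaluation,
  plus shallow k-mer baselines (ridge/lasso/elastic-net/RF/SVM/kNN).
* **Interpretation.** Occlusion relevance
  `(Y − Y_occluded)/Y` for sliding 10-bp windows, cohort-level ±2 SD
  significance masks, consensus clustering (PAM, 50× subsampling of
  80%, Pearson distance) of relevance profiles.
* **Motifs.** Relevant windows are clustered by greedy sequence
  identity (cutoffs 0.8/0.85/0.9, min cluster 5), summarised as
  position weight matrices, trimmed below 0.2 bits, and compared by
  permutation-tested column correlation; minimal MEME text I/O.
* **Rules.** FP-growth frequent-itemset mining of the gene × motif
  occurrence matrix (2-6 motifs, support ≥ 3 genes), support /
  confidence / lift, chi-squared significance with Benjamini-Hochberg
  control, expression SNR (μ/σ) contrasts between single motifs and
  co-occurrence rules, and motif-repurposing fold-range analyses.
* **Engineering.** Exhaustive promoter-half × terminator-half swap
  predictions (n genes → n² constructs, streamed lazily), fold changes
  on the TPM scale, and a dinucleotide-preserving (Altschul-Erickson)
  shuffle null with Levene's test.
* **Coevolution.** JC69 substitution rates
  `d = −(3/4) ln(1 − 4p/3)` per region from ortholog alignments
  (confidence-masked at ≤ 0.2) and their correlation across regions.
* **Synthetic genomes.** A generator that plants a known regulatory
  grammar — motifs, co-occurrence rules with log10 effects, codon
  usage coupled to expression, correlated per-region substitution
  rates — so every stage above is testable against ground truth.

## Worked example

```r
library(regGrammar)

cohort <- generateGenome(syntheticConfig(nGenes = 800), seed = 1)
cohort <- generateExpression(cohort, nExperiments = 60, seed = 2)
cohort
#> SyntheticCohort: 800 genes; regions promoter/utr5/cds/utr3/terminator
#>   expression: 60 experiments (TPM)
#>   planted instances: 4446 | seed: 1

tpm <- expressionMatrix(cohort)
mean(rsdVec(tpm) < 1)          # fraction of stable genes
#> [1] 0.86875
orf <- setNames(cohort@geneData$len_cds, geneIds(cohort))
mt <- medianTarget(tpm, orf)   # TPM -> filter -> Box-Cox -> length-correct
length(mt$kept); round(mt$lambda, 2)
#> [1] 680
#> [1] -0.11

feats <- cohortFeatures(cohort)
keep  <- match(mt$kept, feats$geneIds)
feats <- list(seq = feats$seq[keep, , , drop = FALSE],
              num = feats$num[keep, , drop = FALSE],
              regions = feats$regions, geneIds = mt$kept,
              regionLengths = feats$regionLengths)
y  <- setNames(mt$summary$target, mt$kept)
sp <- splitPlan(mt$kept, seed = 3)

# sequence branch first, then joint fine-tuning (validation-selected)
model <- trainConsecutive(pipelineConfig()$model, feats, y, sp, seed = 4)
ev <- evaluateModel(predictExpression(model, feats, idx = sp$test),
                    y[sp$test])
round(ev$r_squared, 2)
#> [1] 0.54
```

The fitted model then feeds the downstream stages
(`relevanceProfiles()` → `significantPositions()` →
`extractWindows()` → `discoverMotifs()` → `occurrenceMatrix()` →
`mineRules()` → `significantRules()`, and `predictConstructs()` /
`shuffleControl()` for swap engineering). `runPipeline()` executes the
whole chain on a synthetic cohort and writes TSV/FASTA/MEME/JSON
artifacts plus a checksummed manifest.

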