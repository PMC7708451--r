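Package: regGrammar
Title: Sequence-to-Expression Modeling and Regulatory Grammar Discovery
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts mRNA abundance from the complete gene regulatory
    structure (promoter, 5'UTR, coding sequence, 3'UTR and terminator)
    with a convolutional-plus-dense neural network trained on one-hot
    encoded DNA, codon probabilities and mRNA stability covariates.
    Interprets trained models by occlusion relevance profiling, distills
    relevant windows into position weight matrices, mines motif
    co-occurrence rules by frequent-itemset analysis, designs in-silico
    promoter-terminator swaps with dinucleotide-preserving shuffle
    controls, and correlates per-region substitution rates across
    ortholog alignments. Ships a synthetic-genome generator with a
    planted regulatory grammar so the whole pipeline is testable
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    cluster,
    glmnet,
    randomForest,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    MASS,
    car,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: GeneExpression, Regression, MotifDiscovery, Transcriptomics
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'coevolution.R'
    'expression.R'
    'features.R'
    'io.R'
    'models.R'
    'motifs.R'
    'regGrammar-package.R'
    'relevance.R'
    'rules.R'
    'swap.R'
    'synthetic.R'
    'workflow.R'
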