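#' Write motifs in minimal MEME format
#'
#' @param motifs a [MotifSet-class] or a list of motifs with `id` and
#'   `pwm`.
#' @param path output file.
#' @param background named A/C/G/T frequencies.
#' @return invisibly, the path.
#' @export
writeMEME <- function(motifs, path,
                      background = c(A = 0.25, C = 0.25,
                                     G = 0.25, T = 0.25)) {
  ml <- if (is(motifs, "MotifSet")) motifs@motifs else motifs
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: +", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       background["A"], background["C"],
                       background["G"], background["T"]), ""), con)
  for (m in ml) {
    w <- ncol(m$pwm)
    nsites <- if (!is.null(m$members)) nrow(m$members) else 20L
    writeLines(sprintf("MOTIF %s", m$id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0", w,
      nsites), con)
    for (j in seq_len(w))
      writeLines(sprintf(" %.6f %.6f %.6f %.6f", m$pwm["A", j],
                         m$pwm["C", j], m$pwm["G", j], m$pwm["T", j]),
                 con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a minimal MEME motif file
#'
#' @param path MEME text file (version 4 dialect as written by
#'   [writeMEME()]).
#' @return list of motifs with `id` and `pwm`.
#' @export
readMEME <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1
  while (i <= length(lines)) {
    if (grepl("^MOTIF\\s+", lines[i])) {
      id <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
      j <- i + 1
      while (j <= length(lines) &&
             !grepl("letter-probability matrix", lines[j])) j <- j + 1
      w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
      rows <- lines[(j + 1):(j + w)]
      pwm <- t(vapply(rows, function(r)
        as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4)))
      pwm <- t(pwm)
      dimnames(pwm) <- list(c("A", "C", "G", "T"), NULL)
      out[[id]] <- list(id = id, pwm = pwm)
      i <- j + w
    }
    i <- i + 1
  }
  out
}

#' Write a cohort to plain-text files
#'
#' One FASTA per region (record id = gene id), a TSV gene table, the
#' TPM matrix as TSV, the grammar truth as JSON, and the planted PWMs
#' in minimal MEME format.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (r in names(cohort@regions)) {
    p <- file.path(dir, paste0(r, ".fasta"))
    Biostrings::writeXStringSet(cohort@regions[[r]], p)
    paths <- c(paths, p)
  }
  gt <- file.path(dir, "genes.tsv")
  utils::write.table(as.data.frame(cohort@geneData), gt, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths <- c(paths, gt)
  if (length(cohort@expression)) {
    et <- file.path(dir, "expression_tpm.tsv")
    utils::write.table(
      data.frame(gene_id = rownames(cohort@expression),
                 cohort@expression, check.names = FALSE),
      et, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, et)
  }
  tr <- cohort@truth
  truthList <- list(
    codon_coupling = tr@codonCoupling,
    codon_effect = tr@codonEffect,
    baseline_log_expr = tr@baselineLogExpr,
    noise_sd_between = tr@noiseSdBetween,
    noise_sd_residual = tr@noiseSdResidual,
    cross_region_fraction = tr@crossRegionFraction,
    rules = lapply(tr@rules, function(r)
      list(id = r$id, motifs = r$motifs, effect = r$effect,
           adopt_prob = r$adoptProb)),
    motifs = lapply(tr@motifs, function(m)
      list(id = m$id, region = m$region, consensus = m$consensus,
           threshold = m$threshold)))
  tj <- file.path(dir, "truth.json")
  jsonlite::write_json(truthList, tj, auto_unbox = TRUE, digits = NA)
  mm <- file.path(dir, "planted_motifs.meme")
  writeMEME(tr@motifs, mm)
  pl <- file.path(dir, "plantings.tsv")
  utils::write.table(as.data.frame(cohort@plantings), pl, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(paths, tj, mm, pl))
}

#' Read a cohort's sequences and expression back from disk
#'
#' Companion reader for [writeCohort()] covering the parts needed to
#' rerun the pipeline on exported data (sequences, gene table,
#' expression).
#'
#' @param dir directory written by [writeCohort()].
#' @return list with `regions` (named list of `DNAStringSet`), `genes`
#'   (data.frame) and `expression` (matrix or NULL).
#' @export
readCohortData <- function(dir) {
  regions <- list()
  for (r in c("promoter", "utr5", "cds", "utr3", "terminator")) {
    p <- file.path(dir, paste0(r, ".fasta"))
    if (file.exists(p)) regions[[r]] <- Biostrings::readDNAStringSet(p)
  }
  genes <- utils::read.delim(file.path(dir, "genes.tsv"))
  ep <- file.path(dir, "expression_tpm.tsv")
  expression <- NULL
  if (file.exists(ep)) {
    df <- utils::read.delim(ep, check.names = FALSE)
    expression <- as.matrix(df[, -1, drop = FALSE])
    rownames(expression) <- df$gene_id
  }
  list(regions = regions, genes = genes, expression = expression)
}
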