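#' Compute an aggregated pathway-activity score
#'
#' For each sample the score is
#' \deqn{\mathrm{score}_s = \sum_{i \in \mathrm{signature}} z_{is} / \sqrt{n},}
#' the sum of the signature genes' z-scored expression divided by the
#' square root of the number of genes aggregated. With the 10-gene MAPK
#' signature this is the MAPK pathway activity score (MPAS). The score is
#' a relative, within-cohort quantity: its absolute level depends on the
#' assay and normalization, so scores are compared between samples of the
#' same cohort, not across platforms.
#'
#' When some signature genes are absent from the matrix (targeted panels
#' often carry only 5-6 of the 10 genes), \code{missing = "subset"}
#' aggregates the genes present and re-normalizes by \eqn{\sqrt{n_{used}}},
#' recording \code{nGenesUsed} and warning; the default is a hard error.
#'
#' @param m an [MpasExperiment-class] in state \code{"zscored"}.
#' @param sig a [GeneSignature-class].
#' @param missing \code{"error"} (default) or \code{"subset"}.
#' @return A [ScoreTable-class] with one score per sample.
#' @examples
#' z <- matrix(rep(c(-1, 1), each = 10), 10, 2, byrow = FALSE)
#' dimnames(z) <- list(mpasSignature()@genes, c("lo", "hi"))
#' m <- mpasExperiment(z, platform = "rnaseq", state = "zscored")
#' scores(computeScore(m, mpasSignature()))   # -sqrt(10), +sqrt(10)
#' @export
computeScore <- function(m, sig, missing = c("error", "subset")) {
  missing <- match.arg(missing)
  stopifnot(is(m, "MpasExperiment"), is(sig, "GeneSignature"))
  .requireState(m, "zscored", "computeScore")
  z <- exprValues(m)
  present <- intersect(sig@genes, rownames(z))
  absent <- setdiff(sig@genes, rownames(z))
  if (length(absent) && missing == "error")
    stop("signature gene(s) absent: ", paste(absent, collapse = ", "))
  if (length(present) == 0L)
    stop("no signature genes present in the matrix")
  if (length(absent))
    warning(sprintf("scoring with %d of %d '%s' genes (absent: %s)",
                    length(present), length(sig@genes), sig@name,
                    paste(absent, collapse = ", ")))
  s <- colSums(z[present, , drop = FALSE]) / sqrt(length(present))
  scoreTable(colnames(z), s, sig@name, length(present))
}

#' Compute the housekeeping negative-control (CTRL) score
#'
#' Identical aggregation to [computeScore()] over the fixed 4-gene
#' housekeeping set (MLH1, SMARCA4, U2AF, CLTC). Because these genes do
#' not respond to MAPK signalling, the CTRL score carries the scoring
#' pipeline's noise but no pathway signal, and serves as the
#' chance-level reference in predictor comparisons.
#'
#' @inheritParams computeScore
#' @return A [ScoreTable-class].
#' @export
computeCtrlScore <- function(m, missing = c("error", "subset")) {
  computeScore(m, ctrlSignature(), missing = match.arg(missing))
}

#' Recenter scores against a reference cohort
#'
#' Subtracts the reference cohort's mean score, so 0 represents the
#' average sample of the reference. Pairwise score differences are
#' unchanged.
#'
#' @param t a [ScoreTable-class] to recenter.
#' @param reference a non-empty [ScoreTable-class] providing the mean
#'   (may be \code{t} itself).
#' @return A recentered [ScoreTable-class].
#' @export
recenterScores <- function(t, reference = t) {
  stopifnot(is(t, "ScoreTable"), is(reference, "ScoreTable"))
  if (length(reference@score) == 0L) stop("reference is empty")
  scoreTable(t@sampleIds, t@score - mean(reference@score),
             t@signatureName, t@nGenesUsed)
}

#' Write a ScoreTable to CSV
#' @param t a [ScoreTable-class].
#' @param path output path.
#' @param comment optional provenance lines written as \code{#}-comments.
#' @return \code{path}, invisibly.
#' @export
writeScores <- function(t, path, comment = NULL) {
  stopifnot(is(t, "ScoreTable"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(as.data.frame(t), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Score an expression matrix end to end
#'
#' Convenience wrapper running the platform-appropriate processing chain
#' and scoring: for \code{"panel"} data, background flooring,
#' housekeeping normalization, log2 and gene z-scoring; for
#' \code{"rnaseq"}, log2 and z-scoring. Returns both the pathway and the
#' CTRL score.
#'
#' @param m an [MpasExperiment-class] in state \code{"raw"}.
#' @param sig pathway [GeneSignature-class]; default [mpasSignature()].
#' @param housekeeping housekeeping symbols for panel normalization and
#'   the CTRL score; default the [ctrlSignature()] genes.
#' @param negativeControlGenes panel negative-control symbols (ignored
#'   for rnaseq).
#' @param missing passed to [computeScore()].
#' @param zeroVariance passed to [zscoreGenes()].
#' @return list with elements \code{pathway} and \code{ctrl}
#'   ([ScoreTable-class]) and \code{zscored} (the processed matrix).
#' @export
scoreExpression <- function(m, sig = mpasSignature(),
                            housekeeping = ctrlSignature()@genes,
                            negativeControlGenes = character(),
                            missing = "error", zeroVariance = "error") {
  stopifnot(is(m, "MpasExperiment"))
  if (exprPlatform(m) == "panel") {
    m <- filterBackground(m, negativeControlGenes)
    m <- normalizeHousekeeping(m, housekeeping)
  }
  z <- zscoreGenes(logTransform(m), zeroVariance = zeroVariance)
  list(pathway = computeScore(z, sig, missing = missing),
       ctrl = computeScore(z, geneSignature("CTRL", housekeeping),
                           missing = missing),
       zscored = z)
}
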