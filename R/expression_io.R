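#' Read an expression matrix from TSV/CSV
#'
#' Expects a header row of sample identifiers, gene symbols in the first
#' column and a numeric body. Gene symbols are upper-cased; duplicate
#' gene rows are a hard error (no silent averaging).
#'
#' @param path file path.
#' @param format \code{"tsv"} or \code{"csv"}; default guessed from the
#'   file extension.
#' @param platform \code{"panel"} or \code{"rnaseq"}.
#' @return An [MpasExperiment-class] in state \code{"raw"}.
#' @seealso [writeExpression()]
#' @export
readExpression <- function(path, format = c("tsv", "csv"),
                           platform = c("panel", "rnaseq")) {
  if (missing(format)) {
    format <- if (tolower(tools::file_ext(path)) == "csv") "csv" else "tsv"
  } else format <- match.arg(format)
  platform <- match.arg(platform)
  if (!file.exists(path)) stop("expression file not found: ", path)
  sep <- if (format == "tsv") "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, comment.char = "#",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expression file needs a gene column and >= 1 sample")
  genes <- toupper(raw[[1L]])
  if (anyDuplicated(genes))
    stop("duplicate gene row(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  body <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                 dimnames = list(genes, colnames(body))))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value at gene '%s', sample '%s'",
                 genes[bad[1L]], colnames(num)[bad[2L]]))
  }
  mpasExperiment(num, platform = platform, state = "raw")
}

#' Write an expression matrix to TSV/CSV
#'
#' @param m an [MpasExperiment-class].
#' @param path output file path.
#' @param format \code{"tsv"} or \code{"csv"}.
#' @param comment optional provenance lines written as leading
#'   \code{#}-comments.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(m, path, format = c("tsv", "csv"),
                            comment = NULL) {
  format <- match.arg(format)
  stopifnot(is(m, "MpasExperiment"))
  sep <- if (format == "tsv") "\t" else ","
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  v <- exprValues(m)
  writeLines(paste(c("gene", colnames(v)), collapse = sep), con)
  utils::write.table(
    data.frame(gene = rownames(v), v, check.names = FALSE),
    con, sep = sep, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Floor panel counts at the per-sample background level
#'
#' For gene panels, raw counts below background are not quantitative.
#' The per-sample background is \code{max(10, geometric mean of the
#' negative-control gene counts in that sample)}; counts below it are
#' floored to it (the matrix keeps its shape), and the negative-control
#' rows are dropped from the output. When no negative-control gene is
#' present the fixed floor 10 is used with a warning.
#'
#' @param m an [MpasExperiment-class], platform \code{"panel"}, state
#'   \code{"raw"}.
#' @param negativeControlGenes character vector of control gene symbols.
#' @return The floored matrix in state \code{"background_filtered"}.
#' @export
filterBackground <- function(m, negativeControlGenes) {
  stopifnot(is(m, "MpasExperiment"))
  if (exprPlatform(m) != "panel")
    stop("background filtering applies to platform 'panel' only")
  .requireState(m, "raw", "filterBackground")
  v <- exprValues(m)
  if (any(v < 0)) stop("panel counts must be >= 0")
  ctrl <- intersect(toupper(negativeControlGenes), rownames(v))
  if (length(ctrl) == 0L) {
    warning("no negative-control genes found; using fixed floor 10")
    floor_s <- rep(10, ncol(v))
  } else {
    floor_s <- pmax(10, apply(v[ctrl, , drop = FALSE], 2L, geomean))
  }
  keep <- setdiff(rownames(v), ctrl)
  out <- v[keep, , drop = FALSE]
  out <- pmax(out, matrix(floor_s, nrow(out), ncol(out), byrow = TRUE))
  .advanceState(m, out, "background_filtered")
}

#' Normalize panel samples by housekeeping-gene content
#'
#' Standard panel practice: each sample is scaled by
#' \eqn{f_s = G / g_s}, where \eqn{g_s} is the geometric mean of the
#' housekeeping-gene counts in sample \eqn{s} and \eqn{G} the geometric
#' mean of housekeeping counts over the whole matrix, so that after
#' scaling every sample carries the same housekeeping content.
#'
#' @param m an [MpasExperiment-class], platform \code{"panel"}, state
#'   \code{"background_filtered"}.
#' @param housekeeping character vector of housekeeping gene symbols; all
#'   must be present.
#' @return The scaled matrix in state \code{"normalized"}.
#' @export
normalizeHousekeeping <- function(m, housekeeping) {
  stopifnot(is(m, "MpasExperiment"))
  if (exprPlatform(m) != "panel")
    stop("housekeeping normalization applies to platform 'panel' only")
  .requireState(m, "background_filtered", "normalizeHousekeeping")
  v <- exprValues(m)
  hk <- toupper(housekeeping)
  missing <- setdiff(hk, rownames(v))
  if (length(missing))
    stop("housekeeping gene(s) absent: ", paste(missing, collapse = ", "))
  hkv <- v[hk, , drop = FALSE]
  if (any(hkv == 0))
    stop("zero housekeeping count; run filterBackground first")
  g_s <- apply(hkv, 2L, geomean)
  G <- geomean(as.vector(hkv))
  f_s <- G / g_s
  .advanceState(m, sweep(v, 2L, f_s, `*`), "normalized")
}

#' Log-transform expression values
#'
#' Applies \code{log2(x + 1)}, a rank-preserving variance-stabilizing
#' transform appropriate for count-scale data.
#'
#' @param m an [MpasExperiment-class] in state \code{"normalized"}
#'   (panel) or \code{"raw"} (rnaseq).
#' @return The transformed matrix in state \code{"log_transformed"}.
#' @export
logTransform <- function(m) {
  stopifnot(is(m, "MpasExperiment"))
  allowed <- if (exprPlatform(m) == "rnaseq") c("raw", "normalized")
             else "normalized"
  .requireState(m, allowed, "logTransform")
  v <- exprValues(m)
  if (any(v < 0)) stop("log transform requires non-negative values")
  .advanceState(m, log2(v + 1), "log_transformed")
}

#' Z-score each gene across samples
#'
#' Per gene, \eqn{z = (x - \bar{x}) / \sigma} with the population
#' (divisor-N) standard deviation, so a two-sample cohort yields exactly
#' z = -1/+1 per gene. Each output gene row then has mean 0 and
#' (population) sd 1.
#'
#' @param m an [MpasExperiment-class] in state \code{"log_transformed"}
#'   (or \code{"normalized"} for rnaseq data z-scored without a log
#'   step); at least 2 samples.
#' @param zeroVariance \code{"error"} (default) or \code{"zero"}: a
#'   constant gene either aborts or becomes a row of zeros with a
#'   warning.
#' @return The z-scored matrix in state \code{"zscored"}.
#' @export
zscoreGenes <- function(m, zeroVariance = c("error", "zero")) {
  zeroVariance <- match.arg(zeroVariance)
  stopifnot(is(m, "MpasExperiment"))
  allowed <- if (exprPlatform(m) == "rnaseq")
    c("normalized", "log_transformed") else "log_transformed"
  .requireState(m, allowed, "zscoreGenes")
  v <- exprValues(m)
  if (ncol(v) < 2L) stop("z-scoring requires >= 2 samples")
  mu <- rowMeans(v)
  sdv <- sqrt(rowMeans((v - mu)^2))
  flat <- sdv == 0
  if (any(flat)) {
    if (zeroVariance == "error")
      stop("zero-variance gene(s): ",
           paste(rownames(v)[flat], collapse = ", "))
    warning(sum(flat), " zero-variance gene(s) set to 0")
    sdv[flat] <- 1
  }
  z <- (v - mu) / sdv
  z[flat, ] <- 0
  .advanceState(m, z, "zscored")
}

#' Read a clinical table from CSV
#'
#' Columns: \code{sample_id}, \code{time}, \code{event} (0/1), then
#' arbitrary covariate columns.
#'
#' @param path CSV file path (leading \code{#} lines are skipped).
#' @return A [ClinicalTable-class].
#' @export
readClinical <- function(path) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  d <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                       stringsAsFactors = FALSE)
  clinicalTable(d)
}

#' Write a clinical table to CSV
#' @param tbl a [ClinicalTable-class].
#' @param path output path.
#' @param comment optional provenance lines written as \code{#}-comments.
#' @return \code{path}, invisibly.
#' @export
writeClinical <- function(tbl, path, comment = NULL) {
  stopifnot(is(tbl, "ClinicalTable"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(clinicalData(tbl), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
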