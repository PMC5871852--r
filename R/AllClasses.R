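#' @import methods
#' @importFrom S4Vectors SimpleList DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
NULL

.EXPR_STATES <- c("raw", "background_filtered", "normalized",
                  "log_transformed", "zscored")
.EXPR_PLATFORMS <- c("panel", "rnaseq")

#' MpasExperiment: an expression matrix with platform and processing state
#'
#' Extends \linkS4class{SummarizedExperiment} with two bookkeeping slots:
#' the assay platform (\code{"panel"} for raw-count gene panels,
#' \code{"rnaseq"} for sequencing-style normalized values) and the
#' processing \code{state}. States advance monotonically along
#' \code{raw -> background_filtered -> normalized -> log_transformed ->
#' zscored}; each processing step checks that its input is in an
#' admissible state, so out-of-order pipelines fail early rather than
#' silently producing mis-scaled scores.
#'
#' Rows are genes (symbols upper-cased, unique), columns are samples
#' (unique). The single assay \code{"exprs"} holds the values.
#'
#' @slot platform character, one of \code{"panel"}, \code{"rnaseq"}.
#' @slot state character, one of the five processing states above.
#'
#' @seealso [readExpression()], [filterBackground()],
#'   [normalizeHousekeeping()], [logTransform()], [zscoreGenes()]
#' @export
setClass("MpasExperiment",
         contains = "SummarizedExperiment",
         slots = c(platform = "character", state = "character"))

setValidity("MpasExperiment", function(object) {
  msg <- character()
  if (length(object@platform) != 1L || !object@platform %in% .EXPR_PLATFORMS)
    msg <- c(msg, sprintf("platform must be one of: %s",
                          paste(.EXPR_PLATFORMS, collapse = ", ")))
  if (length(object@state) != 1L || !object@state %in% .EXPR_STATES)
    msg <- c(msg, sprintf("state must be one of: %s",
                          paste(.EXPR_STATES, collapse = ", ")))
  gid <- rownames(object)
  sid <- colnames(object)
  if (is.null(gid) || anyNA(gid) || any(gid == ""))
    msg <- c(msg, "gene ids (rownames) must be present and non-empty")
  else if (anyDuplicated(toupper(gid)))
    msg <- c(msg, "duplicate gene ids after case normalization")
  if (is.null(sid) || anyNA(sid))
    msg <- c(msg, "sample ids (colnames) must be present")
  else if (anyDuplicated(sid))
    msg <- c(msg, "duplicate sample ids")
  if (length(msg)) msg else TRUE
})

#' Construct an MpasExperiment from a numeric matrix
#'
#' @param values numeric matrix, genes in rows (rownames = symbols),
#'   samples in columns (colnames = sample ids).
#' @param platform \code{"panel"} (raw counts, non-negative) or
#'   \code{"rnaseq"}.
#' @param state processing state; defaults to \code{"raw"}.
#' @return An [MpasExperiment-class] object. Gene symbols are upper-cased.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(c("DUSP6", "ETV4", "MLH1"),
#'                                        c("s1", "s2")))
#' mpasExperiment(m, platform = "panel")
#' @export
mpasExperiment <- function(values, platform = c("panel", "rnaseq"),
                           state = "raw") {
  platform <- match.arg(platform)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene rownames and sample colnames")
  rownames(values) <- toupper(rownames(values))
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (platform == "panel" && state == "raw" && any(values < 0))
    stop("panel raw counts must be non-negative")
  se <- SummarizedExperiment(assays = SimpleList(exprs = values))
  new("MpasExperiment", se, platform = platform, state = state)
}

#' @describeIn mpasExperiment Values of the single expression assay.
#' @param x an \code{MpasExperiment}.
#' @export
exprValues <- function(x) {
  stopifnot(is(x, "MpasExperiment"))
  assay(x, "exprs")
}

#' @describeIn mpasExperiment Assay platform (\code{"panel"}/\code{"rnaseq"}).
#' @export
exprPlatform <- function(x) x@platform

#' @describeIn mpasExperiment Current processing state.
#' @export
exprState <- function(x) x@state

# replace assay values / advance state, preserving dimnames
.advanceState <- function(x, values, state) {
  from <- match(x@state, .EXPR_STATES)
  to <- match(state, .EXPR_STATES)
  if (is.na(to) || to <= from)
    stop(sprintf("cannot move state '%s' -> '%s': transitions are monotone",
                 x@state, state))
  mpasExperiment(values, platform = x@platform, state = state)
}

.requireState <- function(x, allowed, op) {
  if (!x@state %in% allowed)
    stop(sprintf("%s requires state in {%s}; got '%s'",
                 op, paste(allowed, collapse = ", "), x@state))
  invisible(x)
}

setMethod("show", "MpasExperiment", function(object) {
  cat(sprintf("MpasExperiment: %d genes x %d samples [platform=%s, state=%s]\n",
              nrow(object), ncol(object), object@platform, object@state))
  callNextMethod()
})

#' GeneSignature: a named gene set
#'
#' Holds the gene symbols of an aggregate expression signature. The
#' effective set size \code{n} enters the score denominator
#' \eqn{\sqrt{n}}.
#'
#' @slot name signature label.
#' @slot genes unique upper-cased gene symbols, length >= 1.
#' @seealso [mpasSignature()], [ctrlSignature()], [computeScore()]
#' @export
setClass("GeneSignature",
         slots = c(name = "character", genes = "character"))

setValidity("GeneSignature", function(object) {
  msg <- character()
  if (length(object@name) != 1L || is.na(object@name))
    msg <- c(msg, "name must be a single string")
  if (length(object@genes) < 1L)
    msg <- c(msg, "signature must contain at least one gene")
  if (anyDuplicated(toupper(object@genes)))
    msg <- c(msg, "signature genes must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSignature
#' @param name signature label.
#' @param genes character vector of gene symbols (case-insensitive).
#' @return A [GeneSignature-class].
#' @export
geneSignature <- function(name, genes) {
  new("GeneSignature", name = name, genes = toupper(as.character(genes)))
}

setMethod("show", "GeneSignature", function(object) {
  cat(sprintf("GeneSignature '%s' (n = %d): %s\n", object@name,
              length(object@genes), paste(object@genes, collapse = ", ")))
})

#' ScoreTable: per-sample aggregated pathway-activity scores
#'
#' One score per sample, produced by [computeScore()] or
#' [computeCtrlScore()]. When computed from a matrix z-scored across the
#' full cohort, the scores sum to zero by construction.
#'
#' @slot sampleIds sample identifiers.
#' @slot score numeric score per sample.
#' @slot signatureName label of the signature used.
#' @slot nGenesUsed number of signature genes actually aggregated.
#' @export
setClass("ScoreTable",
         slots = c(sampleIds = "character", score = "numeric",
                   signatureName = "character", nGenesUsed = "integer"))

setValidity("ScoreTable", function(object) {
  msg <- character()
  if (length(object@sampleIds) != length(object@score))
    msg <- c(msg, "one score per sample required")
  if (anyDuplicated(object@sampleIds))
    msg <- c(msg, "duplicate sample ids")
  if (length(object@nGenesUsed) != 1L || object@nGenesUsed < 1L)
    msg <- c(msg, "nGenesUsed must be a single positive integer")
  if (length(msg)) msg else TRUE
})

scoreTable <- function(sampleIds, score, signatureName, nGenesUsed) {
  new("ScoreTable", sampleIds = as.character(sampleIds),
      score = as.numeric(score), signatureName = signatureName,
      nGenesUsed = as.integer(nGenesUsed))
}

setMethod("show", "ScoreTable", function(object) {
  cat(sprintf("ScoreTable '%s': %d samples, %d genes aggregated\n",
              object@signatureName, length(object@score),
              object@nGenesUsed))
  print(utils::head(data.frame(sample_id = object@sampleIds,
                               score = object@score), 6))
  if (length(object@score) > 6) cat("...\n")
})

#' @describeIn ScoreTable-class numeric scores, named by sample id.
#' @param x a \code{ScoreTable}.
#' @export
scores <- function(x) {
  stopifnot(is(x, "ScoreTable"))
  stats::setNames(x@score, x@sampleIds)
}

#' @describeIn ScoreTable-class number of genes aggregated.
#' @export
nGenesUsed <- function(x) x@nGenesUsed

#' Coerce a ScoreTable to data.frame
#' @param x a ScoreTable.
#' @param ... ignored.
#' @export
as.data.frame.ScoreTable <- function(x, ...) {
  data.frame(sample_id = x@sampleIds, score = x@score,
             signature_name = x@signatureName,
             n_genes_used = x@nGenesUsed,
             stringsAsFactors = FALSE)
}

#' DoseResponseSet: viability of one cell line over a dose grid
#'
#' Viabilities are fractions relative to the vehicle control after day-0
#' correction: 1 is vehicle-level growth, 0 is stasis (day-0 level) and
#' negative values represent net cell death. A vehicle point at dose 0 is
#' allowed; positive doses must be strictly increasing.
#'
#' @slot lineId cell-line identifier.
#' @slot doses concentrations in uM, ascending; first may be 0 (vehicle).
#' @slot viability matrix, doses x replicates.
#' @slot day0Corrected logical flag.
#' @export
setClass("DoseResponseSet",
         slots = c(lineId = "character", doses = "numeric",
                   viability = "matrix", day0Corrected = "logical"))

setValidity("DoseResponseSet", function(object) {
  msg <- character()
  d <- object@doses
  if (any(d < 0)) msg <- c(msg, "doses must be >= 0")
  pos <- d[d > 0]
  if (is.unsorted(pos, strictly = TRUE))
    msg <- c(msg, "positive doses must be strictly increasing")
  if (sum(d == 0) > 1L) msg <- c(msg, "at most one vehicle (dose 0) point")
  if (nrow(object@viability) != length(d))
    msg <- c(msg, "viability must have one row per dose")
  if (length(msg)) msg else TRUE
})

#' Construct a DoseResponseSet from viability fractions
#' @param lineId cell-line identifier.
#' @param doses concentrations in uM, ascending (0 allowed as vehicle).
#' @param viability numeric matrix (doses x replicates) or vector of
#'   per-dose viabilities.
#' @param day0Corrected whether viabilities are day-0 corrected.
#' @return A [DoseResponseSet-class].
#' @export
doseResponseSet <- function(lineId, doses, viability, day0Corrected = TRUE) {
  if (!is.matrix(viability)) viability <- matrix(viability, ncol = 1L)
  new("DoseResponseSet", lineId = as.character(lineId),
      doses = as.numeric(doses), viability = viability,
      day0Corrected = day0Corrected)
}

setMethod("show", "DoseResponseSet", function(object) {
  cat(sprintf(
    "DoseResponseSet '%s': %d doses (%g-%g uM), %d replicate(s)%s\n",
    object@lineId, length(object@doses), min(object@doses),
    max(object@doses), ncol(object@viability),
    if (object@day0Corrected) ", day-0 corrected" else ""))
})

#' @describeIn DoseResponseSet-class dose grid in uM.
#' @param x a \code{DoseResponseSet}.
#' @export
doses <- function(x) x@doses

#' @describeIn DoseResponseSet-class replicate-mean viability per dose.
#' @export
viabilityMeans <- function(x) {
  stats::setNames(rowMeans(x@viability), format(x@doses))
}

#' CurveFit: four-parameter logistic dose-response fit
#'
#' Parameters of \eqn{v(d) = bottom + (top - bottom) / (1 + (d/IC50)^h)}.
#' \code{noInhibition} marks flat or increasing data (IC50 is then
#' \code{Inf}); \code{extrapolated} marks an IC50 more than 100-fold
#' outside the tested dose range.
#'
#' @slot top,bottom asymptotic viability fractions (bottom <= top).
#' @slot ic50 inflection concentration in uM (> 0, possibly Inf).
#' @slot hill slope (> 0).
#' @slot rss residual sum of squares of the fit.
#' @slot noInhibition,extrapolated logical flags.
#' @export
setClass("CurveFit",
         slots = c(top = "numeric", bottom = "numeric", ic50 = "numeric",
                   hill = "numeric", rss = "numeric",
                   noInhibition = "logical", extrapolated = "logical"))

setValidity("CurveFit", function(object) {
  msg <- character()
  if (!object@noInhibition) {
    if (object@bottom > object@top + 1e-9)
      msg <- c(msg, "bottom must be <= top")
    if (object@ic50 <= 0) msg <- c(msg, "ic50 must be positive")
    if (object@hill <= 0) msg <- c(msg, "hill must be positive")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "CurveFit", function(object) {
  if (object@noInhibition) {
    cat("CurveFit: no inhibition (IC50 = Inf)\n")
  } else {
    cat(sprintf(
      "CurveFit: top=%.4g bottom=%.4g IC50=%.4g uM hill=%.3g rss=%.3g%s\n",
      object@top, object@bottom, object@ic50, object@hill, object@rss,
      if (object@extrapolated) " [extrapolated]" else ""))
  }
})

#' @describeIn CurveFit-class fitted IC50 in uM (Inf when no inhibition).
#' @param x a \code{CurveFit}.
#' @export
ic50 <- function(x) x@ic50

#' ClinicalTable: per-sample survival outcomes and covariates
#'
#' @slot data data.frame with columns \code{sample_id} (unique),
#'   \code{time} (> 0), \code{event} (0/1) and arbitrary covariate
#'   columns (0/1 mutation flags, factors/characters for subtypes,
#'   numeric scores).
#' @export
setClass("ClinicalTable", slots = c(data = "data.frame"))

setValidity("ClinicalTable", function(object) {
  d <- object@data
  msg <- character()
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(d)))
    msg <- c(msg, sprintf("missing required columns: %s",
                          paste(setdiff(need, names(d)), collapse = ", ")))
  else {
    if (anyDuplicated(d$sample_id)) msg <- c(msg, "duplicate sample ids")
    if (any(!is.finite(d$time)) || any(d$time <= 0))
      msg <- c(msg, "time must be finite and > 0")
    if (!all(d$event %in% c(0, 1))) msg <- c(msg, "event must be 0/1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ClinicalTable
#' @param data data.frame with \code{sample_id}, \code{time}, \code{event}
#'   and optional covariate columns.
#' @return A [ClinicalTable-class].
#' @export
clinicalTable <- function(data) new("ClinicalTable", data = as.data.frame(data))

#' @describeIn ClinicalTable-class underlying data.frame.
#' @param x a \code{ClinicalTable}.
#' @export
clinicalData <- function(x) x@data

setMethod("show", "ClinicalTable", function(object) {
  d <- object@data
  cat(sprintf("ClinicalTable: %d samples, %d events (%.0f%%), covariates: %s\n",
              nrow(d), sum(d$event), 100 * mean(d$event),
              paste(setdiff(names(d), c("sample_id", "time", "event")),
                    collapse = ", ")))
})

#' CoxFit: a fitted Cox proportional-hazards model
#'
#' Per-term log-hazard coefficients with Wald confidence intervals and
#' p-values, plus the partial log-likelihood and (for a single binary
#' term) the log-rank/score-test p-value.
#'
#' @slot table data.frame: term, beta, hr, ci_low, ci_high, se, p.
#' @slot loglik partial log-likelihood at the optimum.
#' @slot logrankP score-test p-value (log-rank for a binary term), NA
#'   for multi-term fits.
#' @slot converged FALSE when the partial likelihood is monotone
#'   (perfect separation).
#' @export
setClass("CoxFit",
         slots = c(table = "data.frame", loglik = "numeric",
                   logrankP = "numeric", converged = "logical"))

setMethod("show", "CoxFit", function(object) {
  cat(sprintf("CoxFit (loglik = %.3f%s)\n", object@loglik,
              if (!object@converged) ", NOT converged" else ""))
  print(object@table, row.names = FALSE, digits = 4)
  if (!is.na(object@logrankP))
    cat(sprintf("log-rank P = %.4g\n", object@logrankP))
})

#' @describeIn CoxFit-class per-term coefficient table.
#' @param x a \code{CoxFit}.
#' @export
coxTable <- function(x) x@table

#' @describeIn CoxFit-class hazard ratios named by term.
#' @export
hazardRatios <- function(x) stats::setNames(x@table$hr, x@table$term)

#' KMScanResult: hazard ratios along a threshold or window scan
#'
#' @slot mode \code{"threshold"} or \code{"window"}.
#' @slot table data.frame: position_pct, hr, ci_low, ci_high, n_high (or
#'   n_in), n_events_high, p. Positions where the hazard ratio is
#'   undefined (fewer than two events on a side) carry NA.
#' @export
setClass("KMScanResult",
         slots = c(mode = "character", table = "data.frame"))

setMethod("show", "KMScanResult", function(object) {
  cat(sprintf("KMScanResult (%s scan, %d positions)\n", object@mode,
              nrow(object@table)))
  print(object@table, row.names = FALSE, digits = 4)
})

#' @describeIn KMScanResult-class scan table.
#' @param x a \code{KMScanResult}.
#' @export
scanTable <- function(x) x@table
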