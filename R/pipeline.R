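#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates simulate (or load) -> normalize/score -> evaluate ->
#' survive, writing deterministic CSV artifacts to an output directory.
#' Every artifact carries a provenance comment header (package version,
#' seed, config hash), and rerunning with the same configuration and
#' seed reproduces the files bit-identically.
#'
#' The configuration is a named list (or a YAML file path) with blocks:
#' \describe{
#'   \item{simulate}{optional; arguments passed to [cohortConfig()].
#'     When absent, \code{inputs} must name an \code{expression} file
#'     (TSV/CSV), a \code{platform}, and optionally \code{clinical}
#'     (CSV) and \code{sensitivity} (CSV with line_id, ic50,
#'     mean_viability, mutant).}
#'   \item{signature}{optional path to a signature config (YAML/JSON,
#'     see [readSignature()]); the built-in 10-gene pathway and 4-gene
#'     control signatures are the default.}
#'   \item{predictors}{subset of mpas/ctrl/enet/mutation for
#'     [comparePredictors()] (default all four on simulated cohorts).}
#'   \item{survival}{optional list: \code{terms} for the multivariate
#'     Cox fit (default \code{"score"}), \code{windowPct},
#'     \code{stepPct}.}
#' }
#'
#' @param config named list or path to a YAML config file.
#' @param outDir output directory (created if needed).
#' @param seed integer seed recorded in every artifact and used for all
#'   randomness.
#' @return manifest: named list of written file paths (invisibly also
#'   written as \code{manifest.json}).
#' @examples
#' \dontrun{
#' runPipeline(list(simulate = list(nSamples = 60)), tempdir(), seed = 7)
#' }
#' @export
runPipeline <- function(config = list(), outDir, seed = 1) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  .validatePipelineConfig(config)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  version <- as.character(utils::packageVersion("mpascore"))
  cfgHash <- .configHash(config)
  prov <- sprintf("mpascore %s | seed=%d | config=%s", version,
                  as.integer(seed), cfgHash)
  manifest <- list()
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tS <- Sys.time()
    message(sprintf("[%s] stage '%s' ...", format(Sys.time(), "%H:%M:%S"),
                    name))
    out <- tryCatch(expr, error = function(e) {
      manifest$failed_stage <<- name
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    message(sprintf("  done in %.2fs",
                    as.numeric(difftime(Sys.time(), tS, units = "secs"))))
    out
  }

  sigs <- if (!is.null(config$signature)) readSignature(config$signature)
          else list(signature = mpasSignature(),
                    housekeeping = ctrlSignature(),
                    negativeControls = character())

  # --- stage 1: simulate or load -----------------------------------
  simulated <- !is.null(config$simulate)
  if (simulated) {
    cohort <- stage("simulate", {
      cfg <- do.call(cohortConfig, config$simulate)
      sim <- simulateCohort(cfg, seed)
      manifest$expression <- writeExpression(
        sim$expr, file.path(outDir, "expression.tsv"), comment = prov)
      manifest$clinical <- writeClinical(
        sim$clinical, file.path(outDir, "clinical.csv"), comment = prov)
      sensPath <- file.path(outDir, "sensitivity.csv")
      con <- file(sensPath, "w")
      writeLines(paste0("# ", prov), con)
      utils::write.csv(sim$sensitivity, con, row.names = FALSE,
                       quote = FALSE)
      close(con)
      manifest$sensitivity <- sensPath
      truth <- list(seed = as.integer(seed),
                    activity = as.list(round(sim$activity, 10)),
                    config = config$simulate)
      manifest$truth <- file.path(outDir, "truth.json")
      jsonlite::write_json(truth, manifest$truth, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      sim
    })
    zscored <- cohort$zscored
    pathwayScores <- cohort$scores
    ctrlScores <- cohort$ctrlScores
    sens <- cohort$sensitivity
    clinical <- cohort$clinical
  } else {
    cohort <- stage("load", {
      inp <- config$inputs
      expr <- readExpression(inp$expression,
                             platform = inp$platform %||% "rnaseq")
      list(expr = expr,
           clinical = if (!is.null(inp$clinical))
             readClinical(inp$clinical) else NULL,
           sensitivity = if (!is.null(inp$sensitivity))
             utils::read.csv(inp$sensitivity, comment.char = "#",
                             stringsAsFactors = FALSE) else NULL)
    })
    sc <- stage("score-raw", scoreExpression(
      cohort$expr, sig = sigs$signature,
      housekeeping = sigs$housekeeping@genes,
      negativeControlGenes = sigs$negativeControls,
      missing = "subset", zeroVariance = "zero"))
    zscored <- sc$zscored
    pathwayScores <- sc$pathway
    ctrlScores <- sc$ctrl
    sens <- cohort$sensitivity
    clinical <- cohort$clinical
  }

  # --- stage 2: scores ---------------------------------------------
  stage("score", {
    manifest$scores <- writeScores(
      pathwayScores, file.path(outDir, "scores.csv"), comment = prov)
    manifest$ctrl_scores <- writeScores(
      ctrlScores, file.path(outDir, "ctrl_scores.csv"), comment = prov)
  })

  # --- stage 3: evaluate predictors --------------------------------
  if (!is.null(sens)) {
    stage("evaluate", {
      preds <- unlist(config$predictors) %||%
        c("mpas", "ctrl", "enet", "mutation")
      logExpr <- zscored
      ev <- comparePredictors(zscored, sens, predictors = preds,
                              sig = sigs$signature, logExpr = logExpr,
                              seed = seed)
      evalPath <- file.path(outDir, "evaluation.csv")
      con <- file(evalPath, "w")
      writeLines(paste0("# ", prov), con)
      utils::write.csv(ev, con, row.names = FALSE, quote = FALSE)
      close(con)
      manifest$evaluation <- evalPath
    })
  }

  # --- stage 4: survival -------------------------------------------
  if (!is.null(clinical)) {
    stage("survive", {
      sv <- config$survival %||% list()
      terms <- unlist(sv$terms) %||% "score"
      cx <- coxFit(clinical, terms)
      coxPath <- file.path(outDir, "cox.csv")
      con <- file(coxPath, "w")
      writeLines(paste0("# ", prov), con)
      utils::write.csv(coxTable(cx), con, row.names = FALSE,
                       quote = FALSE)
      close(con)
      manifest$cox <- coxPath
      sAligned <- scores(pathwayScores)
      thr <- kmThresholdScan(clinical, sAligned)
      win <- slidingWindowScan(clinical, sAligned,
                               windowPct = sv$windowPct %||% 30,
                               stepPct = sv$stepPct %||% 2)
      manifest$scans <- file.path(outDir, "scans.csv")
      con <- file(manifest$scans, "w")
      writeLines(paste0("# ", prov), con)
      both <- rbind(cbind(mode = "threshold", scanTable(thr)),
                    cbind(mode = "window", scanTable(win)))
      utils::write.csv(both, con, row.names = FALSE, quote = FALSE)
      close(con)
    })
  }

  manifest$manifest <- file.path(outDir, "manifest.json")
  jsonlite::write_json(
    c(list(version = version, seed = as.integer(seed),
           config_hash = cfgHash),
      manifest[setdiff(names(manifest), "manifest")]),
    manifest$manifest, auto_unbox = TRUE, pretty = TRUE)
  message(sprintf("pipeline complete in %.2fs",
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(manifest)
}

# aggregate schema errors before any computation
.validatePipelineConfig <- function(config) {
  errs <- character()
  known <- c("simulate", "inputs", "signature", "predictors", "survival")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    errs <- c(errs, paste("unknown config block(s):",
                          paste(unknown, collapse = ", ")))
  if (is.null(config$simulate) && is.null(config$inputs))
    errs <- c(errs, "config needs a 'simulate' or an 'inputs' block")
  if (!is.null(config$simulate) && !is.null(config$inputs))
    errs <- c(errs, "'simulate' and 'inputs' are mutually exclusive")
  if (!is.null(config$inputs)) {
    if (is.null(config$inputs$expression))
      errs <- c(errs, "inputs$expression is required")
    else if (!file.exists(config$inputs$expression))
      errs <- c(errs, paste("expression file not found:",
                            config$inputs$expression))
    for (f in c("clinical", "sensitivity")) {
      p <- config$inputs[[f]]
      if (!is.null(p) && !file.exists(p))
        errs <- c(errs, sprintf("%s file not found: %s", f, p))
    }
  }
  if (!is.null(config$signature) && !file.exists(config$signature))
    errs <- c(errs, paste("signature config not found:",
                          config$signature))
  if (!is.null(config$predictors)) {
    bad <- setdiff(unlist(config$predictors),
                   c("mpas", "ctrl", "enet", "mutation"))
    if (length(bad))
      errs <- c(errs, paste("unknown predictor(s):",
                            paste(bad, collapse = ", ")))
  }
  if (length(errs))
    stop("invalid pipeline config:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  invisible(TRUE)
}

# md5 of the canonical JSON serialization of the config
.configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA),
             tmp)
  unname(tools::md5sum(tmp))
}
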