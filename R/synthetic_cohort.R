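#' Configuration of the synthetic cohort generator
#'
#' The generator emulates the statistical structure the analyses assume:
#' a latent per-sample pathway-activity factor \eqn{a_s \sim N(\mu_a,
#' \sigma_a^2)} drives correlated expression of the signature genes
#' (per-gene loading \eqn{\beta_i}), housekeeping and filler genes are
#' independent of it, drug sensitivity is monotonically coupled to
#' activity (mean viability through a logistic link, IC50 through a
#' log-linear link), mutation flags are Bernoulli with configurable —
#' by default negligible — activity coupling, and survival times follow
#' an exponential proportional-hazards model
#' \eqn{\lambda_0 \exp(\beta_{surv} \cdot score)} with uniform
#' censoring on \eqn{(0, c_{max})}.
#'
#' @param nSamples cohort size (default 200).
#' @param platform \code{"rnaseq"} (default) or \code{"panel"}
#'   (integer counts with negative-control genes, some below
#'   background).
#' @param muActivity,sigmaActivity latent activity mean and sd (0, 1).
#' @param signatureGenes,signatureLoadings signature gene symbols and
#'   their positive loadings on activity (default: the 10 MPAS genes,
#'   loading 1).
#' @param housekeepingGenes activity-independent control genes (default:
#'   the 4 CTRL genes).
#' @param nNoiseGenes additional activity-independent filler genes (36).
#' @param negativeControlGenes panel negative-control gene names.
#' @param sigmaG per-gene expression noise sd on the log scale (0.5).
#' @param sensK,sensMid,sensNoiseSd mean-viability link
#'   \eqn{MV_s = logistic(-k (a_s - a_0)) + N(0, sd)}, clipped to
#'   (-0.5, 1.5); defaults k = 1.5, a0 = 0, sd = 0.1.
#' @param ic50LogMid,ic50Slope,ic50NoiseSd IC50 link
#'   \eqn{\log_{10} IC50_s = c - d\, a_s + N(0, sd)} in uM; defaults
#'   0, 0.5, 0.3 (so the cohort straddles the 1 uM cutoff).
#' @param hill Hill slope of the shared inhibition curve (1).
#' @param doses dose grid in uM: vehicle 0 plus 9 log-spaced points in
#'   0.0015-10.
#' @param doseNoiseSd,nReplicates viability assay noise sd (0.05) and
#'   replicates (3).
#' @param mutBase,mutCoupling mutation prevalence (0.3) and
#'   logit-scale activity coupling (0: mutation status carries no
#'   activity information, the default regime).
#' @param subtypeProb,betaSubtype binary subtype covariate prevalence
#'   (0.5) and its own log-hazard (0).
#' @param lambda0,betaSurv,cMax baseline hazard (0.1), log-hazard per
#'   score unit (log 1.5) and censoring-time upper bound (30; about 30%
#'   censoring at the defaults).
#' @return A validated list of class \code{"CohortConfig"}.
#' @export
cohortConfig <- function(nSamples = 200, platform = c("rnaseq", "panel"),
                         muActivity = 0, sigmaActivity = 1,
                         signatureGenes = mpasSignature()@genes,
                         signatureLoadings = rep(1, length(signatureGenes)),
                         housekeepingGenes = ctrlSignature()@genes,
                         nNoiseGenes = 36,
                         negativeControlGenes = paste0("NEG_", LETTERS[1:4]),
                         sigmaG = 0.5,
                         sensK = 1.5, sensMid = 0, sensNoiseSd = 0.1,
                         ic50LogMid = 0, ic50Slope = 0.5, ic50NoiseSd = 0.3,
                         hill = 1,
                         doses = c(0, 10^seq(log10(0.0015), 1,
                                             length.out = 9)),
                         doseNoiseSd = 0.05, nReplicates = 3,
                         mutBase = 0.3, mutCoupling = 0,
                         subtypeProb = 0.5, betaSubtype = 0,
                         lambda0 = 0.1, betaSurv = log(1.5), cMax = 30) {
  platform <- match.arg(platform)
  cfg <- list(nSamples = as.integer(nSamples), platform = platform,
              muActivity = muActivity, sigmaActivity = sigmaActivity,
              signatureGenes = toupper(signatureGenes),
              signatureLoadings = signatureLoadings,
              housekeepingGenes = toupper(housekeepingGenes),
              nNoiseGenes = as.integer(nNoiseGenes),
              negativeControlGenes = toupper(negativeControlGenes),
              sigmaG = sigmaG, sensK = sensK, sensMid = sensMid,
              sensNoiseSd = sensNoiseSd, ic50LogMid = ic50LogMid,
              ic50Slope = ic50Slope, ic50NoiseSd = ic50NoiseSd,
              hill = hill, doses = doses, doseNoiseSd = doseNoiseSd,
              nReplicates = as.integer(nReplicates), mutBase = mutBase,
              mutCoupling = mutCoupling, subtypeProb = subtypeProb,
              betaSubtype = betaSubtype, lambda0 = lambda0,
              betaSurv = betaSurv, cMax = cMax)
  class(cfg) <- "CohortConfig"
  validateCohortConfig(cfg)
  cfg
}

#' Validate a cohort configuration
#'
#' Checks run before any sampling, so an invalid configuration never
#' consumes random numbers.
#'
#' @param cfg a \code{CohortConfig}.
#' @return \code{cfg}, invisibly, or an error.
#' @export
validateCohortConfig <- function(cfg) {
  stopifnot(inherits(cfg, "CohortConfig"))
  with(cfg, {
    if (nSamples < 2L) stop("nSamples must be >= 2")
    if (sigmaActivity < 0 || sigmaG < 0 || sensNoiseSd < 0 ||
        ic50NoiseSd < 0 || doseNoiseSd < 0)
      stop("all standard deviations must be >= 0")
    if (sensK <= 0) stop("sensitivity coupling sensK must be > 0")
    if (any(signatureLoadings <= 0))
      stop("signature loadings must be > 0")
    if (length(signatureLoadings) != length(signatureGenes))
      stop("one loading per signature gene required")
    if (anyDuplicated(c(signatureGenes, housekeepingGenes,
                        negativeControlGenes)))
      stop("gene name collision across signature/housekeeping/controls")
    if (hill <= 0) stop("hill must be > 0")
    if (any(doses < 0) || sum(doses == 0) > 1L ||
        is.unsorted(doses[doses > 0], strictly = TRUE))
      stop("doses must be >= 0, ascending, at most one vehicle point")
    if (mutBase <= 0 || mutBase >= 1) stop("mutBase must be in (0, 1)")
    if (lambda0 <= 0) stop("lambda0 must be > 0")
    if (cMax <= 0) stop("censoring bound cMax must be > 0")
  })
  invisible(cfg)
}

.cohortGenes <- function(cfg) {
  noise <- if (cfg$nNoiseGenes > 0)
    sprintf("GENE%03d", seq_len(cfg$nNoiseGenes)) else character()
  c(cfg$signatureGenes, cfg$housekeepingGenes, noise)
}

# expression values for given per-sample activity (columns);
# consumes RNG — callers wrap in withSeed
.exprDraw <- function(cfg, activity, baselines, sampleNames) {
  genes <- .cohortGenes(cfg)
  load <- stats::setNames(numeric(length(genes)), genes)
  load[cfg$signatureGenes] <- cfg$signatureLoadings
  n <- length(activity)
  eps <- matrix(stats::rnorm(length(genes) * n, 0, cfg$sigmaG),
                length(genes), n)
  mu <- baselines[genes] + outer(load, activity) + eps
  if (cfg$platform == "panel") {
    counts <- round(exp(mu))
    negMu <- matrix(stats::rnorm(length(cfg$negativeControlGenes) * n,
                                 2, 0.3),
                    length(cfg$negativeControlGenes), n)
    v <- rbind(counts, round(exp(negMu)))
    rownames(v) <- c(genes, cfg$negativeControlGenes)
  } else {
    v <- 2^mu
    rownames(v) <- genes
  }
  colnames(v) <- sampleNames
  v
}

.drawBaselines <- function(cfg) {
  genes <- .cohortGenes(cfg)
  lo <- if (cfg$platform == "panel") 3.5 else 4
  hi <- if (cfg$platform == "panel") 5.5 else 8
  stats::setNames(stats::runif(length(genes), lo, hi), genes)
}

#' Generate a synthetic expression cohort
#'
#' Draws the latent activity vector and an expression matrix in state
#' \code{"raw"}: signature-gene rows track activity through their
#' loadings, housekeeping/filler rows do not, and panel mode emits
#' integer counts (including negative-control rows and occasional
#' counts below the background floor). The latent activity is returned
#' so recovery can be checked against ground truth.
#'
#' @param cfg a [cohortConfig()].
#' @param seed integer seed; identical (cfg, seed) pairs give
#'   bit-identical output.
#' @return list: \code{expr} ([MpasExperiment-class]), \code{activity}
#'   (named numeric), \code{baselines}.
#' @export
generateExpression <- function(cfg, seed = 1) {
  validateCohortConfig(cfg)
  withSeed(seed, {
    ids <- sprintf("S%04d", seq_len(cfg$nSamples))
    a <- stats::setNames(
      stats::rnorm(cfg$nSamples, cfg$muActivity, cfg$sigmaActivity), ids)
    baselines <- .drawBaselines(cfg)
    v <- .exprDraw(cfg, a, baselines, ids)
    list(expr = mpasExperiment(v, platform = cfg$platform, state = "raw"),
         activity = a, baselines = baselines)
  })
}

#' Generate drug-sensitivity records coupled to activity
#'
#' Mean viability follows the logistic link
#' \eqn{MV_s = logistic(-k (a_s - a_0)) + noise} (clipped to (-0.5,
#' 1.5)), log10 IC50 the linear link \eqn{c - d \, a_s + noise}, and the
#' mutation flag is Bernoulli with prevalence \code{mutBase} shifted on
#' the logit scale by \code{mutCoupling x activity} (0 by default).
#'
#' @param cfg a [cohortConfig()].
#' @param activity named latent-activity vector from
#'   [generateExpression()].
#' @param seed integer seed.
#' @return data.frame: line_id, activity, mean_viability, ic50, label,
#'   mutant.
#' @export
generateSensitivity <- function(cfg, activity, seed = 1) {
  validateCohortConfig(cfg)
  withSeed(seed, {
    n <- length(activity)
    mv <- stats::plogis(-cfg$sensK * (activity - cfg$sensMid)) +
      stats::rnorm(n, 0, cfg$sensNoiseSd)
    mv <- pmin(pmax(mv, -0.5), 1.5)
    lic <- cfg$ic50LogMid - cfg$ic50Slope * activity +
      stats::rnorm(n, 0, cfg$ic50NoiseSd)
    ic <- 10^lic
    mut <- stats::rbinom(n, 1,
                         stats::plogis(stats::qlogis(cfg$mutBase) +
                                         cfg$mutCoupling * activity))
    data.frame(line_id = names(activity), activity = unname(activity),
               mean_viability = unname(mv), ic50 = unname(ic),
               label = classifySensitivity(ic), mutant = mut,
               stringsAsFactors = FALSE)
  })
}

#' Generate a treated dose series for one line
#'
#' Viability and signature expression share one Hill inhibition curve:
#' with fractional effect \eqn{E(d) = d^h / (d^h + IC50_s^h)}, the
#' treated latent activity is \eqn{a_s (1 - E(d))} and viability is
#' \eqn{1 - E(d)} plus assay noise, so the transcriptional profile
#' tracks growth inhibition by construction (vehicle dose 0 gives
#' viability exactly 1 in the noiseless limit, and \eqn{E(IC50) = 1/2}).
#'
#' @param cfg a [cohortConfig()].
#' @param activity single named latent activity value for the line.
#' @param ic50 the line's IC50 in uM (e.g. from
#'   [generateSensitivity()]).
#' @param seed integer seed.
#' @return list: \code{dr} ([DoseResponseSet-class]), \code{exprByDose}
#'   ([MpasExperiment-class], columns named by dose), \code{effect}
#'   (E(d)).
#' @export
generateDoseResponse <- function(cfg, activity, ic50, seed = 1) {
  validateCohortConfig(cfg)
  stopifnot(length(activity) == 1L, length(ic50) == 1L, ic50 > 0)
  lineId <- if (!is.null(names(activity))) names(activity) else "line"
  withSeed(seed, {
    d <- cfg$doses
    E <- ifelse(d == 0, 0, d^cfg$hill / (d^cfg$hill + ic50^cfg$hill))
    viab <- matrix(rep(1 - E, cfg$nReplicates), length(d),
                   cfg$nReplicates) +
      matrix(stats::rnorm(length(d) * cfg$nReplicates, 0,
                          cfg$doseNoiseSd),
             length(d), cfg$nReplicates)
    if (cfg$doseNoiseSd == 0) viab[d == 0, ] <- 1  # exact vehicle point
    baselines <- .drawBaselines(cfg)
    treated <- unname(activity) * (1 - E)
    v <- .exprDraw(cfg, treated, baselines, as.character(d))
    list(dr = doseResponseSet(lineId, d, viab),
         exprByDose = mpasExperiment(v, platform = cfg$platform,
                                     state = "raw"),
         effect = E)
  })
}

#' Generate clinical survival outcomes from scores
#'
#' Event times are exponential with hazard
#' \eqn{\lambda_0 \exp(\beta_{surv} \cdot score_s)}; censoring times are
#' uniform on \eqn{(0, c_{max})}; the observed time is the minimum with
#' the event indicator. Mutation flags (Bernoulli, optionally
#' activity-coupled) and an independent binary subtype covariate with
#' its own hazard multiplier \code{betaSubtype} are attached as
#' covariates.
#'
#' @param cfg a [cohortConfig()].
#' @param scores a [ScoreTable-class] or named numeric vector of
#'   per-sample scores driving the hazard.
#' @param seed integer seed.
#' @param activity optional named activity vector for the mutation
#'   coupling (defaults to zero coupling shift).
#' @return A [ClinicalTable-class] with columns sample_id, time, event,
#'   score, mutant, subtype.
#' @export
generateClinical <- function(cfg, scores, seed = 1, activity = NULL) {
  validateCohortConfig(cfg)
  s <- if (is(scores, "ScoreTable")) scores(scores) else scores
  if (any(!is.finite(s))) stop("scores must be finite")
  ids <- if (!is.null(names(s))) names(s) else
    sprintf("S%04d", seq_along(s))
  act <- if (is.null(activity)) rep(0, length(s)) else activity[ids]
  withSeed(seed, {
    n <- length(s)
    subtype <- stats::rbinom(n, 1, cfg$subtypeProb)
    rate <- cfg$lambda0 * exp(cfg$betaSurv * unname(s) +
                                cfg$betaSubtype * subtype)
    tEvent <- stats::rexp(n, rate)
    tCens <- stats::runif(n, 0, cfg$cMax)
    mut <- stats::rbinom(n, 1,
                         stats::plogis(stats::qlogis(cfg$mutBase) +
                                         cfg$mutCoupling * unname(act)))
    clinicalTable(data.frame(
      sample_id = ids,
      time = pmin(tEvent, tCens),
      event = as.integer(tEvent <= tCens),
      score = unname(s), mutant = mut, subtype = subtype,
      stringsAsFactors = FALSE))
  })
}

#' Analytic censoring fraction implied by a configuration
#'
#' For exponential event times with per-sample rate
#' \eqn{\lambda_s = \lambda_0 e^{\beta s}} and uniform censoring on
#' \eqn{(0, c)}, the probability a record is censored is
#' \eqn{(1 - e^{-\lambda_s c}) / (\lambda_s c)}, averaged over samples.
#'
#' @param cfg a [cohortConfig()].
#' @param scores per-sample scores entering the hazard.
#' @return expected censored fraction.
#' @export
expectedCensoring <- function(cfg, scores) {
  s <- if (is(scores, "ScoreTable")) scores(scores) else scores
  lam <- cfg$lambda0 * exp(cfg$betaSurv * s)
  mean((1 - exp(-lam * cfg$cMax)) / (lam * cfg$cMax))
}

#' Simulate a full analysis-ready cohort
#'
#' One call chaining the generator stages: expression (+ latent
#' activity), platform-appropriate scoring, sensitivity records, and
#' clinical outcomes with hazard driven by the pathway score.
#' Sub-stages draw from seeds \code{seed}, \code{seed + 1},
#' \code{seed + 2}, so the whole cohort is reproducible from
#' \code{(cfg, seed)}.
#'
#' @param cfg a [cohortConfig()].
#' @param seed integer seed.
#' @return list: \code{expr} (raw), \code{zscored}, \code{activity},
#'   \code{scores} (pathway [ScoreTable-class]), \code{ctrlScores},
#'   \code{sensitivity} (data.frame), \code{clinical}
#'   ([ClinicalTable-class]).
#' @export
simulateCohort <- function(cfg = cohortConfig(), seed = 1) {
  gx <- generateExpression(cfg, seed)
  sc <- scoreExpression(gx$expr,
                        negativeControlGenes = cfg$negativeControlGenes,
                        housekeeping = cfg$housekeepingGenes,
                        missing = "subset", zeroVariance = "zero")
  sens <- generateSensitivity(cfg, gx$activity, seed + 1)
  clin <- generateClinical(cfg, sc$pathway, seed + 2,
                           activity = gx$activity)
  list(expr = gx$expr, zscored = sc$zscored, activity = gx$activity,
       scores = sc$pathway, ctrlScores = sc$ctrl, sensitivity = sens,
       clinical = clin)
}
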