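#' Day-0-corrected relative viability
#'
#' Converts raw luminescence readings to growth-relative viability:
#' \deqn{v(d) = \frac{raw(d) - \overline{day0}}{\overline{vehicle} -
#' \overline{day0}},}
#' so the vehicle control maps to 1, the day-of-treatment (day 0) level
#' maps to 0 (cell stasis) and values below 0 represent net cell death.
#' Values are not clipped. The transform is affine in the luminescence
#' unit, so rescaling the readout leaves viabilities unchanged.
#'
#' @param raw numeric matrix of luminescence, doses x replicates (all
#'   values >= 0).
#' @param day0 replicate luminescence values on the day of treatment.
#' @param vehicle replicate luminescence values of the vehicle control at
#'   endpoint; mean must exceed the day-0 mean (cells grew).
#' @param doses concentrations in uM matching the rows of \code{raw}.
#' @param lineId cell-line identifier.
#' @return A [DoseResponseSet-class] with \code{day0Corrected = TRUE}.
#' @export
relativeViability <- function(raw, day0, vehicle, doses, lineId = "line") {
  if (!is.matrix(raw)) raw <- matrix(raw, ncol = 1L)
  if (any(raw < 0)) stop("raw luminescence must be >= 0")
  if (nrow(raw) != length(doses))
    stop("one row of 'raw' per dose required")
  m0 <- mean(day0); mv <- mean(vehicle)
  if (!(mv > m0))
    stop("vehicle mean must exceed day-0 mean (no growth window)")
  doseResponseSet(lineId, doses, (raw - m0) / (mv - m0),
                  day0Corrected = TRUE)
}

# 4PL mean response at dose d (d = 0 gives top)
.fourPL <- function(d, top, bottom, ic50, hill) {
  bottom + (top - bottom) / (1 + (d / ic50)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' \eqn{v(d) = bottom + (top - bottom)/(1 + (d/IC50)^{hill})} to the
#' replicate-mean viabilities. Starting values run over a fixed
#' deterministic grid — hill in \{0.5, 1, 2\} crossed with an IC50 start
#' at every tested positive dose — and the converged fit with the lowest
#' residual sum of squares is kept, so repeated fits of the same data are
#' identical. Flat or monotone-increasing response (no inhibition) is
#' flagged with \code{noInhibition = TRUE} and an \code{Inf} IC50 rather
#' than forced through the sigmoid; an IC50 beyond 100-fold of the tested
#' dose range is flagged \code{extrapolated}.
#'
#' @param dr a [DoseResponseSet-class] with >= 4 distinct positive doses.
#' @param flatTol minimal viability span treated as a real response
#'   (default 0.01).
#' @return A [CurveFit-class].
#' @export
fit4PL <- function(dr, flatTol = 0.01) {
  stopifnot(is(dr, "DoseResponseSet"))
  d <- dr@doses
  v <- rowMeans(dr@viability)
  if (any(!is.finite(v))) stop("replicate means must be finite")
  pos <- d > 0
  if (sum(pos) < 4L) stop("need >= 4 positive doses to fit")
  vflat <- mean(v)
  rssFlat <- sum((v - vflat)^2)
  span <- max(v) - min(v)
  vp <- v[pos]
  increasing <- if (span < flatTol) NA_real_ else
    suppressWarnings(stats::cor(seq_along(vp), vp, method = "spearman"))
  if (span < flatTol || (!is.na(increasing) && increasing > 0 &&
                         vp[length(vp)] >= vp[1L])) {
    return(new("CurveFit", top = vflat, bottom = vflat, ic50 = Inf,
               hill = NA_real_, rss = rssFlat, noInhibition = TRUE,
               extrapolated = FALSE))
  }
  dat <- data.frame(d = d, v = v)
  top0 <- max(v); bot0 <- min(v)
  best <- NULL
  for (h0 in c(0.5, 1, 2)) for (ic0 in d[pos]) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ bottom + (top - bottom) / (1 + (d / exp(logIc50))^exp(logHill)),
        data = dat,
        start = list(top = top0, bottom = bot0, logIc50 = log(ic0),
                     logHill = log(h0)),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(rss = rss, coef = stats::coef(fit))
  }
  if (is.null(best))
    stop(sprintf(
      "4PL fit failed to converge from any of %d starts (line '%s')",
      3L * sum(pos), dr@lineId))
  if (best$rss > rssFlat) {
    return(new("CurveFit", top = vflat, bottom = vflat, ic50 = Inf,
               hill = NA_real_, rss = rssFlat, noInhibition = TRUE,
               extrapolated = FALSE))
  }
  cf <- best$coef
  top <- unname(cf["top"]); bottom <- unname(cf["bottom"])
  if (bottom > top) {
    # best least-squares curve rises with dose: no inhibition signal
    return(new("CurveFit", top = vflat, bottom = vflat, ic50 = Inf,
               hill = NA_real_, rss = rssFlat, noInhibition = TRUE,
               extrapolated = FALSE))
  }
  ic <- exp(unname(cf["logIc50"]))
  hill <- exp(unname(cf["logHill"]))
  rng <- range(d[pos])
  new("CurveFit", top = top, bottom = bottom, ic50 = ic, hill = hill,
      rss = best$rss, noInhibition = FALSE,
      extrapolated = (ic < rng[1L] / 100 || ic > rng[2L] * 100))
}

#' Mean viability over the tested dose grid
#'
#' MV is the unweighted arithmetic mean of the replicate-mean viabilities
#' over the positive doses of the grid; \code{1 - MV} is the sensitivity
#' measure used in predictor comparisons. The dose grid is returned as an
#' attribute so the averaging range is auditable.
#'
#' @param dr a [DoseResponseSet-class] with >= 2 positive doses.
#' @return MV as a single numeric, with attribute \code{doses}.
#' @export
meanViability <- function(dr) {
  stopifnot(is(dr, "DoseResponseSet"))
  pos <- dr@doses > 0
  if (sum(pos) < 2L) stop("need >= 2 positive doses for mean viability")
  mv <- mean(rowMeans(dr@viability[pos, , drop = FALSE]))
  structure(mv, doses = dr@doses[pos])
}

#' Classify drug sensitivity from IC50
#'
#' A line is called \code{"sensitive"} when its IC50 is strictly below
#' 1 uM (the average clinical serum concentration range of the MEK
#' inhibitor is 0.1-1 uM), otherwise \code{"resistant"}; an IC50 of
#' exactly 1 uM and the \code{Inf} no-inhibition sentinel are resistant.
#'
#' @param ic50 numeric vector of IC50 values in uM (> 0 or \code{Inf}).
#' @return character vector of \code{"sensitive"}/\code{"resistant"}.
#' @export
classifySensitivity <- function(ic50) {
  if (any(is.na(ic50)) || any(ic50 <= 0))
    stop("ic50 must be positive (or Inf for no inhibition)")
  ifelse(ic50 < 1.0, "sensitive", "resistant")
}

#' Dose-dependent pathway-score inhibition profile
#'
#' Computes the pathway score at each dose of a treated dose series
#' (z-scoring each gene across the doses of that one line), correlates it
#' with the viability curve, and fits the same 4PL model to the
#' score profile rescaled to [0, 1] so the transcriptional IC50 can be
#' compared with the growth-inhibition IC50.
#'
#' @param exprByDose an [MpasExperiment-class] whose columns are the
#'   doses of the series (column names must parse to the dose grid of
#'   \code{dr}).
#' @param sig a [GeneSignature-class].
#' @param dr the matching [DoseResponseSet-class].
#' @return list: \code{doses}, \code{mpas} (score per dose),
#'   \code{viability} (replicate means), \code{r} (Pearson correlation of
#'   score and viability across doses), \code{mpasFit} and
#'   \code{viabilityFit} ([CurveFit-class]) and \code{ic50Ratio}
#'   (score IC50 / viability IC50).
#' @export
mpasDoseProfile <- function(exprByDose, sig, dr) {
  stopifnot(is(exprByDose, "MpasExperiment"), is(sig, "GeneSignature"),
            is(dr, "DoseResponseSet"))
  dExpr <- suppressWarnings(as.numeric(colnames(exprByDose)))
  if (anyNA(dExpr) || length(dExpr) != length(dr@doses) ||
      any(abs(dExpr - dr@doses) > 1e-9 * pmax(1, dr@doses)))
    stop("expression dose grid does not match the viability dose grid")
  m <- exprByDose
  if (exprState(m) == "raw") m <- logTransform(m)
  z <- suppressWarnings(zscoreGenes(m, zeroVariance = "zero"))
  mpas <- unname(scores(computeScore(z, sig, missing = "subset")))
  v <- unname(rowMeans(dr@viability))
  r <- stats::cor(mpas, v, method = "pearson")
  rngM <- range(mpas)
  mpas01 <- if (diff(rngM) > 0) (mpas - rngM[1L]) / diff(rngM)
            else rep(0.5, length(mpas))
  mpasFit <- fit4PL(doseResponseSet(dr@lineId, dr@doses, mpas01))
  viabFit <- fit4PL(dr)
  list(doses = dr@doses, mpas = mpas, viability = v, r = r,
       mpasFit = mpasFit, viabilityFit = viabFit,
       ic50Ratio = ic50(mpasFit) / ic50(viabFit))
}
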