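#' @importFrom survival coxph Surv survfit
NULL

.survData <- function(tbl) {
  stopifnot(is(tbl, "ClinicalTable"))
  clinicalData(tbl)
}

#' Kaplan-Meier estimate of the survival function
#'
#' Product-limit estimator with the median survival time defined as the
#' first time at which the estimated survival drops to 0.5 or below
#' (\code{NA} when never reached).
#'
#' @param times positive event/censoring times.
#' @param events 0/1 event indicators (1 = event observed).
#' @return list: \code{time}, \code{surv} (step-function values at the
#'   observed times), \code{median}, and the underlying
#'   \code{survfit} object as \code{fit}.
#' @export
kmEstimate <- function(times, events) {
  if (length(times) == 0L) stop("empty input")
  if (any(times <= 0)) stop("times must be > 0")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  fit <- survfit(Surv(times, events) ~ 1)
  med <- fit$time[fit$surv <= 0.5][1L]
  list(time = fit$time, surv = fit$surv,
       median = if (length(med) && !is.na(med)) med else NA_real_,
       fit = fit)
}

# build model matrix for the requested terms, expanding factors;
# errors on constant or collinear columns
.coxModelMatrix <- function(d, terms) {
  missing <- setdiff(terms, names(d))
  if (length(missing))
    stop("covariate(s) absent from clinical table: ",
         paste(missing, collapse = ", "))
  sub <- d[terms]
  for (nm in terms) {
    v <- sub[[nm]]
    if (is.character(v)) sub[[nm]] <- factor(v)
    if (is.numeric(v) && any(!is.finite(v)))
      stop("non-finite values in covariate '", nm, "'")
    if (length(unique(v)) < 2L)
      stop("constant covariate: '", nm, "'")
  }
  mm <- stats::model.matrix(~ ., data = sub)[, -1L, drop = FALSE]
  qrm <- qr(cbind(1, mm))
  if (qrm$rank < ncol(mm) + 1L) {
    aliased <- colnames(mm)[qrm$pivot[-seq_len(qrm$rank)] - 1L]
    stop("collinear covariate term(s): ", paste(aliased, collapse = ", "))
  }
  mm
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the partial likelihood with the Breslow approximation for
#' tied event times (so duplicating every record leaves the coefficients
#' unchanged). Per-term hazard ratios carry Wald 95% confidence
#' intervals \eqn{\exp(\beta \pm 1.96\,se)} and Wald p-values; for a
#' single binary term the score-test (log-rank) p-value is also
#' reported. Character/factor covariates are expanded to indicator
#' terms; collinear or constant covariates are an error naming the
#' offending term.
#'
#' @param tbl a [ClinicalTable-class] with >= 2 events.
#' @param terms names of covariate columns to include.
#' @return A [CoxFit-class]. Monotone-likelihood fits (perfect
#'   separation) are returned with \code{converged = FALSE}.
#' @export
coxFit <- function(tbl, terms) {
  d <- .survData(tbl)
  if (sum(d$event) < 2L) stop("need >= 2 events to fit")
  mm <- .coxModelMatrix(d, terms)
  converged <- TRUE
  fit <- withCallingHandlers(
    coxph(Surv(d$time, d$event) ~ mm, ties = "breslow"),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be", conditionMessage(w)))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  if (any(!is.finite(stats::coef(fit)))) converged <- FALSE
  beta <- unname(stats::coef(fit))
  se <- sqrt(diag(stats::vcov(fit)))
  tab <- data.frame(
    term = colnames(mm), beta = beta, hr = exp(beta),
    ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
    se = unname(se), p = 2 * stats::pnorm(-abs(beta / se)),
    stringsAsFactors = FALSE, row.names = NULL)
  binarySingle <- ncol(mm) == 1L && all(mm[, 1L] %in% c(0, 1))
  logrankP <- if (binarySingle)
    unname(summary(fit)$sctest["pvalue"]) else NA_real_
  new("CoxFit", table = tab, loglik = fit$loglik[2L],
      logrankP = logrankP, converged = converged)
}

#' Dichotomize scores at the cohort median
#'
#' "high" if and only if the score is strictly above the median (ties
#' are "low") — the same deterministic rule as [medianClassify()].
#'
#' @param scores a [ScoreTable-class] or named numeric vector (>= 2
#'   samples, not all identical).
#' @return character vector \code{"high"}/\code{"low"}, named by sample.
#' @export
medianDichotomize <- function(scores) {
  pos <- medianClassify(scores, direction = "high_is_positive")
  stats::setNames(ifelse(pos, "high", "low"), names(pos))
}

# align a score vector with a clinical table by sample id
.alignScores <- function(d, scores) {
  s <- if (is(scores, "ScoreTable")) scores(scores) else scores
  if (!is.null(names(s))) {
    missing <- setdiff(d$sample_id, names(s))
    if (length(missing))
      stop("scores missing for sample(s): ",
           paste(utils::head(missing, 5L), collapse = ", "))
    s <- s[d$sample_id]
  } else if (length(s) != nrow(d))
    stop("unnamed scores must match the clinical table length")
  unname(s)
}

.hrRow <- function(position, ind, d, minEvents = 2L) {
  na <- data.frame(position_pct = position, hr = NA_real_,
                   ci_low = NA_real_, ci_high = NA_real_,
                   n_high = sum(ind), n_events_high = sum(d$event[ind]),
                   p = NA_real_)
  if (sum(d$event[ind]) < minEvents || sum(d$event[!ind]) < minEvents)
    return(na)
  tmp <- clinicalTable(cbind(d[c("sample_id", "time", "event")],
                             grp = as.integer(ind)))
  cf <- tryCatch(coxFit(tmp, "grp"), error = function(e) NULL)
  if (is.null(cf) || !cf@converged) return(na)
  t1 <- coxTable(cf)
  data.frame(position_pct = position, hr = t1$hr, ci_low = t1$ci_low,
             ci_high = t1$ci_high, n_high = sum(ind),
             n_events_high = sum(d$event[ind]), p = t1$p)
}

#' Kaplan-Meier threshold scan
#'
#' Sweeps the high/low cutoff over score percentiles (default 10th to
#' 90th, inclusive) and computes at each threshold the hazard ratio of
#' high vs low from a univariate Cox fit on the indicator
#' \code{score > quantile}. At the 50th percentile the labels coincide
#' exactly with [medianDichotomize()]. Positions with fewer than two
#' events on either side are reported with \code{NA} rather than
#' dropped, so the grid stays rectangular.
#'
#' @param tbl a [ClinicalTable-class].
#' @param scores a [ScoreTable-class] or named numeric vector aligned by
#'   sample id.
#' @param loPct,hiPct percentile range of the scan (default 10-90).
#' @param stepPct grid step in percentile points (default 5).
#' @return A [KMScanResult-class] with mode \code{"threshold"}.
#' @export
kmThresholdScan <- function(tbl, scores, loPct = 10, hiPct = 90,
                            stepPct = 5) {
  d <- .survData(tbl)
  s <- .alignScores(d, scores)
  if (loPct < 0 || hiPct > 100 || loPct >= hiPct || stepPct <= 0)
    stop("invalid percentile grid")
  grid <- seq(loPct, hiPct, by = stepPct)
  rows <- lapply(grid, function(q) {
    thr <- stats::quantile(s, q / 100, type = 7, names = FALSE)
    .hrRow(q, s > thr, d)
  })
  new("KMScanResult", mode = "threshold", table = do.call(rbind, rows))
}

#' Sliding percentile-window hazard scan
#'
#' Slides a window spanning \code{windowPct} percentile points of the
#' score distribution across the cohort in \code{stepPct}-point
#' increments (defaults: a 30-point window moved by 2 points, i.e. the
#' 0-30th-percentile group first, the 70-100th last) and computes a
#' hazard ratio for each window, indexed by the window's median
#' percentile (15 ... 85 for the defaults). With
#' \code{comparison = "population"} (default) the window members are
#' contrasted against the entire cohort by stacking the window on a full
#' cohort copy; \code{"remainder"} fits the membership indicator over
#' the cohort records, contrasting members with non-members. Windows
#' with fewer than two events (either side) yield \code{NA}.
#'
#' @param tbl a [ClinicalTable-class].
#' @param scores a [ScoreTable-class] or named numeric vector.
#' @param windowPct window width in percentile points (default 30; 15
#'   gives the narrower variant).
#' @param stepPct slide increment (default 2).
#' @param comparison \code{"population"} or \code{"remainder"}.
#' @return A [KMScanResult-class] with mode \code{"window"}; the count
#'   column is \code{n_high} = window size.
#' @export
slidingWindowScan <- function(tbl, scores, windowPct = 30, stepPct = 2,
                              comparison = c("population", "remainder")) {
  comparison <- match.arg(comparison)
  d <- .survData(tbl)
  s <- .alignScores(d, scores)
  if (windowPct <= 0 || windowPct >= 100 || stepPct <= 0 ||
      stepPct > 100 - windowPct)
    stop("window/step must satisfy 0 < window < 100, 0 < step <= 100 - window")
  n <- nrow(d)
  r <- rank(s, ties.method = "first")
  starts <- seq(0, 100 - windowPct, by = stepPct)
  rows <- lapply(starts, function(q) {
    member <- r > n * q / 100 & r <= n * (q + windowPct) / 100
    pos <- q + windowPct / 2
    if (comparison == "remainder") {
      .hrRow(pos, member, d)
    } else {
      stacked <- rbind(
        cbind(d[c("time", "event")], grp = 0L),
        cbind(d[member, c("time", "event")], grp = 1L))
      stacked$sample_id <- seq_len(nrow(stacked))
      na <- data.frame(position_pct = pos, hr = NA_real_,
                       ci_low = NA_real_, ci_high = NA_real_,
                       n_high = sum(member),
                       n_events_high = sum(d$event[member]),
                       p = NA_real_)
      if (sum(d$event[member]) < 2L || sum(d$event) < 2L) return(na)
      cf <- tryCatch(coxFit(clinicalTable(stacked), "grp"),
                     error = function(e) NULL)
      if (is.null(cf) || !cf@converged) return(na)
      t1 <- coxTable(cf)
      data.frame(position_pct = pos, hr = t1$hr, ci_low = t1$ci_low,
                 ci_high = t1$ci_high, n_high = sum(member),
                 n_events_high = sum(d$event[member]), p = t1$p)
    }
  })
  new("KMScanResult", mode = "window", table = do.call(rbind, rows))
}

#' Binomial test of the death proportion in the high group
#'
#' Of the K deaths observed in the cohort, tests whether the number
#' occurring in the high group is compatible with its share of the
#' cohort: a two-sided exact binomial test of k (deaths among "high")
#' out of K against \eqn{p_0 = n_{high} / n}.
#'
#' @param tbl a [ClinicalTable-class] with >= 1 death.
#' @param groups \code{"high"}/\code{"low"} labels (e.g. from
#'   [medianDichotomize()]), aligned by name or position.
#' @return the two-sided p-value.
#' @export
binomialDeathTest <- function(tbl, groups) {
  d <- .survData(tbl)
  g <- if (!is.null(names(groups))) groups[d$sample_id] else groups
  if (length(g) != nrow(d) || anyNA(g))
    stop("groups must cover every sample")
  if (!all(g %in% c("high", "low")))
    stop("groups must be 'high'/'low'")
  K <- sum(d$event)
  if (K < 1L) stop("no deaths observed")
  k <- sum(d$event[g == "high"])
  p0 <- mean(g == "high")
  stats::binom.test(k, K, p = p0, alternative = "two.sided")$p.value
}

#' Multivariate Cox report for a score plus clinical covariates
#'
#' One joint Cox fit of the continuous score together with mutation
#' flags, subtype or treatment covariates (factors expanded to
#' indicators), reporting hazard ratio, 95% CI and p per term — the
#' tabular companion of a forest plot. With a single term the result
#' equals the univariate [coxFit()].
#'
#' @param tbl a [ClinicalTable-class] containing all term columns.
#' @param terms covariate names (include the score column name).
#' @return A [CoxFit-class].
#' @export
multivariateSurvivalReport <- function(tbl, terms) coxFit(tbl, terms)

#' Write a scan result to CSV
#' @param x a [KMScanResult-class].
#' @param path output path.
#' @param comment optional provenance lines written as \code{#}-comments.
#' @return \code{path}, invisibly.
#' @export
writeScan <- function(x, path, comment = NULL) {
  stopifnot(is(x, "KMScanResult"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(scanTable(x), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
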