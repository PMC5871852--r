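#' Median-based classification of a continuous score
#'
#' Predicts a sample positive when its score lies strictly above the
#' cohort median; ties at the median are negative. With
#' \code{direction = "low_is_positive"} scores are negated first, so low
#' values (e.g. predicted viability) are the positive class. The rule is
#' deterministic: with all-distinct scores exactly \code{floor(n/2)}
#' samples are positive.
#'
#' @param scores a [ScoreTable-class] or named numeric vector (>= 2
#'   samples, not all identical).
#' @param direction which tail is the positive class.
#' @return logical vector (TRUE = predicted positive), named by sample.
#' @export
medianClassify <- function(scores,
                           direction = c("high_is_positive",
                                         "low_is_positive")) {
  direction <- match.arg(direction)
  s <- if (is(scores, "ScoreTable")) scores(scores) else scores
  if (length(s) < 2L) stop("median classification needs >= 2 samples")
  if (max(s) == min(s))
    stop("all scores identical: median classification undefined")
  if (direction == "low_is_positive") s <- -s
  s > stats::median(s)
}

#' Confusion-matrix summary of a binary predictor
#'
#' Counts true/false positives/negatives of predicted against true
#' labels and derives the true positive rate TPR = TP/(TP+FN), false
#' positive rate FPR = FP/(FP+TN) and accuracy ACC = (TP+TN)/N. A rate
#' with a zero denominator is reported as \code{NA}.
#'
#' @param predicted logical vector (TRUE = called positive) or character
#'   \code{"sensitive"}/\code{"resistant"}.
#' @param truth same form and length as \code{predicted}; TRUE /
#'   \code{"sensitive"} is the positive class.
#' @return list with \code{tp}, \code{fp}, \code{tn}, \code{fn},
#'   \code{n}, \code{tpr}, \code{fpr}, \code{acc}.
#' @export
confusionMetrics <- function(predicted, truth) {
  toLogical <- function(x) {
    if (is.character(x) || is.factor(x)) as.character(x) == "sensitive"
    else as.logical(x)
  }
  p <- toLogical(predicted); t <- toLogical(truth)
  if (length(p) != length(t)) stop("predicted and truth lengths differ")
  if (anyNA(p) || anyNA(t)) stop("labels must be non-missing")
  tp <- sum(p & t); fp <- sum(p & !t)
  fn <- sum(!p & t); tn <- sum(!p & !t)
  n <- length(p)
  list(tp = tp, fp = fp, tn = tn, fn = fn, n = n,
       tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
       acc = (tp + tn) / n)
}

#' Mutation status as a sensitivity predictor
#'
#' Predicts a line sensitive if and only if it carries the mutation —
#' the genotype-driven baseline the expression scores are compared
#' against.
#'
#' @param flags 0/1 (or logical) mutation indicator per line.
#' @return logical predicted-sensitive vector.
#' @export
mutationAsPredictor <- function(flags) {
  if (!all(flags %in% c(0, 1))) stop("mutation flags must be 0/1")
  as.logical(flags)
}

#' Spearman rank correlation with asymptotic p-value
#'
#' Spearman's rho with average ranks for ties, tested against zero with
#' the large-sample t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors, length >= 3, finite, non-constant.
#' @return list with \code{rho}, \code{p} and \code{n}.
#' @export
rankCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("need n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("values must be finite")
  if (max(x) == min(x) || max(y) == min(y))
    stop("constant vector: correlation undefined")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Percentile of a correlation within a benchmark distribution
#'
#' Top-oriented convention: percentile = 100 x (number of reference
#' values strictly greater than \code{value}) / N, so 0 means the value
#' beats every competitor and 100 means every competitor beats it.
#' Monotone non-increasing in \code{value}.
#'
#' @param value a correlation coefficient.
#' @param reference non-empty numeric vector of competitor correlations
#'   (all within [-1, 1]).
#' @return percentile in [0, 100].
#' @export
percentileInReference <- function(value, reference) {
  if (length(reference) == 0L) stop("reference distribution is empty")
  if (any(abs(reference) > 1) || abs(value) > 1)
    stop("correlations must lie in [-1, 1]")
  100 * sum(reference > value) / length(reference)
}

#' Elastic-net expression model of drug sensitivity
#'
#' Trains a penalized linear model of the response (mean viability) on
#' gene-expression features with mixing parameter alpha = 0.5 and the
#' penalty lambda minimizing the 5-fold cross-validated squared error
#' over a 100-point log-spaced grid spanning
#' [lambda_max x 1e-4, lambda_max]. Each gene is standardized to mean 0,
#' sd 1 before fitting, removing absolute-expression bias and making
#' predictions invariant to per-gene affine rescaling of the input. Fold
#' assignment is drawn from \code{seed}, so the fit is deterministic.
#'
#' @param expr an [MpasExperiment-class] in state \code{"log_transformed"}
#'   (or \code{"zscored"}), >= 30 samples.
#' @param response numeric response per sample (e.g. mean viability).
#' @param alpha elastic-net mixing parameter (default 0.5).
#' @param nfolds number of CV folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @return list: \code{model} (the \code{cv.glmnet} fit),
#'   \code{selectedFeatures}, \code{coefficients}, \code{intercept},
#'   \code{lambda}, \code{cvR} (Pearson correlation of out-of-fold
#'   predictions with the response), \code{cvPredictions},
#'   \code{geneMeans}, \code{geneSds} (the standardization applied), and
#'   \code{predict(newExpr)} closure.
#' @export
fitEnet <- function(expr, response, alpha = 0.5, nfolds = 5, seed = 1) {
  stopifnot(is(expr, "MpasExperiment"))
  .requireState(expr, c("log_transformed", "zscored"), "fitEnet")
  x <- t(exprValues(expr))          # samples x genes
  n <- nrow(x)
  if (n < 30L) stop("elastic-net fit needs >= 30 samples")
  if (length(response) != n) stop("one response per sample required")
  if (any(!is.finite(response))) stop("response must be finite")
  if (n < nfolds) stop("fewer samples than folds")
  mu <- colMeans(x)
  sdv <- apply(x, 2L, popSd)
  keep <- sdv > 0
  xs <- sweep(sweep(x[, keep, drop = FALSE], 2L, mu[keep]), 2L,
              sdv[keep], `/`)
  foldid <- withSeed(seed, sample(rep_len(seq_len(nfolds), n)))
  cv <- glmnet::cv.glmnet(xs, response, alpha = alpha, foldid = foldid,
                          nlambda = 100, lambda.min.ratio = 1e-4,
                          standardize = FALSE, keep = TRUE,
                          family = "gaussian")
  i <- which(cv$lambda == cv$lambda.min)[1L]
  oof <- cv$fit.preval[, i]
  cvR <- stats::cor(oof, response)
  beta <- as.matrix(stats::coef(cv, s = "lambda.min"))
  coefs <- beta[-1L, 1L]
  sel <- names(coefs)[coefs != 0]
  predictFun <- function(newExpr) {
    nx <- t(exprValues(newExpr))[, keep, drop = FALSE]
    nxs <- sweep(sweep(nx, 2L, mu[keep]), 2L, sdv[keep], `/`)
    as.numeric(stats::predict(cv, newx = nxs, s = "lambda.min"))
  }
  list(model = cv, selectedFeatures = sel,
       coefficients = coefs[coefs != 0], intercept = beta[1L, 1L],
       alpha = alpha, lambda = cv$lambda.min, cvR = cvR,
       cvPredictions = oof, geneMeans = mu[keep], geneSds = sdv[keep],
       predict = predictFun)
}

#' Compare sensitivity predictors on one cohort
#'
#' Evaluates the pathway score, the housekeeping CTRL score, an
#' elastic-net expression model and mutation status as predictors of
#' drug sensitivity on the same lines. Truth labels come from the 1 uM
#' IC50 rule ([classifySensitivity()]); continuous predictors are
#' dichotomized at their cohort median (scores: high = sensitive;
#' elastic-net predicted viability: low = sensitive, taken from
#' out-of-fold predictions so the model is not graded on its training
#' fit). Each predictor row carries the confusion metrics and the
#' Spearman correlation with measured sensitivity (1 - MV).
#'
#' @param zscored an [MpasExperiment-class] in state \code{"zscored"}
#'   (used for MPAS/CTRL).
#' @param sensitivity data.frame with columns \code{line_id},
#'   \code{ic50}, \code{mean_viability} and optionally \code{mutant}
#'   (0/1), rows matching the matrix columns.
#' @param predictors subset of \code{c("mpas", "ctrl", "enet",
#'   "mutation")}.
#' @param sig pathway signature for the score predictor.
#' @param logExpr matrix for the elastic-net fit (state
#'   \code{"log_transformed"}); defaults to \code{zscored}.
#' @param seed seed for the elastic-net fold assignment.
#' @return data.frame: predictor, tp, fp, tn, fn, tpr, fpr, acc,
#'   spearman_rho, p.
#' @export
comparePredictors <- function(zscored, sensitivity,
                              predictors = c("mpas", "ctrl", "enet",
                                             "mutation"),
                              sig = mpasSignature(), logExpr = zscored,
                              seed = 1) {
  stopifnot(is(zscored, "MpasExperiment"))
  predictors <- match.arg(predictors, several.ok = TRUE)
  ids <- colnames(zscored)
  if (!all(ids %in% sensitivity$line_id))
    stop("sensitivity table missing lines: ",
         paste(setdiff(ids, sensitivity$line_id), collapse = ", "))
  sens <- sensitivity[match(ids, sensitivity$line_id), ]
  truth <- classifySensitivity(sens$ic50) == "sensitive"
  measured <- 1 - sens$mean_viability
  rows <- list()
  evalOne <- function(name, predictedPositive, continuous) {
    cm <- confusionMetrics(predictedPositive, truth)
    rc <- tryCatch(rankCorrelation(continuous, measured),
                   error = function(e) list(rho = NA_real_, p = NA_real_))
    data.frame(predictor = name, tp = cm$tp, fp = cm$fp, tn = cm$tn,
               fn = cm$fn, tpr = cm$tpr, fpr = cm$fpr, acc = cm$acc,
               spearman_rho = rc$rho, p = rc$p)
  }
  if ("mpas" %in% predictors) {
    s <- scores(computeScore(zscored, sig, missing = "subset"))
    rows$mpas <- evalOne("mpas", medianClassify(s), s)
  }
  if ("ctrl" %in% predictors) {
    s <- scores(computeCtrlScore(zscored, missing = "subset"))
    rows$ctrl <- evalOne("ctrl", medianClassify(s), s)
  }
  if ("enet" %in% predictors) {
    fit <- fitEnet(logExpr, sens$mean_viability, seed = seed)
    pred <- fit$cvPredictions
    rows$enet <- evalOne("enet",
                         medianClassify(pred,
                                        direction = "low_is_positive"),
                         -pred)
  }
  if ("mutation" %in% predictors) {
    if (is.null(sens$mutant))
      stop("'mutation' predictor requires a 'mutant' column")
    rows$mutation <- evalOne("mutation", mutationAsPredictor(sens$mutant),
                             sens$mutant + 0)
  }
  out <- do.call(rbind, rows[predictors])
  rownames(out) <- NULL
  out
}
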