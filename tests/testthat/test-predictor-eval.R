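test_that("median classification labels strictly-above-median as positive", {
  expect_equal(unname(medianClassify(c(a = 1, b = 2, c = 3, d = 4))),
               c(FALSE, FALSE, TRUE, TRUE))
  # ties at the median are negative
  expect_equal(unname(medianClassify(c(1, 2, 2, 3))),
               c(FALSE, FALSE, FALSE, TRUE))
  # low_is_positive flips the tail
  expect_equal(unname(medianClassify(c(1, 2, 3, 4),
                                     direction = "low_is_positive")),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_error(medianClassify(c(2, 2, 2)), "identical")
  # distinct scores give exactly floor(n/2) positives
  set.seed(21)
  for (n in c(5, 8, 13, 20)) {
    s <- sample(seq_len(100), n)
    expect_identical(sum(medianClassify(s)), as.integer(floor(n / 2)))
  }
})

test_that("confusion metrics reproduce the worked 8-line example exactly", {
  truth <- c("sensitive", "sensitive", "sensitive", "resistant",
             "resistant", "resistant", "resistant", "resistant")
  predicted <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE)
  cm <- confusionMetrics(predicted, truth)
  expect_identical(c(cm$tp, cm$fn, cm$fp, cm$tn), c(2L, 1L, 2L, 3L))
  expect_equal(cm$tpr, 2 / 3)
  expect_equal(cm$fpr, 0.4)
  expect_equal(cm$acc, 0.625)
})

test_that("confusion metrics agree with exhaustive counting for n <= 6", {
  checkOne <- function(p, t) {
    cm <- confusionMetrics(p, t)
    n <- length(p)
    # brute-force counts
    tp <- 0L; fp <- 0L; tn <- 0L; fn <- 0L
    for (j in seq_len(n)) {
      if (p[j] && t[j]) tp <- tp + 1L
      else if (p[j] && !t[j]) fp <- fp + 1L
      else if (!p[j] && t[j]) fn <- fn + 1L
      else tn <- tn + 1L
    }
    sameNa <- function(a, b) (is.na(a) && is.na(b)) ||
      (!is.na(a) && !is.na(b) && abs(a - b) < 1e-12)
    identical(c(cm$tp, cm$fp, cm$tn, cm$fn), c(tp, fp, tn, fn)) &&
      cm$tp + cm$fp + cm$tn + cm$fn == cm$n &&
      abs(cm$acc - (tp + tn) / n) < 1e-12 &&
      sameNa(cm$tpr, if (tp + fn > 0) tp / (tp + fn) else NA) &&
      sameNa(cm$fpr, if (fp + tn > 0) fp / (fp + tn) else NA)
  }
  for (n in c(3L, 6L)) {
    combos <- expand.grid(rep(list(c(FALSE, TRUE)), 2 * n))
    ok <- vapply(seq_len(nrow(combos)), function(i)
      checkOne(as.logical(combos[i, 1:n]),
               as.logical(combos[i, (n + 1):(2 * n)])),
      logical(1))
    expect_true(all(ok))
  }
})

test_that("mutation predictor: FPR 0 when mutants are all truly sensitive", {
  truth <- c(rep("sensitive", 4), rep("resistant", 4))
  flags <- c(1, 1, 0, 0, 0, 0, 0, 0)   # mutants subset of the sensitive
  cm <- confusionMetrics(mutationAsPredictor(flags), truth)
  expect_equal(cm$fpr, 0)
  expect_gt(cm$fn, 0)                  # wild-type sensitives missed
  # no mutants: TPR 0, accuracy = prevalence of resistant
  cm0 <- confusionMetrics(mutationAsPredictor(rep(0, 8)), truth)
  expect_equal(cm0$tpr, 0)
  expect_equal(cm0$acc, 0.5)
  expect_error(mutationAsPredictor(c(0, 2)), "0/1")
})

test_that("rank correlation equals Pearson on ranks with asymptotic p", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8, 9.7, 9.3)
  y <- c(2, 7, 1, 8, 2.8, 1.8, 2.9, 0.5, 0.77, 1.1)
  rc <- rankCorrelation(x, y)
  rho0 <- cor(rank(x), rank(y))
  expect_equal(rc$rho, rho0, tolerance = 1e-12)
  tstat <- rho0 * sqrt((10 - 2) / (1 - rho0^2))
  expect_equal(rc$p, 2 * pt(-abs(tstat), 8), tolerance = 1e-10)
  expect_equal(rankCorrelation(x, x)$rho, 1)
  expect_equal(rankCorrelation(x, -x)$rho, -1)
  expect_error(rankCorrelation(x, rep(1, 10)), "constant")
  expect_error(rankCorrelation(x[1:2], y[1:2]), "n >= 3")
})

test_that("percentile in reference is top-oriented and monotone", {
  ref <- seq(0.1, 0.9, by = 0.1)
  expect_equal(percentileInReference(0.65, ref), 100 * 3 / 9)
  expect_equal(percentileInReference(0.95, ref), 0)
  expect_equal(percentileInReference(0.05, ref), 100)
  vals <- seq(-1, 1, by = 0.05)
  pct <- vapply(vals, percentileInReference, numeric(1), ref = ref)
  expect_true(all(diff(pct) <= 0))
})

test_that("elastic net recovers a noiseless sparse linear response", {
  set.seed(31)
  n <- 200; g <- 50
  v <- matrix(rnorm(n * g), g, n,
              dimnames = list(sprintf("G%03d", 1:g),
                              sprintf("s%03d", 1:n)))
  m <- mpasExperiment(v + 10, platform = "rnaseq",
                      state = "log_transformed")
  y <- 2 * v["G001", ] - 1.5 * v["G002", ] + 0.8 * v["G003", ]
  fit <- fitEnet(m, y, seed = 1)
  expect_true(all(c("G001", "G002", "G003") %in% fit$selectedFeatures))
  expect_gt(fit$cvR, 0.99)
  # predictions invariant to per-gene affine rescaling of input
  v2 <- v * 3 + 100
  m2 <- mpasExperiment(v2, platform = "rnaseq",
                       state = "log_transformed")
  fit2 <- fitEnet(m2, y, seed = 1)
  expect_equal(fit2$cvPredictions, fit$cvPredictions, tolerance = 1e-8)
})

test_that("elastic net on a permuted response has near-zero CV correlation", {
  sim <- simulateCohort(cohortConfig(), seed = 2)
  lt <- logTransform(sim$expr)
  y <- sim$sensitivity$mean_viability
  yPerm <- y[mpascore:::withSeed(99, sample.int(length(y)))]
  fit <- fitEnet(lt, yPerm, seed = 1)
  expect_lt(abs(fit$cvR), 0.25)
  expect_error(fitEnet(lt[, 1:20], y[1:20], seed = 1), ">= 30")
})

test_that("predictor comparison ranks MPAS above CTRL on coupled cohorts", {
  sim <- simulateCohort(cohortConfig(nSamples = 40), seed = 7)
  ev <- comparePredictors(sim$zscored, sim$sensitivity,
                          predictors = c("mpas", "ctrl"), seed = 7)
  expect_gt(ev$acc[ev$predictor == "mpas"],
            ev$acc[ev$predictor == "ctrl"])
  # perfect coupling, no noise, balanced truth: MPAS classifies perfectly
  cfgPerfect <- cohortConfig(nSamples = 40, sigmaG = 0,
                             sensNoiseSd = 0, ic50NoiseSd = 0)
  a <- setNames(seq(-1, 1, length.out = 40), sprintf("S%04d", 1:40))
  sensP <- generateSensitivity(cfgPerfect, a, seed = 1)
  z <- zscoreGenes(zMatrix(
    outer(rep(1, 10), a) + 5, genes = mpasSignature()@genes,
    samples = names(a), state = "log_transformed"),
    zeroVariance = "zero")
  evP <- comparePredictors(z, sensP, predictors = "mpas", seed = 1)
  expect_equal(evP$acc, 1)
})

test_that("MPAS accuracy rises with the activity-sensitivity coupling", {
  accAt <- function(k, seeds) {
    vapply(seeds, function(s) {
      sim <- simulateCohort(cohortConfig(nSamples = 40, sensK = k,
                                         ic50Slope = 0.5 * k / 1.5),
                            seed = s)
      ev <- comparePredictors(sim$zscored, sim$sensitivity,
                              predictors = "mpas", seed = s)
      ev$acc
    }, numeric(1))
  }
  seeds <- 1:50
  a <- vapply(c(0.3, 1.5, 6), accAt, numeric(length(seeds)),
              seeds = seeds)
  means <- colMeans(a)
  expect_true(all(diff(means) > 0))
})
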