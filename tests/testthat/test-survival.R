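test_that("KM estimator matches the hand product-limit computation", {
  km <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2/3, 1/3, 0), tolerance = 1e-12)
  expect_equal(km$median, 2)
  # no events: flat at 1, median undefined
  km0 <- kmEstimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km0$surv == 1))
  expect_true(is.na(km0$median))
  # censored random data vs oracle
  set.seed(41)
  t <- round(rexp(60, 0.2), 3) + 0.001
  e <- rbinom(60, 1, 0.7)
  km2 <- kmEstimate(t, e)
  orc <- kmOracle(t, e)
  expect_equal(km2$surv[km2$fit$n.event > 0], orc$surv,
               tolerance = 1e-12)
  # never increases, starts at 1
  expect_true(all(diff(km2$surv) <= 1e-12))
  expect_true(km2$surv[1] <= 1)
  expect_error(kmEstimate(numeric(0), numeric(0)), "empty")
})

test_that("Cox fit matches numeric maximization of the partial likelihood", {
  tbl <- clinicalTable(data.frame(
    sample_id = paste0("p", 1:4),
    time = c(1, 2, 3, 4), event = c(1, 1, 1, 0), x = c(1, 0, 1, 0)))
  cf <- coxFit(tbl, "x")
  opt <- optimize(function(b)
    coxPartialLogLik(b, c(1, 2, 3, 4), c(1, 1, 1, 0), c(1, 0, 1, 0)),
    c(-5, 5), maximum = TRUE)
  expect_equal(coxTable(cf)$beta, opt$maximum, tolerance = 1e-5)
  expect_equal(cf@loglik, opt$objective, tolerance = 1e-6)
  expect_equal(coxTable(cf)$hr, exp(coxTable(cf)$beta), tolerance = 1e-12)
  # log-rank p reported for the single binary term
  expect_false(is.na(cf@logrankP))
})

test_that("Breslow ties: duplicating every record leaves beta unchanged", {
  set.seed(42)
  d <- data.frame(sample_id = sprintf("p%03d", 1:80),
                  time = round(rexp(80, 0.1), 1) + 0.1,
                  event = rbinom(80, 1, 0.7), x = rnorm(80))
  b1 <- coxTable(coxFit(clinicalTable(d), "x"))$beta
  d2 <- rbind(d, transform(d, sample_id = paste0(sample_id, "b")))
  b2 <- coxTable(coxFit(clinicalTable(d2), "x"))$beta
  expect_equal(b1, b2, tolerance = 1e-9)
})

test_that("Cox fit rejects degenerate covariates and flags separation", {
  d <- data.frame(sample_id = paste0("p", 1:6),
                  time = c(1, 2, 3, 4, 5, 6), event = rep(1, 6),
                  const = 1, x = c(1, 1, 1, 0, 0, 0))
  expect_error(coxFit(clinicalTable(d), "const"), "constant")
  # early deaths all in one group: monotone likelihood
  cfSep <- coxFit(clinicalTable(d), "x")
  expect_false(cfSep@converged)
  # collinear terms named in the error
  d$y <- d$x + 1
  expect_error(multivariateSurvivalReport(clinicalTable(d), c("x", "y")),
               "collinear")
})

test_that("null Cox fit is well calibrated over seeds", {
  hits <- 0L; betas <- numeric(100)
  for (s in 1:100) {
    set.seed(600 + s)
    n <- 500
    x <- rnorm(n)
    t <- rexp(n, 0.1)
    cens <- runif(n, 0, 30)
    d <- data.frame(sample_id = seq_len(n), time = pmin(t, cens),
                    event = as.integer(t <= cens), x = x)
    tab <- coxTable(coxFit(clinicalTable(d), "x"))
    betas[s] <- tab$beta
    if (tab$ci_low <= 1 && tab$ci_high >= 1) hits <- hits + 1L
  }
  expect_lt(abs(mean(betas)), 0.05)
  expect_gte(hits, 90L)
})

test_that("median dichotomization uses the strictly-above rule", {
  expect_equal(unname(medianDichotomize(c(-1, 0, 1, 2))),
               c("low", "low", "high", "high"))
  expect_equal(unname(medianDichotomize(c(1, 2, 3))),
               c("low", "low", "high"))
  set.seed(43)
  s <- sample(seq_len(50), 21)
  expect_identical(sum(medianDichotomize(s) == "high"), 10L)
})

test_that("threshold scan at the 50th percentile equals median dichotomization", {
  cfg <- cohortConfig(nSamples = 120)
  sim <- simulateCohort(cfg, seed = 9)
  s <- scores(sim$scores)
  scan <- kmThresholdScan(sim$clinical, s)
  row50 <- scanTable(scan)[scanTable(scan)$position_pct == 50, ]
  labels <- medianDichotomize(s)
  d <- clinicalData(sim$clinical)
  tmp <- clinicalTable(data.frame(d[c("sample_id", "time", "event")],
                                  grp = as.integer(labels == "high")))
  direct <- coxTable(coxFit(tmp, "grp"))
  expect_identical(row50$n_high, sum(labels == "high"))
  expect_equal(row50$hr, direct$hr, tolerance = 1e-12)
  # grid covers 10..90 inclusive
  expect_equal(range(scanTable(scan)$position_pct), c(10, 90))
})

test_that("sliding window scan covers positions 15 to 85 at defaults", {
  cfg <- cohortConfig(nSamples = 200)
  sim <- simulateCohort(cfg, seed = 10)
  scan <- slidingWindowScan(sim$clinical, sim$scores)
  pos <- scanTable(scan)$position_pct
  expect_equal(pos[1], 15)
  expect_equal(pos[length(pos)], 85)
  expect_equal(diff(pos), rep(2, length(pos) - 1))
  # first window holds the lowest 30% of samples
  expect_equal(scanTable(scan)$n_high[1], 60L)
  expect_error(slidingWindowScan(sim$clinical, sim$scores,
                                 windowPct = 30, stepPct = 80),
               "window")
})

test_that("protective score yields lower hazard in high-score windows", {
  ok <- 0L
  for (s in 1:30) {
    cfg <- cohortConfig(nSamples = 300, betaSurv = -log(2))
    sim <- simulateCohort(cfg, seed = 2000 + s)
    scan <- scanTable(slidingWindowScan(sim$clinical, sim$scores))
    hr15 <- scan$hr[scan$position_pct == 15]
    hr85 <- scan$hr[scan$position_pct == 85]
    if (!is.na(hr15) && !is.na(hr85) && hr85 < hr15) ok <- ok + 1L
  }
  expect_gte(ok, 27L)
})

test_that("binomial death test matches exact binomial arithmetic", {
  # 10 of 10 deaths in a half-sized high group
  d <- data.frame(sample_id = paste0("p", 1:20),
                  time = c(rep(1, 10), rep(5, 10)),
                  event = c(rep(1, 10), rep(0, 10)))
  g <- setNames(rep(c("high", "low"), each = 10), d$sample_id)
  p <- binomialDeathTest(clinicalTable(d), g)
  expect_equal(p, 2 * 0.5^10, tolerance = 1e-12)
  # proportional split is maximally compatible
  d2 <- data.frame(sample_id = paste0("p", 1:20),
                   time = rep(1, 20),
                   event = rep(c(1, 0), 10))
  g2 <- setNames(rep(c("high", "low"), each = 10), d2$sample_id)
  expect_equal(binomialDeathTest(clinicalTable(d2), g2), 1)
  # enumeration oracle for K <= 12
  for (K in c(5L, 12L)) {
    nHigh <- 8L; n <- 20L
    p0 <- nHigh / n
    for (k in c(0L, 3L, min(K, nHigh))) {
      dd <- data.frame(
        sample_id = seq_len(n),
        time = rep(1, n),
        event = c(rep(1, k), rep(0, nHigh - k),
                  rep(1, K - k), rep(0, n - nHigh - (K - k))))
      gg <- rep(c("high", "low"), c(nHigh, n - nHigh))
      pv <- binomialDeathTest(clinicalTable(dd), gg)
      pmf <- dbinom(0:K, K, p0)
      expected <- sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)])
      expect_equal(pv, min(1, expected), tolerance = 1e-9)
    }
  }
  dNo <- data.frame(sample_id = 1:4, time = 1:4, event = rep(0, 4))
  expect_error(binomialDeathTest(clinicalTable(dNo),
                                 rep(c("high", "low"), 2)), "death")
})

test_that("multivariate fit separates score and null subtype effects", {
  covers1 <- 0L; excludes1 <- 0L
  for (s in 1:30) {
    cfg <- cohortConfig(nSamples = 300, betaSurv = log(1.6))
    sim <- simulateCohort(cfg, seed = 3000 + s)
    cf <- coxTable(multivariateSurvivalReport(sim$clinical,
                                              c("score", "subtype")))
    rowScore <- cf[cf$term == "score", ]
    rowSub <- cf[cf$term == "subtype", ]
    if (rowScore$ci_low > 1) excludes1 <- excludes1 + 1L
    if (rowSub$ci_low <= 1 && rowSub$ci_high >= 1) covers1 <- covers1 + 1L
  }
  expect_gte(excludes1, 24L)  # >= 80% of seeds
  expect_gte(covers1, 24L)
  # joint fit with one term equals the univariate fit
  sim <- simulateCohort(cohortConfig(nSamples = 150), seed = 11)
  expect_equal(coxTable(multivariateSurvivalReport(sim$clinical, "score")),
               coxTable(coxFit(sim$clinical, "score")))
})
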