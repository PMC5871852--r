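test_that("round-trip through TSV/CSV preserves values and structure", {
  v <- matrix(c(1.5, 2, 3, 10, 20.25, 30), 3, 2,
              dimnames = list(c("DUSP6", "etv4", "MLH1"), c("s1", "s2")))
  m <- mpasExperiment(v, platform = "panel")
  expect_equal(dim(m), c(3L, 2L))
  expect_identical(exprState(m), "raw")
  expect_identical(rownames(m), c("DUSP6", "ETV4", "MLH1"))  # upper-cased
  for (fmt in c("tsv", "csv")) {
    path <- tempfile(fileext = paste0(".", fmt))
    writeExpression(m, path, format = fmt)
    back <- readExpression(path, format = fmt, platform = "panel")
    expect_equal(exprValues(back), exprValues(m), tolerance = 1e-12)
  }
})

test_that("malformed expression files are rejected with informative errors", {
  dup <- tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "DUSP6\t1\t2", "dusp6\t3\t4"), dup)
  expect_error(readExpression(dup, platform = "panel"), "DUSP6")

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "DUSP6\t1\tx"), bad)
  expect_error(readExpression(bad, platform = "panel"),
               "non-numeric.*DUSP6.*s2")
})

test_that("background filtering floors at max(10, per-sample control geomean)", {
  m <- panelCounts()
  f <- filterBackground(m, c("NEG_A", "NEG_B", "NEG_C"))
  expect_identical(exprState(f), "background_filtered")
  # control rows removed
  expect_false(any(grepl("^NEG_", rownames(f))))
  # per-sample floors: geomean of controls vs 10
  v <- exprValues(m)
  gm <- apply(v[c("NEG_A", "NEG_B", "NEG_C"), ], 2, function(x)
    exp(mean(log(x))))
  floors <- pmax(10, gm)
  # sample 1 controls (4, 9, 25): geomean ~ 9.65 -> floor 10
  expect_equal(unname(gm[1]), (4 * 9 * 25)^(1/3), tolerance = 1e-12)
  expect_equal(unname(floors[1]), 10)
  out <- exprValues(f)
  for (j in seq_len(ncol(out)))
    expect_true(all(out[, j] >= floors[j]))
  # a count of 9 under floor 10 becomes 10
  v2 <- matrix(c(9, 50, 4, 9, 25), 5, 1,
               dimnames = list(c("DUSP6", "ETV4", "NEG_A", "NEG_B",
                                 "NEG_C"), "s1"))
  m2 <- mpasExperiment(v2, platform = "panel")
  f2 <- filterBackground(m2, c("NEG_A", "NEG_B", "NEG_C"))
  expect_equal(exprValues(f2)["DUSP6", "s1"], 10)
  # counts already above the floor pass through unchanged
  expect_equal(exprValues(f2)["ETV4", "s1"], 50)
})

test_that("background filtering is idempotent and warns without controls", {
  m <- panelCounts()
  f1 <- filterBackground(m, c("NEG_A", "NEG_B", "NEG_C"))
  # second pass (controls gone) warns, values unchanged
  raw2 <- mpasExperiment(exprValues(f1), platform = "panel")
  expect_warning(f2 <- filterBackground(raw2, c("NEG_A", "NEG_B", "NEG_C")),
                 "fixed floor 10")
  expect_equal(exprValues(f2), exprValues(f1))
})

test_that("housekeeping normalization equalizes per-sample housekeeping geomeans", {
  hk <- ctrlSignature()@genes
  m <- panelCounts()
  f <- filterBackground(m, c("NEG_A", "NEG_B", "NEG_C"))
  nrm <- normalizeHousekeeping(f, hk)
  expect_identical(exprState(nrm), "normalized")
  gms <- apply(exprValues(nrm)[hk, ], 2, function(x) exp(mean(log(x))))
  expect_equal(unname(diff(range(gms))), 0, tolerance = 1e-10)
  # per-sample rescaling is absorbed up to one global reference factor
  v2 <- exprValues(f)
  v2[, 2] <- v2[, 2] * 2
  f2 <- mpasExperiment(v2, platform = "panel",
                       state = "background_filtered")
  nrm2 <- normalizeHousekeeping(f2, hk)
  ratio <- exprValues(nrm2) / exprValues(nrm)
  expect_equal(unname(diff(range(ratio))), 0, tolerance = 1e-12)
  # a sample that is an exact multiple of another becomes identical to it
  v3 <- exprValues(f)
  v3[, 2] <- v3[, 1] * 2
  nrm3 <- normalizeHousekeeping(
    mpasExperiment(v3, platform = "panel",
                   state = "background_filtered"), hk)
  expect_equal(exprValues(nrm3)[, 2], exprValues(nrm3)[, 1],
               tolerance = 1e-12, ignore_attr = TRUE)
  # missing housekeeping gene is an error naming it
  expect_error(normalizeHousekeeping(f, c(hk, "NOSUCHGENE")),
               "NOSUCHGENE")
})

test_that("log transform is log2(x+1) and preserves within-gene ranking", {
  v <- matrix(c(0, 7, 3, 1, 15, 255), 2, 3,
              dimnames = list(c("A1", "B1"), paste0("s", 1:3)))
  m <- mpasExperiment(v, platform = "rnaseq", state = "raw")
  lt <- logTransform(m)
  expect_equal(exprValues(lt)["A1", "s1"], 0)
  expect_equal(exprValues(lt)["B1", "s1"], 3)    # log2(8)
  expect_equal(exprValues(lt), log2(v + 1))
  for (g in rownames(v))
    expect_identical(rank(exprValues(lt)[g, ]), rank(v[g, ]))
})

test_that("z-scoring uses population sd and matches direct recomputation", {
  m <- zMatrix(matrix(c(5, 9), 1, 2), genes = "G01",
               state = "log_transformed")
  z <- zscoreGenes(m)
  expect_equal(unname(exprValues(z)[1, ]), c(-1, 1))
  # random matrix oracle
  set.seed(7)
  v <- matrix(rnorm(200), 10, 20)
  mo <- zMatrix(v, state = "log_transformed")
  z2 <- exprValues(zscoreGenes(mo))
  for (i in seq_len(nrow(v))) {
    mu <- mean(v[i, ]); sdv <- sqrt(mean((v[i, ] - mu)^2))
    expect_equal(unname(z2[i, ]), (v[i, ] - mu) / sdv, tolerance = 1e-12)
  }
  expect_true(all(abs(rowMeans(z2)) < 1e-10))
  expect_true(all(abs(sqrt(rowMeans(z2^2)) - 1) < 1e-10))
  # idempotence within tolerance
  z2m <- zMatrix(z2, state = "log_transformed")
  expect_equal(exprValues(zscoreGenes(z2m)), z2, tolerance = 1e-10)
})

test_that("z-scoring handles degenerate inputs per the zeroVariance mode", {
  m <- zMatrix(matrix(c(3, 3, 3), 1, 3), genes = "FLAT",
               state = "log_transformed")
  expect_error(zscoreGenes(m), "FLAT")
  expect_warning(z <- zscoreGenes(m, zeroVariance = "zero"),
                 "zero-variance")
  expect_equal(unname(exprValues(z)[1, ]), c(0, 0, 0))
  one <- zMatrix(matrix(1.5, 1, 1), genes = "G",
                 state = "log_transformed")
  expect_error(zscoreGenes(one), ">= 2 samples")
})

test_that("state transitions are monotone and enforced", {
  m <- panelCounts()
  expect_error(normalizeHousekeeping(m, ctrlSignature()@genes),
               "requires state")
  expect_error(zscoreGenes(m), "requires state")
  f <- filterBackground(m, c("NEG_A", "NEG_B", "NEG_C"))
  expect_error(filterBackground(f, c("NEG_A")), "requires state")
})
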