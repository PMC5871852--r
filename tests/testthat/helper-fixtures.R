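# shared fixtures built in code

# z-scored matrix wrapping arbitrary values (no processing chain)
zMatrix <- function(values, genes = NULL, samples = NULL,
                    state = "zscored") {
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  mpasExperiment(values, platform = "rnaseq", state = state)
}

# matrix whose 10 signature-gene rows take value -1/+1 across 2 samples
twoSampleSignatureMatrix <- function() {
  v <- matrix(rep(c(5, 9), times = 10), 10, 2, byrow = TRUE,
              dimnames = list(mpasSignature()@genes, c("lo", "hi")))
  mpasExperiment(v, platform = "rnaseq", state = "log_transformed")
}

# small panel count matrix with negative-control and housekeeping rows
panelCounts <- function() {
  genes <- c("DUSP6", "ETV4", "SPRY2", mpascore::ctrlSignature()@genes,
             "NEG_A", "NEG_B", "NEG_C")
  set.seed(42)
  v <- matrix(round(runif(length(genes) * 4, 20, 400)), length(genes), 4,
              dimnames = list(genes, paste0("s", 1:4)))
  v["NEG_A", ] <- c(4, 5, 6, 7)
  v["NEG_B", ] <- c(9, 8, 10, 12)
  v["NEG_C", ] <- c(25, 6, 9, 11)
  mpasExperiment(v, platform = "panel", state = "raw")
}

# independent product-limit recomputation (oracle for kmEstimate)
kmOracle <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  s <- 1
  surv <- numeric(length(ut))
  for (i in seq_along(ut)) {
    atRisk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events == 1)
    s <- s * (1 - d / atRisk)
    surv[i] <- s
  }
  list(time = ut, surv = surv)
}

# hand-written Breslow partial log-likelihood for a single covariate
coxPartialLogLik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}
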