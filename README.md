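# mpascore

Transcriptional pathway-activity scoring for the RAS–RAF–MEK–ERK (MAPK)
cascade, and the statistical machinery to evaluate such a score as a
drug-sensitivity predictor and a prognostic biomarker.

Mutations in RTK/RAS/RAF genes are routinely used to select patients for
MAPK-targeted therapy, yet pathway output is shaped by feedback,
epigenetics and cellular context, so genotype and actual pathway
activity often disagree. A direct transcriptional readout — the
aggregate expression of canonical ERK target genes — summarizes the
pathway's signalling flux in a single per-sample number. `mpascore`
implements that readout and everything needed to stress-test it.

## The score

For a cohort expression matrix, each gene is z-scored across samples and
the MAPK pathway activity score of sample *s* is

```
MPAS_s = ( Σ_{i=1..n} z_is ) / √n ,    n = 10
```

over the ten ERK target genes *PHLDA1, SPRY2, SPRY4, DUSP4, DUSP6,
CCND1, EPHA2, EPHA4, ETV4, ETV5*. A negative-control CTRL score is
built identically from four housekeeping genes (*MLH1, SMARCA4, U2AF,
CLTC*); it carries the pipeline's noise but no pathway signal and
anchors chance-level performance. Scores are relative quantities within
a cohort — the √n denominator keeps them comparable across signatures of
different size, and cohort-z-scored input makes them sum to zero.

Around the score the package provides:

* **Expression I/O and normalization** — TSV/CSV matrices; for count
  panels, background flooring at `max(10, geometric mean of
  negative-control counts)` per sample, housekeeping geometric-mean
  normalization; `log2(x+1)`; population-sd gene z-scoring. Processing
  states are tracked and enforced (`raw → background_filtered →
  normalized → log_transformed → zscored`).
* **Dose–response** — day-0-corrected relative viability (1 = vehicle
  growth, 0 = stasis, negative = cell death), deterministic multi-start
  4-parameter-logistic fits (IC50, Hill), mean viability (MV), the
  strict 1 µM sensitive/resistant rule, and dose-dependent score
  inhibition profiles.
* **Predictor evaluation** — median-based classification, confusion
  metrics (TPR, FPR, ACC), Spearman rank correlations, percentile
  placement in a benchmark distribution, and an elastic-net expression
  model (α = 0.5, λ by 5-fold CV) as the multivariate comparator.
* **Survival** — Cox proportional-hazards fits (Breslow ties, Wald CIs,
  log-rank p), Kaplan–Meier estimates, median dichotomization,
  threshold scans over the 10th–90th score percentiles, sliding
  percentile-window hazard scans, and an exact binomial test of the
  death share in the score-high group.
* **Synthetic cohorts** — a seeded generator in which a latent
  per-sample activity factor drives signature-gene expression, drug
  sensitivity (MV, IC50) and survival hazard, with housekeeping genes
  independent of it; every analysis is testable against planted ground
  truth.

## Worked example

```r
library(mpascore)

sim <- simulateCohort(cohortConfig(nSamples = 100), seed = 1)
sim$scores
#> ScoreTable 'MPAS': 100 samples, 10 genes aggregated
#>   sample_id      score
#> 1     S0001 -2.5231585
#> 2     S0002  0.9305131
#> 3     S0003 -3.3912009
#> ...

coxFit(sim$clinical, "score")
#> CoxFit (loglik = -225.364)
#>   term   beta    hr ci_low ci_high      se         p
#>  score 0.4345 1.544  1.382   1.725 0.05654 1.532e-14

comparePredictors(sim$zscored, sim$sensitivity, seed = 1)
#>   predictor tp fp tn fn   tpr   fpr  acc spearman_rho        p
#> 1      mpas 38 12 36 14 0.731 0.250 0.74        0.884 3.50e-34
#> 2      ctrl 27 23 25 25 0.519 0.479 0.52       -0.128 2.04e-01
#> 3      enet 39 11 37 13 0.750 0.229 0.76        0.868 1.65e-31
#> 4  mutation 20 14 34 32 0.385 0.292 0.54        0.215 3.17e-02
```

The simulated cohort plants a hazard ratio of 1.5 per score unit; the
univariate Cox fit recovers HR = 1.54 (95% CI 1.38–1.73). In the
predictor table the pathway score and the elastic net classify
sensitivity far above chance (ACC 0.74 and 0.76) while the
housekeeping CTRL score sits at chance (0.52) and mutation status adds
little (0.54) — mutation calls the mutant lines sensitive, which is
specific but misses sensitive wild-type lines.

A full run (simulate → score → evaluate → survive) with provenance
headers on every artifact:

```r
runPipeline(list(simulate = list(nSamples = 100)), "out/", seed = 1)
```

or from a shell via `inst/scripts/run-pipeline.R --config cohort.yaml
--out-dir out/ --seed 1`.

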