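---
title: "Pathway-activity scoring and biomarker evaluation: methods and design"
author: "mpascore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-activity scoring and biomarker evaluation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpascore)
```

## The model

The package's central quantity is an aggregated transcriptional
pathway-activity score. Given a genes × samples expression matrix, each
gene is z-scored across the cohort and sample *s* receives

$$\mathrm{score}_s = \frac{\sum_{i=1}^{n} z_{is}}{\sqrt{n}},$$

with $n = 10$ for the MAPK signature (*PHLDA1, SPRY2, SPRY4, DUSP4,
DUSP6, CCND1, EPHA2, EPHA4, ETV4, ETV5*) and $n = 4$ for the
housekeeping negative control (*MLH1, SMARCA4, U2AF, CLTC*). The
underlying assumption is that ERK pathway output is reflected in the
coordinated expression of its direct target genes, so an unweighted
aggregate — no regression coefficients, no training step — already
captures most of the usable signal, while the $\sqrt{n}$ denominator
gives scores a comparable scale across signatures of different size:
if the $z_i$ were independent standard normals the score would itself
be standard normal for any $n$.

Two consequences matter in practice. First, the score is *relative*:
z-scoring is performed within a cohort, so absolute values depend on
cohort composition, platform and normalization, and only within-cohort
comparisons are meaningful. `recenterScores()` shifts scores against a
named reference cohort for display. Second, with the population
(divisor-$N$) standard deviation in the z-score, a two-sample cohort
gives $z = \pm 1$ per gene exactly, hence scores of $\pm\sqrt{n}$ —
a convenient analytic anchor used in the tests.

## Processing chain and its parameters

`MpasExperiment` tracks a processing `state` along
`raw → background_filtered → normalized → log_transformed → zscored`;
each step validates its input state so mis-ordered pipelines fail
immediately.

* **Background flooring (panels).** Count panels have a detection
  floor. Per sample the floor is `max(10, geometric mean of the
  negative-control gene counts)`; counts below it are set to the floor.
  Flooring rather than dropping keeps the matrix rectangular, which the
  downstream z-scoring requires; the fixed constant 10 reflects the
  count level below which panel measurements are noise. When no
  negative-control genes are present the constant alone is used, with a
  warning.
* **Housekeeping normalization (panels).** Sample $s$ is scaled by
  $f_s = G / g_s$, where $g_s$ is the geometric mean of the
  housekeeping counts in $s$ and $G$ the geometric mean over the whole
  matrix — standard panel practice. Note the global reference $G$: a
  multiplicative distortion of one sample is absorbed into that
  sample's factor, leaving between-sample structure invariant, though
  all absolute values shift by a common factor (which the subsequent
  z-scoring removes entirely).
* **Variance stabilization.** `log2(x + 1)`: rank-preserving, exact at
  0, and adequate for count-scale data ahead of z-scoring. Sequencing
  data arriving already normalized may be log-transformed directly
  from `raw`.
* **Z-scoring.** Population-sd, per gene, requiring ≥ 2 samples. A
  zero-variance gene is an error by default; `zeroVariance = "zero"`
  emits a zero row instead, which is the right behaviour inside the
  panel chain where flooring can flatten a gene.

Missing signature genes are a hard error by default. Targeted panels
often carry only 5–6 of the 10 genes, so `missing = "subset"`
aggregates the genes present and renormalizes by $\sqrt{n_\mathrm{used}}$,
recording $n_\mathrm{used}$; on synthetic cohorts 5-gene subset scores
correlate with full scores at $\rho \ge 0.7$, which is why the mode is
offered rather than forbidden. Whether renormalizing by
$\sqrt{n_\mathrm{used}}$ or keeping $\sqrt{10}$ is the better
convention is not decidable from first principles; renormalization was
chosen because it preserves the unit-variance heuristic above, and the
recorded $n_\mathrm{used}$ keeps the choice auditable.

## Dose–response

Viability is day-0-corrected and vehicle-relative:
$v(d) = (\mathrm{raw}(d) - \overline{day0}) / (\overline{vehicle} -
\overline{day0})$, so 1 is vehicle-level growth, 0 is stasis and
negative values are net cell death; values are deliberately not
clipped. Curves are fitted with the four-parameter logistic
$v(d) = b + (t - b)/(1 + (d/\mathrm{IC50})^{h})$ by least squares on
the replicate means, with a fixed deterministic multi-start grid
(Hill ∈ {0.5, 1, 2} × IC50 at every tested positive dose) so the same
data always yield the same fit. Flat or rising dose series are flagged
`noInhibition` with IC50 = ∞ rather than forced through a sigmoid, and
an IC50 more than 100× outside the tested range is flagged
`extrapolated`. Mean viability (MV) is the unweighted mean of
replicate-mean viabilities over the positive doses, with the dose grid
attached to the result so the averaging range is explicit — the tested
grid defines MV, and a different grid gives a different MV.
Sensitivity classification uses the strict rule IC50 < 1 µM
(clinically motivated by the drug's serum-concentration range); the
boundary value 1 µM and the ∞ sentinel are both resistant.

`mpasDoseProfile()` z-scores a treated dose series *within the line*
(doses as samples), computes the score per dose, and fits the same 4PL
to the score rescaled to [0, 1], allowing the transcriptional IC50 to
be compared with the growth IC50. On coupled synthetic series the two
agree within a factor of 2 by construction.

## Predictor evaluation

Continuous predictors are dichotomized at the cohort median with a
deterministic tie rule: strictly above the median is positive. The
evaluation cohort's own median is used (no training-derived cutoff is
carried across cohorts). For the elastic-net comparator the prediction
target is MV and *low* predicted viability means predicted sensitive;
classification uses the out-of-fold CV predictions, so the comparator
is not graded on its training fit. Confusion metrics are the standard
TPR = TP/(TP+FN), FPR = FP/(FP+TN), ACC = (TP+TN)/N, with
zero-denominator rates reported as `NA`. Rank correlations are
Spearman's ρ with average ranks and the large-sample t approximation
for p-values. Percentile placement in a benchmark distribution of
competitor correlations is top-oriented with strict inequality
(0 = beats everyone); without the competition's raw values any
interpolation rule is a convention, and this one is monotone and
exact at the reference points.

The elastic net uses mixing α = 0.5 and λ minimizing 5-fold
cross-validated squared error over a 100-point log-spaced grid spanning
$[\lambda_{max} \cdot 10^{-4}, \lambda_{max}]$. Genes are standardized
to mean 0, sd 1 before fitting, which removes absolute-expression bias
and makes predictions invariant to per-gene affine rescaling; fold
assignment derives from an explicit seed, so fits are reproducible.

## Survival analysis

Cox models maximize the partial likelihood with Breslow tie handling —
the simplest convention that makes replicated records a no-op, which
the tests exploit as an invariant. Each term carries
$\mathrm{HR} = e^{\beta}$, Wald 95% CI $e^{\beta \pm 1.96\,se}$ and
Wald p; for a single binary term the score-test (log-rank) p-value is
also reported, since both flavours are conventionally quoted.
Collinear and constant covariates are rejected by rank-checking the
model matrix before fitting, naming the offending term; monotone
likelihoods (perfect separation) are returned flagged rather than
hidden.

Two scan procedures probe how the choice of cutoff affects the hazard
estimate:

* **Threshold scan** — the high/low cutoff sweeps the 10th–90th score
  percentiles (step 5 by default, endpoints included); each position
  fits a univariate Cox model on the indicator `score > quantile`. The
  50th-percentile position coincides exactly with median
  dichotomization.
* **Sliding-window scan** — a window spanning 30 percentile points
  (15 is the common narrower variant) slides in 2-point steps, from the
  0–30 group (reported at its median position, 15) to 70–100 (position
  85). By default each window is contrasted against the *entire*
  cohort by stacking the window's records onto a full cohort copy;
  `comparison = "remainder"` instead fits the membership indicator
  within the cohort, contrasting members against non-members. Both
  conventions appear in applied work and they converge for narrow
  windows; offering both keeps the comparison explicit. The default
  window is 30 points, with 15 available, as both widths are in
  circulation for this procedure.

Grid positions where a hazard ratio is undefined (fewer than two events
on a side) are reported as `NA` rather than dropped, keeping scan
tables rectangular. The binomial death test asks whether the
score-high group's share of the K observed deaths is compatible with
its share of the cohort: exact two-sided binomial test of k deaths
among K at $p_0 = n_{high}/n$.

## The synthetic-cohort generator

The generator defines the conditions under which the package's claims
are tested. A latent activity $a_s \sim N(0, 1)$ drives:

* **Expression** — signature genes load on $a_s$ with coefficient 1
  and log-scale noise sd 0.5 (giving score–activity Spearman ρ ≈ 0.98
  at n = 200, comfortably above the 0.8 the tests demand);
  housekeeping and 36 filler genes have loading 0. Panel mode emits
  integer counts $\mathrm{round}(e^{c_0 + \beta_i a_s + \varepsilon}$)
  with gene baselines $c_0 \sim U(3.5, 5.5)$ — median counts of a few
  dozen to a few hundred, with a realistic sub-background tail — plus
  four negative-control genes near counts of 7.
* **Drug sensitivity** — $MV_s = \mathrm{logistic}(-1.5\,a_s) +
  N(0, 0.1)$, clipped to (−0.5, 1.5), and $\log_{10} IC50_s =
  -0.5\,a_s + N(0, 0.3)$, placing the cohort astride the 1 µM cutoff
  with roughly balanced classes. Dose series share one Hill curve per
  line: effect $E(d) = d^h/(d^h + IC50_s^h)$ scales both viability
  ($1 - E$) and the treated latent activity ($a_s(1 - E)$), so the
  transcriptional and growth IC50s agree by construction.
* **Mutation flags** — Bernoulli with prevalence 0.3 and, by default,
  *zero* coupling to activity: genotype is deliberately uninformative
  about pathway output in the default regime, and the coupling is a
  dial for studying the informative regime.
* **Survival** — exponential event times with hazard
  $0.1 \cdot e^{\beta_{surv} \cdot score}$, $\beta_{surv} = \log 1.5$
  by default, and uniform censoring on (0, 30), giving ≈ 30–35%
  censoring (the analytic value is available via
  `expectedCensoring()`).

All randomness flows through explicit seeds; generation restores the
caller's RNG state and identical (config, seed) pairs are bit-identical.
The default 9-point log dose grid spans 0.0015–10 µM plus a vehicle
point, matching a typical 0–10 µM assay layout.

What the generator does *not* emulate: whole-transcriptome covariance,
mutation co-occurrence structure, tissue-specific baselines, batch
effects, or non-proportional hazards. Tests passing on these cohorts
show the *procedures* are correct and calibrated under the assumed
structure — a latent factor with monotone links — not that the
signature generalizes to any particular clinical dataset.

## Numerical choices and degenerate inputs

* Population-sd z-scores (exact ±1 in the two-sample case); z-scoring
  is idempotent to 1e-10.
* Median-classification ties go to the negative/low class; all-equal
  scores are an error, not an arbitrary split.
* 4PL fits take the lowest-RSS converged start from the fixed grid; if
  the best sigmoid cannot beat the flat model, the series is reported
  as no-inhibition.
* Scan positions are reported at exact percentile arithmetic; window
  membership uses first-tie ranking, so windows are deterministic
  under tied scores.
* All-censored or near-all-censored cohorts fail fast in `coxFit()`
  (≥ 2 events required) rather than producing fragile estimates.

## Problem sizes

The test suite and the acceptance script run cohorts of n = 40–500
samples, 50 genes, 50-seed replications for calibration claims and
100 repeats for noisy curve-fit recovery — sizes at which the planted
effects are comfortably identified and a full run completes in about a
minute on a single core.

## Known limitations

* The score is a within-cohort quantity; no cross-platform calibration
  is attempted or claimed.
* The elastic-net comparator is trained and evaluated on the same
  synthetic cohort (via out-of-fold predictions); it is a baseline,
  not a production sensitivity predictor.
* The exact MV definition (dose range, clipping) follows the declared
  grid convention above; other panels define MV over other ranges.
* The sliding-window "population" contrast duplicates window records
  against the cohort copy without robust variance correction; its CIs
  are approximate and the remainder mode is the cleaner inferential
  object.
* Signature genes are matched by upper-cased symbol only; synonym and
  identifier mapping is out of scope.
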