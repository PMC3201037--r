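---
title: "Re-evaluating polytomous questionnaires with the graded response model and DIF analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Re-evaluating polytomous questionnaires with the graded response model and DIF analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradedDIF)
```

## Scope and model

gradedDIF implements the psychometric re-evaluation workflow for
Likert-type questionnaires in the low-vision quality-of-life setting: each
dimension of an instrument is treated as a unidimensional scale of ordered
polytomous items and analysed under Samejima's graded response model
(GRM). A person with disability level $\theta$ answers item $i$ in
category $j$ or higher with cumulative probability

$$P^*_{ij}(\theta) = \frac{\exp[\alpha_i(\theta - \beta_{ij})]}
 {1 + \exp[\alpha_i(\theta - \beta_{ij})]},$$

so that $P_{ij} = P^*_{ij} - P^*_{i,j+1}$ with $P^*_{i0} = 1$ and
$P^*_{i,m+1} = 0$. Every item carries one discrimination $\alpha_i > 0$
(logit units per trait unit) and $m$ ordered thresholds $\beta_{ij}$
(trait units); the LVQOL items have six categories coded 0 "No problem" to
5 "Not able because of vision", hence five thresholds, and expected item
scores live on that 0–5 scale. The trait prior is standard normal and is
never re-standardised after fitting — that convention identifies the
scale, so fitted thresholds are directly comparable across calibrations.

Key assumptions inherited from this model family: unidimensionality per
dimension, local independence given $\theta$, a logistic link, and
monotone expected scores. The package screens local independence
(residual correlations) and item fit (S-X²) but does not test
dimensionality itself; factor-analytic preprocessing is assumed done.

## Calibration

`fitGRM()` maximises the marginal likelihood with a Bock–Aitkin EM: the
E-step forms each person's posterior over a fixed quadrature grid
(default 61 equally spaced points on $[-6, 6]$ with renormalised
standard-normal weights — against a 101-point grid the default changes the
log-likelihood of the test fixture by well under $10^{-4}$); the M-step
improves each item's expected complete-data log-likelihood by a few BFGS
steps with analytic gradients ("generalized EM" — fully maximising every
M-step is wasted effort when the E-step is re-run immediately). The
parameterization (log slope, first threshold, log threshold increments)
keeps every iterate a valid ordered GRM, so threshold ordering never has
to be repaired. Convergence requires both an absolute log-likelihood
change below `tol` (default $10^{-5}$) and a maximum parameter change
below `parTol` (default $10^{-4}$); non-convergence within `maxIter` flags
the result rather than erroring. The `mstepIter` knob trades more, cheaper
EM iterations against fewer, more exact ones; all settings reach the same
optimum on our fixtures, differing only in wall time.

Numerical/degenerate-input choices:

* Missing responses are ignorable — skipped in every likelihood product —
  matching the published LVQOL analysis, which calibrated with ~4.5% item non-response
  and no imputation.
* An item with an unobserved intermediate category is collapsed onto its
  lower neighbouring category for estimation (ordinality is preserved);
  the mapping is reported in the result. An item with fewer than two
  observed categories is a hard error naming the item.
* Standard errors, when requested, come from the inverse of a
  finite-difference observed-information matrix at the solution.

Person scores are posterior (EAP) means with posterior SDs;
`subjectSeparation()` reports the empirical reliability
$\mathrm{var}(\hat\theta) / (\mathrm{var}(\hat\theta) +
\overline{\mathrm{SD}^2_{post}})$. The exact separation formula behind the
published 0.83–0.94 indices is not reproducible without the raw data; this
standard empirical-reliability form is adopted and, on synthetic data of
the study's size, lands in the same range (0.83 for a 4-item dimension at
n = 296, 0.94 for the 7-item reading dimension).

## Item fit

`sx2ItemFit()` is the summed-score item test for polytomous items:
observed item-category counts are cross-classified by the *rest score*
(scale total minus the studied item, chosen over the full total so the
studied item does not contaminate its own conditioning variable), and
compared with the model-expected table
$E_{ks} \propto \int P_k(\theta)\,P(\text{rest} = s\,|\,\theta)\,dF(\theta)$,
built from the Lord–Wingersky recursion generalised to graded items
(`summedScoreDistribution()`, verified exactly against brute-force pattern
enumeration). Sparse cells are collapsed deterministically: rest-score
groups merge toward the nearer tail until each group's total expected
count could support all categories at the minimum expected count (default
1.0, configurable), then sparse categories merge with their
smaller-expected neighbour. Degrees of freedom count the independent
retained cells — one less than the cell count per rest-score group —
minus the studied item's free parameters, floored at 1; with that
convention the test's p-values are approximately uniform under the
generating model (checked by simulation with per-replicate
re-calibration). Rows missing the studied item are dropped; rows keep
contributing while at least 80% of the rest items are observed (the
conditional rest-score distribution is then built per missingness
pattern). Misfit is declared at p < 0.01.

Local dependence is screened by residual correlations: each item pair's
observed Pearson correlation minus the correlation implied by the fitted
model under local independence (moments by quadrature). Pairs at or above
0.10 in absolute value are flagged — just above the 0.09 level treated as
unproblematic in the published LVQOL screening. A per-person residual formulation
(observed code minus expected score at the EAP) was rejected by design:
with the short scales involved it carries a mechanical negative bias of up
to −0.4 under perfect local independence, which would swamp a 0.10 flag
threshold.

## DIF testing and the removal rule

`difTest()` follows the IRT likelihood-ratio DIF scheme: all items except
the studied one anchor the two groups (single pass, no purification,
matching the published single-pass workflow); the reference group's prior is fixed at
N(0, 1) while the focal group's mean and SD are estimated, so population
*impact* is separated from item DIF (the reference framework requires
this even though the published analysis does not state it; we free both moments and
document it). Three nested fits — studied item free, slope-equal, and
all-equal — give the hierarchical tests: non-uniform DIF by
$G^2 = 2(\ell_{free} - \ell_{slope-equal})$ on 1 df, and, only when that
is not significant, uniform DIF by
$G^2 = 2(\ell_{slope-equal} - \ell_{all-equal})$ on $m$ df. The fixed
$\alpha = 0.01$ per test is the published analysis's multiple-testing control; no FDR
layer is added. Under the null the slope statistic's empirical 0.99
quantile sits near the $\chi^2_1$ value of 6.63 (simulation in the test
suite).

DIF magnitude is `expectedScoreDIF()`: the signed difference of group
expected-score curves, scanned on $\theta \in [-8, 8]$ in steps of 0.01 —
wide because threshold DIF can push the extremum far into the tails (one
published maximum sits at $\theta = 5.4$); the signed value of largest
magnitude and its location (smallest $\theta$ on ties) are reported, with
the first-listed group minus the second as sign convention.

`removalDecision()` removes an item when (a) any $|ES_{\Delta max}|$
exceeds 1 point, (b) significant DIF appears on ≥ 2 subgroup variables, or
(c) DIF covers a large part of the disability continuum. Clause (c) has no
numeric definition in the published analysis; we operationalise it as
$|ES(\theta)| > 0.5$ over a region holding at least half of the
standard-normal mass. The mass threshold matters: at 25% the clause would
also remove two items the published analysis explicitly kept (their
expected-score gaps of 0.75–0.80 points span 29–47% of the continuum),
while at 50% it reproduces every published keep/remove decision and still
fires, as a supporting reason, for the item the study described as
differing "along a relatively large part" of the continuum. Both clause
parameters are configurable.

## The pipeline and the synthetic-data generator

`runReevaluation()` chains the full workflow per dimension — calibrate,
item fit for every item, DIF for every item × subgroup variable, removal,
re-calibration without removed items, DIF re-tests for the
flagged-but-kept items of dimensions that lost an item, then information
curves and subject separation. Dimensions are always calibrated
independently, never jointly. Total information adds a unit term for the
standard-normal prior by default: the published information maxima are
marginal-software outputs, and hand-summing the printed item informations
reproduces them only with that +1 (e.g. 24.07 + 1 ≈ 25.0 for the reading
dimension at $\theta = -0.4$); `priorIncluded = FALSE` gives the bare sum.
Information curves default to $\theta \in [-4, 4]$ in steps of 0.1 — the
source does not state its grid, and its reported maxima locations suggest
a coarse one; we make no claim of matching that software's grid. Reports
are deterministic given the seed and serialise to JSON/CSV via
`writeReport()`.

`simulateResponses()` generates the data structure the analysis assumes:
traits N(0, 1) for the reference group and N(focalMean, focalSd²) for the
focal group, GRM responses from group-specific parameters, and MCAR
missingness. Defaults mirror the LVQOL study population: n = 296, 6 categories,
4.5% non-response, 61.8% focal-group share (the study's female fraction).
Uniform DIF is injected as a constant shift of all focal thresholds (the
simplest realisation of a consistently higher/lower response likelihood;
per-threshold shift vectors are also accepted since polytomous uniform DIF
may differ per threshold), non-uniform DIF as a slope factor. What it does
*not* emulate: informative missingness, multidimensionality, response
styles, or real-data misfit — so green simulation tests certify the
methods under their own assumptions, not the behaviour of any field
dataset.

## Problem sizes used in the test suite

The simulation studies are sized to be decisive yet routine on a laptop:
parameter recovery at n = 1000–2000; DIF type-I error over 500 null
replicates at 500 persons per group on a 4-item scale with a 21-point
quadrature grid and slightly relaxed EM tolerances (the induced $G^2$
error, ≤ 0.04 against high-accuracy fits, is negligible at the 6.63
rejection threshold); S-X² calibration over 200 replicates at n = 500 with
per-replicate re-calibration; and end-to-end pipeline runs at n = 300–600.

## Known limitations

* One latent dimension per scale; no partial-credit/Rasch
  parameterizations or non-logistic links.
* Two groups per DIF variable; no observed-score DIF methods
  (Mantel–Haenszel, logistic regression) and no longitudinal invariance
  testing.
* All items of a dimension must share one category count for simulation
  and pipeline use.
* The published $G^2$/S-X² statistics, p-values and separation indices
  depend on the original 296 respondents and cannot be recomputed from
  printed tables; the package instead verifies the printed expected-score
  DIF magnitudes and information maxima exactly, and validates its own
  statistics by calibration simulations.
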