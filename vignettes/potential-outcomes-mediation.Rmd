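---
title: "Potential-outcomes mediation of maternal racial disparities: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Potential-outcomes mediation of maternal racial disparities: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pomediate)
```

## The scientific question

Black women in the United States face markedly different risks for several
maternal outcomes — higher risk of gestational hypertension, hypertension
eclampsia, cesarean delivery and ICU admission, and lower probability of
parturition induction — than the rest of the population. Two modifiable
factors known to interact as causes of these outcomes are prepartum body mass
index (BMI) and gestational weight gain (GWG). The mediation question this
package answers is: *if BMI and/or GWG were brought to their optimal levels
for everyone, how much of the racial disparity in each outcome would
disappear?* The answer can be negative — optimizing a mediator can *widen* a
disparity when the mediator currently protects the disadvantaged group more.

## The model

### One interaction node instead of a path diagram

Multiple interacting mediators make classical path-based mediation models
intractable without strong assumptions. Here the cause of interest
(race, $X \in \{1,2\}$ with 2 = Black) and the two binary mediators
($M_1$ = BMI class, $M_2$ = GWG class; 1 = optimal, 2 = non-optimal) are
folded into a single eight-level *interaction node*: every combination
$(x, m_1, m_2)$ is its own stratum with its own outcome probability
$\mathrm{PO}[x, m_1, m_2]$, the potential outcome. Exposure–mediator and
mediator–mediator interaction is thereby represented exactly, not tested
for.

### Likelihood and priors

The data reduce to eight rows, one per cell, each holding a case count $r_i$
and a birth count $n_i$:

$$ r_i \sim \mathrm{Binomial}(\mathrm{PO}[x_i, m_{1i}, m_{2i}],\; n_i),
\qquad \mathrm{PO}[1{:}2, 1{:}2, 1{:}2] \sim \mathrm{Uniform}(0, 1). $$

Because the cells are a priori independent and the Uniform(0,1) prior is
Beta(1,1), each rate has the exact conjugate posterior
$\mathrm{Beta}(1 + r,\; 1 + n - r)$. A potential outcome with a mediator
index "treated as missing" (written NA) is fit on the *pooled* counts of the
collapsed cells — exactly what supplying the aggregated data row to the
binomial likelihood does. The mixture-of-cell-posteriors alternative would
target the same population quantity but with a different (wider) posterior;
we use collapsed-count fitting as the faithful reading of the NA-index
estimator in the BUGS idiom.

### Effects

* **Total effect**: $\mathrm{TE} = \mathrm{PO}[2,\mathrm{NA},\mathrm{NA}] -
  \mathrm{PO}[1,\mathrm{NA},\mathrm{NA}]$, reported as cases per 1000 births.
* **Controlled direct effects** fix mediators at optimal:
  $\mathrm{CDE}_{M_1} = \mathrm{PO}[2,1,\mathrm{NA}] -
  \mathrm{PO}[1,1,\mathrm{NA}]$, analogously for $M_2$, and
  $\mathrm{CDE}_{M_1 M_2} = \mathrm{PO}[2,1,1] - \mathrm{PO}[1,1,1]$.
* **Percent attributable**: $\mathrm{PA} = 100\,(\mathrm{TE} -
  \mathrm{CDE})/\mathrm{TE}$, the share of the disparity eliminated by the
  optimization scenario; negative values mean the disparity would grow.

PA is computed **per posterior draw** and then summarized. Medians do not
commute with ratios, so $100(\tilde{\mathrm{TE}} -
\tilde{\mathrm{CDE}})/\tilde{\mathrm{TE}}$ computed from summarized medians
is a different (and wrong) estimator; a regression test asserts the two
disagree in general. Draws where TE is exactly zero leave PA undefined;
they are excluded from summaries with a logged count rather than clamped.

Summaries are posterior medians with equal-tailed 95% credible intervals
(2.5th/97.5th percentiles of the draws); an effect is *significant* exactly
when the interval excludes zero.

## Estimation engines

The default engine samples each needed node directly from its exact Beta
posterior: $S = 10{,}000$ independent draws per node, mirroring the
kept-iteration count of the classical MCMC protocol for this model. A
`gibbs` engine reproduces that protocol literally — full-conditional sweeps
over the cells, a burn-in of 5,000 discarded iterations, kept iterations
pooled over at least two chains with disparate starts, split-chain
$\hat{R}$ reported and flagged above 1.05. Because the model factorizes, the
full conditionals are the conjugate Betas themselves, so the sampler mixes
immediately; it exists as a fidelity/validation mode, and a
Kolmogorov–Smirnov test in the suite asserts its distributional agreement
with the closed form.

### Seed policy and pairing

One master seed drives everything. Each potential-outcome node draws from a
substream derived deterministically (`substream_seed`) from the master seed
and a label containing the node's collapse pattern and pooled counts —
deliberately *not* the race index. Consequences:

* TE and CDE draws for an outcome are coherently paired, so the draw-wise
  PA has a well-defined joint distribution per iteration (as in a single
  MCMC chain evaluating all nodes).
* Swapping the race labels negates TE draws *exactly*, an invariant the
  suite checks verbatim.
* The one side effect: if both races carry identical pooled counts under the
  same pattern, the two nodes share a stream and their contrast degenerates
  to exactly zero — a common-random-numbers artifact that is harmless for
  inference (the contrast is then genuinely null) but worth knowing about.

## Record-level preparation

Record data carry race class, height, prepregnancy weight, delivery weight,
the obstetric gestation estimate and five 0/1 outcome flags.

* BMI $= \mathrm{kg}/\mathrm{m}^2$ from height and prepregnancy weight.
* GWG is corrected to 40 weeks by proportional scaling,
  $(\mathrm{delivery} - \mathrm{prepregnancy}) \times 40/\mathrm{weeks}$.
  Only a "linear correction" is specified by the source protocol; we chose
  the simplest linear map with value zero at zero gain. Weight loss
  (negative adjusted GWG) is retained and classified non-optimal.
* Optimal BMI is $[18.5, 25)$ — half-open because "18.5 to 25" is ambiguous
  at the top and the IOM's upper normal is 24.9 — and optimal GWG is the
  closed $[11.5, 16]$ kg. Both conventions are arguments of
  `classify_mediators()`.
* Deletions happen in two logged stages, in order: records missing any of
  the five outcomes, then records missing (or with non-positive) height,
  prepregnancy weight, delivery weight or gestation weeks. No plausibility
  trimming is applied beyond that: extreme non-missing values survive.
* Readers map 999-style sentinel codes to missing (configurable list) and
  convert imperial units at read time (1 in = 2.54 cm,
  1 lb = 0.45359237 kg); the pipeline core is metric.

## The synthetic-data generator

Because the model consumes only eight binomial rows, full-published-scale
inference runs in seconds; the generator exists so every stage is testable
with known ground truth.

* **Cell level** (`simulate_cell_counts`): births per cell are the rounded
  expected counts $n_{\mathrm{race}} \times$ prevalence; cases are
  Binomial(n, p) draws.
* **Record level** (`simulate_records`): the mediator combination is drawn
  from the race's joint prevalence; anthropometrics are *back-solved* so the
  preparation stage reproduces the drawn classes — BMI uniform within the
  class interval (non-optimal support bounded to [15, 18.5) ∪ [25, 45]),
  adjusted GWG likewise ([0, 11.5) ∪ (16, 30] for non-optimal), height
  uniform 150–180 cm, gestation uniform 37–42 weeks. Missingness is applied
  missing-completely-at-random per field: the source protocol reports only
  deletion counts, not a mechanism, so MCAR is the one defensible default.
* **Calibration** (`calibrate_cell_probs`) inverts the contrasts: all
  non-Black cells carry a baseline rate; Black cells constrained by a CDE
  target carry the required contrast (constrained single-mediator cells
  share one rate, making the conditionally-weighted margin hit the target
  for any prevalence); remaining Black cells share one rate solved linearly
  for the TE target. The (non-optimal, non-optimal) cell is never
  CDE-constrained, so the system is always uniquely solvable; solutions
  outside [0,1] raise an error naming the cell, and every returned solution
  is forward-verified against its targets to $10^{-12}$.

The reference prevalence table (`reference_prevalence()`) reproduces the
published joint mediator distribution of 17.7M US singleton births
2016–2021; the printed Black column sums to 99.9% from rounding, so
`prevalence_table()` rescales rows to exactly 100 (refusing discrepancies
over 0.5%).

What the generator does **not** emulate: confounding between mediators and
outcome beyond the cell structure, informative missingness, within-cell
heterogeneity, secular trends, or the fixed-width layout of real natality
files. Passing recovery tests therefore demonstrate the *estimator's*
correctness under the model, not robustness to violations of it.

## Numerical and design choices

* Quantiles use the R default (type 7) throughout.
* `n = 0` margins degrade to the Uniform prior with a warning rather than
  erroring, matching the prior-only behaviour of the Bayesian model.
* Effect summaries require at least 100 defined draws; the pipeline default
  is $S = 10{,}000$.
* Problem sizes in the test suite: recovery simulations run at the published
  scale (14M/3M births) for cell-level checks, $10^5$–$3\times 10^5$ births
  per race for record-level round-trips, 200 replicates at $2\times 10^5$
  births for interval-coverage checks — sizes chosen so each property is
  measured well inside its Monte-Carlo tolerance while the whole suite stays
  interactive.
* For rare outcomes (ICU admission, rate ≈ 0.002) the draw-wise PA posterior
  is wide and its recovered median has a sampling standard error of roughly
  13 percentage points even at the 17M-birth scale: the Black
  optimal/optimal cell holds only ~290k births, and PA divides by a TE of
  $7\times 10^{-4}$. Wide published intervals for such outcomes are a
  feature of the data, not an estimation artifact.

## Known limitations

* Controlled direct effects only. Natural direct/indirect effects require
  cross-world assumptions the interaction-node model deliberately avoids;
  no "proportion mediated" under rare-outcome approximations is offered.
* One race group versus the rest; the multi-race "one at a time" extension
  is out of scope.
* No covariate adjustment or hierarchical priors: the model conditions only
  on the eight-cell structure.
* No multiple-testing adjustment across the five outcomes, matching the
  source analysis.
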