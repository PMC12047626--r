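---
title: "Modeling how TOT and FOK states shape confidence sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling how TOT and FOK states shape confidence sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metagrt)
```

## The question and the model

In a two-stage metamemory experiment, people first try to recall a target
(a famous person's name, or the answer to a general-knowledge question).
When recall fails, they report a metacognitive state — a tip-of-the-tongue
(TOT) judgment (yes/no) or a feeling-of-knowing (FOK) judgment (high/low) —
then make a two-choice recognition decision about a provided candidate
answer, and finally rate their confidence in that decision on a 4-point
scale. Three stimulus conditions are interleaved: the candidate is the true
answer (*correct name*), a false answer (*incorrect name*), or the item has
no true answer at all (*catch*). The scientific question is whether being in
a TOT or high-FOK state changes the **metacognitive sensitivity of the
confidence rating** — how well confidence discriminates the person's own
correct from incorrect recognition responses.

`metagrt` answers this with a bivariate general recognition theory (GRT)
model. Each stimulus condition is a bivariate Gaussian in a
two-dimensional evidence space: `x` is recognition/confidence evidence,
`y` is metacognitive (TOT or FOK) evidence. The catch condition is anchored
at the origin and all marginal variances are fixed at 1, so the famous
conditions' means `mu_x`, `mu_y` and the within-stimulus correlations
`rho_s` are the free group parameters. The correlations are the scientific
heart of the model: `rho_s` couples metacognitive evidence to recognition
evidence within a condition, and any dependence of confidence sensitivity
on the metacognitive state enters only through them.

Responses are generated by three axis-parallel criteria (decisional
separability on both axes): `c_y` splits state-present from state-absent
reports, and `c_x1 < c_x2` split the `x` axis into confident-incorrect,
not-confident, and confident-correct. Four-level confidence ratings are
reclassified to two levels before fitting ({3, 4} = confident) so that all
six joint response categories stay populated; the descriptive analyses keep
the raw 1–4 scale.

### Individual differences

All participants share the group means and correlations, but participant
`i` sees a rescaled copy of the space: marginal variances
`1 / (kappa_i * lambda_i)` on `x` and `1 / (kappa_i * (1 - lambda_i))` on
`y`, plus individual criteria. `kappa_i > 0` is global scaling (overall
signal-to-noise); `lambda_i` in (0, 1) divides it between the two axes.
Cell probabilities are exact bivariate-normal rectangle masses, and the
model is fitted by maximizing the multinomial log-likelihood of the
3 (stimulus) x 6 (joint response) count table of every participant jointly.

```{r, eval = FALSE}
counts <- aggregate_counts(trials, judgment = "tot")
fit <- fit_grt_wind(counts, n_restarts = 100, seed = 1)
```

### Identifiability: why the anchor has two constraints

Fixing the catch mean at the origin and the group variances at 1 does *not*
make the scale identifiable: rescaling the `x` axis by `a` and the `y` axis
by `b` (means and criteria multiplied accordingly) can be absorbed exactly
by every participant's `(kappa_i, lambda_i)`, leaving all cell
probabilities — hence the likelihood — unchanged. This orbit is
two-dimensional, one factor per axis, because `kappa_i * lambda_i` and
`kappa_i * (1 - lambda_i)` are separate precisions. A single constraint on
`kappa` alone therefore still lets the two axes drift in opposite
directions (we observed exactly this in recovery experiments before fixing
it). The package pins both factors: after every restart the solution is
renormalized so that the geometric means over participants of
`kappa_i * lambda_i` and of `kappa_i * (1 - lambda_i)` are both 1 — the
"average" participant perceives unit variances, consistent with the unit
group variances (and implying `kappa = 2` for a `lambda = 0.5`
participant). The transformation moves along the flat orbit only, so the
reported likelihood and fit quality are unaffected; only the labeling of
the scale is.

A reflection of the `x` axis is *not* a symmetry of the likelihood: it
would swap the labeled confident-incorrect and confident-correct cells, and
the data distinguish them. The axis convention (correct-name condition on
the positive side) is therefore enforced only through the distribution of
random starting points; a converged fit that violated it would indicate
pathological data and raises a warning rather than being silently
reflected.

### Optimization

Each restart runs BFGS on an unconstrained parameter vector
(`atanh(rho)`, `log(kappa)`, `logit(lambda)`, and the upper confidence
criterion as `c_x1 + exp(gap)`), relative tolerance `1e-8`, at most 2000
iterations, with 100 random restarts by default (bootstrap refits default
to 10). Gradients are central finite differences that exploit the
likelihood's structure: a participant's parameters only touch their own
rows of the count table, so one batched evaluation per parameter type
yields every participant's partial derivative, making the gradient cost
independent of the number of participants. Restart seeds are drawn from a
master seed through a fixed stream, so results are bit-reproducible and
independent of execution order. Cell probabilities are clamped at `1e-300`
before logs so that a positive count on a numerically-empty cell yields a
large finite penalty instead of `-Inf`.

The bivariate-normal rectangle masses themselves come from a vectorized
Gauss–Legendre evaluation of the bivariate normal CDF (with the standard
tail-transformed expansion for `|rho| >= 0.925`), accurate to machine
precision; the test suite cross-checks it against an independent
implementation and against Monte-Carlo sampling.

## The type-2 SvM curve

From a fitted group model the package derives, for every point `y` on the
metacognitive axis:

* the **relative likelihood** `L(y)`: the equal-weight mixture of the two
  famous conditions' metacognitive marginals divided by the catch marginal.
  It converts the binary state report into a graded state strength and is
  the curve's x axis. Equal weighting follows the design (the two famous
  conditions are presented equally often); the weighting sits behind a
  single function should a different convention be needed.
* the **objective criterion** `y*`, the root of `L(y) = 1` — where an
  optimal observer with equal priors would divide low- from high-likelihood
  states. With both famous metacognitive means positive the root is unique;
  if a model with means straddling zero produces several roots, the largest
  is returned with a warning (it is the operative low/high boundary on the
  right tail). Both-means-zero has no root and is an error.
* the **conditional meta-d'**: slice the model at height `y`
  (bivariate-normal conditioning gives the distribution of `x` given `y`
  per condition), compute the implied 3-category confidence probabilities
  at the group-coordinate reference criteria, and find the equal-variance
  SDT observer (means at `+/- meta_d / 2`, unit SDs, free ordered criteria)
  whose category probabilities come closest. The discrepancy is unweighted
  least squares over the six probabilities (a KL option is provided); the
  optimizer uses a moment-matched start plus dispersed deterministic
  starts, and the suite verifies it against a dense grid-search oracle.
  `meta_d` is positive when confident-correct responses are more likely
  under the correct-name condition.

Reference criteria aggregate the participants' individual criteria: each is
rescaled into group coordinates by the SD ratio implied by that
participant's scaling (`sqrt(kappa * lambda)` for `x` criteria,
`sqrt(kappa * (1 - lambda))` for `c_y`), then averaged arithmetically. The
same rescaling maps each participant's `c_y` onto the curve's
relative-likelihood axis for display. This is one defensible aggregation
rule; it is isolated in `reference_criteria()`.

The default grid is 201 evenly spaced points on `[-3, max(mu_y) + 3]`,
which covers more than 99.8% of the marginal mass of every condition; both
the grid and the number of optimization starts are arguments.

```{r, eval = FALSE}
curve <- build_svm_curve(fit)
autoplot(curve)
```

A rising curve with `meta_d > 0` even left of `y*` is the signature
pattern: confidence sensitivity grows with the strength of the
metacognitive state, while some sensitivity survives in its absence.

## Bootstrap bands

`bootstrap_svm_band()` simulates count tables from the fitted model with
the observed per-row totals, refits each replicate (10 restarts by
default — the full-restart setting is configurable but a desk-scale
default of 100 x 1000 refits would be disproportionate), rebuilds the
curve, and reads meta-d' off at a fixed logarithmically spaced grid of
relative-likelihood values (0.1–20, 101 points). `L` is the common axis
because refits live on their own `y` scales. Pointwise simple percentiles
(actual replicate values, no smoothing) give the band, 99% by default.
Replicates whose refit has a non-invertible `L` (a famous metacognitive
mean at or below zero) are dropped and counted; more than 20% failures
aborts. Every replicate gets two child seeds from the master seed through
the same fixed stream, so partial and reordered runs reproduce.

## The synthetic-data generator

`generate_study()` emulates the experimental design so that every stage of
the pipeline can be exercised against known ground truth: 70 participants
by default, 600 trials each in 30-trial blocks (10 per condition) across
three sessions. Famous trials are recalled with probability 0.35 — the
recall process itself is deliberately not modeled; only its censoring
effect matters, so recall success is an independent coin flip — and
recalled trials carry no metacognitive data. Catch items have no correct
answer and are never recalled. For each recall failure a bivariate draw
from the participant's scaled stimulus distribution produces the TOT
report (`y > c_y`), the FOK report (`y > c_y - 0.4`: one shared evidence
axis with offset criteria, so the two judgments are positively associated
and FOK-high is the more liberal report — an emulation convenience; the
analysis fits TOT and FOK in separate models, as intended), the
recognition response (`x` against the criteria midpoint, consistent with a
confidence axis that carries no separate recognition criterion), and the
4-level confidence (distance of `x` past/inside the confidence criteria,
split at sub-criteria 0.5 and 0.3).

The default generating model is `mu_x = +/-1`, `mu_y = 1`,
`rho = (+0.5, -0.5, 0)` — the configuration that produces the rising SvM
curve — with `kappa` log-normal(log 2, 0.3), `lambda` uniform on
[0.35, 0.65] and criterion noise SD 0.3 around anchors
`(c_y, c_x1, c_x2) = (0.5, -1, 1)`. The population hyperparameters are not
derivable from any printed source; these values give realistic
inter-participant spread (roughly 2:1 variation in perceived noise) while
keeping all joint response categories populated, and the generator is
consistent with the fitting anchor by construction (`E log(kappa*lambda)`
and `E log(kappa*(1-lambda))` are both approximately 0). What the
generator does **not** emulate: recall difficulty that correlates with
evidence, session/block order effects, TOT-first/FOK-first
counterbalancing, learning across sessions, and any non-Gaussian evidence
structure. Passing recovery tests therefore demonstrates internal
consistency of the pipeline, not correctness of the Gaussian model for any
particular real dataset.

## Descriptive analyses

`apply_exclusions()` implements the strict participant rules (recall of
more than 80% of famous items, or recognition accuracy below 51% on famous
recall failures; accuracy is undefined on catch trials, which have no
correct answer, so they are excluded from the accuracy denominator — a
documented choice). `state_mean_confidence()` compares raw 1–4 confidence
means between state-present and state-absent trials; catch trials carry
metacognitive and confidence responses and are included by default
(`include_catch = FALSE` reverses this). The comparison uses a Friedman
rank test implemented with within-row average ranks and the standard tie
correction, referred to chi-squared with `k - 1` degrees of freedom; `k = 2`
is kept (not replaced by a sign test) to mirror the analysis it supports.
The fully tied input is defined to give statistic 0 and p = 1.

## Design choices where the design was open

* **Catch correlation** `rho_catch` is a free parameter; nothing in the
  model requires the no-knowledge distribution to be separable, and the
  anchor constraints make it identifiable.
* **Variance accounted for** is `100 * r^2` between observed cell
  proportions and model probabilities pooled over participants x stimuli x
  cells (rows with zero totals excluded). An alternative `1 - SSE/SST`
  definition exists; `r^2` is the shipped definition and the function is a
  single small surface should the other be preferred.
* **Curve comparison axis** for bootstrap bands and recovery scoring is
  `L`, interpolated per replicate, rather than `y` or grid index — `L` is
  the quantity the curve is plotted against.

## Problem sizes used by the test suite

The suite validates the pipeline at sizes chosen to exercise every code
path with comfortable statistical power: parameter recovery at 20
participants x 200 trials per condition with 20 restarts (group-mean RMSE
below 0.15, correlations within 0.1, curve within 0.3 meta-d' over
`L` in [0.5, 5]); bootstrap behavior at 5 participants with 200 replicates
of 10 restarts; Monte-Carlo validation of cell probabilities at 1000
random parameter sets x 10^6 draws; and a dense grid-search oracle for the
conditional meta-d' optimizer on 50 random inputs (agreement within 0.02).
`scripts/acceptance.R` re-runs the recovery study, the descriptive
comparison and a reduced bootstrap from a command-line seed and writes the
resulting quantities as JSON.

## Known limitations

* Fixed unit variances and shared group means are modeling commitments,
  not tested hypotheses; models with per-stimulus variance or curved
  decision bounds are out of scope.
* The conditional meta-d' at a single `y` compares two conditional
  distributions with (in general) unequal SDs to an equal-variance SDT
  observer; when `|rho_correct| != |rho_incorrect|` the fit is an
  approximation and the residual `loss` column of the curve reports how
  close it is.
* Standard errors from the Hessian, model comparison across GRT variants,
  response-specific meta-d', and hierarchical Bayesian estimation are not
  provided.
* With two confidence criteria and three categories the model uses 2
  confidence levels; finer confidence resolution would require more
  criteria and denser data.
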