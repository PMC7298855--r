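---
title: "Methods: choice models and forecasting for linked-data preference DCEs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: choice models and forecasting for linked-data preference DCEs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcelink)
```

This vignette is the package's own account of its methods: the
random-utility model behind every stage, the assumptions built into the
synthetic-data generator, the numerical choices in the estimator, and the
design decisions that were genuinely open.

## The choice setting

Respondents face choice sets of two unlabelled data-use scenarios plus an
opt-out ("neither is acceptable").  Scenarios are described by five
attributes — who the researchers are, what data are linked, the purpose,
profit arrangements, and oversight — with (4, 4, 3, 4, 4) levels, so 768
distinct profiles and 294,528 unordered scenario pairs exist.  Each
attribute's last-listed level is its base: the least restrictive, "worst"
variant, against which all part-worths are measured.

## Random-utility model

Utility of alternative $j$ for respondent $i$ in a choice set is

$$U_{ij} = \lambda_i V_{ij} + \varepsilon_{ij}, \qquad
  \varepsilon_{ij} \sim \text{Gumbel}(0,1) \text{ iid},$$

where $V_{ij} = x_{ij}'\beta + \text{optout}_{ij}\,\delta$.  The vector
$x_{ij}$ holds one dummy per non-base attribute level (14 in the default
space); the opt-out carries no attribute dummies, only the
alternative-specific constant $\delta$.  A positive $\delta$ means that,
all else equal, respondents prefer their data not to be used.  Gumbel
errors give multinomial-logit choice probabilities within each set.

Three estimators share this structure (`dce_clogit()`):

* **per-country** conditional logit: $(\beta, \delta)$ on one country's
  data;
* **pooled with nationality interactions**: reference-country
  $(\beta, \delta)$ plus shifts $\gamma$ for every level and the constant,
  with the nationality indicator equal to 1 for Scottish respondents.
  Because the model is fully interacted, it reproduces the two separate
  country fits exactly (coefficients and the sum of log-likelihoods) — a
  reparameterisation identity the tests assert;
* **heteroskedastic**: the pooled model with scale
  $\lambda_i = e^{\theta\,\text{scot}_i}$ multiplying the whole systematic
  utility.  Scale captures differences in choice *consistency* (inverse
  error variance) between countries; Sweden is the reference
  ($\lambda = 1$).  Scale and interactions are not jointly identified
  unless one attribute's interactions are restricted to zero.  The
  restriction default is `"auto"`: the attribute whose interactions are
  jointly least significant in the pooled fit, measured by the Wald
  statistic $\gamma' V_\gamma^{-1}\gamma$ per degree of freedom, ties
  broken by smaller value then attribute order.  A likelihood-ratio
  criterion would be equally defensible; the Wald form needs no extra
  restricted fits.

## Forecasting rule

A scenario's acceptance probability compares its observable utility with
the opt-out's:

$$P = \frac{e^{V}}{e^{V} + e^{\delta}}.$$

$V$ sums the fitted part-worths of the scenario's non-base levels; base
levels contribute zero, so the all-base "worst case" has $V = 0$.  The
rule for forming a Scottish $V$ from a pooled fit was genuinely open: the
options implemented are adding all interaction terms, none, or only those
significant at a chosen level (Wald $z$, default $\alpha = 0.05$), with
the scale optionally applied.  The package default — significant-only at
5%, scale ignored — is the configuration under which forecasts from the
bundled published pooled heteroskedastic estimates reproduce all nine
published headline figures (85.7 / 82.4 / 75.0 / 72.1 / 35.0 percent and
the 6.1 / 7.1 / 11.0 / 12.6 percentage-point drops), which the acceptance
tests verify; the alternatives are selectable but do not reproduce those
figures.  Percentage-point changes are computed from unrounded
probabilities and reported to one decimal.

## What the synthetic-data generator emulates

The study deposited no respondent-level data, so the generator recreates
the data-generating structure the analysis assumes:

* **Panels** (`simulate_population()`): 1004 Scottish and 974 Swedish
  completers with gender, age-band and working-status quotas set to the
  published sample composition.  Working-status proportions are
  renormalised over the two observed categories because a handful of
  respondents did not report employment.  Quotas are filled by
  largest-remainder apportionment and shuffled under the seed, so realised
  proportions match targets to rounding; quota dimensions are independent
  (no joint distribution was published).
* **Screening** (`simulate_screening()`): six questions answered in order;
  the first "data linkage should never be permitted" answer routes the
  respondent out.  Per-question hazards are calibrated so expected exits
  match the published route-out counts given the invited totals
  (1465 / 1487): hazard = exits / respondents still at risk.  Sequential
  exit is an assumption — respondents are recorded with exactly one exit
  question.
* **Choices** (`simulate_choices()`): respondents are assigned blocks
  round-robin, and choices are drawn from the random-utility model above.
  The true coefficients default to the bundled published per-country
  estimates (`default_preferences()`), so parameter-recovery studies
  measure the estimator against realistic effect sizes.

What it does **not** emulate: panel recruitment and attrition, item
nonresponse, within-country preference heterogeneity (every respondent of
a country shares one coefficient vector), attitudinal survey content, and
the exact historical choice sets.  Passing recovery tests therefore show
the estimator is consistent and well-calibrated *under the stated model*,
not that the model describes any particular real population.

## Design generation

The original design came from proprietary software; only its shape
(40 blocks × 6 sets) and the intent to remove implausible sets are known.
The package's `generate_design()` is a seeded random-swap heuristic: draw
distinct non-dominated pairs, then repeatedly propose single-set
replacements, accepting those that increase the determinant of the
main-effects information matrix at null coefficients (D-efficiency,
opt-out included).  "Implausible" is operationalised purely as pairwise
dominance under a declared worst-to-best quality order (default: base
level worst, remaining levels ranked by listing position).  This is a
stand-in with the right shape and diagnostics, not a reconstruction of
the fielded design.

## Numerical choices

* Likelihood maximisation: zero start, BFGS with analytic gradients
  (checked against central finite differences in the tests), then Newton
  polishing with step-halving to gradient max-norm below $10^{-6}$
  (hard failure above $10^{-3}$ after the iteration budget of 500).
* $\theta$ enters as a log-scale, so $\lambda > 0$ by construction.
* Within-set log-sum-exp is max-shifted; probabilities use `plogis`, so
  forecasts are overflow-safe at any utility.
* Standard errors: inverse observed information (numerically differenced
  analytic gradients).  Whether the original analysis clustered by
  respondent is unknown, so a respondent-clustered sandwich is available
  (`cluster_se = TRUE`) but classical SEs are the default.
* Choice sets with no variation across alternatives carry no information
  and are dropped with a message; a dataset whose sets all lack a unique
  chosen alternative is rejected.
* Possible separation (a level perfectly predicting choice) is flagged by
  a warning naming the unstable coefficients rather than silently
  returned.

## Problem sizes in the test suite

The tests simulate 5-block designs and panels of 120–1004 respondents per
country; parameter recovery uses 20 simulation seeds at the full study
sizes (1004 / 974), scale recovery uses $\theta = 0.25$, and
oracle-equivalence checks use 50,000 simulated respondents on a single
fixed choice set.  These sizes give Monte-Carlo error comfortably inside
the asserted 3-standard-error bands while keeping the suite quick.

## Known limitations

* The bundled reference estimates are transcribed point estimates with a
  diagonal covariance (the full matrix was not published); Wald tests on
  interactions are exact, but joint tests across terms would understate
  dependence.
* The heteroskedastic scale is weakly identified at the study's sample
  size (SE ≈ 0.13 around $\theta = 0.25$ in simulation); single-dataset
  scale estimates should be read with that in mind.
* Forecasts are average (representative-respondent) probabilities from
  point estimates; they carry no sampling uncertainty and no taste
  heterogeneity.
* No willingness-to-pay measures: the design has no cost attribute.
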