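---
title: "Modelling the clinical utility of risk-stratified intervention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the clinical utility of risk-stratified intervention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskstrat)
```

## The question the package answers

Polygenic risk scores (PRSs) rank people by inherited liability to a
condition. A natural policy is to treat only the highest-ranked fraction of
the population — but for most chronic diseases the events are rare enough
that even a good score calls many people positive who would never become
cases. Whether tail-targeting is worthwhile therefore hinges on four
numbers: the prevalence of the condition, the fraction of the population
targeted, how strongly the score concentrates risk in that tail, and the
fraction of treated cases in which treatment actually prevents the event.
`riskstrat` turns those four inputs into the quantities a prescriber or
payer reasons with: precision (PPV), negative predictive value, sensitivity,
specificity, accuracy, the fraction of preventable events captured, the
fraction of all cases prevented, and the number needed to treat (NNT),
population-wide and within the target group.

## The scenario algebra

A scenario is `(p, t, d)`: prevalence `p`, target fraction `t`, and one
discrimination parameter `d`. Discrimination can be given three equivalent
ways, and each determines the others once `p` and `t` are fixed:

* **sensitivity** `s` — the fraction of all eventual cases inside the target;
* **relative risk** `RR` — prevalence inside the target divided by prevalence
  in the untargeted remainder, the way score tails are usually quoted
  ("the top 5% have 3.3 times the risk of everyone else"). Writing both
  group prevalences in terms of `s` makes the population prevalence cancel:

  $$RR = \frac{s\,p/t}{(1-s)\,p/(1-t)}
  \quad\Longleftrightarrow\quad
  s = \frac{RR\,t}{1 - t + RR\,t},$$

  so the sensitivity implied by a quoted tail RR is prevalence-free;
* **PPV** — precision of the positive call, inverted through `s = PPV·t/p`.

Note the remainder-referenced convention: the reference group is everyone
*not* targeted, not the population average and not a bottom quantile. This
is the only convention under which the full set of shipped scenario tables
is internally consistent, and quoted "odds ratios" for score tails are
treated as the same ratio (at these prevalences the distinction is well
below the rounding in a printed table).

From a feasible scenario the population 2×2 table is `tp = s·p`,
`fn = (1-s)·p`, `fp = t - tp`, `tn = 1 - t - fn`, and every classification
metric follows. Infeasible combinations (a PPV that would exceed 1, more
missed cases than the remainder can hold) raise typed errors rather than
being clamped: silently clamping would fabricate a different scenario than
the one requested.

Treatment effectiveness `e` is the fraction of treated cases whose event is
prevented. It may differ between target (`e_t`) and remainder (`e_r`),
because trial populations enriched for the at-risk genotype can show higher
response. Then, treating only the target:

* cases prevented: `s·p·e_t`; as a fraction of all cases, `s·e_t`;
* events preventable if *everyone* were treated: `p(s·e_t + (1-s)·e_r)`;
  the ratio of the two is the "percent of preventable" captured;
* `NNT_all = 1/(p(s·e_t + (1-s)·e_r))` and `NNT_targeted = 1/(PPV·e_t)`.

Under uniform effectiveness the percent of preventable collapses to the
sensitivity — a useful sanity check that holds exactly in the code.

```{r}
sc  <- cohort_scenario(0.02, 0.05, relative_risk = 4.7)
scenario_metrics(sc)
intervention_outcomes(sc, effectiveness_model(0.9))
```

A complementary negative-prediction calculation (`two_group_prevention()`)
covers the case where a score is used to rule *out* low-risk people: a
low-risk fraction at a known risk ratio to the remainder, with the two
group risks solved so the mixture reproduces the overall prevalence, and
intervention concentrated on the high-risk group.

## The liability-threshold curve

The scenario algebra treats the score tail as a black box. To draw the
whole risk-by-percentile relationship the package adopts the standard
Gaussian liability-threshold model: liability is `g + e` with
`g ~ N(0, r2)` the score component and `e ~ N(0, 1 - r2)` the residual,
and disease occurs above the threshold `T = qnorm(1 - K)` fixed by the
prevalence `K`. The two parameters are `K` and `r2`, the variance in
liability explained by the score. Conditional risk at score percentile `q`
is

$$P(\text{disease} \mid q) =
  \Phi\!\left(\frac{\sqrt{r2}\,\Phi^{-1}(q) - T}{\sqrt{1 - r2}}\right),$$

which rises smoothly and accelerates in the upper tail — the
characteristic shape of empirical PRS-percentile plots. No claim is made
that any particular published curve is reproduced point-by-point; the
model is the package's generative stand-in, accepted on its internal
properties (below) and on Monte Carlo agreement.

Integrals over percentile bands (the true-positive mass above a cutoff,
per-bin average risks) are computed by fixed-order Gauss–Legendre
quadrature applied after substituting `u = pnorm(z)`, so the integrand
`risk(z)·dnorm(z)` is smooth everywhere; the tail is truncated at
`|z| = 8`, discarding mass below 1e−15. The law of total probability —
the percentile-average of conditional risk equals `K` — then holds to
better than 1e−6 on a 100-bin grid, and that tolerance is asserted in the
tests. `calibrate_r2_to_rr()` root-finds the `r2` at which a given
percentile cutoff attains a quoted relative risk, bridging the curve
module to scenarios specified by RR.

```{r}
r2 <- calibrate_r2_to_rr(0.02, 4.7, 0.95)
r2
metrics_above_percentile(liability_model(0.02, r2), 0.95)$ppv  # ~0.079
```

## The Monte Carlo cohort simulator

`simulate_cohort()` draws the same model at the individual level:
`n` liabilities `g + e`, disease by thresholding, target membership as the
top `t` of the cohort *ranked by the score component* (the score, not the
outcome, is what a deployment would rank on), and one Bernoulli
counterfactual response per individual at that person's group
effectiveness. Drawing the response once per individual
(potential-outcome style) keeps "prevented" counts consistent when the
same cohort is evaluated under treat-everyone and treat-target policies.
`empirical_metrics()` then recovers every closed-form quantity by direct
counting, with binomial standard errors.

The simulator emulates exactly what the closed forms assume: a Gaussian
score, a homogeneous threshold, independent response draws, no covariates,
no calibration error, no time-to-event structure. Passing tests therefore
show the algebra and the generative model are mutually consistent — they
do not show that any real score is Gaussian or that real treatment
response is independent of liability.

Validation runs in the test suite use cohorts of 200,000 individuals per
scenario column, sized so that three-standard-error bands are narrower
than one printed percentage point for most cells. At that size a handful
of the several hundred simultaneous three-sigma comparisons are expected
to brush their bounds by chance in any given realisation; the quantities
with the fewest underlying events (NNT within a small, rare-disease
target group, where a few hundred prevented events carry the estimate)
have the widest relative sampling error, and the suite's fixed seeds are
deliberately not selected to hide that.

## Scenario tables and the command line

`load_scenarios()` reads a flat key–value config (one `[column]` block per
scenario: `prevalence`, `target`, exactly one of `rr`/`sensitivity`/`ppv`,
`effect_target`, optional `effect_remainder`); unknown keys, duplicate
keys and infeasible columns are rejected with the offending line or column
named. `evaluate_set()` renders the standard thirteen-row table with raw
fractions alongside integer display values. Two presets ship in
`inst/extdata/`: sixteen modelled columns spanning rare (2%) and common
(20%) conditions, and eleven approximate observed scenarios (opioid use
disorder, coronary events, bone fracture). Three printed cells in the
originals are internally inconsistent with every other cell in their own
column (a sensitivity/specificity pair and one percent-preventable cell);
the engine emits the model-consistent values (33, 83, 36) and the golden
tests document the exclusions.

Integer rendering rounds half away from zero, with an absolute 1e−9 guard
on the scaled value so closed forms that land on exact ties (22.5%) are
not mis-rounded by floating point.

The CLI (`inst/cli/riskstrat`, a thin wrapper over `riskstrat_cli()`)
exposes `metrics`, `intervene`, `curve`, `simulate` and `tables`
subcommands with `--json` output everywhere and a mandatory `--seed` for
simulation.

## Numerical and design choices

* Everything internal is a fraction in [0, 1]; percentages exist only at
  I/O boundaries.
* `required_rr_for_precision()` is the exact closed-form inversion
  `RR = PPV(1-t)/(p - PPV·t)`; the tests check it against independent
  bisection on the forward map. A precision goal quoted after rounding
  (e.g. "at least 50%") inverts to the RR that hits the goal exactly, so
  an RR quoted alongside it in a source may differ in the second digit —
  the forward direction (RR in, precision out) is canonical here.
* Annualised prevalences (events per year) are treated as ordinary
  per-period prevalences; no time-to-event modelling.
* `r2 = 1` is rejected as degenerate (risk becomes a step function);
  `r2 = 0` is the exact chance-level baseline and is used as such in
  tests.
* NNTs are reported raw and as integers, because printed tables round but
  downstream arithmetic should not.

## Limitations

Confidence intervals on the closed-form metrics, harms/NNH, adherence,
cost-effectiveness and QALY modelling are out of scope. The liability
model is a single-threshold, single-score Gaussian; non-Gaussian
liabilities, covariate adjustment, LD-aware genotype simulation and
fitting `r2` from real GWAS data are not attempted.
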