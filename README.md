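# riskstrat

Closed-form modelling of the clinical utility of risk-stratified
intervention with polygenic risk scores (PRSs), for epidemiologists,
clinical geneticists and health-policy analysts deciding whether a score
is strong enough to target treatment.

## The model

Four variables drive the assessment: the prevalence of the condition
*p*, the fraction of the population targeted *t* (e.g. the top tail of a
PRS), the discrimination of the score, and the therapeutic response rate
*e* (fraction of treated cases whose event is prevented). Discrimination
can be supplied as sensitivity *s*, as precision (PPV), or — as score
tails are usually quoted — as the remainder-referenced relative risk

    RR = [s·p/t] / [(1−s)·p/(1−t)]   ⟺   s = RR·t / (1 − t + RR·t),

in which prevalence cancels. From a feasible scenario the package builds
the population 2×2 table (tp = s·p, fp = t − tp, fn = (1−s)·p,
tn = 1 − t − fn) and derives PPV, NPV, sensitivity, specificity,
accuracy, the fraction of preventable events captured by target-only
treatment, the fraction of all cases prevented (s·e_t), and the number
needed to treat: NNT_all = 1/(p·(s·e_t + (1−s)·e_r)) and
NNT_targeted = 1/(PPV·e_t), allowing different effectiveness inside
(e_t) and outside (e_r) the target.

Around this core:

* a Gaussian **liability-threshold model** (`liability_model()`,
  `risk_curve()`, `calibrate_r2_to_rr()`) generates risk-by-percentile
  curves from prevalence and the variance in liability explained by the
  score, and links percentile targeting to quoted relative risks;
* a **Monte Carlo cohort simulator** (`simulate_cohort()`,
  `empirical_metrics()`) draws individual-level cohorts and recovers
  every closed form by counting, with binomial standard errors;
* a **scenario-table engine** (`load_scenarios()`, `evaluate_set()`)
  evaluates config-driven scenario sets and ships two presets
  (`preset_scenarios("table1")`, `"table2"`);
* a **CLI** (`inst/cli/riskstrat`) with `metrics`, `intervene`, `curve`,
  `simulate` and `tables` subcommands.

## Worked example

A rare condition (prevalence 2%) with a score whose top 5% carries 4.7
times the risk of everyone else, and a 90%-effective intervention:

```r
library(riskstrat)
sc <- cohort_scenario(0.02, 0.05, relative_risk = 4.7)
scenario_metrics(sc)
#> <classification_summary>
#>   ppv            7.93%
#>   npv           98.31%
#>   sensitivity   19.83%
#>   specificity   95.30%
#>   accuracy      93.79%
#>   rel. risk      4.70
intervention_outcomes(sc, effectiveness_model(0.9))
#> <intervention_outcome>
#>   percent of preventable   19.8%
#>   percent of all prevented 17.8%
#>   NNT all                   55.56
#>   NNT targeted              14.01
```

Read: only ~8% of the people called positive would ever become cases
(rare outcome, so precision is low even at RR 4.7), the targeted 5%
contains ~20% of all future cases, and treating just that group prevents
~18% of all cases at an NNT of 14 — against an NNT of 56 if everyone
were treated.

The same machinery renders whole scenario tables, e.g. the first columns
of the observed-scenarios preset:

```sh
$ riskstrat tables --preset table2 | cut -f1-5
Attribute               opioid_1  opioid_2  opioid_3  cad_1
Prevalence              5         8         8         2.2
Relative Risk           6         8.7       2         3.3
Target                  1%        5%        33%       5%
PPV/Precision           29        50        12        7
NPV                     95        94        94        98
Accuracy                95        92        67        93
Sensitivity             6         31        50        15
Specificity             99        97        68        95
Effectiveness           80%       80%       50%       25%
Percent of Preventable  6%        31%       50%       15%
Percent of All Prevented 5%       25%       25%       4%
NNT All                 25        16        25        182
NNT Targeted            4         2         17        61
```

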