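# winbayes

Bayesian subgroup analysis of treatment effects on right-censored survival
data.

## The problem

For rare cancers (the motivating setting is synovial sarcoma registry data),
randomized evidence on adjuvant treatments such as radiation therapy (RT) or
chemotherapy is scarce, and observational cohorts are confounded: sicker
patients are treated more often, so naive survival comparisons mislead.
Average effects can be recovered by propensity-score matching, but an
average hides heterogeneity — a treatment may help one covariate profile and
harm another.  `winbayes` implements a conditional-treatment-effect (CTE)
workflow for clinical researchers who want to ask: *which* patients benefit?

## The method

Nine baseline covariates are dichotomized (age > 20 y; sex; tumor longest
diameter > 5 cm; extremity vs axial site; advanced SEER stage; surgery;
the co-administered adjuvant treatment; spindle-cell histology; biphasic
histology) and patients are stratified exhaustively into the
2<sup>9</sup> = 512 covariate cells.  Within a cell *u*, the treatment
effect is summarized by the **win probability**

> Y = P(a treated patient of *u* survives longer than an untreated patient of *u*),

with Y = 0.5 meaning no effect.  All treated × untreated pairs in the cell
are compared by a censoring-aware concordance rule (a pair is comparable iff
the smaller observed time ends in death), giving γ wins out of n comparable
pairs.  Under a binomial reading of (γ, n) and a uniform Beta(1, 1) prior,

> Y | data ~ Beta(1 + γ, 1 + n − γ).

Each cell is gated by the Savage–Dickey Bayes factor against the point null
Y = 0.5 (BF > 3, "substantial" evidence).  The **optimal** subgroup is the
gated cell whose lower 95% credible bound on Y is highest (and above 0.5);
the **worst** subgroup is the mirror image with the upper bound below 0.5.
The net benefit of a selected subgroup S\* is the posterior probability that
its win probability exceeds that of the pooled complement,
P(Y<sub>S\*</sub> > Y<sub>rest</sub>), declared significant at ≥ 0.95.
Supporting machinery: KNN imputation, Newton-fitted logistic propensity
scores with greedy logit-caliper matching (0.2 × SD), Kaplan–Meier curves,
pair-stratified log-rank tests, and O/E hazard ratios.  A fully seeded
synthetic cohort generator (Weibull proportional hazards, logistic
confounded assignment, exponential censoring, masked covariates) provides
planted ground truth: a cell with treatment hazard ratio r has closed-form
win probability 1/(1 + r).

## Worked example

```r
library(winbayes)

cfg <- simulation_config(2000, seed = 7, missing_frac = 0.02,
                         effect_map = c("45" = log(1/3)))   # planted HR 1/3
cohort <- generate_cohort(cfg)
report <- run_pipeline(cohort, "chemo", seed = 7)
print(report)
```

```
Subgroup analysis of 'chemo' on 2000 records
  matched pairs: 938 (caliper 0.0210 on logit scale)
  matched stratified log-rank p = 0.9658
  matched O/E hazard ratio (treated vs untreated): 1.014 (0.902-1.141)
  non-empty subgroups: 233
  optimal subgroup: key 161 (age_over_20+surgery+spindle), n = 18, mean win prob 0.900, 95% CI (0.740, 0.987), BF 767
    P(win prob > pooled complement) = 1.0000
  worst subgroup: key 175 (age_over_20+male+size_over_5cm+extremity+surgery+spindle), n = 425, mean win prob 0.150, 95% CI (0.118, 0.185), BF 1.31e+49
    P(win prob > pooled complement) = 0.0000
```

Reading this output: treatment assignment is unconfounded in this simulated
world, so the matched average effect is null (HR ≈ 1, log-rank p = 0.97) —
the planted benefit hides in one cell (key 45, true win probability 0.75 by
`planted_truth(cfg)`).  The run also illustrates the method's main hazard:
the selected "optimal" (key 161, 18 pairs from 9 patients) and "worst"
(key 175) cells are chance fluctuations amplified by correlated pairs, and
key 45 itself (posterior mean ≈ 0.7 here) is out-ranked.  Treat selections
from small cells with suspicion; `min_n` tightens the gate.

## Command line

`inst/cli/winbayes.R` exposes `simulate`, `match`, `subgroups` and `report`
subcommands over delimited cohort files; see the header of that script.
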