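---
title: "Bayesian win-probability subgroup analysis for censored survival data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian win-probability subgroup analysis for censored survival data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(winbayes)
```

## The model

`winbayes` targets observational cohorts of a rare disease with a binary
adjuvant treatment, right-censored overall survival, and a small set of
prognostic covariates.  Because treatment assignment is confounded, effects
are only compared between patients with *identical* covariate values: the
nine baseline covariates are dichotomized and the cohort is stratified
exhaustively into the $2^9 = 512$ cells of the binary covariate vector
$(b_1,\dots,b_9)$, packed into an integer key $\sum_i b_i 2^{i-1}$.  Within
a cell the conditional treatment effect is expressed as a **win
probability**

$$Y_u = P(T_{\text{treated}} > T_{\text{untreated}} \mid u),$$

estimated from concordance comparisons of all treated × untreated pairs in
the cell.  Under right censoring a pair is *comparable* only when the
ordering is determinable: the smaller observed time must end in death; at
tied times exactly one death (the death losing).  Incomparable pairs are
dropped from $n$ and reported (`n_incomparable`), preserving a binomial
reading of ($\gamma$ wins, $n$ pairs).  With a conjugate uniform prior,

$$Y_u \sim \mathrm{Beta}(1,1), \qquad
  Y_u \mid \gamma, n \sim \mathrm{Beta}(1+\gamma,\; 1+n-\gamma).$$

Cells are screened by the Bayes factor of $H_1$ ($Y$ free under the Beta
prior) against the point null $H_0: Y = 1/2$, computed as the Savage–Dickey
density ratio

$$\mathrm{BF}_{10} = \frac{p_{\text{prior}}(1/2)}{p_{\text{posterior}}(1/2)}
 = \frac{B(\alpha+\gamma,\ \beta+n-\gamma)}{B(\alpha,\beta)}\, 2^{n},$$

the second equality (marginal-likelihood route) being verified to $10^{-10}$
in the test suite.  Among cells with $\mathrm{BF} > 3$ and at least `min_n`
comparable pairs, the **optimal** subgroup maximizes the lower equal-tailed
95% credible bound of $Y$ (which must exceed 0.5); the **worst** subgroup
minimizes the upper bound (below 0.5); either may be absent.  The net
benefit of a selected cell $S^\ast$ is
$P(Y_{S^\ast} > Y_{\text{rest}})$ under independent posteriors, where the
complement pools the raw tallies of all other cells ($\sum\gamma$,
$\sum n$) into one conjugate update — pooling tallies rather than averaging
posteriors keeps the binomial likelihood well defined.  The probability is
estimated by Monte Carlo (default $10^5$ draws) and declared significant at
$\ge 0.95$; tests check it against deterministic quadrature
$\int f_{S^\ast}(x) F_{\text{rest}}(x)\,dx$.

Average effects are assessed separately by propensity methods: a logistic
model of treatment on the nine bits (Newton iteration, score convergence
$10^{-8}$, quasi-separation flagged), greedy 1:1 nearest-neighbour matching
without replacement on the logit score with caliper $0.2 \times
\mathrm{SD}(\mathrm{logit})$, balance diagnosed by standardized mean
differences, and matched arms compared by Kaplan–Meier curves, a
pair-stratified log-rank test, and an O/E hazard ratio.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| prior $(\alpha,\beta)$ | (1, 1) | uniform prior on the win probability; any Beta accepted |
| `bf_threshold` | 3 | "substantial" evidence on the conventional Bayes-factor scale |
| `level` | 0.95 | credible level for the selection bounds |
| `min_n` | 10 | minimum comparable pairs for a cell to compete (0 restores strict selection) |
| `caliper_mult` | 0.2 | caliper in SDs of the logit propensity score |
| `k` (imputation) | 5 | neighbours for KNN imputation |
| age / size cutoffs | 20 y, 5 cm | strict `>` dichotomization boundaries |
| `advanced_stages` | 3 | registry stages coded as the "advanced" bit |

The stage binarization is genuinely open: three registry stages must map to
one bit, and published extreme subgroups pin down only stages 1 and 3.  We
code `advanced := (stage == 3)` (distant disease) and expose
`advanced_stages` so `{2,3}` can be tried; results for stage-2 patients are
sensitive to this choice.  `NOS` histology is treated as the reference
category of the two histology bits rather than a tenth variable.  The O/E
(Mantel–Haenszel-type) hazard ratio was chosen over a Cox fit so the module
is fully specified and dependency-free; Cox regression is a non-goal.  The
caliper rule is the conventional 0.2 × SD(logit) greedy nearest-neighbour
match, processing treated records in descending score order with seeded tie
shuffling.

## The synthetic world

`simulation_config()` states a complete generative model: nine covariate
bits drawn from marginal prevalences chosen to resemble a registry sarcoma
cohort (85% over 20 y, 49% male, 61% large tumors, 77% extremity, 13%
distant stage, 90% resected, 37%/23% spindle/biphasic from one
three-category histology draw); continuous age and size drawn consistently
with their bits; logistic treatment assignment on the bits (confounding is
planted through `propensity_coefs`); Weibull proportional-hazards survival
(shape 1.2, scale 60 months) with per-bit log-hazards and a per-cell
treatment log-hazard-ratio (`effect_map`); exponential censoring at
0.01/month; and Bernoulli masking of covariate entries (5%).  Substreams
for covariates, treatment, survival, censoring and masking are seeded
separately, so e.g. changing the missingness does not perturb survival
draws.  Because treated and untreated share the Weibull shape, a cell with
hazard ratio $r$ has closed-form win probability $1/(1+r)$, certified by
the Monte-Carlo `planted_truth()` oracle.

What the generator does **not** emulate: real registry marginal joint
structure (bits are independent), competing risks, time-varying treatment,
informative censoring, and measurement error beyond random masking.  A green
test therefore establishes algorithmic correctness and behaviour under a
clean proportional-hazards world — not clinical validity on registry data.

## Numerical choices

Beta quantiles use the inverse regularized incomplete beta (`qbeta`),
cross-checked against bisection to $10^{-6}$; Bayes factors are computed in
log space; the log-rank variance uses the standard hypergeometric
multi-death tie correction, with censored records at a death time counted
at risk through that time; a zero log-rank variance yields statistic 0 and
$p = 1$ with a warning.  Matching ties in the processing order are broken
by a seeded shuffle and equal-distance controls by record order, making the
whole pipeline byte-reproducible from one master seed.  KNN imputation
standardizes numeric features, one-hot encodes categoricals, averages
squared differences over mutually observed features, and resolves
categorical vote ties by the nearest tied donor, then record order; donors
always come from the original table so field order cannot matter.

## Known limitations

The central caveat is inherited from the method itself and deliberately not
corrected: **pairs within a cell share patients**, so ($\gamma$, $n$) is
overdispersed relative to the binomial model the posterior assumes.  A cell
with 4 treated and 3 untreated patients yields 12 pairs, and under the null
all 12 are treated-wins with probability $1/35$ — the posterior
Beta(13, 1) and Bayes factor $\approx 300$ then vastly overstate the
evidence.  With hundreds of small cells, the selection rule (maximize the
lower credible bound) is dominated by such fluctuations: in the package's
own acceptance experiments (n = 5000, 50 seeds), a planted cell with true
win probability 0.75 and ~150 patients is recovered only ~28% of the time,
and a fully null world yields a (spurious) optimal subgroup in essentially
every seed.  The corresponding acceptance tests assert the original
recovery/calibration expectations and fail honestly; they document the
method's operating characteristics rather than a coding defect (the
counting, updating and Bayes-factor layers are verified exactly against
independent oracles).  Raising `min_n` helps only marginally, because the
effective information in a cell scales with patients, not pairs.  Users
should read selected subgroups as hypotheses for confirmation — e.g. by the
matched survival analysis of the selected cell — not as calibrated
discoveries.  A second caveat: when one arm is much larger than the other,
greedy matching consumes the entire minority pool and the matched subset of
the majority arm is a selected, not random, subset; balance should always
be inspected via `standardized_differences()`.
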