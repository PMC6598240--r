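---
title: "Methods: absolute EAC risk with competing mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: absolute EAC risk with competing mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eacrisk)
```

## The estimation problem

Esophageal adenocarcinoma is rare enough that raw incidence tells an
individual little: what matters clinically is the *absolute* probability
of developing the cancer over a planning horizon, given age, sex, race,
Barrett's esophagus (BE) status and a handful of lifestyle and clinical
factors — and given that death from other causes may come first. `eacrisk`
estimates that probability and, separately, asks how well such a score
separates people who develop the cancer from the general population.

## Absolute risk with competing mortality

The engine combines three ingredients over a 10-year horizon in annual
steps, hazards held constant within each step and evaluated at the
mid-step age $a + t + 0.5$:

1. **Baseline hazard.** Population incidence $I(\cdot)$ is an average over
   everyone's risk factors, so the hazard of a person at the lowest-risk
   (reference) level of every factor is smaller. Under independent,
   multiplicative factors the population-mean relative risk is
   $\overline{RR} = \prod_f \sum_l p_{fl}\,RR_{fl}$, and the baseline
   hazard is $h_0(t) = I(a+t+0.5)/\overline{RR}$. Equivalently
   $1/\overline{RR} = 1 - \mathrm{PAR}$: dividing by the mean RR is
   exactly the population-attributable-risk correction.
2. **Individual relative risk.** $r = \prod_f RR_{f,\text{selected}}$,
   1 for an all-reference profile.
3. **Competing mortality.** The all-cause mortality hazard $m(t)$ at the
   same ages. We do not subtract EAC-specific deaths from $m$: they are a
   negligible share of all-cause mortality at these ages, and the
   all-cause table is what the inputs provide.

With $h(t) = h_0(t)\,r$ the absolute risk is the cause-specific
cumulative incidence for piecewise-constant hazards,

$$AR = \sum_{t=0}^{9} \frac{h(t)}{h(t)+m(t)}
       \left(1 - e^{-(h(t)+m(t))}\right)
       \prod_{u<t} e^{-(h(u)+m(u))},$$

which telescopes to $\frac{h}{h+m}(1-e^{-10(h+m)})$ when both hazards are
constant — the identity the test suite checks to $10^{-12}$. Annual steps
match the granularity of the rate inputs; a finer grid changes nothing
because the smoothed rates vary slowly within a year.

A useful consistency property follows from construction: averaging $AR$
over profiles drawn from the factor prevalence distribution reproduces
the risk computed from the unsmoothed population incidence. The
acceptance suite exercises this end-to-end with 100,000 simulated
profiles and requires agreement within three Monte-Carlo standard errors.

## Rate inputs and smoothing

Incidence and mortality arrive as 5-year age-group tables (40–44 … 80–84,
85+) per sex and race, the shape of registry extracts. For continuous-age
evaluation each stratum is smoothed by ordinary least squares of
log(rate) on age-group midpoints with a cubic polynomial. Choices that
matter:

* **Log scale.** A cubic fitted to raw rates can dip negative; on the log
  scale the fitted rate is positive everywhere by construction. The fit
  is unweighted: with only ten age groups per stratum, weighting schemes
  add assumptions without changing the curve materially.
* **Midpoints.** The closed group $[l, l+4]$ uses $(l + l + 4)/2$; the
  open 85+ group is stored as 85–89 and uses midpoint 87.
* **Zero cells.** Rare strata can contain zero rates, whose log is
  undefined. They are floored at half the smallest positive rate in the
  table, and a message records how many cells were floored — a documented
  imputation rather than a silent failure.
* **Domain.** Ages above the fitted domain clamp to the domain maximum
  (cubics extrapolate wildly); ages below 40 are an error, because the
  inputs carry no information there and the calculator's scope is 40+.

## The Barrett's stratum

Once BE is diagnosed, both ingredients change. Incidence uses an anchored
exponential model instead of the registry polynomial: 0.0031 events per
person-year for white men at age 62 (the midpoint of the 60–64 group, a
typical age at diagnosis), scaled by $1.04^{\,a-62}$, times 0.4 for white
women and 0.75 for black men. Strata without a multiplier — black women in
particular, for whom reliable progression data do not exist — raise a
"stratum unsupported" error; silently extrapolating would manufacture
numbers with no evidential basis, so absence of input rows is the
package's representation of "unsupported".

The factor set changes too: segment length and dysplasia dominate
progression, smoking and BMI play smaller roles, NSAID and statin use
remain protective, and physical activity and family history drop out for
lack of evidence. For reflux symptoms in the BE stratum, the packaged
default enters each level's RR as the square root of the
general-population RR — halving the trend coefficient on the log scale.
The halving scale is a genuine ambiguity; log-scale halving keeps the
reference level at exactly 1 and is the interpretation we adopt
throughout.

## Confidence intervals

Each selected level's 95% CI yields a log-RR standard error
$\widehat{se}_f = (\log ci_{high} - \log ci_{low})/(2 z_{0.975})$. The
delta method then needs $\partial \log AR / \partial \log RR_f$, which is
*not* simply the naive elasticity: perturbing a factor's RR also moves
$\overline{RR}$ and hence the baseline hazard. We therefore perturb the
selected level's RR by $e^{\pm 10^{-4}}$ and take central differences of
$\log AR$, capturing the PAR feedback numerically; the step $10^{-4}$ on
the log scale is far above double-precision noise and far below any
curvature scale of the map. Factor estimates are treated as independent
(the same assumption the multiplicative model already makes), so
$\mathrm{Var}(\log AR) = \sum_f g_f^2 \widehat{se}_f^2$ and the interval
is $AR\,e^{\mp z\,sd}$, capped at 1. The test suite checks this against
a 10,000-draw parametric (log-normal) bootstrap that recomputes the risk
from first principles, requiring CI widths to agree within 10%, and
against the analytic small-risk limit, where the CI ratio collapses to
the factor's own CI ratio.

## Display forms

Probabilities are shown as risk per 1000 (one decimal), as "1 in N" with
$N = \mathrm{round}(1000/\text{per-}1000)$ — computed from the *rounded*
per-1000 figure so the two printed numbers are always consistent — and as
a category from fixed log-spaced bins on the per-1000 scale: below 0.5,
0.5–2, 2–8, 8–32, and 32 up. Log spacing matches how the risk itself
spans orders of magnitude across profiles; the bin edges are fixed and
documented so category labels are stable across configurations. A zero
probability returns the sentinel category "none expected" rather than a
division by zero. Comparator 10-year mortality probabilities for selected
causes use the same competing-risk machinery (each cause against all
other mortality) and are demographic averages only — they do not see the
individual's risk factors, so a smoker's true lung-cancer mortality is
higher than displayed.

## Discrimination on case-control data

The evaluation pipeline reproduces what a pooled case-control analysis
must do before it can score records:

* **Constrained assignment.** Factors never measured in the source
  studies (statin use, physical activity, family history) are assigned
  randomly: controls from population prevalences, cases from the tilted
  distribution $p_{1l} \propto p_{0l} RR_l$, whose two-level special case
  $p_1 = OR\,q/(1+OR\,q)$, $q = p_0/(1-p_0)$, reproduces the target odds
  ratio exactly in expectation.
* **Imputation.** Missing levels are hot-deck imputed from donors
  matching on case status, sex and 10-year age band, ten completed
  copies, risks averaged per record across copies. Hot-deck within
  strata is deliberately simple: it preserves observed level
  distributions exactly and is transparent to audit; cells without
  donors fall back to the marginal distribution with a logged message.
* **Reweighting.** Controls ascertained to mirror cases' age-sex
  distribution are post-stratified so their weighted distribution equals
  a reference population table; a reference cell with mass but no
  controls is an error (listing the cells), not a silent renormalization.
* **Metrics.** At every distinct observed risk threshold: weighted
  sensitivity (case weight at/above), specificity (control weight
  below), and PPV. Case-control data carry no population prevalence, so
  the PPV at a threshold is defined as the weighted mean *model* risk
  among flagged **controls** — the reweighted controls are the population
  proxy, and each flagged person contributes their own predicted
  10-year probability. Cases are excluded from this projection because
  their sampling fraction is enormous relative to the population; using
  them would inflate PPV arbitrarily. This definition is a documented
  modeling choice, not an estimate of the classical PPV.
* **AUC.** The weighted probability that a random case outscores a
  random control, ties counting half — computed by cumulative control
  weights over sorted scores, and verified in tests against an exhaustive
  $O(n^2)$ pairwise oracle and against the trapezoidal area under the
  weighted ROC curve. The CI is a stratified bootstrap (cases and
  controls resampled separately, 1000 replicates by default, seeded):
  with post-stratification weights in play, closed-form AUC variances do
  not apply.

## The synthetic-data generator

`generate_case_control()` emulates the *structure* of pooled
population-based case-control studies: an age-sex distribution shared by
cases and controls (controls are ascertained to match), independent
factor levels at stated control prevalences, case levels tilted per
factor by the ground-truth RRs, optional missing-completely-at-random
gaps, and full determinism under a seed. Case tilting is per-factor
independent — exactly the multiplicative, independent-factor model the
engine assumes — so parameter-recovery tests probe the pipeline, not model
misspecification. What it does **not** emulate: between-study
heterogeneity, correlated risk factors (reflux and BMI travel together in
real data), differential recall or selection bias, and
not-at-random missingness. Passing tests therefore certify the machinery
under the model's own assumptions; they cannot certify the published
discrimination of any real dataset, whose individual-level records are
not redistributable.

`generate_rate_table()` provides constant, Gompertz and exact-cubic
tables; the cubic shape makes polynomial recovery exactly testable (the
fit must return the generating coefficients to $10^{-6}$; in practice it
is accurate to $10^{-13}$).

## The packaged default configuration

The five CSVs under `inst/extdata/config/` are **synthetic placeholders**
with realistic structure: RR and prevalence values in the range reported
across the observational literature (reflux trend RRs rising to ~6.5,
BMI trend to ~3, statin OR 0.57 at 33% prevalence, segment-length and
dysplasia RRs dominating the BE set), incidence curves saturating around
25 per 100,000 for older white men with white women at 0.15× and black
men at 0.25×, and Gompertz all-cause mortality. They make the package
fully runnable and testable offline and are meant to be replaced
wholesale: every number the engine uses is in those files, none is
hard-coded. Black females are intentionally absent from the rate files —
the supported-strata mechanism, not an oversight.

## Problem sizes and seeds

Simulation-backed tests use sizes chosen to make their tolerances
meaningful at interactive runtimes: 200,000 records per arm for
assignment prevalence checks (binomial SE ≈ 0.001), 100,000 profiles for
the PAR identity (three Monte-Carlo SEs ≈ 0.5% of the estimate), 100,000
per arm for empirical odds-ratio recovery, 50 replicates of 5,000 per arm
for logistic coverage, 10,000 draws for the CI bootstrap comparison, and
500–1000 bootstrap replicates for AUC intervals. All stochastic tests fix
their seeds; the acceptance script derives every stream from its `--seed`
argument.

## Known limitations

* Factors are assumed independent and multiplicative in both the PAR
  correction and the variance propagation; joint distributions are out
  of scope, and extreme combined profiles lean on sparse evidence.
* The CI reflects RR uncertainty only — not sampling error in the rate
  tables or prevalence estimates.
* Applicability is limited to populations resembling the rate inputs
  (US registry data in the intended use); the packaged configuration is
  synthetic and must be replaced for any substantive use.
* The competing hazard is all-cause mortality unadjusted for the EAC
  deaths it contains; at EAC's incidence this bias is far below every
  other uncertainty in play.
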