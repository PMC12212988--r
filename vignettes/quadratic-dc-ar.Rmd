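---
title: "Testing developmental-constraints and adaptive-response hypotheses with quadratic regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing developmental-constraints and adaptive-response hypotheses with quadratic regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The scientific problem

Early-life adversity predicts worse adult outcomes across many long-lived
species. Two classes of evolutionary explanations are commonly invoked.
*Developmental constraints* (DC, the "silver spoon" idea) holds that a
poor developmental environment is itself costly: adult outcomes improve
monotonically with the quality of the developmental environment
$e_0$. *Adaptive response* (AR) hypotheses — covering both predictive and
developmental adaptive responses, which are empirically indistinguishable
from mismatch data alone — hold instead that organisms calibrate a
phenotype to their developmental environment and pay a cost when the adult
environment $e_1$ differs from it: outcomes worsen as the mismatch
$|\Delta e| = |e_1 - e_0|$ grows.

The two ideas are easily conflated because $e_0$, $e_1$, and $\Delta e$
are arithmetically entangled ($e_0 + \Delta e = e_1$). `dcar` implements a
testing strategy that keeps them apart: approximate the adult-outcome
surface $y_1 = F(e_0, |\Delta e|)$ by its second-order Taylor expansion,

$$
y_1 = \gamma + \gamma_0 e_0 + \gamma_d |\Delta e| + \gamma_{00} e_0^2 +
\gamma_{dd} |\Delta e|^2 + \gamma_{0d}\, e_0 |\Delta e| + u,
$$

and test each hypothesis through the sign of the relevant partial
derivative of the fitted surface:

* DC predicts $\partial y_1 / \partial e_0 =
  \gamma_0 + 2\gamma_{00} e_0 + \gamma_{0d} |\Delta e| > 0$;
* AR predicts $\partial y_1 / \partial |\Delta e| =
  \gamma_d + 2\gamma_{dd} |\Delta e| + \gamma_{0d} e_0 < 0$.

A term for $e_1$ itself is deliberately absent: given the model's premise
that $e_0$ and $\Delta e$ jointly generate $e_1$, the adult environment is
an endogenous by-product and not separately testable.

The motivating application is fertility in wild female baboons — three
binary outcomes (conceiving in a cycling month, a pregnancy ending in a
live birth, an infant surviving to 70 weeks) against two environmental
variables (mean monthly rainfall, proportional dominance rank) — but every
layer of the package is generic over any binary outcome with a
developmental and an adult environment measure.

## Risk-set construction

`build_conception_table()`, `build_livebirth_table()` and
`build_infantsurvival_table()` turn raw longitudinal records into
conditional risk sets:

* **Conception**: one record per female-month in which the female was
  cycling on the first day of the month. Months beginning pregnant or in
  postpartum amenorrhea are not at risk and never enter the denominator.
* **Live birth**: one record per completed pregnancy; in-progress
  pregnancies are censored and dropped (with a logged reason).
* **Infant survival**: one record per live birth, outcome 1 if the infant
  reached 70 weeks (490 days, average weaning age). Infants still under
  70 weeks when observation ends are censored; records where the mother
  died before the infant's outcome resolved are excluded, because early
  maternal loss itself predicts infant death and would contaminate the
  environmental signal.

Windows are half-open on calendar dates: the "first year of life" is
$[\text{birth}, \text{birth} + 12\ \text{months})$, and adult rainfall is
the 12 months ending at the event anchor (first day of the cycling month;
pregnancy end date; infant death or 70-week date). Twelve-month windows
are used for rainfall because the study system is strongly seasonal —
shorter windows would confound the window's placement in the year with
its rainfall level. Rainfall is normalised by the number of window months
(always 12), not elapsed days, so the quantity is a mean *monthly*
rainfall even across leap spans. Rank windows are gap-tolerant: the
three-month window around a month (the month plus its neighbours) takes
the mean of whatever months are observed, which retains records around
occasional gaps; single-month and three-month ranks correlate at >0.99 in
the motivating data, so the averaging is innocuous. A fully empty window
drops the record with reason `missing_rank_window`. We never impute a
missing environment: dropped records are counted and logged, mirroring
how real datasets end up with slightly different Ns per outcome.

Covariates are age at the event, age squared (fertility is lower at both
age extremes), and mean daily group size over the outcome-appropriate
span. Parity and prior-infant fate are deliberately *not* conditioned on
in conception models: they may be downstream consequences of the
environmental exposures under test, and adjusting for them could mask the
very effect being estimated.

Two genuinely open choices were resolved as follows: rank aggregation
over a pregnancy uses calendar months (conception month through end
month), and reproductive states are taken as given for whatever months
they are supplied — the builders do not second-guess adolescence or
observation-effort boundaries.

## Estimation and inference

The outcome is binary, so the quadratic model is fitted as a linear
probability model (`fit_lpm()`): least squares of the 0/1 outcome on the
five environment terms plus covariates. A probability-scale model is used
because the derivative tests and all effect translations are reported on
the probability scale; an analyst preferring a logistic surface can
generate data under one (`link = "logistic"`) and verify, as our tests
do, that the derivative tests retain their signs under that
misspecification.

Fixed effects come in two flavours with different scientific meanings:

* **Group fixed effects** compare females within social groups,
  absorbing between-group differences in habitat quality. Both DC and AR
  are testable.
* **Individual fixed effects** compare a female to herself across time —
  the strongest AR design, since it removes all stable between-female
  differences. Because each female has exactly one developmental
  environment, $e_0$ and $e_0^2$ are absorbed and **DC is untestable**
  in this design; the package refuses rather than silently reporting a
  meaningless number. The interaction $e_0 |\Delta e|$ varies within
  female and is retained. Females contributing a single observation are
  dropped (logged) since they carry no within-female information.

Fixed effects are removed either by within-demeaning or by explicit
dummies; the two give identical slopes (verified to 1e-8 in the test
suite) and `"auto"` picks demeaning for the many-level individual case.
Collinear columns are dropped by QR pivoting and reported by name;
absorbed terms are flagged not-estimable rather than reported as zeros.

Inference clusters on the female: repeated observations of one female are
arbitrarily correlated. `cluster_vcov()` computes the one-way
cluster-robust sandwich with the CR1 small-sample factor
$\frac{G}{G-1}\cdot\frac{N-1}{N-K}$ — the convention of the replication
software most analysts in this literature use, so that results are
comparable across implementations. The parameter count $K$ counts
absorbed fixed-effect levels when the cluster variable differs from the
absorbed factor, but not when clustering on the absorbed factor itself
(the within-estimator convention); both choices are standard, this one is
fixed and documented here. Derivative tests are delta-method linear
combinations $c'\hat\gamma$ with $se = \sqrt{c' V c}$, referred to a
$t_{G-1}$ distribution ($G$ = clusters). P-values are two-sided; the
directional prediction enters through the `consistent_with_theory` flag
(sign matches the theory *and* $p < \alpha$), so a significant effect in
the wrong direction is never counted as support.

Derivatives are evaluated by default at the sample means of $e_0$ and
$|\Delta e|$ — the natural reporting point, and the one whose context
(means and sds) the results table carries — with arbitrary evaluation
points available for sensitivity analysis.

### Effect translation

`percentile_contrast()` turns a fitted surface into the kind of sentence
results sections need: predicted outcomes at the 10th and 90th empirical
percentiles of one variable, everything else at sample means, fixed
effects at their sample average. The relative difference compares failure
probabilities between the adverse percentile (low $e_0$, or high
$|\Delta e|$) and the favourable one, as a percentage of the mean failure
probability; `relative_to_absolute()` then rescales by the baseline mean
outcome (a 13.18% relative difference on a 73.74% baseline is a 9.72
percentage-point difference). Whether such a contrast should condition
covariates at means or average over the sample is not uniquely
determined; conditioning at means is used, and the convention travels
inside the result object. Both the relative and the absolute figure are
always emitted so a reader can apply either convention.

### Asymmetry of gains and losses

Working with $|\Delta e|$ forces upward and downward environmental
changes of equal size to act identically. `asymmetry_test()` relaxes
this: the $|\Delta|$ terms are replaced by $\Delta^+ = \max(\Delta, 0)$
and $\Delta^- = \max(-\Delta, 0)$, each with its square (the interaction
is kept as $e_0|\Delta e|$), and a joint cluster-robust Wald test
($F_{2, G-1}$) asks whether the positive and negative coefficient pairs
are equal. This particular construction — which terms are sign-split and
that the test is joint — is one reasonable choice among several; the
result object records it, and a noiseless symmetric dataset yields
exactly $W = 0$, $p = 1$.

### Multiple testing

One full run produces 18 derivative tests (three outcomes, two
environments, DC under group fixed effects, AR under both). The family is
adjusted with sharpened two-stage FDR q-values: a step-up at the deflated
level $q/(1+q)$ estimates the number of true nulls from its rejections,
and a second step-up at the sharpened level $q' m / \hat m_0$ decides.
`sharpened_qvalues()` reports, for each test, the smallest level on the
grid $\{0.001, \dots, 0.999\}$ at which it is rejected (1 if never); the
grid matches the three-decimal precision at which such q-values are
conventionally reported. The family is whatever set of labelled p-values
the caller provides — `run_full_analysis()` uses all tests of the run —
because no canonical family definition exists beyond the analysis
actually performed. Q-values can legitimately undercut their p-values
when many strong discoveries shrink the estimated null count.

## The synthetic-data generator

`simulate_panel()` generates panels with the dependence structure the
analysis assumes, and is the package's test bed:

* $e_0$ is drawn once per female — Uniform(0,1) for rank-like
  environments, or a right-skewed lognormal with mean 28.8 mm/month and
  sd ~10.5 for rainfall-like ones, matching the observed
  developmental-rainfall moments of the motivating system (the lognormal
  shape itself is a modelling choice; the real delta distributions are
  not digitised anywhere we could consume).
* $e_1$ is drawn per observation from a Gaussian copula with correlation
  `rho` (default 0.71, the developmental/adult rank correlation reported
  for the motivating population). For the uniform marginal the latent
  correlation is adjusted ($2\sin(\pi\rho/6)$) so the achieved Pearson
  correlation equals `rho`; for the skewed marginal the achieved value is
  reported and warned about only when a large sample misses by more
  than 0.05. `rho = 1` produces identical environments, zero deltas, and
  a flagged degenerate design on which AR is rightly not estimable.
* The latent probability is the quadratic surface plus female and group
  random intercepts, covariate terms, and Gaussian observation noise;
  the binary outcome is Bernoulli after clipping the latent value to
  $[0,1]$ (the default, matching the linear probability analysis model)
  or a logistic squash. Clipping beyond 20% of observations triggers a
  configuration warning. By default the `gamma` coefficients apply to
  z-scored environment terms, so effect sizes are in interpretable
  per-sd units; `standardize_effects = FALSE` gives raw-scale
  coefficients, which the parameter-recovery tests use so truth and
  estimate live on the same scale.

Default panel dimensions are 300 females with 10 observations each in 8
social groups — the cluster count and within-female replication of a
large wild-primate dataset at a size every simulation in the test suite
can afford. The null regime keeps all environment coefficients at zero
with female sd 0.05, group sd 0.02, noise sd 0.1; the strong regimes put
0.5 (DC) or −0.5 (AR) on one standardized term with noise sd 0.5. Under
the strong regimes substantial latent clipping is intentional — the
regime is meant to be unambiguous, and the attenuation it causes works
against the test, making full sensitivity a conservative claim.

What the generator does *not* emulate: mechanistic demography (group
fissions, matriline overthrows, mortality), serially correlated
within-female environments beyond the shared $e_0$, seasonal structure in
adult windows, and state-machine consistency between consecutive
reproductive events. Passing simulations therefore certify the
*statistical* machinery — estimator, variance, size, power, FDR — not the
ecological realism of any particular dataset.

## What the simulations show, at which sizes

All study sizes below are the package's own choices, stated here so every
number in the test suite has a context:

* **Sensitivity**: 200 replicates of each strong regime. The DC test
  rejects in the predicted direction in 100% of replicates; the AR test
  (individual fixed effects) exceeds 90% — in practice it also sits
  at 100%. `scripts/acceptance.R` recomputes both figures from scratch.
* **Size**: 1000 null replicates; both tests' two-sided rejection rates
  at $\alpha = 0.05$ fall inside [0.03, 0.07], and null p-values are
  close to uniform.
* **Parameter recovery**: 100 seeded panels of 2000 records with known
  raw-scale coefficients and a noiseless link; each environment
  coefficient lands within 3 cluster-robust SEs of truth in ≥95% of
  replicates.
* **Oracle equivalence**: the cluster vcov matches a brute-force
  per-cluster outer-product sandwich to 1e-10 (relative); both
  derivative estimates match central finite differences of the fitted
  surface to 1e-6; q-values match an independent `p.adjust`-based
  re-implementation exactly on random families.
* **FDR**: over 2000 all-null families of 18 uniform p-values, the share
  of families with any $q \le 0.05$ stays below $0.05$ plus 3 binomial
  MC standard errors.
* **Bootstrap cross-check**: the delta-method AR standard error agrees
  with an 800-replicate cluster bootstrap within 10%.

## Numerical choices and degenerate inputs

* Time windows half-open; month arithmetic rolls back (31 Jan + 1 month
  → 28/29 Feb) rather than spilling into the next month.
* Missing rain days are an error by default (`missing = "zero"` opts
  into treating them as dry); missing rank months inside a window are
  averaged over; a fully missing window excludes the record.
* `e1` is stored as `e0 + delta` so the identity $e_0 + \Delta = e_1$
  holds bit-exactly in every record.
* Rank-deficient designs drop pivoted columns with a warning; a
  numerically singular bread matrix aborts with its condition number.
* A zero standard error with a non-zero estimate is an error
  (degenerate variance), while an exactly zero estimate with zero se
  reports $p = 1$.
* Fewer than two female clusters abort before any fitting; equal-count
  binning spreads remainders over leading bins and degrades (with a
  warning) when records are scarcer than bins.

## Known limitations

* The linear probability model can predict outside $[0,1]$ far from the
  data; contrasts are reported at interior percentiles where this is
  immaterial, but extreme evaluation points deserve the logistic
  cross-check.
* Observational rank data cannot rule out that "rank effects" reflect
  stable female quality; the within-female AR design mitigates, and the
  group-FE DC design cannot. This is a design limit of the science, not
  of the implementation.
* The sensitivity figures are achievable-regime checks under this
  generator's conditions, not universal power statements.
* The asymmetry test is one defensible construction of a test whose
  original specification is not public; treat its p-values as the answer
  to *this* construction's question.
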