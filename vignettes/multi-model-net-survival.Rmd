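---
title: "Multi-model inference for population cancer net survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-model inference for population cancer net survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netmma)
```

## The problem

Cancer registries need to state, close to the point of diagnosis, what the
survival prospects of recently diagnosed patients are — including patients
whose follow-up has barely begun (prediction) and patients who will only be
diagnosed next year (projection). The quantity of interest is *net
survival*: the survival that would be observed if the studied cancer were
the only possible cause of death. Net survival is independent of background
mortality and therefore comparable across populations and calendar time.

Because cause-of-death coding is unreliable, net survival is estimated in
the relative-survival framework: the observed mortality hazard of the
cohort is decomposed as

$$\lambda(t, x) = \lambda_E(t, x) + \lambda_P(a + t,\, y + t,\, z),$$

where $\lambda_E$ is the *excess* hazard attributable to the cancer and
$\lambda_P$ is the expected (general population) hazard taken from a life
table at attained age $a+t$, attained calendar year $y+t$, and demographic
strata $z$ (sex, deprivation, ...).

No single model can be assumed to hold: the baseline hazard shape, the
linearity of covariate effects, and their constancy over follow-up time are
all in doubt, and different plausible models give different predictions.
This package therefore implements *multi-model inference*: a stepwise
search over functional forms that deliberately retains every model whose
information criterion is within 2 of the minimum, followed by
criterion-weighted averaging of the predicted hazards.

## The excess hazard model

The log baseline excess hazard is a restricted cubic spline in $\log t$:

$$\log \lambda_0(t) = \gamma_0 + \gamma_1 B_1(\log t) + \gamma_2 B_2(\log t)
  + \gamma_3 B_3(\log t),$$

with two internal knots at the tertiles of the uncensored event-time
distribution and boundary knots at its extremes. Covariates enter as

$$\lambda_E(t, x) = \lambda_0(t)\,
  \exp\Big(\beta_1(t) f(x_1) + \sum_{j \ge 2} \beta_{2,j}(t)\,
  I(x_2 = j)\Big),$$

where $f$ is the identity for a linear effect or a restricted cubic spline
for a non-linear one, and a time-dependent effect replaces the constant
$\beta$ by $\beta \cdot \log t$ — exactly a log-time interaction, not a
spline of log-time. Pairwise interactions multiply the linear/dummy codings
of two variables, optionally with the same $\log t$ multiplier.

Parameters are estimated by maximising

$$L = \sum_i \delta_i \log\{\lambda_P(t_i) + \lambda_E(t_i)\}
  - \Lambda_E(t_i),$$

which requires no cause-of-death information. $\Lambda_E$ has no closed
form for spline/time-dependent hazards and is computed by Gauss-Legendre
quadrature.

```{r fit-demo}
lt <- make_synthetic_life_table(sexes = "male")
sc <- scenario_preset("colon", n = 1500, years = c(2002, 2008),
                      censor_date = 2011, seed = 7)
d <- simulate_cohort(sc)
fit <- fit_excess_hazard(
  d, eh_spec(3, effects = list(eh_effect("age"), eh_effect("year"))), lt)
glance(fit)
```

## Model selection: keep everything within 2

Starting from the simplest model (all effects linear and proportional), the
search upgrades one variable at a time — non-linearity first, then
time-dependency, then pairwise interactions — and compares the two
candidate fits' criteria. A gap larger than 2 discards the worse model; a
gap of at most 2 keeps *both*, and each branch is expanded further. The
result is the set of models with comparable support, every retained
$\Delta_m = XIC_m - XIC_{\min} \le 2$.

The number 2 is anchored by evidence ratios. With model likelihood
$\exp(-\Delta_m / 2)$ and weights $w_m$ normalised to sum to one, the
evidence ratio of the best model over one at gap $\Delta_n$ is
$\exp(\Delta_n / 2)$: about 2.7 at $\Delta = 2$, 7.4 at 4, and 54.6
at 8. Within 2, the evidence for preferring the best model alone is weak;
beyond it, it grows exponentially. The same threshold has a testing
interpretation: preferring the larger of two nested models differing by one
parameter on AIC is a likelihood-ratio test at statistic 2, an implied
p-value of `r round(pchisq(2, 1, lower.tail = FALSE), 3)`.

Two scheduling variants are provided. `"adapted"` orders variables by their
single-upgrade criterion improvement over the base model (the
information-criterion translation of "most significant first");
`"interaction-first"` keeps the user-given variable order and settles main
effects before interactions are scanned. Both log every comparison so the
schedule is auditable. Branches are capped (default 16, pruning the
worst-criterion branch with a warning) because the retained set rarely
exceeds ten models while an unbounded search can explode combinatorially.
Ties are broken lexicographically on the canonical spec string, and
converging branches are merged by that string so no spec is counted twice.

```{r select-demo}
ms <- select_models(d, eh_spec(3, effects = list(eh_effect("age"),
                                                 eh_effect("year"))),
                    lt, criterion = "AIC")
tidy(ms)
```

## Averaging predictions, not parameters

Structural parameters of non-linear models must not be averaged; the
averaged quantity is the predicted hazard itself. For each subject $i$ and
time $t$ on a pre-defined grid (monthly by default):

1. $\hat\lambda_{i,MA}(t) = \sum_m w_m \hat\lambda_{i,m}(t)$;
2. $\hat\Lambda_{i,MA}(t) = \sum_m w_m \hat\Lambda_{i,m}(t)$;
3. $\hat S_{i,MA}(t) = \exp\{-\hat\Lambda_{i,MA}(t)\}$;
4. cohort net survival $\hat S_{MA}(t) = N^{-1}\sum_i \hat S_{i,MA}(t)$.

The order matters: the averaged cumulative hazard is exponentiated, not the
per-model survival curves averaged (for $\Lambda \in \{1, 2\}$ at equal
weights the two orders give 0.2231 vs 0.2518; this package returns 0.2231).

The variance of the averaged hazard is the unconditional
(selection-uncertainty-aware) estimator

$$\widehat{\mathrm{var}}(\hat\lambda_{i,MA}) = \Big[\sum_m w_m
  \sqrt{\widehat{\mathrm{var}}(\hat\lambda_{i,m})
  + (\hat\lambda_{i,m} - \hat\lambda_{i,MA})^2}\Big]^2,$$

which combines delta-method within-model variances with the between-model
spread and assumes perfect pairwise correlation of model deviations —
deliberately conservative. The variance is computed on the hazard scale,
where averaging is defined; survival-scale intervals are obtained by the
monotone transform $\exp(-\cdot)$ of cumulative-hazard-scale intervals.
Whether survival intervals should instead be built on another scale is
genuinely open; the transform policy is declared here so results are
reproducible.

## Reference estimators: Pohar-Perme, cohort and period

The non-parametric benchmark is the Pohar-Perme estimator,
$\hat S_E(t) = \exp\{-\hat\Lambda_E(t)\}$, with each patient's
contributions to the death, at-risk and expected-mortality processes
weighted by $1/S_{P,i}(t)$ — the inverse of their expected survival — to
correct the informative removal of patients by other-cause death. The
expected-death term is accumulated exactly over the piecewise-constant
life-table cells, using
$\int_a^b \lambda_{P,i}(u) / S_{P,i}(u)\, du = 1/S_{P,i}(b) -
1/S_{P,i}(a)$. The variance is a Poisson-type variance of the weighted
increments, delta-method transformed to the survival scale; the original
publications admit several variance constructions and this choice is the
package's own.

The period variant restricts each patient to the person-time falling inside
a calendar window (left truncation at window entry, censoring at exit),
approximating the survival of recently diagnosed patients without any
parametric extrapolation. When only an integer diagnosis year is supplied,
diagnosis is placed at mid-year for window intersection.

## Quantifying prediction accuracy: RMISD

Predicted and reference curves are compared per patient group $g$ (age band
$\times$ deprivation quintile by default, with age bands 15-44, 45-54,
55-64, 65-74, 75-99) by the integrated square difference to a horizon $H$
(1 and 5 years by default):

$$ISD_g = \int_0^H \{\hat S_g(u) - S_g(u)\}^2\, du, \qquad
RMISD = \sqrt{\tfrac1G \sum_g ISD_g}.$$

Integrals use 20-node Gauss-Legendre quadrature, exact for polynomial
differences up to degree 19. Non-parametric step curves are evaluated at
the nodes right-continuously from $S(0) = 1$; model curves are evaluated
exactly. The same 20-node rule is used for every cumulative-hazard integral
in the package — one quadrature policy throughout, cross-checked against a
60-node refinement in the tests.

## The synthetic registry generator

Real registry data are confidential, so the package ships a generator whose
truth is known in closed form. The true excess hazard is Weibull-like with
log-time interactions,

$$\lambda_E(t, x) = \rho \kappa t^{\kappa - 1}
  \exp\{\eta(x) + \zeta(x) \log t\},$$

so $\Lambda_E(t) = \rho\kappa e^{\eta} t^{\kappa + \zeta} / (\kappa +
\zeta)$ and cancer death times are drawn by exact inversion. Other-cause
deaths are drawn by inverting the patient's piecewise-constant expected
cumulative hazard from the same life table later used in estimation, so the
background-mortality assumption holds exactly by construction; follow-up is
administratively censored at a calendar cut-off and the observed status is
all-cause. Draws flow through named RNG streams so adding a covariate does
not shift the other draws, and a fixed seed reproduces a cohort exactly.

Three presets cover qualitative regimes seen in registry practice —
`"lung"` (high lethality, a calendar-trend slope break, a time-dependent
deprivation effect), `"colon"` (moderate lethality, steady trend),
`"breast"` (low lethality, slow steady trend, female) — with a Gompertz
life table ($2\times10^{-5} e^{0.095\,a}$, deprivation multipliers 0.85 to
1.35, a mild negative calendar trend). All effect sizes are this package's
own choices of realistic magnitudes; they are not estimates from any
registry. What the generator deliberately omits: data-quality artifacts
(duplicate records, date errors), missing stage and its imputation, and
life-table misspecification (available as an explicit multiplier switch).
Passing tests on these cohorts therefore demonstrate correctness of the
machinery under a correctly specified background, not robustness to real
registry data quality.

## Numerical choices

* **Quadrature**: 20 Gauss-Legendre nodes per integral, everywhere.
* **Knot placement**: internal knots at equally spaced percentiles of the
  uncensored event times, probabilities rounded to four decimals (33.33%,
  66.67% for three degrees of freedom), resolved by the inverse empirical
  CDF (type-1 quantile). The rounding makes knot selection deterministic
  and documented so independent oracles can reproduce it exactly.
* **Working scale**: the baseline spline acts on $\log t$ with knots on log
  event times; covariate splines act on the identity scale. Whether spline
  bases should act on $t$ or $\log t$ is a defensible either way; the
  log-time choice matches the standard flexible parametric fitting tools
  and can be revisited by supplying a custom basis.
* **Zero survival times**: events recorded at $t = 0$ are shifted to one
  day (1/365.25 years) since the log-time baseline is undefined at 0.
* **Deprivation** is modelled as a categorical factor (quintile dummies,
  quintile 1 reference); a time-dependent deprivation effect multiplies
  every dummy by $\log t$. Registry quintiles are ordinal labels, not
  scores.
* **Centering**: continuous covariates are centered at their sample means
  internally for optimizer conditioning; centers are stored in the model
  frame and applied to new data, so predictions are unaffected.
* **Optimiser**: BFGS with analytic gradients; starting values are the
  null exponential rate for the intercept and zeros elsewhere; the
  covariance is the inverse observed information (analytic Hessian) at the
  optimum. Rank-deficient designs and zero-event data fail with explicit
  errors rather than returning silently regularised fits.
* **Age clamping, no year extrapolation**: attained ages above the life
  table maximum use the maximum-age row; attained calendar years outside
  the table raise an error, because extrapolating population mortality
  trends silently would fabricate the very trend the models are trying to
  estimate. Projections one year past the window extrapolate only the
  *fitted year-of-diagnosis effect*, which is exactly what a parametric
  model permits and the period approach cannot do.

## Problem sizes

The statistical test suite uses cohorts of 2000-5000 patients, 20-50
simulation replicates per property, and selection problems of two to three
covariates. These sizes were chosen to give each check adequate power —
parameter recovery within two standard errors, selection consistency above
90%, and accuracy orderings above 80% — while keeping each property
testable in minutes on a single core.

## Limitations

Cure models, frailty, and non-log-link alternatives are out of scope, as is
cause-of-death-based (cause-specific) survival. Age-standardised net
survival and hybrid cohort/period estimators are not provided. The
selection search is a stepwise scan, not an exhaustive one: it inherits the
path-dependence of stepwise procedures, which the retention-within-2 rule
and the audited comparison log mitigate but do not remove.
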