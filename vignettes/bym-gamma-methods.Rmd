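---
title: "Methods: spatial gamma regression for standardized small-area prevalence"
author: "bymGamma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial gamma regression for standardized small-area prevalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bymGamma)
```

## The problem

Community health surveys such as the Korea Community Health Survey interview
on the order of 900 adults per administrative district (si/gun/gu) per year.
From those records one wants to know whether a district's smoking burden —
current smoking rate, passive smoking at home, passive smoking at work — is
associated with its prevalence of cardiovascular disease (hypertension,
stroke, myocardial infarction, angina), both nationally and district by
district. Two statistical obstacles shape the analysis:

1. Districts differ in age and sex composition, so raw prevalences are not
   comparable. The package therefore computes **directly standardized**
   prevalences and exposure rates per district-year.
2. Standardized prevalences of rare conditions are positive, right-skewed
   quantities (a Shapiro–Wilk screen on the panel confirms non-normality),
   and neighbouring districts are correlated. The package therefore fits a
   **Bayesian hierarchical gamma regression with a log link** and a
   Besag–York–Mollié (BYM) spatial random intercept.

## Direct standardization

For a binary survey variable and sex-age strata $s$ with standard weights
$w_s$ (normalized to 1), the standardized rate is
$100 \sum_s w_s \bar r_s$, where $\bar r_s$ is the stratum mean among
non-missing responses. Conventions, chosen where the field leaves latitude:

* **Standard population.** Default is the pooled study sample's sex-age
  distribution of the same calendar year (`pooledStandard()`), i.e.
  standardization "to the year of study"; any external standard can be
  supplied as a CSV. Standardizing with the sample's own demography
  reproduces the crude rate exactly — a unit-tested identity.
* **Age bands** default to 5-year bands 19–24 … 80+. Outcome-specific
  age restrictions (hypertension ≥ 30, stroke ≥ 50, myocardial infarction
  and angina ≥ 40) keep only bands wholly above the cutoff; a band
  straddling a cutoff is a configuration error, not a silent approximation.
* **Missingness** is handled complete-case within stratum. Strata with
  standard weight but no observed respondents have their weight
  redistributed proportionally over observed strata (a switch allows
  dropping that weight instead).
* **Zero prevalence** cells are never altered at this stage; they are
  flagged `nonpositive` and resolved by the model stage's positivity policy.

## The hierarchical model

For district $i$ and year $t$, the standardized prevalence $y_{it}$ (percent)
of one outcome is modelled as

$$y_{it} \sim \mathrm{Gamma}(\alpha,\ \alpha / \mu_{it}), \qquad
\log \mu_{it} = \beta_0 + \beta_x x_{it} + \beta_b \mathrm{bmi}_{it}
 + \beta_d \mathrm{drink}_{it} + \beta_t (t - \bar t) + u_i + v_i + b_i x_{it},$$

where $x_{it}$ is the chosen smoking exposure in percent. The shape $\alpha$
is shared across cells, so the response has constant coefficient of
variation $1/\sqrt{\alpha}$.

* $u$ is the **structured (ICAR)** intercept: improper Gaussian prior with
  precision $\tau_u Q$, $Q$ the graph Laplacian of the district contiguity
  graph; its kernel penalizes squared differences between neighbours. Each
  connected component (islands!) carries its own sum-to-zero constraint,
  enforced by per-component recentering with the offset absorbed into
  $\beta_0$; the $\mathrm{rank}(Q)/2 \cdot \log \tau_u$ pseudo-determinant
  term enters the $\tau_u$ update analytically.
* $v$ is the **unstructured** iid intercept; $u + v$ is the classic
  two-component BYM decomposition.
* $b$ is an **iid random slope** on the exposure; intercepts and slopes are
  mutually independent.
* Priors: every random-effect precision has a $\mathrm{Gamma}(1,\ 5\times
  10^{-5})$ prior (shape, rate); fixed effects are independent
  $N(0, 1000)$ (precision $10^{-3}$), realized as independent normals
  rather than a structured multivariate prior; $\alpha$ has a weakly
  informative $\mathrm{Gamma}(1, 0.01)$ prior.

Covariates enter **uncentered in natural units**, so the relative risk per
5-percentage-point exposure increase is $\exp(5\beta_x)$ nationally and
$\exp(5(\beta_x + b_i))$ for district $i$. The year is centered at the
mid-study year only to decorrelate it from the intercept. One model fits one
outcome-exposure pair; the pipeline loops over the 4 × 3 grid when asked.

**Positivity policy.** A gamma response requires $y > 0$. Default: exclude
nonpositive cells with a warning; option: impute half the minimum positive
value. Exclusion is the least inventive choice and is visible in the logs.

## Posterior computation

The posterior is computed by Metropolis-within-Gibbs (`runSampler()`, C++
core) rather than by INLA, the deterministic approximation usually reached
for with BYM models: MCMC keeps every conditional update auditable against
closed forms and simulation oracles, which is what this package optimizes
for.

* Fixed effects: componentwise random-walk Metropolis on internally
  standardized covariates (the prior is evaluated on the natural scale after
  back-transformation). Scalar updates adapt toward 44% acceptance during
  burn-in only (Robbins–Monro, frozen afterwards to preserve detailed
  balance).
* $u_i, v_i, b_i$: single-site random-walk updates touching only the
  region's own likelihood terms.
* $\tau_u, \tau_v, \tau_b$: conjugate Gibbs draws from
  $\mathrm{Gamma}(a + r/2,\ c + S/2)$ with $r$ the iid length or ICAR rank
  and $S$ the sum of squares or ICAR quadratic form.
* $\alpha$: random-walk on $\log \alpha$ with the Jacobian included.
* **Ridge-breaking moves.** Three exact Gibbs "sweep" updates remove the
  flat directions that slow naive samplers: translation of all $v_i$
  against $\beta_0$; translation of all $b_i$ against $\beta_x$; and a
  partially collapsed update of $(\tau_u, \tau_v, u)$ given $s = u + v$ in
  the ICAR eigenbasis, where $s_k \sim N(0, (\tau_u \lambda_k)^{-1} +
  \tau_v^{-1})$ with $u$ integrated out, including a symmetric proposal
  that swaps the roles of the two components.

Initialization is deterministic: least squares on $\log y$ for the fixed
effects, zeros for random effects, method-of-moments for $\alpha$. Chains
are seeded `seed + chain - 1`; identical inputs give bit-identical draws.

### A note on BYM identifiability

The likelihood sees only $u_i + v_i$, and the $\mathrm{Gamma}(1, 5\times
10^{-5})$ prior has prior *mean precision* $2\times 10^4$: it favours
shutting either component off. The posterior of the $(\tau_u, \tau_v)$ split
is therefore genuinely bimodal — one component absorbs the identified total
variance while the other's precision escapes to the prior scale — and chains
alternate between the two labelings. Split-$\hat R$ for $\tau_u$, $\tau_v$
and the log posterior can consequently sit well above 1.05 at desk-scale run
lengths while every identified quantity (fixed effects, $\alpha$, $\tau_b$,
all RR functionals, $u+v$) converges with $\hat R \approx 1.00$ and
effective sample sizes in the hundreds to thousands (checked against 20×
longer reference chains). `samplerDiagnostics()` reports all parameters;
judge convergence of the BYM precisions on the identified quantities, or run
longer chains if the split itself is of interest.

## Reported quantities

`nationalRR()` and `regionalRR()` transform slope draws draw-wise into
$RR = \exp(\delta \beta)$ with $\delta = 5$ points by default. The point
estimate is the **posterior mean of the RR draws** (a `point = "median"`
switch exists); intervals are equal-tailed 2.5/97.5 posterior percentiles,
which — `exp` being monotone — equal the transformed slope percentiles. A
"significant" RR (95% CI excluding 1) is exactly a slope CI excluding 0.
`rankRegions()` orders districts by posterior mean RR with ties broken by
district id.

Note that the mean-of-RR estimator carries the usual Jensen inflation
$\exp(\delta^2 \mathrm{Var}(\beta)/2)$ relative to $\exp(\delta \hat\beta)$;
with diffuse slope posteriors the two can differ by a percent or more.

## The synthetic-data generator

Real community-health microdata are restricted, so `generatorConfig()`,
`sampleTruth()`, `generatePanel()` and `generateSurveyRecords()` provide a
forward model with known truth at two levels:

* **Panel level** — exactly the model above: covariate surfaces are drawn
  as logit-normal rates (normal BMI) matched to published district-level
  descriptive moments for Korea 2008–2013 (smoking 25.2% ± 2.9, passive
  smoking at home 11.8% ± 4.1 and at work 29.2% ± 9.3, monthly drinking
  56.5% ± 5.4, BMI 23.0 ± 0.7 kg/m²; hypertension 18.2% ± 2.4, stroke
  3.3% ± 1.1, myocardial infarction 1.4% ± 0.6, angina 1.9% ± 0.7), with
  30% of each SD allocated to within-district year-to-year variation. The
  modelled outcome (default: stroke, with a true slope of
  $\log(1.060)/5$, i.e. RR 1.060 per 5 points) is drawn from the gamma
  likelihood around $\exp(\eta_{it})$; the other outcomes are
  moment-matched gamma draws around district means. $u$ is drawn from the
  ICAR distribution via the precision's positive eigenspace, which makes
  the per-component centering exact by construction.
* **Record level** — about 900 respondents per district-year from a
  configurable sex-age demography (default: roughly half the adults aged
  50+, as in aging rural districts), Bernoulli exposure and drinking
  flags at the district rates, and within-stratum Bernoulli disease
  indicators whose mild age profile is normalized over each outcome's
  eligible strata so that the directly standardized prevalence has
  expectation $\exp(\eta_{it})$. Standardizing the generated records
  therefore reproduces the panel surface up to binomial sampling error —
  the pipeline-closure property the acceptance suite quantifies.

Default truth values not fixed by the study design were chosen once for
realism and left alone: $\tau_u = \tau_v = 50$ (regional log-risk SD ≈ 0.14
per component), $\tau_b = 2000$ (regional RR per 5 points ranging roughly
0.90–1.12), $\alpha = 50$ (within-district CV ≈ 14%). $\beta_0$ is
calibrated analytically so the modelled outcome's mean prevalence matches
its target, including log-normal corrections for the random-effect
variances.

What the generator deliberately does **not** emulate: the survey's
probability-proportional-to-size sampling design, nonresponse,
self-report measurement error, and any real contiguity map (tests use rook
lattices; the real analysis reads an adjacency file). Passing recovery tests
on synthetic data therefore validates the estimator under the model's own
assumptions, not the design-based properties of a real survey.

## Verification strategy and problem sizes

The test suite checks, at sizes chosen to keep a laptop run comfortable:

* ICAR structure on random graphs (n ≤ 20): zero row sums, zero-eigenvalue
  count equal to component count, quadratic form equal to the brute-force
  neighbour sum.
* Conjugate precision draws against closed-form Gamma moments (10⁵ draws).
* The full sampler against a dense-grid numerical posterior on a 3-region,
  2-year instance with only $(\beta_0, \beta_x)$ free.
* The degenerate limit: precisions fixed at $10^8$ reproduce a fixed-effects
  gamma GLM (`stats::glm`) within two posterior SDs.
* Parameter recovery over 20 replicate 50-district, 6-year studies
  (2 chains × 4000 iterations each) and null calibration (true RR = 1) over
  30 reduced-scale replicates.
* Standardization identities (exact) and record-to-panel closure at
  n = 900 per cell.

Numerical conventions: region order is the lexicographic order of region
ids everywhere; the sum-to-zero tolerance is $10^{-8}$; ranking ties break
by region id; degenerate zero-variance inputs raise errors rather than
silently passing.

## Known limitations

* The BYM variance split is prior-dominated (above); only $u+v$ should be
  interpreted.
* One exposure per fitted model; the three smoking indices are analysed in
  separate fits, as in the reported tables, not jointly.
* Survey design weights and variance estimation for the standardized rates
  are out of scope; standardized prevalences enter the model as exact
  observations.
* The gamma likelihood is unbounded above, so model-generated "prevalences"
  can exceed 100% under extreme random-slope regimes; real standardized
  rates are bounded by construction.
* Exposures estimated from finite samples carry sampling noise (a
  standardized smoking rate from ~900 respondents has SE ≈ 1.5 points
  against a between-district SD of ≈ 2.9), which attenuates fitted slopes
  toward zero by the classical measurement-error factor, here roughly 20%.
  The model treats covariates as exact, as the original analysis does; the
  record-level closure tests make the effect visible rather than hiding it.
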