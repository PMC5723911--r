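# bymGamma

Bayesian spatial gamma regression for sex/age-standardized small-area
disease prevalence.

Community health surveys (the motivating setting is the Korea Community
Health Survey: 253 si/gun/gu districts, annual waves, roughly 900 adult
respondents per district-year) ask whether a district's smoking burden —
current smoking, passive smoking at home, passive smoking at work — is
associated with its prevalence of cardiovascular disease (hypertension,
stroke, myocardial infarction, angina), nationally and district by
district. `bymGamma` implements that analysis end to end for
epidemiologists working with areal survey data:

1. **Standardize** — direct sex/age standardization of individual survey
   records into a district-year panel of prevalences (with outcome-specific
   age restrictions: hypertension ≥ 30, stroke ≥ 50, MI/angina ≥ 40 years)
   and exposure rates, plus a Shapiro–Wilk normality screen.
2. **Model** — a hierarchical gamma regression with log link,

   y<sub>it</sub> ~ Gamma(α, α/μ<sub>it</sub>),&nbsp;&nbsp;
   log μ<sub>it</sub> = β₀ + β<sub>x</sub>x<sub>it</sub> +
   β<sub>b</sub>bmi<sub>it</sub> + β<sub>d</sub>drink<sub>it</sub> +
   β<sub>t</sub>(t − t̄) + u<sub>i</sub> + v<sub>i</sub> +
   b<sub>i</sub>x<sub>it</sub>,

   with a Besag–York–Mollié intercept (intrinsic CAR u over the district
   contiguity graph + iid v), an independent random slope b on the
   exposure, Gamma(1, 5e-5) priors on all random-effect precisions and
   zero-mean normal priors on fixed effects.
3. **Fit** — Metropolis-within-Gibbs MCMC (C++ core): conjugate precision
   updates, adaptive scalar random walks, and exact ridge-breaking sweeps,
   including a partially collapsed BYM update in the ICAR eigenbasis.
4. **Report** — national and per-district relative risks per 5-point
   exposure increase, RR = exp(5β) draw-wise, with equal-tailed 95%
   credibility intervals and top/bottom district rankings.

A synthetic-data generator reproduces the survey's structure (contiguity
graph, annual waves, ~900 respondents per district-year, marginal moments
matched to published Korean district statistics) with known ground truth,
so every stage is testable without the restricted microdata.

## Worked example

Simulate a 50-district study with a true smoking–stroke relative risk of
1.060 per 5 percentage points, fit it, and summarise:

```r
library(bymGamma)

graph <- latticeGraph(5, 10)                    # stand-in contiguity map
gen   <- generatorConfig(nRegions = 50, graph = graph,
                         years = 2008:2013, seed = 42)
truth <- sampleTruth(gen)                       # true RR = 1.060 per 5 pts
panel <- generatePanel(truth, gen)
panel
#> RegionYearPanel: 50 regions x 6 years, 4 outcome(s), 1200 prevalence cells ( 0 nonpositive )

fit <- runSampler(panel, modelSpec(), graph,
                  samplerConfig(nIter = 8000, nBurnin = 4000, thin = 4,
                                nChains = 2, seed = 7))
nationalRR(fit)
#>      level rr_mean rr_ci_low rr_ci_high delta
#> 1 national 1.01752 0.9218945   1.113466     5

rankRegions(regionalRR(fit), k = 3)$top
#>   region_id  rr_mean rr_ci_low rr_ci_high delta
#> 1    R02_09 1.425340  1.295304   1.556340     5
#> 2    R01_05 1.341355  1.203807   1.482485     5
#> 3    R01_02 1.218230  1.080761   1.359975     5
```

The national summary reads: a 5-point increase in district smoking rate
multiplies expected stroke prevalence by 1.018 (95% CI 0.92–1.11) — the
interval covers the simulated truth of 1.060, and this single dataset's
point estimate scatters around it as the recovery tests quantify. The
ranking lists the districts whose *district-specific* slopes
exp(5(β<sub>x</sub>+b<sub>i</sub>)) are highest; CIs excluding 1 flag
districts where the exposure-prevalence association is credibly positive.

The same objects come from real data via `readSurveyRecords()` +
`buildPanel()` (standardization) and `readAdjacency()` (the real contiguity
list), or from disk-based runs via `pipelineSimulate()`,
`pipelineStandardize()`, `pipelineFit()` and `pipelineReport()` driven by a
single YAML config.

## Layout

- `R/` — S4 classes (`SpatialGraph`, `ICARStructure`, `RegionYearPanel`,
  `ModelSpec`, `SamplerConfig`, `PosteriorSamples`) and exported functions
  per stage.
- `src/` — the Rcpp sampler core.
- `tests/testthat/` — unit, property and acceptance suites (all fixtures
  generated in code).
- `vignettes/bym-gamma-methods.Rmd` — model, priors, sampler, generator
  calibration, limitations.
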