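# Shared fixture builders. Everything is generated in code; no data files.

# A minimal survey-record data.frame; vectors are recycled to the longest.
makeRecords <- function(region_id = "R1", year = 2010L, sex = "M",
                        age_group = "30-34", hypertension = 0L, stroke = 0L,
                        myocardial_infarction = 0L, angina = 0L,
                        current_smoker = 0L, passive_home = 0L,
                        passive_work = 0L, bmi = 23, drinks_monthly = 0L) {
  data.frame(region_id = region_id, year = year, sex = sex,
             age_group = age_group, hypertension = hypertension,
             stroke = stroke, myocardial_infarction = myocardial_infarction,
             angina = angina, current_smoker = current_smoker,
             passive_home = passive_home, passive_work = passive_work,
             bmi = bmi, drinks_monthly = drinks_monthly,
             stringsAsFactors = FALSE)
}

# A small hand-assembled panel: one outcome over a region x year grid.
tinyPanel <- function(regions, years, y, x, outcome = "stroke",
                      bmi = 23, drink = 56, expected = NA_real_) {
  grid <- expand.grid(year = years, region_id = regions,
                      stringsAsFactors = FALSE)[, c(2, 1)]
  grid <- grid[order(grid$region_id, grid$year), ]
  out <- data.frame(region_id = grid$region_id, year = grid$year,
                    outcome = outcome, prevalence = y, expected = expected,
                    n = 900L, nonpositive = y <= 0, stringsAsFactors = FALSE)
  cov <- data.frame(region_id = grid$region_id, year = grid$year,
                    smoking_rate = x, passive_home_rate = 12,
                    passive_work_rate = 29, mean_bmi = bmi,
                    drinking_rate = drink, n = 900L, stringsAsFactors = FALSE)
  new("RegionYearPanel", outcomes = out, covariates = cov)
}

# Assemble a PosteriorSamples object from explicit draw matrices.
makePosterior <- function(chains, regionIds = character(),
                          spec = modelSpec(), config = samplerConfig()) {
  new("PosteriorSamples", draws = chains,
      accept = c(beta = 0.4, u = 0.4, v = 0.4, b = 0.4, alpha = 0.4),
      regionIds = regionIds, spec = spec, config = config)
}

# Brute-force ICAR quadratic form: sum over edges of squared differences.
bruteQuadForm <- function(graph, u) {
  em <- graphEdges(graph)
  if (!nrow(em)) return(0)
  sum((u[em[, 1]] - u[em[, 2]])^2)
}

# Erdos-Renyi-ish random graph on n regions for property tests.
randomGraph <- function(n, p = 0.25) {
  ids <- sprintf("G%02d", seq_len(n))
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  em <- cbind(ids[pairs[keep, 1]], ids[pairs[keep, 2]])
  spatialGraph(ids, if (nrow(em)) em else matrix(character(), 0, 2))
}

# Simulate + fit one synthetic study; returns slope draws and RR summary.
fitSynthetic <- function(genSeed, fitSeed, graph, years = 2008:2013,
                         tauU = 25, tauV = 25, tauB = 25, alpha = 50,
                         betaX = log(1.060) / 5, nIter = 4000,
                         nBurnin = 2000, nChains = 2, thin = 2) {
  gc <- generatorConfig(nRegions = nRegions(graph), graph = graph,
                        years = years, seed = genSeed)
  tr <- sampleTruth(gc, betaX = betaX, tauU = tauU, tauV = tauV,
                    tauB = tauB, alpha = alpha)
  pan <- generatePanel(tr, gc)
  cfg <- samplerConfig(nIter = nIter, nBurnin = nBurnin, thin = thin,
                       nChains = nChains, seed = fitSeed)
  s <- runSampler(pan, modelSpec(), graph, cfg)
  list(truth = tr, samples = s,
       beta = drop(drawMatrix(s, "^beta\\.smoking_rate$")),
       rr = nationalRR(s))
}
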