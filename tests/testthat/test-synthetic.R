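test_that("sampled truths respect the ICAR constraint and precisions", {
  g <- spatialGraph(c(regionIds(latticeGraph(3, 3)), "Island"),
                    graphEdges(latticeGraph(3, 3)) |>
                      (\(e) cbind(regionIds(latticeGraph(3, 3))[e[, 1]],
                                  regionIds(latticeGraph(3, 3))[e[, 2]]))())
  gc <- generatorConfig(nRegions = 10, graph = g, seed = 3)
  tr <- sampleTruth(gc)
  comp <- icarComponents(icarStructure(g))
  cm <- tapply(tr$u, comp, mean)
  expect_lt(max(abs(cm)), 1e-10)

  # an isolated region's structured effect is pinned to its component mean 0
  expect_equal(unname(tr$u["Island"]), 0)

  # tau_u -> infinity pins u to zero
  tr2 <- sampleTruth(gc, tauU = 1e10)
  expect_lt(max(abs(tr2$u)), 1e-3)

  # empirical variance of b across many truths matches 1/tau_b
  gc50 <- generatorConfig(nRegions = 50, graph = latticeGraph(5, 10), seed = 1)
  bs <- unlist(lapply(1:200, function(s) {
    gcs <- generatorConfig(nRegions = 50, graph = latticeGraph(5, 10),
                           seed = s)
    sampleTruth(gcs, tauB = 4)$b
  }))
  expect_equal(var(bs), 0.25, tolerance = 0.04)
})

test_that("panel generation is calibrated, deterministic and concentrates", {
  gc <- generatorConfig(seed = 20)  # defaults: 253 regions, 2008-2013
  tr <- sampleTruth(gc)
  pan <- generatePanel(tr, gc)
  o <- panelOutcomes(pan)
  hyp <- o$prevalence[o$outcome == "hypertension"]
  expect_gt(mean(hyp), 17.2)
  expect_lt(mean(hyp), 19.2)
  smk <- panelCovariates(pan)$smoking_rate
  expect_equal(mean(smk), 25.2, tolerance = 0.06)
  expect_equal(sd(smk), 2.9, tolerance = 0.12)
  expect_true(all(smk > 0 & smk < 100))

  pan2 <- generatePanel(tr, gc)
  expect_identical(panelOutcomes(pan2), o)

  # huge shape: observations collapse onto their expectations
  trBig <- sampleTruth(gc, alpha = 1e6)
  p3 <- panelOutcomes(generatePanel(trBig, gc))
  p3 <- p3[p3$outcome == trBig$outcome, ]
  expect_lt(max(abs(p3$prevalence / p3$expected - 1)), 0.02)

  # noise-free surface equals the expected column
  p4 <- panelOutcomes(generatePanel(tr, gc, noise = FALSE))
  expect_equal(p4$prevalence, p4$expected)
})

test_that("infeasible moment targets are rejected", {
  tg <- bymGamma:::.DEFAULT_TARGETS
  tg$stroke <- c(5, 10)
  expect_error(generatorConfig(targets = tg), "infeasible")
  tg2 <- bymGamma:::.DEFAULT_TARGETS
  tg2$smoking_rate <- c(90, 8)
  expect_error(generatorConfig(targets = tg2), "above 100")
})

test_that("survey records reproduce the surface and handle empty cells", {
  g <- latticeGraph(3, 3)
  gc <- generatorConfig(nRegions = 9, graph = g, years = 2010L,
                        nPerCell = 900L, seed = 5)
  tr <- sampleTruth(gc)
  rec <- generateSurveyRecords(tr, gc)
  expect_identical(nrow(rec), 9L * 900L)
  expect_true(all(rec$sex %in% c("M", "F")))
  expect_true(all(rec$bmi > 0))

  suppressWarnings(pan <- buildPanel(rec))
  ref <- panelOutcomes(generatePanel(tr, gc, noise = FALSE))
  o <- panelOutcomes(pan)
  m <- merge(o, ref, by = c("region_id", "year", "outcome"),
             suffixes = c("", ".ref"))
  # smoke-level closure; the acceptance suite quantifies it per cell
  expect_lt(mean(abs(m$prevalence - m$expected.ref)), 1.5)

  cs <- data.frame(region_id = regionIds(g)[1], year = 2010L, n = 0L)
  gc0 <- generatorConfig(nRegions = 9, graph = g, years = 2010L,
                         nPerCell = 50L, seed = 5, cellSizes = cs)
  expect_warning(rec0 <- generateSurveyRecords(tr, gc0), "0 respondents")
  expect_false(regionIds(g)[1] %in% rec0$region_id)
  expect_warning(pan0 <- generatePanel(tr, gc0), "0 respondents")
  expect_false(regionIds(g)[1] %in% panelOutcomes(pan0)$region_id)
})

test_that("a vanishing baseline yields all-zero prevalence, all flagged", {
  g <- latticeGraph(2, 2)
  gc <- generatorConfig(nRegions = 4, graph = g, years = 2010L,
                        nPerCell = 200L, seed = 8)
  tr <- sampleTruth(gc, beta0 = -40)  # modeled outcome probability ~ 0
  rec <- generateSurveyRecords(tr, gc)
  expect_true(all(rec[[tr$outcome]] == 0))
  suppressWarnings(pan <- buildPanel(rec, outcomes = tr$outcome))
  expect_true(all(panelOutcomes(pan)$prevalence == 0))
  expect_true(all(panelOutcomes(pan)$nonpositive))
})

test_that("truth objects survive JSON round-trips", {
  gc <- generatorConfig(nRegions = 6, graph = latticeGraph(2, 3), seed = 2)
  tr <- sampleTruth(gc)
  f <- withr::local_tempfile(fileext = ".json")
  writeTruth(tr, f)
  tr2 <- readTruth(f)
  expect_equal(tr2$beta, tr$beta)
  expect_equal(tr2$u, tr$u)
  expect_equal(tr2$tau_b, tr$tau_b)
  expect_identical(regionIds(tr2$graph), regionIds(tr$graph))
  expect_identical(graphEdges(tr2$graph), graphEdges(tr$graph))
})
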