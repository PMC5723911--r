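test_that("conjugate precision update draws from Gamma(a + r/2, c + S/2)", {
  set.seed(1234)
  # zero effects: posterior is Gamma(1 + 10/2, 5e-5)
  d0 <- replicate(2e4, gibbsUpdatePrecision(rep(0, 10)))
  expect_equal(mean(d0), 6 / 5e-5, tolerance = 0.02)

  # iid with sum of squares 2, n = 4: Gamma(3, 1.00005)
  e <- c(1, -1, 0, 0)
  d1 <- replicate(1e5, gibbsUpdatePrecision(e))
  expect_equal(mean(d1), 3 / 1.00005, tolerance = 0.01)
  expect_equal(var(d1), 3 / 1.00005^2, tolerance = 0.03)

  # icar on the path A-B-C with u = (1, 0, -1): S = 2, rank = 2
  path <- spatialGraph(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  ic <- icarStructure(path)
  d2 <- replicate(1e5, gibbsUpdatePrecision(c(1, 0, -1), "icar", icar = ic))
  expect_equal(mean(d2), 2 / 1.00005, tolerance = 0.01)
  expect_equal(var(d2), 2 / 1.00005^2, tolerance = 0.03)

  # with no effects at all the draw is from the prior itself
  set.seed(55)
  dp <- replicate(1e4, gibbsUpdatePrecision(numeric(0)))
  ks <- suppressWarnings(stats::ks.test(dp, stats::pgamma, shape = 1,
                                        rate = 5e-5))
  expect_gt(ks$p.value, 0.001)
})

test_that("random-walk Metropolis has the documented limiting behaviour", {
  set.seed(21)
  # vanishing proposal scale: every move accepted, chain effectively static
  x <- 0.3
  acc <- logical(200)
  for (i in seq_len(200)) {
    st <- mhUpdateBlock(x, function(z) dnorm(z, log = TRUE), 1e-12)
    acc[i] <- st$accepted
    x <- st$value
  }
  expect_true(all(acc))
  expect_equal(x, 0.3, tolerance = 1e-9)

  expect_error(mhUpdateBlock(0, function(z) -Inf, 1), "not finite")
})

test_that("Metropolis chain reproduces a standard normal target", {
  set.seed(8)
  n <- 1e5
  x <- 0
  out <- numeric(n)
  for (i in seq_len(n)) {
    st <- mhUpdateBlock(x, function(z) -0.5 * z^2, 2.4)
    x <- st$value
    out[i] <- x
  }
  thinned <- out[seq(20, n, by = 20)]
  ks <- stats::ks.test(thinned, pnorm)
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(out), 0, tolerance = 0.03)
  expect_equal(sd(out), 1, tolerance = 0.03)
})

test_that("log-scale update targets a Gamma(2,1) density exactly", {
  set.seed(31)
  n <- 4e5
  a <- 0
  s <- 0
  # target for x = exp(a): Gamma(2,1) density plus the log-scale Jacobian
  lt <- function(a) 2 * a - exp(a)
  for (i in seq_len(n)) {
    st <- mhUpdateBlock(a, lt, 1.4)
    a <- st$value
    s <- s + exp(a)
  }
  expect_equal(s / n, 2, tolerance = 0.01)
})

test_that("the sampler is bit-reproducible and respects the u constraint", {
  g <- latticeGraph(2, 3)
  set.seed(3)
  y <- rgamma(12, shape = 30, rate = 30 / 4)
  pan <- tinyPanel(regionIds(g), 2010:2011, y, x = rnorm(12, 25, 2))
  cfg <- samplerConfig(nIter = 400, nBurnin = 200, thin = 2, nChains = 2,
                       seed = 9)
  s1 <- runSampler(pan, modelSpec(), g, cfg)
  s2 <- runSampler(pan, modelSpec(), g, cfg)
  expect_identical(s1@draws, s2@draws)

  um <- drawMatrix(s1, "^u\\.")
  expect_lt(max(abs(rowMeans(um))), 1e-10)
  lp <- drawMatrix(s1, "^log_post$")
  expect_true(all(is.finite(lp)))
  expect_true(all(drawMatrix(s1, "^alpha$") > 0))
  expect_true(all(drawMatrix(s1, "^tau_") > 0))
})

test_that("fixing hyperparameters holds them constant in the draws", {
  g <- latticeGraph(2, 2)
  set.seed(4)
  pan <- tinyPanel(regionIds(g), 2010:2012,
                   rgamma(12, 40, 40 / 3.3), x = rnorm(12, 25, 2))
  cfg <- samplerConfig(nIter = 300, nBurnin = 100, thin = 1, nChains = 1,
                       seed = 2, fixed = c(alpha = 50, tau_u = 10))
  s <- runSampler(pan, modelSpec(), g, cfg)
  expect_true(all(drawMatrix(s, "^alpha$") == 50))
  expect_true(all(drawMatrix(s, "^tau_u$") == 10))
  expect_gt(sd(drawMatrix(s, "^tau_v$")), 0)
})

test_that("diagnostics report split-Rhat, ESS and degeneracies", {
  set.seed(12)
  mk <- function(center) {
    m <- cbind(rnorm(500, center), rnorm(500, 0, 2))
    colnames(m) <- c("theta", "phi")
    m
  }
  good <- makePosterior(list(mk(0), mk(0)))
  d <- samplerDiagnostics(good)
  expect_true(all(abs(d$rhat - 1) < 0.05))
  expect_true(all(d$ess > 300))

  bad <- makePosterior(list(mk(0), mk(10)))
  expect_warning(db <- samplerDiagnostics(bad), "Rhat > 1.05")
  expect_gt(db$rhat[db$parameter == "theta"], 2)

  const <- makePosterior(list(cbind(theta = rep(1, 500)),
                              cbind(theta = rep(1, 500))))
  expect_warning(dc <- samplerDiagnostics(const), "degenerate")
  expect_true(dc$degenerate[1])
  expect_true(is.na(dc$ess[1]))

  single <- makePosterior(list(mk(0)))
  expect_message(ds <- samplerDiagnostics(single), "single chain")
  expect_true(all(is.na(ds$rhat)))
  expect_error(samplerDiagnostics(makePosterior(list(mk(0)[1:50, ]))),
               "at least 100")
})

test_that("samples round-trip through the columnar CSV", {
  g <- latticeGraph(1, 3)
  set.seed(5)
  pan <- tinyPanel(regionIds(g), 2010:2011, rgamma(6, 30, 30 / 3),
                   x = rnorm(6, 25, 2))
  cfg <- samplerConfig(nIter = 200, nBurnin = 100, thin = 1, nChains = 2,
                       seed = 6)
  s <- runSampler(pan, modelSpec(), g, cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  writeSamples(s, f)
  tab <- readSamplesTable(f)
  expect_identical(sort(unique(tab$chain)), c(1L, 2L))
  s2 <- samplesFromTable(tab, modelSpec())
  expect_equal(drawMatrix(s2, "^beta\\.smoking_rate$"),
               drawMatrix(s, "^beta\\.smoking_rate$"), tolerance = 1e-12)
  expect_identical(regionIds(s2), regionIds(g))
})
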