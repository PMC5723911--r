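test_that("gamma log likelihood matches closed forms and dgamma", {
  expect_equal(gammaLogLik(1, 1, 1), -1)  # Exponential(1) at 1
  # independent density oracle on a grid
  grid <- expand.grid(y = c(0.1, 1, 3, 20), mu = c(0.5, 2, 10),
                      alpha = c(0.7, 1, 5, 50))
  ours <- with(grid, gammaLogLik(y, mu, alpha))
  ref <- with(grid, dgamma(y, shape = alpha, rate = alpha / mu, log = TRUE))
  expect_equal(ours, ref, tolerance = 1e-10)
  expect_error(gammaLogLik(-1, 1, 1), "positive")
  expect_error(gammaLogLik(1, 0, 1), "positive")
  expect_error(gammaLogLik(1, 1, -2), "positive")
})

test_that("gamma density integrates to one and has mean mu", {
  dens <- function(y) exp(gammaLogLik(y, mu = 2, alpha = 3))
  expect_equal(integrate(dens, 0, Inf, rel.tol = 1e-10)$value, 1,
               tolerance = 1e-6)
  set.seed(99)
  draws <- rgamma(1e6, shape = 2, rate = 2 / 5)  # shape/mean parameterization
  expect_equal(mean(draws), 5, tolerance = 0.01)
})

test_that("linear predictor assembles all terms in natural units", {
  spec <- modelSpec()
  row <- list(region_id = "A", year = 2010, smoking_rate = 25,
              mean_bmi = 23, drinking_rate = 55)
  zero <- c("(Intercept)" = 0, smoking_rate = 0, mean_bmi = 0,
            drinking_rate = 0, year = 0)
  eff0 <- list(u = c(A = 0), v = c(A = 0), b = c(A = 0))
  expect_equal(linearPredictor(row, zero, eff0, spec), 0)

  cf <- zero; cf[["smoking_rate"]] <- 0.01165
  expect_equal(linearPredictor(row, cf, eff0, spec), 0.29125)

  # adding c to u and subtracting it from the intercept leaves eta unchanged
  cf2 <- cf; cf2[["(Intercept)"]] <- -0.7
  effc <- list(u = c(A = 0.7), v = c(A = 0), b = c(A = 0))
  expect_equal(linearPredictor(row, cf2, effc, spec),
               linearPredictor(row, cf, eff0, spec))

  row_bad <- row; row_bad$mean_bmi <- NULL
  expect_error(linearPredictor(row_bad, cf, eff0, spec), "mean_bmi")
  expect_error(linearPredictor(row, cf,
                               list(u = c(B = 1), v = NULL, b = NULL), spec),
               "absent")
})

test_that("log prior decomposes additively with the documented blocks", {
  spec <- modelSpec()
  path <- spatialGraph(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  ic <- icarStructure(path)
  st <- list(beta = c(0.1, -0.2), u = c(0.3, -0.1, -0.2),
             v = c(0.05, 0, -0.05), b = c(0.01, -0.02, 0.01),
             tau_u = 1, tau_v = 2, tau_b = 3, alpha = 10)
  st$u <- st$u - mean(st$u)
  lp <- logPrior(st, spec, ic)
  blocks <- attr(lp, "blocks")
  expect_equal(sum(blocks), as.numeric(lp))
  # Gamma(1, 5e-5) at tau = 1 is an Exponential(5e-5): log(5e-5) - 5e-5
  expect_equal(unname(blocks["tau_u"]), log(5e-5) - 5e-5)
  # iid block against a brute-force normal density sum
  expect_equal(unname(blocks["v"]),
               sum(dnorm(st$v, 0, 1 / sqrt(st$tau_v), log = TRUE)))
  expect_equal(unname(blocks["b"]),
               sum(dnorm(st$b, 0, 1 / sqrt(st$tau_b), log = TRUE)))
  # ICAR block: rank/2 * log tau - tau/2 * u'Qu
  expect_equal(unname(blocks["u"]),
               0.5 * 2 * log(st$tau_u) -
                 0.5 * st$tau_u * icarQuadraticForm(ic, st$u))
  # doubling v changes exactly the v block
  st2 <- st; st2$v <- 2 * st$v
  lp2 <- logPrior(st2, spec, ic)
  expect_equal(as.numeric(lp2 - lp),
               unname(attr(lp2, "blocks")["v"] - blocks["v"]))

  st_bad <- st; st_bad$u <- st$u + 1e-3
  expect_error(logPrior(st_bad, spec, ic), "sum-to-zero")
  st_neg <- st; st_neg$tau_v <- -1
  expect_error(logPrior(st_neg, spec, ic), "positive")
})

test_that("model spec validates and serializes", {
  expect_error(modelSpec(exposure = "mean_bmi",
                         confounders = c("mean_bmi", "drinking_rate")),
               "exactly once")
  expect_error(modelSpec(positivityPolicy = "drop"), "exclude")
  f <- withr::local_tempfile(fileext = ".yaml")
  spec <- modelSpec(outcome = "angina", exposure = "passive_home_rate",
                    yearTerm = FALSE)
  writeModelSpec(spec, f)
  spec2 <- readModelSpec(f)
  expect_identical(spec2@outcome, "angina")
  expect_identical(spec2@exposure, "passive_home_rate")
  expect_false(spec2@yearTerm)
  expect_equal(spec2@precPrior, c(1, 5e-5))
})

test_that("modelData applies the positivity policy and builds the design", {
  y <- c(2, 0, 3, 4, 5, 6)
  pan <- tinyPanel(c("R1", "R2", "R3"), 2010:2011, y, x = 20 + seq_len(6))
  g <- latticeGraph(1, 3)
  pan@outcomes$region_id <- rep(regionIds(g), each = 2)
  pan@covariates$region_id <- rep(regionIds(g), each = 2)
  spec <- modelSpec()
  expect_warning(md <- modelData(pan, g, spec), "excluded")
  expect_identical(length(md$y), 5L)
  expect_identical(colnames(md$X),
                   c("(Intercept)", "smoking_rate", "mean_bmi",
                     "drinking_rate", "year"))
  expect_equal(md$yearCenter, 2010.5)

  spec2 <- modelSpec(positivityPolicy = "halfmin")
  expect_warning(md2 <- modelData(pan, g, spec2), "imputed")
  expect_identical(length(md2$y), 6L)
  expect_equal(min(md2$y), 1)  # half the minimum positive value (2)

  gsmall <- latticeGraph(1, 2)
  expect_error(suppressWarnings(modelData(pan, gsmall, spec)), "not in graph")
})
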