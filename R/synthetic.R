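# Synthetic survey generator: emulates the structure of restricted community
# health survey microdata (253 districts, annual waves, ~900 adults per
# district-year) with known ground-truth parameters, so standardization and
# model fitting are testable end to end.

# Marginal targets mimicking published descriptive statistics for Korean
# district-level prevalence and exposures: mean, SD (percent or kg/m2).
.DEFAULT_TARGETS <- list(
  hypertension = c(18.2, 2.4), stroke = c(3.3, 1.1),
  myocardial_infarction = c(1.4, 0.6), angina = c(1.9, 0.7),
  smoking_rate = c(25.2, 2.9), passive_home_rate = c(11.8, 4.1),
  passive_work_rate = c(29.2, 9.3), drinking_rate = c(56.5, 5.4),
  mean_bmi = c(23.0, 0.7))

# Adult sex-by-age demography used when drawing respondents: an aging adult
# population with roughly half the adults aged 50 or older, as in rural
# Korean districts.
.DEFAULT_BAND_PROBS <- c(0.09, 0.08, 0.08, 0.08, 0.09, 0.09, 0.09,
                         0.09, 0.08, 0.08, 0.07, 0.05, 0.03)

#' Generator configuration
#'
#' Bundles the study-design constants the generator emulates: the region
#' graph (default: a rook lattice with 253 regions), six annual waves
#' 2008-2013, 900 respondents per region-year, marginal moment targets for
#' prevalences, exposures, BMI and drinking, and the respondent demography.
#'
#' @param nRegions number of regions when no graph is given (default 253).
#' @param graph optional [SpatialGraph-class]; default a rook lattice whose
#'   dimensions are the most square divisor pair of `nRegions`.
#' @param years annual waves (default `2008:2013`).
#' @param nPerCell respondents per region-year (default 900).
#' @param seed master seed; the truth, covariate surface, panel noise and
#'   respondent draws use fixed offsets from it.
#' @param outcome modeled outcome fed through the hierarchical forward model
#'   (default `"stroke"`).
#' @param exposure exposure column carrying the truth slope
#'   (default `"smoking_rate"`).
#' @param targets named list of `c(mean, sd)` marginal targets (percent;
#'   `mean_bmi` in kg/m2).
#' @param bandProbs demography: probability of each [defaultAgeBands()] band.
#' @param temporalFrac fraction of each covariate's SD that is within-region
#'   year-to-year variation (default 0.3).
#' @param cellSizes optional data.frame (`region_id`, `year`, `n`)
#'   overriding `nPerCell` for specific cells; `n = 0` drops the cell.
#' @return a list of class `"bymGeneratorConfig"`.
#' @export
generatorConfig <- function(nRegions = 253L, graph = NULL,
                            years = 2008:2013, nPerCell = 900L, seed = 1L,
                            outcome = "stroke", exposure = "smoking_rate",
                            targets = .DEFAULT_TARGETS,
                            bandProbs = .DEFAULT_BAND_PROBS,
                            temporalFrac = 0.3, cellSizes = NULL) {
  if (is.null(graph)) {
    rows <- max(Filter(function(d) nRegions %% d == 0L,
                       seq_len(floor(sqrt(nRegions)))))
    graph <- latticeGraph(rows, nRegions %/% rows)
  }
  stopifnot(is(graph, "SpatialGraph"), nPerCell >= 0, length(years) >= 1)
  for (nm in names(targets)) {
    tg <- targets[[nm]]
    if (tg[1] <= 0) stop("target mean for ", nm, " must be positive")
    if (tg[1] - 2 * tg[2] <= 0)
      stop("infeasible moments for ", nm, ": SD ", tg[2],
           " forces negative rates at mean ", tg[1])
    if (nm != "mean_bmi" && tg[1] + 2 * tg[2] >= 100)
      stop("infeasible moments for ", nm, ": rates above 100%")
  }
  bandProbs <- bandProbs / sum(bandProbs)
  structure(list(graph = graph, years = as.integer(years),
                 nPerCell = as.integer(nPerCell), seed = as.integer(seed),
                 outcome = outcome, exposure = exposure, targets = targets,
                 bands = defaultAgeBands(), bandProbs = bandProbs,
                 temporalFrac = temporalFrac, cellSizes = cellSizes),
            class = "bymGeneratorConfig")
}

#' Draw ground-truth parameters for the forward model
#'
#' Draws the structured intercept u from the ICAR distribution at `tauU` via
#' the spectral decomposition of the precision matrix (coordinates on the
#' positive eigenspace only, so each connected component is centered exactly),
#' iid normal v and b, and assembles the fixed effects. When `beta0` is
#' `NULL` it is calibrated analytically so the modeled outcome's expected
#' prevalence at covariate means matches the configured target mean
#' (log-normal corrections for the random-effect variances included).
#'
#' @param config a [generatorConfig()].
#' @param betaX exposure slope per percentage point
#'   (default `log(1.060)/5`, a relative risk of 1.060 per 5 points).
#' @param betaBmi,betaDrink,betaYear confounder and linear-year effects.
#' @param tauU,tauV,tauB random-effect precisions (defaults 50, 50, 2000).
#' @param alpha gamma likelihood shape (default 50).
#' @param beta0 intercept; `NULL` calibrates it to the outcome target mean.
#' @return list of class `"bymTruth"` with `beta`, `u`, `v`, `b`, the
#'   precisions, `alpha`, the graph, years, outcome and exposure names.
#' @export
sampleTruth <- function(config, betaX = log(1.060) / 5, betaBmi = 0.02,
                        betaDrink = 0.002, betaYear = -0.005,
                        tauU = 50, tauV = 50, tauB = 2000, alpha = 50,
                        beta0 = NULL) {
  stopifnot(inherits(config, "bymGeneratorConfig"))
  graph <- config$graph
  ids <- regionIds(graph)
  n <- length(ids)
  icar <- icarStructure(graph)
  set.seed(config$seed)
  eg <- eigen(icarPrecision(icar), symmetric = TRUE)
  pos <- eg$values > max(eg$values, 1) * 1e-10
  z <- rnorm(sum(pos))
  u <- drop(eg$vectors[, pos, drop = FALSE] %*%
              (z / sqrt(tauU * eg$values[pos])))
  v <- rnorm(n, 0, 1 / sqrt(tauV))
  b <- rnorm(n, 0, 1 / sqrt(tauB))
  names(u) <- names(v) <- names(b) <- ids
  tg <- config$targets
  mx <- tg[[config$exposure]][1]
  if (is.null(beta0)) {
    var_u <- mean(rowSums(sweep(eg$vectors[, pos, drop = FALSE]^2, 2L,
                                tauU * eg$values[pos], "/")))
    beta0 <- log(tg[[config$outcome]][1]) - betaX * mx -
      betaBmi * tg$mean_bmi[1] - betaDrink * tg$drinking_rate[1] -
      0.5 * (var_u + 1 / tauV + mx^2 / tauB)
  }
  beta <- c(beta0, betaX, betaBmi, betaDrink, betaYear)
  names(beta) <- c("(Intercept)", config$exposure, "mean_bmi",
                   "drinking_rate", "year")
  structure(list(beta = beta, tau_u = tauU, tau_v = tauV, tau_b = tauB,
                 alpha = alpha, u = u, v = v, b = b, graph = graph,
                 years = config$years, outcome = config$outcome,
                 exposure = config$exposure),
            class = "bymTruth")
}

#' Latent region-year surface: covariates and expected prevalences
#'
#' Deterministic given `config$seed`: regional covariate levels (logit-normal
#' rates matched to the configured moments, normal BMI) plus within-region
#' temporal variation, and the model-expected prevalence of every outcome
#' (the modeled outcome through the truth's linear predictor, the others as
#' moment-matched regional means).
#' @noRd
.regionYearSurface <- function(truth, config) {
  graph <- config$graph
  ids <- regionIds(graph)
  n <- length(ids)
  years <- config$years
  ny <- length(years)
  set.seed(config$seed + 1L)
  tf <- config$temporalFrac
  rate_cols <- c("smoking_rate", "passive_home_rate", "passive_work_rate",
                 "drinking_rate")
  sur <- data.frame(region_id = rep(ids, each = ny),
                    year = rep(years, n), stringsAsFactors = FALSE)
  for (cn in rate_cols) {
    tg <- config$targets[[cn]]
    p <- tg[1] / 100
    sd_logit <- (tg[2] / 100) / (p * (1 - p))
    l_reg <- rnorm(n, log(p / (1 - p)), sd_logit * sqrt(1 - tf^2))
    l <- rep(l_reg, each = ny) + rnorm(n * ny, 0, sd_logit * tf)
    sur[[cn]] <- 100 * plogis(l)
  }
  tgb <- config$targets$mean_bmi
  b_reg <- rnorm(n, tgb[1], tgb[2] * sqrt(1 - tf^2))
  sur$mean_bmi <- rep(b_reg, each = ny) + rnorm(n * ny, 0, tgb[2] * tf)

  yc <- mean(range(years))
  bt <- truth$beta
  eta <- bt[["(Intercept)"]] +
    bt[[truth$exposure]] * sur[[truth$exposure]] +
    bt[["mean_bmi"]] * sur$mean_bmi +
    bt[["drinking_rate"]] * sur$drinking_rate +
    bt[["year"]] * (sur$year - yc) +
    truth$u[sur$region_id] + truth$v[sur$region_id] +
    truth$b[sur$region_id] * sur[[truth$exposure]]
  outs <- intersect(.OUTCOMES, names(config$targets))
  for (oc in outs) {
    if (oc == truth$outcome) {
      sur[[paste0("mu_", oc)]] <- exp(unname(eta))
    } else {
      tg <- config$targets[[oc]]
      m <- pmax(rnorm(n, tg[1], tg[2] * 0.8), 0.05 * tg[1])
      sur[[paste0("mu_", oc)]] <- rep(m, each = ny)
    }
  }
  sur
}

#' Cell sizes for every region-year
#' @noRd
.cellSizes <- function(config, sur) {
  nvec <- rep(config$nPerCell, nrow(sur))
  if (!is.null(config$cellSizes)) {
    cs <- config$cellSizes
    key <- paste(sur$region_id, sur$year)
    idx <- match(paste(cs$region_id, cs$year), key)
    nvec[idx[!is.na(idx)]] <- cs$n[!is.na(idx)]
  }
  nvec
}

#' Generate a region-year panel from the forward model
#'
#' The modeled outcome's prevalence is drawn from
#' `Gamma(shape = alpha, mean = exp(eta))` with eta the truth's linear
#' predictor; the remaining outcomes are gamma draws around moment-matched
#' regional means. Covariates come from the latent surface. The `expected`
#' column records the noise-free surface, so sampling-error checks have the
#' exact target available. With `noise = FALSE` prevalences equal their
#' expectations. Regenerating with the same config is bit-identical.
#'
#' @param truth a `"bymTruth"` from [sampleTruth()].
#' @param config the same [generatorConfig()].
#' @param noise draw gamma observation noise (default `TRUE`).
#' @return a [RegionYearPanel-class].
#' @export
generatePanel <- function(truth, config, noise = TRUE) {
  stopifnot(inherits(truth, "bymTruth"),
            inherits(config, "bymGeneratorConfig"))
  sur <- .regionYearSurface(truth, config)
  set.seed(config$seed + 2L)
  nvec <- .cellSizes(config, sur)
  keep <- nvec > 0L
  if (any(!keep))
    warning(sum(!keep), " region-year cell(s) with 0 respondents dropped")
  outs <- intersect(.OUTCOMES, names(config$targets))
  orows <- vector("list", length(outs))
  for (k in seq_along(outs)) {
    oc <- outs[k]
    mu <- sur[[paste0("mu_", oc)]]
    if (oc == truth$outcome) shape <- truth$alpha
    else {
      tg <- config$targets[[oc]]
      shape <- (tg[1] / (0.6 * tg[2]))^2
    }
    y <- if (noise) rgamma(nrow(sur), shape = shape, rate = shape / mu) else mu
    orows[[k]] <- data.frame(region_id = sur$region_id, year = sur$year,
                             outcome = oc, prevalence = y, expected = mu,
                             n = nvec, nonpositive = y <= 0,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, orows)[keep, , drop = FALSE][order(
    rep(sur$region_id, length(outs))[keep],
    rep(sur$year, length(outs))[keep]), , drop = FALSE]
  out <- out[order(out$region_id, out$year, out$outcome), , drop = FALSE]
  cov <- data.frame(region_id = sur$region_id, year = sur$year,
                    smoking_rate = sur$smoking_rate,
                    passive_home_rate = sur$passive_home_rate,
                    passive_work_rate = sur$passive_work_rate,
                    mean_bmi = sur$mean_bmi,
                    drinking_rate = sur$drinking_rate,
                    n = nvec, stringsAsFactors = FALSE)[keep, , drop = FALSE]
  new("RegionYearPanel", outcomes = out, covariates = cov)
}

#' Generate individual-level survey records
#'
#' Respondents are drawn from the configured sex-by-age demography; exposure
#' and drinking flags are Bernoulli at the cell's rates; BMI is normal
#' around the cell mean. Disease indicators are Bernoulli within stratum
#' with probabilities scaled by a mild age profile and normalized over each
#' outcome's age-eligible strata, so the directly standardized prevalence
#' has expectation equal to the surface value `exp(eta)` used by
#' [generatePanel()].
#'
#' @param truth a `"bymTruth"` from [sampleTruth()].
#' @param config the same [generatorConfig()].
#' @return a survey-record data.frame in the [readSurveyRecords()] schema.
#' @export
generateSurveyRecords <- function(truth, config) {
  stopifnot(inherits(truth, "bymTruth"),
            inherits(config, "bymGeneratorConfig"))
  sur <- .regionYearSurface(truth, config)
  set.seed(config$seed + 3L)
  nvec <- .cellSizes(config, sur)
  if (any(nvec == 0L))
    warning(sum(nvec == 0L), " region-year cell(s) with 0 respondents dropped")
  bands <- config$bands
  nb <- length(bands)
  lower <- .parseBands(bands)$lower
  prof <- 0.6 + 0.08 * seq_len(nb)
  outs <- intersect(.OUTCOMES, names(config$targets))
  # per-outcome profile normalizer over age-eligible strata
  norms <- vapply(outs, function(oc) {
    elig <- lower >= .AGE_CUTOFFS[[oc]]
    sum(config$bandProbs[elig] * prof[elig]) / sum(config$bandProbs[elig])
  }, numeric(1L))
  cells <- which(nvec > 0L)
  pieces <- vector("list", length(cells))
  for (t in seq_along(cells)) {
    ci <- cells[t]
    n <- nvec[ci]
    band_idx <- sample.int(nb, n, replace = TRUE, prob = config$bandProbs)
    rec <- data.frame(
      region_id = sur$region_id[ci], year = sur$year[ci],
      sex = ifelse(runif(n) < 0.5, "M", "F"),
      age_group = bands[band_idx], stringsAsFactors = FALSE)
    for (oc in outs) {
      p <- pmin(pmax(sur[[paste0("mu_", oc)]][ci] / 100 *
                       prof[band_idx] / norms[[oc]], 0), 0.95)
      rec[[oc]] <- rbinom(n, 1L, p)
    }
    rec$current_smoker <- rbinom(n, 1L, sur$smoking_rate[ci] / 100)
    rec$passive_home <- rbinom(n, 1L, sur$passive_home_rate[ci] / 100)
    rec$passive_work <- rbinom(n, 1L, sur$passive_work_rate[ci] / 100)
    rec$bmi <- pmax(rnorm(n, sur$mean_bmi[ci], 3.5), 12)
    rec$drinks_monthly <- rbinom(n, 1L, sur$drinking_rate[ci] / 100)
    pieces[[t]] <- rec
  }
  do.call(rbind, pieces)
}

#' Serialize / restore a truth object as JSON
#'
#' @param truth a `"bymTruth"`.
#' @param path JSON path.
#' @return `path` invisibly (write); a `"bymTruth"` (read).
#' @export
writeTruth <- function(truth, path) {
  stopifnot(inherits(truth, "bymTruth"))
  g <- truth$graph
  em <- graphEdges(g)
  jsonlite::write_json(list(
    beta = as.list(truth$beta), tau_u = truth$tau_u, tau_v = truth$tau_v,
    tau_b = truth$tau_b, alpha = truth$alpha,
    u = as.list(truth$u), v = as.list(truth$v), b = as.list(truth$b),
    region_ids = regionIds(g),
    edges = if (nrow(em)) cbind(regionIds(g)[em[, 1L]],
                                regionIds(g)[em[, 2L]]) else character(),
    years = truth$years, outcome = truth$outcome,
    exposure = truth$exposure), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  graph <- spatialGraph(j$region_ids,
                        if (length(j$edges)) j$edges
                        else matrix(character(), 0L, 2L))
  structure(list(beta = unlist(j$beta), tau_u = j$tau_u, tau_v = j$tau_v,
                 tau_b = j$tau_b, alpha = j$alpha, u = unlist(j$u),
                 v = unlist(j$v), b = unlist(j$b), graph = graph,
                 years = j$years, outcome = j$outcome,
                 exposure = j$exposure),
            class = "bymTruth")
}
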