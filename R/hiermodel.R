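# Model definition: gamma likelihood with log link, BYM intercept,
# region-specific random slopes, and all priors.

#' Create a hierarchical model specification
#'
#' One fitted model relates one outcome's standardized prevalence to one
#' smoking exposure, adjusting for mean BMI, monthly drinking rate and a
#' linear calendar-year term, with a BYM (ICAR + iid) random intercept and an
#' iid random slope on the exposure.
#'
#' @param outcome outcome name present in the panel (default `"stroke"`).
#' @param exposure exposure covariate column: one of `"smoking_rate"`,
#'   `"passive_home_rate"`, `"passive_work_rate"` (default `"smoking_rate"`).
#' @param confounders covariate columns entering linearly
#'   (default `c("mean_bmi", "drinking_rate")`).
#' @param yearTerm include a linear term in centered year (default `TRUE`).
#' @param includeStructured,includeUnstructured,includeSlope include the ICAR
#'   intercept u, the iid intercept v, the iid random slope b (all `TRUE` by
#'   default).
#' @param priorFixedPrec prior precision of each fixed effect (default 0.001,
#'   i.e. independent N(0, 1000) coefficients).
#' @param precPrior `c(shape, rate)` of the Gamma prior on every
#'   random-effect precision (default `c(1, 5e-5)`).
#' @param shapePrior `c(shape, rate)` of the Gamma prior on the likelihood
#'   shape (default `c(1, 0.01)`, weakly informative).
#' @param positivityPolicy `"exclude"` or `"halfmin"` handling of nonpositive
#'   prevalence cells.
#' @param constraintTol tolerance on per-component means of u.
#' @return a [ModelSpec-class].
#' @export
modelSpec <- function(outcome = "stroke", exposure = "smoking_rate",
                      confounders = c("mean_bmi", "drinking_rate"),
                      yearTerm = TRUE, includeStructured = TRUE,
                      includeUnstructured = TRUE, includeSlope = TRUE,
                      priorFixedPrec = 0.001, precPrior = c(1, 5e-5),
                      shapePrior = c(1, 0.01), positivityPolicy = "exclude",
                      constraintTol = 1e-8) {
  new("ModelSpec", outcome = outcome, exposure = exposure,
      confounders = confounders, yearTerm = yearTerm,
      includeStructured = includeStructured,
      includeUnstructured = includeUnstructured, includeSlope = includeSlope,
      priorFixedPrec = priorFixedPrec, precPrior = as.numeric(precPrior),
      shapePrior = as.numeric(shapePrior),
      positivityPolicy = positivityPolicy, constraintTol = constraintTol)
}

#' Read / write a ModelSpec as YAML
#' @param path YAML file path.
#' @param spec a [ModelSpec-class].
#' @return a [ModelSpec-class] (read) or `path` invisibly (write).
#' @export
readModelSpec <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(modelSpec, y)
}

#' @rdname readModelSpec
#' @export
writeModelSpec <- function(spec, path) {
  stopifnot(is(spec, "ModelSpec"))
  yaml::write_yaml(list(
    outcome = spec@outcome, exposure = spec@exposure,
    confounders = spec@confounders, yearTerm = spec@yearTerm,
    includeStructured = spec@includeStructured,
    includeUnstructured = spec@includeUnstructured,
    includeSlope = spec@includeSlope, priorFixedPrec = spec@priorFixedPrec,
    precPrior = spec@precPrior, shapePrior = spec@shapePrior,
    positivityPolicy = spec@positivityPolicy,
    constraintTol = spec@constraintTol), path)
  invisible(path)
}

#' Gamma log likelihood in mean/shape parameterization
#'
#' Log density at `y` of a gamma distribution with shape `alpha` and mean
#' `mu` (so rate `alpha / mu`):
#' `alpha*log(alpha/mu) + (alpha-1)*log(y) - alpha*y/mu - lgamma(alpha)`.
#' Vectorized over `y` and `mu`.
#'
#' @param y positive observation(s) (standardized prevalence, percent).
#' @param mu positive mean(s).
#' @param alpha positive shape (common dispersion: `Var(y) = mu^2 / alpha`).
#' @return log density, same length as `y`.
#' @export
gammaLogLik <- function(y, mu, alpha) {
  if (any(y <= 0)) stop("y must be positive")
  if (any(mu <= 0)) stop("mu must be positive")
  if (any(alpha <= 0)) stop("alpha must be positive")
  alpha * log(alpha / mu) + (alpha - 1) * log(y) - alpha * y / mu - lgamma(alpha)
}

#' Linear predictor of the hierarchical model
#'
#' `eta = beta0 + beta_x*x + sum_c beta_c*conf_c + beta_year*(year - yearCenter)
#'  + u_r + v_r + b_r * x`, with `mu = exp(eta)`. Covariates enter in their
#' natural units (percent, kg/m2), uncentered, so the relative risk per
#' 5-point exposure increase is `exp(5 * beta_x)` directly.
#'
#' @param row one observation: list or single-row data.frame with
#'   `region_id`, `year`, and the spec's exposure and confounder columns.
#' @param coef named numeric fixed effects: `"(Intercept)"`, the exposure
#'   name, the confounder names and (if `yearTerm`) `"year"`.
#' @param effects list with named-by-region numeric vectors `u`, `v`, `b`
#'   (omit or zero-length to drop a block).
#' @param spec a [ModelSpec-class].
#' @param yearCenter centering constant for the year term (default: the
#'   row's own year, i.e. a zero year effect).
#' @return scalar eta; `exp(eta)` is the gamma mean.
#' @export
linearPredictor <- function(row, coef, effects, spec,
                            yearCenter = as.numeric(row[["year"]])) {
  need <- c(spec@exposure, spec@confounders)
  for (v in need)
    if (is.null(row[[v]]) || is.na(row[[v]])) stop("missing covariate: ", v)
  x <- as.numeric(row[[spec@exposure]])
  eta <- coef[["(Intercept)"]] + coef[[spec@exposure]] * x
  for (v in spec@confounders) eta <- eta + coef[[v]] * as.numeric(row[[v]])
  if (spec@yearTerm)
    eta <- eta + coef[["year"]] * (as.numeric(row[["year"]]) - yearCenter)
  r <- as.character(row[["region_id"]])
  pick <- function(e) if (length(e)) {
    if (is.na(match(r, names(e)))) stop("region '", r, "' absent from effects")
    e[[r]]
  } else 0
  eta + pick(effects$u) + pick(effects$v) + pick(effects$b) * x
}

#' Joint log prior of all model parameters
#'
#' Additive blocks: independent zero-mean normals for the fixed effects;
#' the ICAR pseudo-density for u at precision `tau_u` (kernel
#' `-tau_u/2 * t(u) Q u` plus `rank(Q)/2 * log(tau_u)`), with the
#' per-component sum-to-zero constraint enforced; iid zero-mean normals for
#' v at `tau_v` and b at `tau_b`; Gamma(shape, rate) log densities for the
#' three precisions and for the likelihood shape alpha.
#'
#' @param state list with `beta` (named numeric), `u`, `v`, `b` (numeric,
#'   region order; may be zero-length when the block is excluded), `tau_u`,
#'   `tau_v`, `tau_b`, `alpha`.
#' @param spec a [ModelSpec-class].
#' @param icar an [ICARStructure-class] (needed when `u` is present).
#' @return scalar log prior with attribute `"blocks"`: the named additive
#'   decomposition.
#' @export
logPrior <- function(state, spec, icar = NULL) {
  stopifnot(is(spec, "ModelSpec"))
  if (any(c(state$tau_u, state$tau_v, state$tau_b, state$alpha) <= 0))
    stop("precisions and alpha must be strictly positive")
  blocks <- c(beta = sum(-0.5 * spec@priorFixedPrec * state$beta^2 +
                         0.5 * log(spec@priorFixedPrec / (2 * pi))))
  if (length(state$u)) {
    if (is.null(icar)) stop("ICAR structure required when u is present")
    comp <- icarComponents(icar)
    cm <- tapply(state$u, comp, mean)
    if (any(abs(cm) > spec@constraintTol))
      stop("sum-to-zero constraint violated: component mean ",
           format(max(abs(cm))), " exceeds tolerance ",
           format(spec@constraintTol))
    S <- icarQuadraticForm(icar, state$u)
    blocks["u"] <- 0.5 * icarRank(icar) * log(state$tau_u) - 0.5 * state$tau_u * S
  }
  iid_block <- function(e, tau) {
    length(e) * 0.5 * (log(tau) - log(2 * pi)) - 0.5 * tau * sum(e^2)
  }
  if (length(state$v)) blocks["v"] <- iid_block(state$v, state$tau_v)
  if (length(state$b)) blocks["b"] <- iid_block(state$b, state$tau_b)
  pp <- spec@precPrior
  blocks["tau_u"] <- dgamma(state$tau_u, shape = pp[1], rate = pp[2], log = TRUE)
  blocks["tau_v"] <- dgamma(state$tau_v, shape = pp[1], rate = pp[2], log = TRUE)
  blocks["tau_b"] <- dgamma(state$tau_b, shape = pp[1], rate = pp[2], log = TRUE)
  sp <- spec@shapePrior
  blocks["alpha"] <- dgamma(state$alpha, shape = sp[1], rate = sp[2], log = TRUE)
  structure(sum(blocks), blocks = blocks)
}

#' Assemble model data from a panel, graph and spec
#'
#' Internal workhorse shared by the sampler and the degenerate-limit checks:
#' merges the outcome rows with the region-year covariates, applies the
#' positivity policy, builds the fixed-effect design matrix (intercept,
#' exposure, confounders, centered year) and the region index.
#'
#' @param panel a [RegionYearPanel-class].
#' @param graph a [SpatialGraph-class] covering all panel regions.
#' @param spec a [ModelSpec-class].
#' @return list: `y`, `X` (design, original units), `xexp` (exposure values,
#'   for the random-slope term), `region` (1-based index into
#'   `regionIds(graph)`), `regionIds`, `yearCenter`, `dropped` (rows excluded
#'   by the positivity policy).
#' @keywords internal
#' @export
modelData <- function(panel, graph, spec) {
  stopifnot(is(panel, "RegionYearPanel"), is(graph, "SpatialGraph"),
            is(spec, "ModelSpec"))
  o <- panel@outcomes
  o <- o[o$outcome == spec@outcome, , drop = FALSE]
  if (!nrow(o)) stop("outcome '", spec@outcome, "' not in panel")
  dat <- merge(o, panel@covariates, by = c("region_id", "year"),
               suffixes = c("", ".cov"))
  missing_regions <- setdiff(unique(dat$region_id), regionIds(graph))
  if (length(missing_regions))
    stop("panel region(s) not in graph: ", missing_regions[1L])
  bad <- is.na(dat$prevalence) | dat$prevalence <= 0
  dropped <- dat[bad, , drop = FALSE]
  if (any(bad)) {
    if (spec@positivityPolicy == "exclude") {
      warning(sum(bad), " nonpositive prevalence cell(s) excluded from the ",
              "gamma fit (positivityPolicy = 'exclude')")
      dat <- dat[!bad, , drop = FALSE]
    } else {
      halfmin <- min(dat$prevalence[!bad]) / 2
      warning(sum(bad), " nonpositive prevalence cell(s) imputed at half the ",
              "minimum positive value (", format(halfmin), ")")
      dat$prevalence[bad] <- halfmin
    }
  }
  if (!nrow(dat)) stop("no usable prevalence cells for '", spec@outcome, "'")
  covs <- c(spec@exposure, spec@confounders)
  for (v in covs) {
    if (!v %in% names(dat)) stop("missing covariate column: ", v)
    if (any(is.na(dat[[v]]))) stop("missing values in covariate: ", v)
  }
  dat <- dat[order(dat$region_id, dat$year), , drop = FALSE]
  yearCenter <- mean(range(dat$year))
  X <- cbind(`(Intercept)` = 1,
             as.matrix(dat[, covs, drop = FALSE]))
  if (spec@yearTerm) X <- cbind(X, year = dat$year - yearCenter)
  list(y = dat$prevalence, X = X, xexp = dat[[spec@exposure]],
       region = match(dat$region_id, regionIds(graph)),
       regionIds = regionIds(graph), yearCenter = yearCenter,
       dropped = dropped, data = dat)
}

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec: gamma(log link) ", object@outcome, " ~ ", object@exposure,
      if (length(object@confounders))
        paste(" +", paste(object@confounders, collapse = " + ")) else "",
      if (object@yearTerm) " + year" else "", "\n", sep = "")
  re <- c(if (object@includeStructured) "u(ICAR)",
          if (object@includeUnstructured) "v(iid)",
          if (object@includeSlope) "b(iid slope)")
  cat("  random effects:", if (length(re)) paste(re, collapse = " + ")
      else "none", "\n")
  cat("  precision prior Gamma(", object@precPrior[1], ", ",
      object@precPrior[2], "); shape prior Gamma(", object@shapePrior[1],
      ", ", object@shapePrior[2], ")\n", sep = "")
})
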